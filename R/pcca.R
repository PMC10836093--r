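#' PCCA+ coarse-graining of a reversible Markov model
#'
#' Robust Perron cluster analysis: the top `n_macro` right eigenvectors of
#' the transition matrix span a simplex whose vertices correspond to
#' metastable macrostates. Vertices are located by the orthogonalization
#' index search; the linear map onto the vertex basis gives fuzzy
#' memberships, which are clipped to `[0, 1]` and row-renormalized. Crisp
#' labels are the argmax memberships and macrostate populations are sums of
#' the stationary distribution over crisp sets.
#'
#' @param model a reversible `MarkovModel` (complex eigenvalues from a
#'   non-reversible estimate are refused).
#' @param n_macro number of macrostates (`2 <= n_macro <= n_states`).
#' @return an object of class `CoarseGraining`: list with `n_macro`,
#'   `memberships` (microstates x macrostates, rows sum to 1), `crisp`
#'   (argmax labels) and `macro_populations`.
#' @export
pcca <- function(model, n_macro) {
  m <- as.integer(n_macro)
  if (m < 2L || m > model$n_states)
    stop("n_macro must satisfy 2 <= n_macro <= n_states")
  if (!isTRUE(model$reversible) ||
      any(abs(Im(model$eigenvalues)) > 1e-10))
    stop("PCCA+ requires a reversible model; re-estimate with ",
         "reversible = TRUE")
  X <- Re(model$right_eigenvectors[, seq_len(m), drop = FALSE])
  X[, 1] <- 1
  idx <- pcca_index_search(X)
  A <- solve(X[idx, , drop = FALSE])
  chi <- X %*% A
  # feasibility repair: clip tiny negatives, renormalize rows
  chi[chi < 0] <- 0
  chi <- chi / rowSums(chi)
  crisp <- max.col(chi, ties.method = "first")
  pops <- vapply(seq_len(m), function(I) sum(model$pi[crisp == I]),
                 numeric(1))
  structure(list(n_macro = m, memberships = chi, crisp = crisp,
                 macro_populations = pops),
            class = "CoarseGraining")
}

#' Build a macrostate Markov model from a PCCA+ partition
#'
#' Stationary-weighted coarse-graining of the microstate transition matrix
#' onto the crisp macrostate sets. For a reversible input model the coarse
#' matrix inherits detailed balance with respect to the macrostate
#' populations, so the result can be fed directly to [tpt()] and [mfpt()].
#'
#' @param model the microstate `MarkovModel`.
#' @param cg a `CoarseGraining` from [pcca()].
#' @return a `MarkovModel` over the macrostates.
#' @export
coarse_grained_model <- function(model, cg) {
  Tc <- coarse_grain_T(model$T, model$pi, cg$crisp, cg$n_macro)
  pi_c <- cg$macro_populations
  sp <- msm_spectrum(Tc, pi_c, model$reversible)
  structure(list(lag = model$lag, dt = model$dt, C = NULL, T = Tc,
                 pi = pi_c, eigenvalues = sp$values,
                 right_eigenvectors = sp$vectors,
                 active_set = seq_len(cg$n_macro),
                 n_states = cg$n_macro,
                 discarded_fraction = 0,
                 reversible = model$reversible),
            class = "MarkovModel")
}

# simplex vertex search: start from the row of largest norm, then
# repeatedly take the row farthest from the span of the chosen vertices
pcca_index_search <- function(X) {
  m <- ncol(X)
  idx <- integer(m)
  idx[1] <- which.max(rowSums(X^2))
  O <- sweep(X, 2, X[idx[1], ])
  for (j in seq_len(m - 1L) + 1L) {
    norms <- sqrt(rowSums(O^2))
    idx[j] <- which.max(norms)
    v <- O[idx[j], ] / norms[idx[j]]
    O <- O - outer(drop(O %*% v), v)
  }
  idx
}
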