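#' Sliding-window transition count matrix
#'
#' Counts transitions `(x_t, x_{t+lag})` for every `t` (sliding window) in
#' each discrete trajectory. Labels must be positive integers; the matrix is
#' indexed `1..max(label)`.
#'
#' @param dtrajs integer vector or list of integer vectors (1-based
#'   microstate labels).
#' @param lag lag time in frames (>= 1).
#' @param n_states optional state count (defaults to the largest label).
#' @return integer count matrix.
#' @export
count_transitions <- function(dtrajs, lag, n_states = NULL) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  lag <- as.integer(lag)
  if (lag < 1L) stop("lag must be >= 1")
  if (is.null(n_states)) n_states <- max(unlist(dtrajs))
  C <- matrix(0, n_states, n_states)
  for (dt in dtrajs) {
    dt <- as.integer(dt)
    if (length(dt) <= lag) next
    from <- dt[seq_len(length(dt) - lag)]
    to <- dt[lag + seq_len(length(dt) - lag)]
    tab <- table(factor(from, levels = seq_len(n_states)),
                 factor(to, levels = seq_len(n_states)))
    C <- C + unclass(tab)
  }
  if (sum(C) == 0) stop("no transitions observed at lag ", lag)
  dimnames(C) <- NULL
  C
}

#' Estimate a Markov state model from discrete trajectories
#'
#' Transition counts are taken at the given lag with a sliding window and
#' restricted to the largest strongly connected set of the count graph
#' (ergodic trimming; the discarded state fraction is recorded). The
#' reversible estimator symmetrizes the counts, `Cbar = (C + t(C))/2`, and
#' row-normalizes, which satisfies detailed balance in closed form with
#' stationary distribution proportional to the `Cbar` row sums; the
#' non-reversible estimator row-normalizes the raw counts. The spectral
#' decomposition (real for the reversible case, computed through the
#' pi-symmetrized matrix) is attached.
#'
#' @param dtrajs integer vector or list of integer vectors.
#' @param lag lag time in frames.
#' @param reversible use the symmetrized reversible estimator (default).
#' @param dt physical time per frame, ns (reporting only).
#' @return an object of class `MarkovModel`: list with `lag`, `dt`, `C`
#'   (restricted counts), `T`, `pi`, `eigenvalues`, `right_eigenvectors`,
#'   `active_set` (original labels), `n_states`, `discarded_fraction`,
#'   `reversible`.
#' @export
estimate_msm <- function(dtrajs, lag = 1L, reversible = TRUE, dt = 1) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  C_full <- count_transitions(dtrajs, lag)
  g <- igraph::graph_from_adjacency_matrix(C_full > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  # among strongly connected components, keep the one with most counts
  sizes <- vapply(seq_len(comp$no), function(k) {
    idx <- which(comp$membership == k)
    sum(C_full[idx, idx])
  }, numeric(1))
  active <- sort(which(comp$membership == which.max(sizes)))
  if (length(active) < 2L)
    stop("count graph has no connected set with >= 2 states")
  total <- sum(unlist(lapply(dtrajs, length)))
  discarded <- 1 - sum(unlist(dtrajs) %in% active) / total
  C <- C_full[active, active, drop = FALSE]
  if (reversible) {
    Cbar <- (C + t(C)) / 2
    T <- Cbar / rowSums(Cbar)
    pi <- rowSums(Cbar) / sum(Cbar)
  } else {
    T <- C / rowSums(C)
    pi <- stationary_distribution(T)
  }
  sp <- msm_spectrum(T, pi, reversible)
  structure(list(lag = lag, dt = dt, C = C, T = T, pi = pi,
                 eigenvalues = sp$values,
                 right_eigenvectors = sp$vectors,
                 active_set = active, n_states = length(active),
                 discarded_fraction = discarded,
                 reversible = reversible),
            class = "MarkovModel")
}

#' Construct a Markov model from a known transition matrix
#'
#' Wraps a given row-stochastic matrix as a `MarkovModel` (stationary
#' distribution, spectral decomposition, detailed-balance check), so that
#' analytic chains can be fed to [pcca()], [mfpt()], [tpt()] and
#' [vamp2_score()] without estimation from data.
#'
#' @param T row-stochastic transition matrix.
#' @param lag lag time in frames the matrix corresponds to.
#' @param dt physical time per frame, ns.
#' @return a `MarkovModel`.
#' @export
markov_model <- function(T, lag = 1L, dt = 1) {
  T <- as.matrix(T)
  if (any(T < 0) || any(abs(rowSums(T) - 1) > 1e-10))
    stop("T must be row-stochastic with non-negative entries")
  pi <- stationary_distribution(T)
  reversible <- max(abs(pi * T - t(pi * T))) < 1e-10
  sp <- msm_spectrum(T, pi, reversible)
  structure(list(lag = as.integer(lag), dt = dt, C = NULL, T = T, pi = pi,
                 eigenvalues = sp$values,
                 right_eigenvectors = sp$vectors,
                 active_set = seq_len(nrow(T)), n_states = nrow(T),
                 discarded_fraction = 0, reversible = reversible),
            class = "MarkovModel")
}

# spectral decomposition of T; for reversible models computed via the
# pi-symmetrized similar matrix so eigenvalues/vectors are real
msm_spectrum <- function(T, pi, reversible) {
  if (reversible && all(pi > 0)) {
    s <- sqrt(pi)
    S <- T * outer(s, 1 / s)
    S <- (S + t(S)) / 2
    e <- eigen(S, symmetric = TRUE)
    vectors <- e$vectors / s
    # normalize sign and scale: first right eigenvector is the constant 1
    vectors <- sweep(vectors, 2, vectors[1, ] / abs(vectors[1, ]), `/`)
    list(values = e$values, vectors = vectors)
  } else {
    e <- eigen(T)
    ord <- order(-Re(e$values))
    list(values = e$values[ord], vectors = e$vectors[, ord, drop = FALSE])
  }
}

#' Implied timescales across lag times
#'
#' `t_i(tau) = -tau / ln(lambda_i(tau))` for the `n` largest non-unit
#' eigenvalues of the MSM estimated at each lag. Eigenvalues outside (0, 1)
#' give `NA` (undefined timescale), not an error.
#'
#' @param dtrajs integer vector or list of integer vectors.
#' @param lags vector of lag times (frames, >= 1).
#' @param n number of timescales per lag.
#' @param reversible,dt passed to [estimate_msm()]; timescales are reported
#'   in physical time (`frames * dt`).
#' @return an object of class `ITSTable`: data.frame with columns `lag`,
#'   `index`, `eigenvalue`, `timescale`.
#' @export
implied_timescales <- function(dtrajs, lags, n = 1L, reversible = TRUE,
                               dt = 1) {
  stopifnot(all(lags >= 1))
  rows <- lapply(lags, function(tau) {
    m <- estimate_msm(dtrajs, lag = tau, reversible = reversible, dt = dt)
    lam <- Re(m$eigenvalues)
    # drop the unit eigenvalue(s), keep the next n
    lam <- lam[-1]
    lam <- lam[seq_len(min(n, length(lam)))]
    ts <- ifelse(lam > 0 & lam < 1, -tau * dt / log(lam), NA_real_)
    data.frame(lag = tau, index = seq_along(lam), eigenvalue = lam,
               timescale = ts)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ITSTable", "data.frame")
  out
}

#' VAMP-2 score of a Markov model
#'
#' Sum of squares of the top-`k` transition-matrix eigenvalues (including
#' the unit eigenvalue). For reversible models this equals the VAMP-2
#' singular-value form; higher scores indicate more slow processes resolved.
#'
#' @param model a `MarkovModel`.
#' @param k number of eigenvalues to include (<= state count).
#' @return numeric score.
#' @export
vamp2_score <- function(model, k) {
  k <- as.integer(k)
  if (k > model$n_states) stop("k must not exceed the state count")
  sum(Re(model$eigenvalues[seq_len(k)])^2)
}

#' Chapman-Kolmogorov test on a metastable partition
#'
#' Compares, per macrostate and lag multiple `f`, the self-transition
#' probability predicted by propagating the coarse-grained base model
#' (`coarse(T)^f`) against the model re-estimated from the data at lag
#' `f * tau` and coarse-grained on the same (fixed) partition.
#'
#' @param dtrajs the discrete trajectories the base model was built from.
#' @param model the base `MarkovModel` at lag `tau`.
#' @param factors integer lag multiples (>= 1).
#' @param n_macro number of macrostates for the PCCA+ partition.
#' @return data.frame with columns `macrostate`, `factor`, `predicted`,
#'   `estimated`.
#' @export
ck_test <- function(dtrajs, model, factors, n_macro) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  stopifnot(all(factors >= 1))
  maxlen <- max(vapply(dtrajs, length, integer(1)))
  if (any(factors * model$lag >= maxlen))
    stop("factor * lag exceeds the trajectory length")
  cg <- pcca(model, n_macro)
  crisp <- cg$crisp                       # over model's active set
  Tc0 <- coarse_grain_T(model$T, model$pi, crisp, n_macro)
  rows <- list()
  for (f in sort(unique(as.integer(factors)))) {
    pred <- matrix_power(Tc0, f)
    m_f <- estimate_msm(dtrajs, lag = f * model$lag,
                        reversible = model$reversible, dt = model$dt)
    # carry the fixed partition onto the re-estimated active set
    lab_f <- crisp[match(m_f$active_set, model$active_set)]
    ok <- !is.na(lab_f)
    est <- coarse_grain_T(m_f$T[ok, ok, drop = FALSE],
                          m_f$pi[ok] / sum(m_f$pi[ok]),
                          lab_f[ok], n_macro)
    for (I in seq_len(n_macro))
      rows[[length(rows) + 1L]] <-
        data.frame(macrostate = I, factor = f,
                   predicted = pred[I, I], estimated = est[I, I])
  }
  do.call(rbind, rows)
}

# pi-weighted coarse-graining of a transition matrix onto crisp sets
coarse_grain_T <- function(T, pi, crisp, n_macro) {
  Tc <- matrix(0, n_macro, n_macro)
  for (I in seq_len(n_macro)) {
    i_set <- which(crisp == I)
    wi <- pi[i_set]
    if (!length(i_set) || sum(wi) == 0) next
    for (J in seq_len(n_macro)) {
      j_set <- which(crisp == J)
      if (!length(j_set)) next
      Tc[I, J] <- sum(wi * rowSums(T[i_set, j_set, drop = FALSE])) / sum(wi)
    }
  }
  Tc
}

matrix_power <- function(M, p) {
  out <- diag(nrow(M))
  for (i in seq_len(p)) out <- out %*% M
  out
}

#' Per-macrostate geometric distance summaries
#'
#' For frames grouped by macrostate, summarizes (mean +/- SD) the four
#' Calpha distances used to characterize an 18-residue hairpin fragment --
#' termini distance (roles 1-18), mid distance (the arithmetic mean of the
#' 3-17, 4-16 and 5-15 pair distances), C-terminal distance (7-18) and
#' N-terminal distance (1-12) -- together with the turn-register ratio.
#'
#' @param ens a `ConformerEnsemble`.
#' @param labels integer macrostate label per frame.
#' @param role_map optional named remap of the 18 role indices onto absolute
#'   residue numbers (a function or integer vector such that
#'   `role_map[i]` is the residue playing role `i`; default identity).
#' @return data.frame with one row per macrostate present.
#' @export
state_distance_profiles <- function(ens, labels, role_map = NULL) {
  stopifnot(length(labels) == n_frames(ens))
  role <- function(i) if (is.null(role_map)) i else role_map[i]
  ca <- function(r) {
    i <- which(ens$atoms$resno == role(r) & ens$atoms$elety == "CA")
    if (!length(i)) stop("residue for role ", r, " has no CA atom")
    i[1]
  }
  pair_d <- function(xyz, r1, r2)
    sqrt(sum((xyz[ca(r1), ] - xyz[ca(r2), ])^2))
  per_frame <- t(vapply(seq_len(n_frames(ens)), function(f) {
    xyz <- frame_coords(ens, f)
    c(termini = pair_d(xyz, 1, 18),
      mid = mean(c(pair_d(xyz, 3, 17), pair_d(xyz, 4, 16),
                   pair_d(xyz, 5, 15))),
      cterm = pair_d(xyz, 7, 18),
      nterm = pair_d(xyz, 1, 12),
      turn_ratio = pair_d(xyz, 4, 12) / pair_d(xyz, 7, 12))
  }, numeric(5)))
  states <- sort(unique(labels))
  empty <- setdiff(seq_len(max(labels)), states)
  if (length(empty))
    warning("macrostate(s) with no frames omitted: ",
            paste(empty, collapse = ", "))
  rows <- lapply(states, function(s) {
    sub <- per_frame[labels == s, , drop = FALSE]
    stats <- c(rbind(colMeans(sub), apply(sub, 2, stats::sd)))
    names(stats) <- as.vector(rbind(paste0(colnames(per_frame), "_mean"),
                                    paste0(colnames(per_frame), "_sd")))
    c(state = s, n_frames = nrow(sub), stats)
  })
  as.data.frame(do.call(rbind, rows))
}
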