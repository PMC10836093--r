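#' Specification for a synthetic Markov trajectory with Gaussian emissions
#'
#' Ground-truth generator for Markov-state-model parameter recovery: a
#' discrete macrostate chain evolves under a known row-stochastic transition
#' matrix, and each visited state emits a point in feature space from a
#' state-specific multivariate Gaussian.
#'
#' @param T_true row-stochastic transition matrix (rows sum to 1 within
#'   1e-12, all entries >= 0).
#' @param means numeric matrix `n_states x n_features` of emission centres.
#' @param covs either a single covariance matrix shared by all states or a
#'   list of per-state covariance matrices.
#' @param n_steps trajectory length (steps).
#' @param lag_unit physical time per step, ns (reporting only).
#' @param seed RNG seed.
#'
#' @return list of class `MarkovEmissionSpec`.
#' @export
markov_emission_spec <- function(T_true, means, covs, n_steps,
                                 lag_unit = 0.1, seed = 1L) {
  spec <- list(T_true = as.matrix(T_true), means = as.matrix(means),
               covs = covs, n_steps = as.integer(n_steps),
               lag_unit = lag_unit, seed = as.integer(seed))
  class(spec) <- "MarkovEmissionSpec"
  validate_markov_emission_spec(spec)
  spec
}

validate_markov_emission_spec <- function(spec) {
  Tm <- spec$T_true
  if (nrow(Tm) != ncol(Tm)) stop("invalid spec: T_true must be square")
  if (any(Tm < 0)) stop("invalid spec: T_true entries must be >= 0")
  if (any(abs(rowSums(Tm) - 1) > 1e-12))
    stop("invalid spec: rows of T_true must sum to 1 within 1e-12")
  if (nrow(spec$means) != nrow(Tm))
    stop("invalid spec: means count must equal state count")
  if (spec$n_steps < 1L) stop("invalid spec: n_steps must be >= 1")
  invisible(spec)
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left Perron eigenvector, normalized to sum to 1.
#'
#' @param T row-stochastic matrix.
#' @return numeric vector of stationary probabilities.
#' @export
stationary_distribution <- function(T) {
  e <- eigen(t(T))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

#' Simulate a discrete Markov trajectory with Gaussian feature emissions
#'
#' The state sequence starts from a draw of the stationary distribution of
#' `T_true` and evolves for `n_steps`; each step emits a feature vector from
#' the state's Gaussian. Reproducible for fixed spec.
#'
#' @param spec a [markov_emission_spec()].
#' @return list with `states` (integer sequence, 1-based), `features`
#'   (matrix `n_steps x n_features`) and `spec`.
#' @export
simulate_markov_trajectory <- function(spec) {
  validate_markov_emission_spec(spec)
  set.seed(spec$seed)
  Tm <- spec$T_true
  k <- nrow(Tm)
  pi0 <- stationary_distribution(Tm)
  states <- integer(spec$n_steps)
  states[1] <- sample.int(k, 1L, prob = pi0)
  if (spec$n_steps > 1L) {
    # draw all uniforms at once, then walk the chain
    u <- stats::runif(spec$n_steps - 1L)
    cum <- t(apply(Tm, 1, cumsum))
    for (t in 2:spec$n_steps) {
      states[t] <- findInterval(u[t - 1L], cum[states[t - 1L], ],
                                left.open = TRUE) + 1L
    }
  }
  d <- ncol(spec$means)
  features <- matrix(NA_real_, nrow = spec$n_steps, ncol = d)
  for (s in seq_len(k)) {
    idx <- which(states == s)
    if (!length(idx)) next
    covs <- if (is.list(spec$covs)) spec$covs[[s]] else spec$covs
    features[idx, ] <- MASS::mvrnorm(length(idx), mu = spec$means[s, ],
                                     Sigma = as.matrix(covs))
  }
  list(states = states, features = features, spec = spec)
}
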