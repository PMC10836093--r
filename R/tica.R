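#' Minimum pairwise residue-distance featurization
#'
#' One feature column per ordered residue pair `(a in groupA, b in groupB)`;
#' the value is the per-frame minimum atom-atom distance between residues
#' `a` and `b`. With `|A| = |B| = 7` this yields the 49-column featurization
#' used to discretize inter-strand contacts of an 18-residue fragment.
#'
#' @param ens a `ConformerEnsemble`.
#' @param groupA,groupB disjoint, non-empty residue index sets.
#' @param dt time per frame, ns (carried as metadata).
#' @return an object of class `FeatureTrajectory`: list with `values`
#'   (frames x features matrix, Angstrom), `feature_labels` and `dt`.
#' @export
featurize_min_distances <- function(ens, groupA, groupB, dt = 0.1) {
  if (!length(groupA) || !length(groupB)) stop("groups must be non-empty")
  if (length(intersect(groupA, groupB))) stop("groups must be disjoint")
  for (r in c(groupA, groupB))
    if (!any(ens$atoms$resno == r))
      stop("residue ", r, " is absent from the ensemble")
  pairs <- expand.grid(b = groupB, a = groupA)[, c("a", "b")]
  atom_sets_a <- lapply(groupA, function(r) which(ens$atoms$resno == r))
  atom_sets_b <- lapply(groupB, function(r) which(ens$atoms$resno == r))
  nf <- n_frames(ens)
  vals <- matrix(NA_real_, nrow = nf, ncol = nrow(pairs))
  for (f in seq_len(nf)) {
    xyz <- frame_coords(ens, f)
    col <- 0L
    for (ia in seq_along(groupA)) {
      A <- xyz[atom_sets_a[[ia]], , drop = FALSE]
      for (ib in seq_along(groupB)) {
        B <- xyz[atom_sets_b[[ib]], , drop = FALSE]
        d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
        col <- col + 1L
        vals[f, col] <- sqrt(max(0, min(d2)))
      }
    }
  }
  labels <- paste0("d_", rep(groupA, each = length(groupB)), "_",
                   rep(groupB, times = length(groupA)))
  structure(list(values = vals, feature_labels = labels, dt = dt),
            class = "FeatureTrajectory")
}

#' Time-lagged independent component analysis (tICA)
#'
#' Solves the generalized eigenproblem of the symmetrized time-lagged
#' covariance against the instantaneous covariance of mean-free data. The
#' eigenvalues are lag-`lag` autocorrelations of the reduced coordinates;
#' components are sorted by decreasing eigenvalue. A singular instantaneous
#' covariance is regularized by adding `1e-10 * trace/dim` to the diagonal
#' (with a warning).
#'
#' @param x a `FeatureTrajectory` or plain frames-by-features matrix.
#' @param lag lag time in frames (>= 1, < number of frames).
#' @return an object of class `TICAModel`: list with `lag`, `mean`,
#'   `components` (loading matrix, columns are tICs), `eigenvalues`.
#' @export
tica_fit <- function(x, lag = 1L) {
  X <- if (inherits(x, "FeatureTrajectory")) x$values else as.matrix(x)
  n <- nrow(X); d <- ncol(X)
  lag <- as.integer(lag)
  if (lag < 1L) stop("lag must be >= 1")
  if (n <= lag) stop("need more frames than the lag")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  m <- n - lag
  X0 <- Xc[seq_len(m), , drop = FALSE]
  Xt <- Xc[lag + seq_len(m), , drop = FALSE]
  # symmetrized instantaneous and time-lagged covariances
  C0 <- (crossprod(X0) + crossprod(Xt)) / (2 * (m - 1))
  Ct <- (crossprod(X0, Xt) + crossprod(Xt, X0)) / (2 * (m - 1))
  e0 <- eigen(C0, symmetric = TRUE)
  tol <- max(e0$values) * 1e-10
  if (any(e0$values < tol)) {
    warning("singular instantaneous covariance; regularizing")
    eps <- 1e-10 * sum(diag(C0)) / d
    C0 <- C0 + diag(eps, d)
    e0 <- eigen(C0, symmetric = TRUE)
  }
  # C0^{-1/2}, dropping numerically null directions
  keep <- e0$values > max(e0$values) * 1e-12
  W <- e0$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e0$values[keep]), sum(keep))
  K <- t(W) %*% Ct %*% W
  ek <- eigen((K + t(K)) / 2, symmetric = TRUE)
  comp <- W %*% ek$vectors
  structure(list(lag = lag, mean = mu, components = comp,
                 eigenvalues = ek$values),
            class = "TICAModel")
}

#' Project features onto tICA components
#'
#' @param model a `TICAModel` from [tica_fit()].
#' @param x a `FeatureTrajectory` or matrix with matching feature count.
#' @param n_components number of leading components to keep.
#' @return matrix frames x n_components.
#' @export
tica_transform <- function(model, x, n_components = 2L) {
  X <- if (inherits(x, "FeatureTrajectory")) x$values else as.matrix(x)
  n_components <- min(n_components, ncol(model$components))
  sweep(X, 2, model$mean) %*% model$components[, seq_len(n_components),
                                               drop = FALSE]
}

#' k-means discretization of a reduced space
#'
#' k-means++ seeding with an explicit RNG seed followed by standard Lloyd
#' iterations ([stats::kmeans()]); every frame is assigned to its nearest
#' centre. Deterministic for fixed seed.
#'
#' @param projected frames x dims matrix (e.g. tICA projection).
#' @param k number of microstates (1 <= k <= frames).
#' @param seed RNG seed.
#' @param iter_max maximum Lloyd iterations.
#' @return an object of class `Discretization`: list with `centers`
#'   (k x dims), `dtraj` (integer labels in 1..k), `seed` and `converged`
#'   (whether Lloyd iterations converged within `iter_max`; a capped pass
#'   is still a valid Voronoi discretization).
#' @export
kmeans_discretize <- function(projected, k, seed = 1L, iter_max = 100L) {
  X <- as.matrix(projected)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(X)) stop("k must not exceed the number of frames")
  set.seed(seed)
  if (k == 1L) {
    ctr <- matrix(colMeans(X), nrow = 1L)
    return(structure(list(centers = ctr, dtraj = rep(1L, nrow(X)),
                          seed = seed, converged = TRUE),
                     class = "Discretization"))
  }
  init <- kmeanspp_init(X, k)
  converged <- TRUE
  km <- withCallingHandlers(
    stats::kmeans(X, centers = init, iter.max = iter_max,
                  algorithm = "Lloyd"),
    warning = function(w) {
      if (grepl("did not converge", conditionMessage(w))) {
        # a capped Lloyd pass is still a valid Voronoi discretization;
        # record the status instead of warning
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  structure(list(centers = km$centers, dtraj = as.integer(km$cluster),
                 seed = seed, converged = converged),
            class = "Discretization")
}

# k-means++ seeding (Arthur & Vassilvitskii): probability proportional to
# squared distance to the nearest chosen centre
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, nrow = k, ncol = ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in 2:k) {
    p <- d2 / sum(d2)
    centers[j, ] <- X[sample.int(n, 1L, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

#' Free-energy surface over a 2-D projection
#'
#' 2-D histogram of the projected samples converted to `-ln(density)` and
#' shifted so the minimum is 0; empty bins are `Inf` (unreachable).
#'
#' @param projected 2-column matrix of reduced coordinates.
#' @param n_bins bins per axis.
#' @param weights optional per-frame weights.
#' @return list with `x`, `y` bin centres and `energy` matrix (kT units).
#' @export
free_energy_surface <- function(projected, n_bins = 50L, weights = NULL) {
  X <- as.matrix(projected)
  if (nrow(X) < 2L) stop("need at least 2 frames")
  if (ncol(X) < 2L) stop("need a 2-column projection")
  if (is.null(weights)) weights <- rep(1, nrow(X))
  bx <- seq(min(X[, 1]), max(X[, 1]), length.out = n_bins + 1L)
  by <- seq(min(X[, 2]), max(X[, 2]), length.out = n_bins + 1L)
  ix <- pmin(pmax(findInterval(X[, 1], bx, all.inside = TRUE), 1L), n_bins)
  iy <- pmin(pmax(findInterval(X[, 2], by, all.inside = TRUE), 1L), n_bins)
  H <- matrix(0, n_bins, n_bins)
  for (i in seq_len(nrow(X))) H[ix[i], iy[i]] <- H[ix[i], iy[i]] + weights[i]
  E <- -log(H / sum(H))
  E <- E - min(E[is.finite(E)])
  list(x = (bx[-1] + bx[-length(bx)]) / 2,
       y = (by[-1] + by[-length(by)]) / 2,
       energy = E)
}
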