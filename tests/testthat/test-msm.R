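test_that("min-distance featurization has one column per residue pair", {
  ens <- make_hairpin_ensemble(hairpin_spec(18, 9, noise_sd = 0.3,
                                            n_frames = 5, seed = 1))
  ft <- featurize_min_distances(ens, 1:7, 12:18)
  expect_equal(ncol(ft$values), 49L)
  expect_equal(nrow(ft$values), 5L)
  ft2 <- featurize_min_distances(ens, 1:2, 10:12)
  expect_equal(ncol(ft2$values), 6L)
  # single-atom residues: the column is the plain pair distance
  x <- frame_coords(ens, 1)
  expect_equal(ft2$values[1, 1], sqrt(sum((x[1, ] - x[10, ])^2)))
  expect_error(featurize_min_distances(ens, 1:2, 25), "absent")
  expect_error(featurize_min_distances(ens, 1:3, 3:5), "disjoint")
})

test_that("tICA recovers AR(1) autocorrelation structure", {
  set.seed(77)
  n <- 1e5
  phi <- 0.8
  x <- as.numeric(stats::arima.sim(list(ar = phi), n))
  m <- tica_fit(matrix(x, ncol = 1), lag = 1)
  expect_equal(m$eigenvalues[1], phi, tolerance = 0.02)
  # white noise has no autocorrelation
  w <- tica_fit(matrix(rnorm(n), ncol = 1), lag = 1)
  expect_lt(abs(w$eigenvalues[1]), 0.05)
})

test_that("tICA unmixes slow and fast directions", {
  set.seed(78)
  n <- 1e5
  slow <- as.numeric(stats::arima.sim(list(ar = 0.99), n))
  fast <- as.numeric(stats::arima.sim(list(ar = 0.5), n))
  theta <- 0.6
  R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2)
  X <- cbind(slow, fast) %*% t(R)
  m <- tica_fit(X, lag = 1)
  # leading tIC projects onto the slow direction: undo the mixing
  v <- m$components[, 1]
  slow_dir <- R[, 1]
  cosang <- abs(sum(v * slow_dir)) / sqrt(sum(v^2) * sum(slow_dir^2))
  expect_gt(cosang, 0.95)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
  expect_true(all(abs(m$eigenvalues) <= 1 + 1e-9))
})

test_that("k-means discretization is seeded and recovers blobs", {
  set.seed(5)
  X1 <- matrix(rnorm(400, 0, 0.3), ncol = 2)
  X2 <- matrix(rnorm(400, 5, 0.3), ncol = 2)
  X <- rbind(X1, X2)
  truth <- rep(1:2, each = 200)
  d1 <- kmeans_discretize(X, 2, seed = 1)
  d2 <- kmeans_discretize(X, 2, seed = 1)
  expect_identical(d1$centers, d2$centers)
  agree <- max(mean(d1$dtraj == truth), mean(d1$dtraj == 3 - truth))
  expect_gt(agree, 0.99)
  # k = 1 center is the data mean
  d3 <- kmeans_discretize(X, 1, seed = 1)
  expect_equal(as.numeric(d3$centers), colMeans(X))
  expect_error(kmeans_discretize(X, nrow(X) + 1, 1), "frames")
})

test_that("MSM estimation recovers known transition probabilities", {
  # alternating trajectory
  m <- estimate_msm(rep(1:2, 100), lag = 1)
  expect_equal(m$T, matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)
  # 3-state ground truth at large n
  ch <- recovery_chain()
  sim <- simulate_markov_trajectory(
    markov_emission_spec(ch$T, ch$means, ch$cov, n_steps = 1e6, seed = 13))
  mhat <- estimate_msm(sim$states, lag = 1)
  expect_lt(max(abs(mhat$T - ch$T)), 0.01)
  expect_lt(max(abs(mhat$pi - ch$pi)), 0.01)
})

test_that("reversible estimator satisfies its structural invariants", {
  Tm <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, byrow = TRUE)
  sim <- simulate_markov_trajectory(
    markov_emission_spec(Tm, rbind(0, 5), matrix(1), n_steps = 5e4,
                         seed = 21))
  m <- estimate_msm(sim$states, lag = 2)
  expect_equal(rowSums(m$T), rep(1, 2), tolerance = 1e-10)
  expect_equal(as.numeric(m$pi %*% m$T), m$pi, tolerance = 1e-8)
  # detailed balance of the symmetrized estimator
  expect_lt(max(abs(m$pi * m$T - t(m$pi * m$T))), 1e-8)
  # pi equals normalized row sums of the symmetrized counts
  Cbar <- (m$C + t(m$C)) / 2
  expect_equal(m$pi, rowSums(Cbar) / sum(Cbar), tolerance = 1e-12)
  expect_error(estimate_msm(c(1L), lag = 1), "no transitions")
})

test_that("implied timescales match the analytic 2-state spectrum", {
  # deterministic count pattern is unnecessary: build from the exact model
  a <- b <- 0.1
  Tm <- matrix(c(1 - a, a, b, 1 - b), 2, byrow = TRUE)
  sim <- simulate_markov_trajectory(
    markov_emission_spec(Tm, rbind(0, 5), matrix(1), n_steps = 2e5,
                         seed = 3))
  its <- implied_timescales(sim$states, lags = 1, n = 1)
  expect_equal(its$timescale, -1 / log(1 - a - b), tolerance = 0.1)
  # Markovian input: timescale flat in lag within 10%
  its10 <- implied_timescales(sim$states, lags = c(1, 2, 5, 10), n = 1)
  expect_true(all(abs(its10$timescale / (-1 / log(0.8)) - 1) < 0.1))
  # non-positive eigenvalue gives an undefined marker, not an error
  osc <- estimate_msm(rep(1:2, 500), lag = 1)
  its_osc <- implied_timescales(rep(1:2, 500), lags = 1, n = 1)
  expect_true(is.na(its_osc$timescale))
})

test_that("VAMP-2 score equals the eigenvalue sum of squares", {
  # near-identity chain: score approaches k = 2
  m_id <- markov_model(matrix(c(0.999, 0.001, 0.001, 0.999), 2))
  expect_equal(vamp2_score(m_id, 2), 1 + 0.998^2, tolerance = 1e-9)
  a <- b <- 0.1
  m2 <- markov_model(matrix(c(1 - a, a, b, 1 - b), 2, byrow = TRUE))
  expect_equal(vamp2_score(m2, 2), 1 + 0.8^2, tolerance = 1e-9)
  expect_gte(vamp2_score(m2, 2), vamp2_score(m2, 1))
  expect_error(vamp2_score(m2, 3), "state count")
})

test_that("CK test validates Markovian data and flags lumped memory", {
  ch <- recovery_chain()
  sim <- simulate_markov_trajectory(
    markov_emission_spec(ch$T, ch$means, ch$cov, n_steps = 3e5, seed = 17))
  m <- estimate_msm(sim$states, lag = 1)
  ck <- ck_test(sim$states, m, factors = 1:5, n_macro = 2)
  f1 <- ck[ck$factor == 1, ]
  expect_equal(f1$predicted, f1$estimated, tolerance = 1e-10)
  expect_true(all(abs(ck$predicted - ck$estimated) < 0.05))
  # hidden 4-state cycle observed through 2 merged states: the lumped
  # process alternates a,a,b,b,... and is strongly non-Markovian
  Th <- matrix(c(0.1, 0.9, 0,   0,
                 0,   0.1, 0.9, 0,
                 0,   0,   0.1, 0.9,
                 0.9, 0,   0,   0.1), 4, byrow = TRUE)
  hidden <- sim_chain(Th, 1e5, seed = 19)
  lumped <- ifelse(hidden <= 2, 1L, 2L)
  ml <- estimate_msm(lumped, lag = 1)
  ckl <- ck_test(lumped, ml, factors = 1:5, n_macro = 2)
  expect_gt(max(abs(ckl$predicted - ckl$estimated)), 0.05)
})

test_that("per-macrostate distance profiles follow their definitions", {
  hp <- make_hairpin_ensemble(hairpin_spec(18, 9, n_frames = 3))
  ex <- make_extended_ensemble(18, n_frames = 2)
  ens <- bind_ensembles(hp, ex)
  labels <- c(1L, 1L, 1L, 2L, 2L)
  prof <- state_distance_profiles(ens, labels)
  # identical frames within a state: SD 0
  expect_equal(prof$termini_sd, c(0, 0), tolerance = 1e-12)
  # extended template: termini distance 64.6 A and mid = mean of 3 pairs
  expect_equal(prof$termini_mean[2], 64.6)
  x <- frame_coords(ex, 1)
  d <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  expect_equal(prof$mid_mean[2], mean(c(d(3, 17), d(4, 16), d(5, 15))))
  expect_warning(state_distance_profiles(ens, c(1L, 1L, 1L, 3L, 3L)),
                 "omitted")
})

test_that("free-energy surface reproduces analytic population gaps", {
  set.seed(41)
  n <- 1e5
  z <- runif(n) < 0.9
  # two tight blobs with 9:1 weights; uniform y so the bin split is even
  X <- cbind(ifelse(z, rnorm(n, 0.25, 0.01), rnorm(n, 0.75, 0.01)),
             runif(n))
  fes <- free_energy_surface(X, n_bins = 2)
  finite <- fes$energy[is.finite(fes$energy)]
  expect_equal(min(finite), 0)
  gap <- max(finite) - min(finite)
  expect_equal(gap, log(9), tolerance = 0.1)
})
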