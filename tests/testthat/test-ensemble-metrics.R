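# hand-built two-residue, multi-atom test ensemble
two_res_ensemble <- function(frames) {
  atoms <- data.frame(resno = c(1L, 1L, 2L),
                      resid = "ALA",
                      elety = c("CA", "CB", "CA"))
  coords <- array(NA_real_, dim = c(length(frames), 3L, 3L))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  conformer_ensemble(coords, atoms)
}

test_that("minimum-distance map takes the per-frame minimum, then the mean", {
  # residue 1 has atoms at 3 A and 7 A from residue 2's atom
  f1 <- rbind(c(0, 0, 0), c(0, 0, -4), c(0, 0, 3))
  ens <- two_res_ensemble(list(f1))
  dm <- min_distance_map(ens)
  expect_equal(dm$values[1, 2], 3)
  expect_equal(dm$values[2, 1], 3)
  expect_equal(diag(dm$values), c(0, 0))
  # two frames with minima 2 and 4 average to 3
  f2 <- rbind(c(0, 0, 0), c(0, 0, -4), c(0, 0, 2))
  f3 <- rbind(c(0, 0, 0), c(0, 0, -4), c(0, 0, 4))
  dm2 <- min_distance_map(two_res_ensemble(list(f2, f3)))
  expect_equal(dm2$values[1, 2], 3)
  # symmetry holds on a noisy ensemble
  noisy <- make_hairpin_ensemble(hairpin_spec(12, 6, noise_sd = 1,
                                              n_frames = 4, seed = 2))
  dmn <- min_distance_map(noisy)
  expect_equal(dmn$values, t(dmn$values))
  expect_true(all(dmn$values >= 0))
  expect_error(min_distance_map(noisy, elety = "CB"), "empty")
})

test_that("group centroid distance matches hand computation", {
  f <- rbind(c(0, 0, 0), c(0, 0, 9))
  ens <- conformer_ensemble(array(f, dim = c(1, 2, 3)),
                            data.frame(resno = 1:2, resid = "ALA",
                                       elety = "CA"))
  expect_equal(group_com_distance(ens, 1, 2), 9)
  # centroid of (+-1, 0, 0) sits at the origin
  f2 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 0, 5))
  ens2 <- conformer_ensemble(array(f2, dim = c(1, 3, 3)),
                             data.frame(resno = c(1L, 2L, 3L),
                                        resid = "ALA", elety = "CA"))
  expect_equal(group_com_distance(ens2, c(1, 2), 3), 5)
  expect_error(group_com_distance(ens2, c(1, 2), 2), "disjoint")
  # hairpin template: groups 1-6 vs 12-18 against direct evaluation
  ens3 <- make_hairpin_ensemble(hairpin_spec(18, 9, strand_sep = 4.8))
  x <- frame_coords(ens3, 1)
  expected <- sqrt(sum((colMeans(x[1:6, ]) - colMeans(x[12:18, ]))^2))
  expect_equal(group_com_distance(ens3, 1:6, 12:18), expected)
})

test_that("turn-register ratio classifies and is rigid-motion invariant", {
  left <- make_hairpin_ensemble(hairpin_spec(18, 7, strand_sep = 4.8,
                                             n_frames = 3))
  rp <- turn_register(left)
  expect_true(all(rp$ratio < 0.75))
  expect_true(all(rp$classification == "left"))
  # rigid motion and uniform scaling leave the ratio unchanged
  rot <- rotate_ensemble(left)
  expect_equal(turn_register(rot)$ratio, rp$ratio, tolerance = 1e-9)
  scaled <- left
  scaled$coords <- scaled$coords * 2.7
  expect_equal(turn_register(scaled)$ratio, rp$ratio, tolerance = 1e-9)
  # collinear extended chain: ratio = 8/5
  ext <- make_extended_ensemble(18)
  rpe <- turn_register(ext)
  expect_equal(rpe$ratio[1], 8 / 5)
  expect_equal(rpe$classification[1], "right")
  # coincident role atoms are flagged, not fatal
  degen <- ext
  degen$coords[1, 7, ] <- degen$coords[1, 12, ]
  expect_warning(rpd <- turn_register(degen), "excluded")
  expect_equal(rpd$n_degenerate, 1L)
})

test_that("fitted RMSD agrees with quaternion and bio3d oracles", {
  set.seed(31)
  a <- matrix(rnorm(12), 4, 3)
  expect_equal(rmsd_fit(a, a), 0)
  # rigidly displaced copy fits back to zero
  b <- a %*% t(rotation_matrix(c(0, 1, 1), 0.7)) +
    matrix(c(3, 4, 5), 4, 3, byrow = TRUE)
  expect_lt(rmsd_fit(b, a), 1e-10)
  # one displaced atom: match two independent superposition oracles
  d <- a; d[2, ] <- d[2, ] + c(1.2, -0.4, 0.9)
  expect_equal(rmsd_fit(d, a), quaternion_rmsd(d, a), tolerance = 1e-8)
  # bio3d rounds its result to 3 decimals
  expect_equal(rmsd_fit(d, a),
               bio3d::rmsd(as.vector(t(a)), as.vector(t(d)),
                           fit = TRUE),
               tolerance = 2e-3)
  expect_error(rmsd_fit(a[1:3, ], a), "mismatch")
})

test_that("pairwise RMSD matrix is symmetric and elementwise correct", {
  ens <- make_hairpin_ensemble(hairpin_spec(12, 6, noise_sd = 1.5,
                                            n_frames = 3, seed = 5))
  pr <- pairwise_rmsd(ens)
  expect_equal(pr$values, t(pr$values), tolerance = 1e-9)
  expect_equal(diag(pr$values), rep(0, 3))
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(pr$values[i, j],
                 rmsd_fit(frame_coords(ens, i), frame_coords(ens, j)))
  same <- make_hairpin_ensemble(hairpin_spec(12, 6, n_frames = 4))
  expect_true(all(pairwise_rmsd(same)$values < 1e-10))
})

test_that("GROMOS clustering matches the brute-force greedy oracle", {
  ens <- bind_ensembles(
    make_hairpin_ensemble(hairpin_spec(10, 5, noise_sd = 0.8,
                                       n_frames = 25, seed = 9)),
    make_extended_ensemble(10, noise_sd = 0.8, n_frames = 25, seed = 10))
  cl <- gromos_cluster(ens, cutoff = 2.5)
  coord_list <- lapply(seq_len(n_frames(ens)),
                       function(f) frame_coords(ens, f))
  oracle <- bruteforce_gromos(coord_list, 2.5)
  expect_identical(cl$assignments, oracle)
  expect_equal(sum(cl$populations), 1, tolerance = 1e-9)
  expect_true(all(diff(cl$populations) <= 1e-12))
})

test_that("GROMOS clustering degenerate cases", {
  same <- make_hairpin_ensemble(hairpin_spec(10, 5, n_frames = 6))
  cl <- gromos_cluster(same, cutoff = 0.1)
  expect_equal(cl$populations, 1)
  expect_equal(unique(cl$assignments), 1L)
  # cutoff below any pairwise RMSD: every frame its own cluster
  spread <- make_hairpin_ensemble(hairpin_spec(10, 5, noise_sd = 2,
                                               n_frames = 8, seed = 3))
  cl2 <- gromos_cluster(spread, cutoff = 1e-4)
  expect_equal(length(cl2$populations), 8L)
  # nm cutoffs convert at the boundary
  cl3 <- gromos_cluster(spread, cutoff = 0.54, cutoff_unit = "nm")
  cl4 <- gromos_cluster(spread, cutoff = 5.4)
  expect_identical(cl3$assignments, cl4$assignments)
})

test_that("top cluster population recovers a known mixture fraction", {
  f <- 0.7
  n <- 60
  ens <- bind_ensembles(
    make_hairpin_ensemble(hairpin_spec(12, 6, noise_sd = 0.5,
                                       n_frames = round(f * n), seed = 21)),
    make_extended_ensemble(12, noise_sd = 0.5,
                           n_frames = n - round(f * n), seed = 22))
  cl <- gromos_cluster(ens, cutoff = 4)
  expect_equal(cl$populations[1], f, tolerance = 0.05)
})
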