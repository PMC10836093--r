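record <- function(score = 30, fdr = 0.01, ppm = 0, tic = 20, len = 8,
                   pos1 = 280L, pos2 = 311L, rep = "rep1", nseen = 3L) {
  data.frame(kind = "crosslink", pos1 = pos1, pos2 = pos2, score = score,
             fdr = fdr, mass_error_ppm = ppm, tic_pct = tic,
             pep_len = len, replicate = rep, nseen = nseen,
             stringsAsFactors = FALSE)
}

test_that("identification filter applies the acceptance thresholds", {
  ok <- record(score = 26, fdr = 0.01, ppm = 0, tic = 20, len = 8)
  expect_equal(nrow(filter_ids(ok)), 1L)
  # boundary: score 25 is not > 25
  expect_equal(nrow(filter_ids(record(score = 25))), 0L)
  expect_equal(nrow(filter_ids(record(fdr = 0.05))), 0L)
  expect_equal(nrow(filter_ids(record(ppm = -2.3))), 0L)
  expect_equal(nrow(filter_ids(record(ppm = 3.8))), 1L)
  expect_equal(nrow(filter_ids(record(tic = 10))), 0L)
  expect_equal(nrow(filter_ids(record(len = 5))), 0L)
  expect_equal(nrow(filter_ids(record(len = 6))), 1L)
  # rejection bookkeeping, including malformed rows
  tab <- rbind(ok, record(score = 10), record(fdr = NA))
  out <- filter_ids(tab)
  rej <- attr(out, "rejections")
  expect_equal(unname(rej["score"]), 1)
  expect_equal(unname(rej["malformed"]), 1)
})

test_that("filter output equals generator ground truth exactly", {
  tab <- make_crosslink_tables(synthetic_link_spec(
    n_replicates = 5, n_links_per_rep = 400, seed = 101))
  kept <- filter_ids(tab)
  expect_true(any(tab$truth_pass) && any(!tab$truth_pass))
  expect_identical(which(tab$truth_pass), as.integer(rownames(kept)))
  # monotone: tightening any threshold never increases the retained count
  thr <- xquest_default_thresholds()
  thr$score_min <- 30
  expect_lte(nrow(filter_ids(tab, thr)), nrow(kept))
  thr$tic_min <- 15
  thr$fdr_max <- 0.02
  expect_lte(nrow(filter_ids(tab, thr)), nrow(kept))
})

test_that("replicate consensus keeps links seen in enough replicates", {
  five <- do.call(rbind, lapply(1:5, function(r)
    record(rep = paste0("rep", r))))
  four <- do.call(rbind, lapply(1:4, function(r)
    record(pos1 = 254L, pos2 = 340L, rep = paste0("rep", r))))
  tab <- rbind(five, four)
  cs <- consensus(tab)                      # default: all replicates
  expect_equal(nrow(cs), 1L)
  expect_equal(cs$pos1, 280L)
  cs4 <- consensus(tab, n_required = 4)
  expect_equal(nrow(cs4), 2L)
  cs1 <- consensus(tab, n_required = 1)
  expect_equal(nrow(cs1), 2L)               # union of replicates
  # nesting: consensus(k) is a superset of consensus(k + 1)
  key4 <- paste(cs4$pos1, cs4$pos2)
  key5 <- paste(cs$pos1, cs$pos2)
  expect_true(all(key5 %in% key4))
})

test_that("frequency normalization divides by replicate totals", {
  tab <- rbind(record(nseen = 3L, pos1 = 254L, pos2 = 259L),
               record(nseen = 7L))
  nf <- normalize_frequency(tab)
  expect_equal(sort(nf$records$freq), c(0.3, 0.7))
  expect_equal(sum(nf$records$freq), 1)
  # identical replicates: per-link SD is zero
  tab2 <- rbind(tab,
                transform(tab, replicate = "rep2"))
  nf2 <- normalize_frequency(tab2)
  expect_equal(nf2$per_link$sd_freq, c(0, 0))
  # raw-mean mode skips the normalization
  nfr <- normalize_frequency(tab, mode = "raw_mean")
  expect_equal(sort(nfr$records$freq), c(3, 7))
  bad <- record(nseen = 0L)
  expect_error(normalize_frequency(bad), "zero total")
})

test_that("contact-order classes follow the separation bins", {
  expect_equal(classify_contact_order(294, 298), "local")
  expect_equal(classify_contact_order(280, 311), "intermediate")
  expect_equal(classify_contact_order(280, 290), "local")
  expect_equal(classify_contact_order(244, 311), "long")
  # bin edges
  expect_equal(classify_contact_order(100, 110), "local")
  expect_equal(classify_contact_order(100, 111), "intermediate")
  expect_equal(classify_contact_order(100, 139), "intermediate")
  expect_equal(classify_contact_order(100, 140), "long")
  # symmetric in the positions
  expect_equal(classify_contact_order(311, 280),
               classify_contact_order(280, 311))
  expect_error(classify_contact_order(280, NA), "mono")
})

test_that("repeat binning uses the tau repeat bounds", {
  expect_equal(bin_by_repeat(294), "R2")
  expect_equal(bin_by_repeat(311), "R3")
  expect_equal(bin_by_repeat(243), "outside")
  expect_equal(bin_by_repeat(c(244, 274, 275, 369, 380, 381)),
               c("R1", "R1", "R2", "R'", "R'", "outside"))
  bad <- data.frame(label = c("A", "B"), start = c(1L, 5L),
                    end = c(10L, 20L))
  expect_error(bin_by_repeat(3, bad), "overlap")
})

test_that("recovered class proportions match the generator weights", {
  w <- c(0.5, 0.3, 0.2)
  n <- 1e4
  tab <- make_crosslink_tables(synthetic_link_spec(
    class_weights = w, n_replicates = 1, n_links_per_rep = n, seed = 71))
  cls <- classify_contact_order(tab$pos1, tab$pos2)
  expect_identical(cls, tab$truth_class)
  prop <- table(factor(cls, c("local", "intermediate", "long"))) / n
  # binomial error: 4 sigma on each class proportion
  for (i in 1:3)
    expect_lt(abs(prop[i] - w[i]), 4 * sqrt(w[i] * (1 - w[i]) / n))
})

test_that("link-pattern clustering recovers planted groups", {
  set.seed(61)
  # 6 constructs x 12 links, two planted column groups
  base <- rbind(matrix(1, 3, 6), matrix(0, 3, 6))
  mat <- cbind(base, 1 - base) + matrix(rnorm(6 * 12, 0, 0.05), 6, 12)
  colnames(mat) <- paste0("L", 1:12)
  res <- cluster_link_patterns(mat, n_groups = 2)
  truth <- rep(1:2, each = 6)
  expect_equal(adjusted_rand(res$groups, truth), 1.0)
  expect_length(res$groups, 12L)
  # identical columns merge at height zero
  m2 <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9))
  r2 <- cluster_link_patterns(m2, n_groups = 2)
  expect_equal(r2$hclust$height[1], 0)
  expect_equal(r2$groups[["a"]], r2$groups[["b"]])
  expect_warning(cluster_link_patterns(matrix(1, 3, 4)), "constant")
})

test_that("modification fractions normalize peak areas", {
  fr <- modification_fractions(c(unmodified = 60, monolink1 = 30,
                                 monolink2 = 10, looplink = 0))
  expect_equal(unname(fr), c(0.6, 0.3, 0.1, 0))
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  # replicate matrix: summary equals hand arithmetic
  m <- rbind(c(60, 30, 10, 0), c(50, 30, 10, 10),
             c(70, 20, 10, 0), c(60, 25, 10, 5))
  colnames(m) <- c("unmodified", "monolink1", "monolink2", "looplink")
  fr4 <- modification_fractions(m)
  expect_equal(rowSums(fr4), rep(1, 4), tolerance = 1e-12)
  sm <- attr(fr4, "summary")
  expect_equal(sm$mean, colMeans(m / rowSums(m)), ignore_attr = TRUE)
  expect_error(modification_fractions(c(0, 0)), "zero total")
})
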