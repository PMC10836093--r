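#' Filter cross-link identifications on quality thresholds
#'
#' Retains records with `score > 25`, `fdr < 0.05`, mass error within
#' `[-2.2, +3.8]` ppm, `%TIC > 10` and peptide length `>= 6` aa (the
#' xQuest post-search acceptance criteria; all thresholds configurable).
#' Per-criterion rejection counts are attached as the `"rejections"`
#' attribute; malformed rows (NA in a filtered field) are skipped and
#' counted under `malformed`.
#'
#' @param records data.frame with columns `score`, `fdr`, `mass_error_ppm`,
#'   `tic_pct`, `pep_len` (a `LinkTable` qualifies).
#' @param thresholds list with `score_min`, `fdr_max`, `ppm_range`,
#'   `tic_min`, `pep_len_min`.
#' @return the retained records, with attribute `"rejections"` (named
#'   integer vector of per-criterion rejection counts).
#' @export
filter_ids <- function(records, thresholds = xquest_default_thresholds()) {
  req <- c("score", "fdr", "mass_error_ppm", "tic_pct", "pep_len")
  if (!all(req %in% names(records)))
    stop("records lack required columns: ",
         paste(setdiff(req, names(records)), collapse = ", "))
  need <- c("score_min", "fdr_max", "ppm_range", "tic_min", "pep_len_min")
  if (!all(need %in% names(thresholds)))
    stop("thresholds incomplete: need ",
         paste(setdiff(need, names(thresholds)), collapse = ", "))
  malformed <- !stats::complete.cases(records[, req])
  ok <- records[!malformed, , drop = FALSE]
  crit <- cbind(
    score = ok$score > thresholds$score_min,
    fdr = ok$fdr < thresholds$fdr_max,
    mass_error = ok$mass_error_ppm >= thresholds$ppm_range[1] &
      ok$mass_error_ppm <= thresholds$ppm_range[2],
    tic = ok$tic_pct > thresholds$tic_min,
    pep_len = ok$pep_len >= thresholds$pep_len_min)
  keep <- rowSums(!crit) == 0
  out <- ok[keep, , drop = FALSE]
  rej <- c(colSums(!crit), malformed = sum(malformed))
  attr(out, "rejections") <- rej
  out
}

#' Replicate consensus of cross-link position pairs
#'
#' Unique `(pos1, pos2)` pairs present in at least `n_required` replicates
#' (default: all replicates, the "five out of five" rule), with the
#' per-replicate frequency (`nseen`) carried along.
#'
#' @param records filtered records with columns `pos1`, `pos2`,
#'   `replicate`, `nseen`.
#' @param n_required replicates a link must appear in (default all).
#' @return an object of class `ConsensusSet`: data.frame with `pos1`,
#'   `pos2`, `n_replicates` and one `nseen.<replicate>` column per
#'   replicate; attribute `"n_required"`.
#' @export
consensus <- function(records, n_required = NULL) {
  reps <- sort(unique(records$replicate))
  if (!length(reps)) stop("no replicates present")
  if (is.null(n_required)) n_required <- length(reps)
  key <- paste(records$pos1, records$pos2, sep = "-")
  agg <- stats::aggregate(nseen ~ key + replicate, data =
                            data.frame(key = key,
                                       replicate = records$replicate,
                                       nseen = records$nseen),
                          FUN = sum)
  wide <- stats::reshape(agg, idvar = "key", timevar = "replicate",
                         direction = "wide")
  counts <- rowSums(!is.na(wide[, -1, drop = FALSE]))
  keep <- wide[counts >= n_required, , drop = FALSE]
  pos <- do.call(rbind, strsplit(keep$key, "-", fixed = TRUE))
  out <- data.frame(pos1 = as.integer(pos[, 1]), pos2 = as.integer(pos[, 2]),
                    n_replicates = counts[counts >= n_required])
  out <- cbind(out, keep[, -1, drop = FALSE])
  out <- out[order(out$pos1, out$pos2), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ConsensusSet", "data.frame")
  attr(out, "n_required") <- n_required
  out
}

#' Within-replicate frequency normalization
#'
#' In `"replicate_total"` mode (default) each record's spectral count
#' (`nseen`) is divided by its replicate's total, so normalized values sum
#' to 1 per replicate; per-link mean and SD across replicates are then
#' reported. `"raw_mean"` mode skips the normalization and averages the raw
#' counts.
#'
#' @param records records with columns `pos1`, `pos2`, `replicate`,
#'   `nseen`.
#' @param mode `"replicate_total"` or `"raw_mean"`.
#' @return list with `records` (input plus `freq` column) and `per_link`
#'   (data.frame `pos1`, `pos2`, `mean_freq`, `sd_freq`).
#' @export
normalize_frequency <- function(records,
                                mode = c("replicate_total", "raw_mean")) {
  mode <- match.arg(mode)
  totals <- tapply(records$nseen, records$replicate, sum)
  if (any(totals <= 0)) stop("replicate with zero total nseen")
  records$freq <- if (mode == "replicate_total")
    records$nseen / as.numeric(totals[records$replicate])
  else records$nseen
  key <- interaction(records$pos1, records$pos2, drop = TRUE)
  per_link <- data.frame(
    pos1 = tapply(records$pos1, key, `[`, 1),
    pos2 = tapply(records$pos2, key, `[`, 1),
    mean_freq = tapply(records$freq, key, mean),
    sd_freq = tapply(records$freq, key, stats::sd))
  per_link <- per_link[order(per_link$pos1, per_link$pos2), ]
  rownames(per_link) <- NULL
  list(records = records, per_link = per_link)
}

# contact-order bins: local <= 10, intermediate 11-39, long >= 40 residues
classify_separation <- function(s) {
  ifelse(s <= 10, "local", ifelse(s <= 39, "intermediate", "long"))
}

#' Contact-order class of a cross-link
#'
#' Classifies by absolute residue separation `s = |pos2 - pos1|`: contacts
#' within a repeat (`local`, s <= 10), between adjacent repeats
#' (`intermediate`, 11 <= s <= 39) and long-range (`long`, s >= 40).
#' Symmetric in the two positions.
#'
#' @param pos1,pos2 1-based residue positions (vectors allowed).
#' @return character vector of classes.
#' @export
classify_contact_order <- function(pos1, pos2) {
  if (any(is.na(pos1)) || any(is.na(pos2)))
    stop("mono-links (missing second position) cannot be classified")
  classify_separation(abs(pos2 - pos1))
}

#' Default tau repeat-domain bins
#'
#' The four pseudo-repeats and the R' tail of the tau repeat domain in 2N4R
#' numbering.
#'
#' @return data.frame with columns `label`, `start`, `end`.
#' @export
tau_repeat_bins <- function() {
  data.frame(label = c("R1", "R2", "R3", "R4", "R'"),
             start = c(244L, 275L, 306L, 337L, 369L),
             end = c(274L, 305L, 336L, 368L, 380L),
             stringsAsFactors = FALSE)
}

#' Assign a residue position to a repeat bin
#'
#' Interval lookup; positions outside every bin get the explicit label
#' `"outside"`.
#'
#' @param position 1-based residue position(s).
#' @param bins data.frame with `label`, `start`, `end` (non-overlapping,
#'   ordered); defaults to [tau_repeat_bins()].
#' @return character vector of bin labels.
#' @export
bin_by_repeat <- function(position, bins = tau_repeat_bins()) {
  if (any(bins$start > bins$end)) stop("invalid bins: start > end")
  if (nrow(bins) > 1L && any(bins$start[-1] <= bins$end[-nrow(bins)]))
    stop("invalid bins: intervals overlap or are unordered")
  vapply(position, function(p) {
    hit <- which(p >= bins$start & p <= bins$end)
    if (length(hit)) bins$label[hit] else "outside"
  }, character(1))
}

#' Hierarchical clustering of cross-link frequency patterns
#'
#' Agglomerative clustering (average linkage, Euclidean distance) of the
#' link columns of a constructs-by-links normalized frequency matrix, cut
#' into `n_groups` groups. A constant matrix collapses to a single group
#' with a warning.
#'
#' @param mat numeric matrix, constructs in rows, links in columns.
#' @param n_groups number of groups to cut the dendrogram into (default 4).
#' @return list with `hclust` (the tree), `groups` (named integer labels
#'   per link column) and `n_groups`.
#' @export
cluster_link_patterns <- function(mat, n_groups = 4L) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need at least 2 links to cluster")
  d <- stats::dist(t(mat), method = "euclidean")
  if (all(d == 0)) {
    warning("constant frequency matrix; returning a single group")
    groups <- stats::setNames(rep(1L, ncol(mat)), colnames(mat))
    return(list(hclust = NULL, groups = groups, n_groups = 1L))
  }
  hc <- stats::hclust(d, method = "average")
  groups <- stats::cutree(hc, k = min(n_groups, ncol(mat)))
  list(hclust = hc, groups = groups, n_groups = max(groups))
}

#' Peptide modification fractions from peak areas
#'
#' Each species' peak area divided by the total area (per replicate);
#' fractions sum to 1.
#'
#' @param peak_areas named non-negative numeric vector (e.g. `unmodified`,
#'   `monolink1`, `monolink2`, `looplink`) or a matrix/data.frame with one
#'   row per replicate.
#' @return fractions with the same shape; for a matrix input the attribute
#'   `"summary"` holds per-species mean and SD across replicates.
#' @export
modification_fractions <- function(peak_areas) {
  if (is.matrix(peak_areas) || is.data.frame(peak_areas)) {
    m <- as.matrix(peak_areas)
    if (any(m < 0)) stop("peak areas must be >= 0")
    tot <- rowSums(m)
    if (any(tot <= 0)) stop("zero total peak area in a replicate")
    fr <- m / tot
    attr(fr, "summary") <- data.frame(species = colnames(m),
                                      mean = colMeans(fr),
                                      sd = apply(fr, 2, stats::sd))
    return(fr)
  }
  x <- as.numeric(peak_areas)
  if (any(x < 0)) stop("peak areas must be >= 0")
  if (sum(x) <= 0) stop("zero total peak area")
  stats::setNames(x / sum(x), names(peak_areas))
}
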