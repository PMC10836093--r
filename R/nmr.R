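#' Random-coil and full-structure Halpha reference shifts
#'
#' Bundled reference constants for Halpha chemical shifts: the random-coil
#' value per amino-acid type (ppm) and the expected deviation from random
#' coil in a fully formed alpha helix (negative) and beta sheet (positive).
#' Adapted from the published random-coil and secondary-structure shift
#' statistics that underpin shift-based structure-propensity calculators;
#' the table is exported so callers can substitute their own reference.
#'
#' @return data.frame with columns `aa` (one-letter code), `rc_ha` (ppm),
#'   `helix_dev`, `sheet_dev` (ppm).
#' @export
ha_reference_table <- function() {
  data.frame(
    aa = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "V", "W", "Y"),
    rc_ha = c(4.32, 4.34, 4.74, 4.64, 4.55, 4.34, 4.35, 3.96, 4.73, 4.17,
              4.34, 4.32, 4.48, 4.62, 4.42, 4.47, 4.35, 4.12, 4.66, 4.55),
    helix_dev = rep(-0.38, 20),
    sheet_dev = rep(0.38, 20),
    stringsAsFactors = FALSE)
}

#' Secondary Halpha chemical shifts
#'
#' Computes the secondary shift `delta_obs - delta_rc` per residue by
#' looking up the random-coil reference for each residue's amino-acid type.
#'
#' @param obs data.frame with columns `residue_index`, `aa` (one-letter
#'   code) and `shift_ppm` (observed Halpha shift).
#' @param rc_table reference table with columns `aa` and `rc_ha`; defaults
#'   to the bundled [ha_reference_table()].
#' @return an object of class `ShiftSeries`: data.frame with
#'   `residue_index`, `aa`, `delta_obs`, `delta_rc`, `delta` (ppm).
#' @export
secondary_shifts <- function(obs, rc_table = ha_reference_table()) {
  req <- c("residue_index", "aa", "shift_ppm")
  if (!all(req %in% names(obs)))
    stop("'obs' needs columns residue_index, aa, shift_ppm")
  obs <- obs[order(obs$residue_index), , drop = FALSE]
  hit <- match(obs$aa, rc_table$aa)
  if (any(is.na(hit)))
    stop("no random-coil reference for residue(s) ",
         paste(obs$residue_index[is.na(hit)], collapse = ", "),
         " (type ", paste(unique(obs$aa[is.na(hit)]), collapse = ", "), ")")
  out <- data.frame(residue_index = obs$residue_index, aa = obs$aa,
                    delta_obs = obs$shift_ppm,
                    delta_rc = rc_table$rc_ha[hit],
                    delta = obs$shift_ppm - rc_table$rc_ha[hit],
                    stringsAsFactors = FALSE)
  class(out) <- c("ShiftSeries", "data.frame")
  out
}

#' Neighbour-corrected secondary-structure propensity (ncSP)
#'
#' Per residue, the secondary Halpha shifts are averaged over a symmetric
#' neighbour window (truncated at the termini), normalized by the
#' full-structure reference deviation, and sign-adjusted so that positive
#' values mean helical and negative values mean extended/beta propensity
#' (Halpha shifts move upfield in helices, so the Halpha contribution enters
#' with inverted sign). Values are clamped to `[-1.5, 1.5]`; the number of
#' clamped residues is recorded. Uniform within-window weights are used.
#'
#' @param series a `ShiftSeries` from [secondary_shifts()].
#' @param window neighbour window half-width in residues (>= 1; the window
#'   at residue `i` spans `i - window .. i + window`).
#' @param ref_table reference table with columns `aa` and `sheet_dev`.
#' @return an object of class `PropensityProfile`: data.frame with
#'   `residue_index`, `aa`, `ncsp`; attribute `n_clamped`.
#' @export
ncsp <- function(series, window = 3L, ref_table = ha_reference_table()) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  n <- nrow(series)
  idx <- series$residue_index
  dev <- ref_table$sheet_dev[match(series$aa, ref_table$aa)]
  vals <- numeric(n)
  for (i in seq_len(n)) {
    in_win <- which(abs(idx - idx[i]) <= window)
    # propensity normalized by the full-structure deviation magnitude;
    # Halpha sign inverted so positive = helix
    vals[i] <- -mean(series$delta[in_win]) / mean(dev[in_win])
  }
  clamped <- sum(vals < -1.5 | vals > 1.5)
  vals <- pmin(pmax(vals, -1.5), 1.5)
  out <- data.frame(residue_index = idx, aa = series$aa, ncsp = vals,
                    stringsAsFactors = FALSE)
  class(out) <- c("PropensityProfile", "data.frame")
  attr(out, "window") <- window
  attr(out, "n_clamped") <- clamped
  out
}

#' Ensemble-averaged NOE effective distances
#'
#' For each requested atom pair, `r_eff = (mean over frames of r^-6)^(-1/6)`
#' -- the r^-6-weighted average that governs NOESY cross-peak intensities.
#' Short-distance frames dominate, so `min(r) <= r_eff <= mean(r)`. Pairs
#' with `r_eff` below the threshold are flagged as observable (~4 A for a
#' short peptide).
#'
#' @param ens a `ConformerEnsemble`.
#' @param pairs data.frame with columns `resno1`, `elety1`, `resno2`,
#'   `elety2` naming the atoms of each pair (Calpha proxies are accepted for
#'   Calpha-only fixtures; the observability threshold is calibrated for
#'   protons).
#' @param threshold observability threshold, Angstrom.
#' @return an object of class `EffectiveDistanceMap`: data.frame with pair
#'   labels, `r_eff`, `r_min`, `r_mean` and `observable`.
#' @export
noe_effective_distances <- function(ens, pairs, threshold = 4.0) {
  req <- c("resno1", "elety1", "resno2", "elety2")
  if (!all(req %in% names(pairs)))
    stop("'pairs' needs columns resno1, elety1, resno2, elety2")
  find_atom <- function(resno, elety) {
    i <- which(ens$atoms$resno == resno & ens$atoms$elety == elety)
    if (!length(i))
      stop("atom ", elety, " of residue ", resno, " not found")
    i[1]
  }
  i1 <- mapply(find_atom, pairs$resno1, pairs$elety1)
  i2 <- mapply(find_atom, pairs$resno2, pairs$elety2)
  np <- nrow(pairs)
  nf <- n_frames(ens)
  r <- matrix(NA_real_, nf, np)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(ens, f)
    r[f, ] <- sqrt(rowSums((xyz[i1, , drop = FALSE] -
                              xyz[i2, , drop = FALSE])^2))
  }
  if (any(r == 0))
    stop("zero inter-atomic distance encountered (nonphysical overlap)")
  r_eff <- colMeans(r^-6)^(-1 / 6)
  out <- data.frame(
    pair = paste0(pairs$resno1, ".", pairs$elety1, "-",
                  pairs$resno2, ".", pairs$elety2),
    r_eff = r_eff,
    r_min = apply(r, 2, min),
    r_mean = colMeans(r),
    observable = r_eff < threshold,
    stringsAsFactors = FALSE)
  class(out) <- c("EffectiveDistanceMap", "data.frame")
  attr(out, "threshold") <- threshold
  out
}
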