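#' Mean minimum inter-residue distance map
#'
#' Entry `(i, j)` is the mean over frames of the minimum atom-atom distance
#' between residues `i` and `j` within the selection (the `gmx mdmat`-style
#' contact map). The result is symmetric with a zero diagonal.
#'
#' @param ens a `ConformerEnsemble`.
#' @param resno,elety atom selection (see [select_atoms()]).
#' @return an object of class `DistanceMap`: list with `residues` (index
#'   vector), `values` (square matrix, Angstrom) and `units`.
#' @export
min_distance_map <- function(ens, resno = NULL, elety = NULL) {
  sel <- select_atoms(ens, resno = resno, elety = elety)
  res <- sort(unique(ens$atoms$resno[sel]))
  if (length(res) < 2L) stop("selection must span at least 2 residues")
  rid <- match(ens$atoms$resno[sel], res)
  nr <- length(res)
  acc <- matrix(0, nr, nr)
  for (f in seq_len(n_frames(ens))) {
    D <- as.matrix(stats::dist(frame_coords(ens, f)[sel, , drop = FALSE]))
    M <- matrix(Inf, nr, nr)
    for (i in seq_len(nr)) {
      ai <- which(rid == i)
      for (j in seq_len(nr)) {
        if (j <= i) next
        M[i, j] <- min(D[ai, rid == j])
      }
    }
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    diag(M) <- 0
    acc <- acc + M
  }
  structure(list(residues = res, values = acc / n_frames(ens),
                 units = "angstrom"),
            class = "DistanceMap")
}

#' Per-frame distance between group centroids
#'
#' Euclidean distance between the (optionally mass-weighted) centroids of
#' two disjoint residue groups, evaluated on the atom selection in every
#' frame.
#'
#' @param ens a `ConformerEnsemble`.
#' @param groupA,groupB disjoint, non-empty residue index sets.
#' @param elety atom-name filter applied within each group (default all).
#' @param mass_weighted weight atoms by element mass inferred from the atom
#'   name (default `FALSE`, plain centroid; identical for Calpha-only
#'   ensembles).
#' @return numeric vector, one distance (Angstrom) per frame.
#' @export
group_com_distance <- function(ens, groupA, groupB, elety = NULL,
                               mass_weighted = FALSE) {
  if (!length(groupA) || !length(groupB)) stop("groups must be non-empty")
  if (length(intersect(groupA, groupB)))
    stop("groups must be disjoint")
  selA <- select_atoms(ens, resno = groupA, elety = elety)
  selB <- select_atoms(ens, resno = groupB, elety = elety)
  wA <- if (mass_weighted) atom_masses(ens$atoms$elety[selA]) else
    rep(1, length(selA))
  wB <- if (mass_weighted) atom_masses(ens$atoms$elety[selB]) else
    rep(1, length(selB))
  vapply(seq_len(n_frames(ens)), function(f) {
    xyz <- frame_coords(ens, f)
    ca <- colSums(xyz[selA, , drop = FALSE] * wA) / sum(wA)
    cb <- colSums(xyz[selB, , drop = FALSE] * wB) / sum(wB)
    sqrt(sum((ca - cb)^2))
  }, numeric(1))
}

# element masses from the leading element letter of a PDB atom name
atom_masses <- function(elety) {
  el <- substr(gsub("^[0-9]", "", elety), 1, 1)
  m <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)
  out <- m[el]
  out[is.na(out)] <- 12.011
  unname(out)
}

#' Beta-hairpin turn-register ratio
#'
#' Computes, per frame, `rho = d(CA_i4, CA_i12) / d(CA_i7, CA_i12)` for the
#' three role residues and classifies the turn register: `rho < 0.75` left-
#' shifted, `rho > 1` right-shifted, otherwise centered. The ratio is
#' invariant under rigid motions and uniform scaling of the coordinates.
#' Frames with a coincident-atom zero denominator are flagged and excluded
#' from the summary with a warning count.
#'
#' @param ens a `ConformerEnsemble` (Calpha atoms are used).
#' @param role_indices integer vector `c(i4, i7, i12)` naming which absolute
#'   residues play roles 4, 7 and 12 of the statistic.
#' @return an object of class `RegisterProfile`: list with per-frame `ratio`,
#'   `classification`, `index_map`, `n_degenerate` and a `summary` row
#'   (mean/sd over valid frames).
#' @export
turn_register <- function(ens, role_indices = c(4L, 7L, 12L)) {
  ri <- as.integer(role_indices)
  if (length(ri) != 3L || anyDuplicated(ri))
    stop("role_indices must be three distinct residue indices")
  idx <- vapply(ri, function(r) {
    i <- which(ens$atoms$resno == r & ens$atoms$elety == "CA")
    if (!length(i)) stop("residue ", r, " has no CA atom in the ensemble")
    i[1]
  }, integer(1))
  nf <- n_frames(ens)
  ratio <- numeric(nf)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(ens, f)
    d412 <- sqrt(sum((xyz[idx[1], ] - xyz[idx[3], ])^2))
    d712 <- sqrt(sum((xyz[idx[2], ] - xyz[idx[3], ])^2))
    ratio[f] <- if (d712 == 0) NA_real_ else d412 / d712
  }
  n_bad <- sum(is.na(ratio))
  if (n_bad > 0)
    warning(n_bad, " frame(s) had coincident role atoms and were excluded")
  cls <- ifelse(is.na(ratio), NA_character_,
                ifelse(ratio < 0.75, "left",
                       ifelse(ratio > 1, "right", "centered")))
  ok <- !is.na(ratio)
  structure(list(ratio = ratio, classification = cls,
                 index_map = stats::setNames(ri, c("res4", "res7", "res12")),
                 n_degenerate = n_bad,
                 summary = c(mean = mean(ratio[ok]),
                             sd = stats::sd(ratio[ok]))),
            class = "RegisterProfile")
}

# Kabsch optimal superposition of mobile onto ref (n x 3 matrices);
# returns the rotated+translated mobile coordinates
kabsch_fit <- function(mobile, ref) {
  mc <- colMeans(mobile); rc <- colMeans(ref)
  A <- sweep(mobile, 2, mc); B <- sweep(ref, 2, rc)
  s <- svd(crossprod(A, B))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(A %*% t(R), 2, rc, `+`)
}

#' Root-mean-square deviation after least-squares superposition
#'
#' Optimal rotation + translation (Kabsch), then RMSD, using the same atom
#' selection for fitting and measurement (as `gmx rms` does by default).
#'
#' @param mobile,ref coordinate matrices `n x 3` (same atom count), or
#'   frames extracted with [frame_coords()].
#' @param fit superpose before measuring (default `TRUE`).
#' @return RMSD in Angstrom (>= 0).
#' @export
rmsd_fit <- function(mobile, ref, fit = TRUE) {
  mobile <- as.matrix(mobile); ref <- as.matrix(ref)
  if (!all(dim(mobile) == dim(ref)))
    stop("atom mismatch: mobile and reference differ in size")
  if (fit) mobile <- kabsch_fit(mobile, ref)
  sqrt(mean(rowSums((mobile - ref)^2)))
}

#' Pairwise (2-D) RMSD matrix over strided frames
#'
#' @param ens a `ConformerEnsemble`.
#' @param stride keep every `stride`-th frame (>= 1).
#' @param resno,elety atom selection.
#' @return list with `frames` (indices used) and `values` (symmetric
#'   zero-diagonal matrix, Angstrom).
#' @export
pairwise_rmsd <- function(ens, stride = 1L, resno = NULL, elety = NULL) {
  stopifnot(stride >= 1L)
  sel <- select_atoms(ens, resno = resno, elety = elety)
  frames <- seq(1L, n_frames(ens), by = stride)
  xyz <- lapply(frames, function(f)
    frame_coords(ens, f)[sel, , drop = FALSE])
  n <- length(frames)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    M[i, j] <- M[j, i] <- rmsd_fit(xyz[[i]], xyz[[j]])
  }
  list(frames = frames, values = M)
}

#' GROMOS conformational clustering
#'
#' The greedy neighbour-count algorithm: the frame with the most neighbours
#' within the RMSD cutoff (fitted RMSD) becomes a cluster centre; it and its
#' neighbours are removed and the procedure repeats. Ties in neighbour count
#' are broken by lowest frame index, so output is deterministic. Clusters
#' are returned in decreasing size order.
#'
#' @param ens a `ConformerEnsemble`.
#' @param cutoff RMSD cutoff, in `cutoff_unit`.
#' @param cutoff_unit `"angstrom"` (default) or `"nm"` (converted at the
#'   boundary; all internal geometry is Angstrom).
#' @param resno,elety atom selection.
#' @return an object of class `ClusterResult`: list with `cutoff` (Angstrom),
#'   `assignments` (frame -> cluster label, 1 = largest), `populations`
#'   (fractions, sum 1), `centers` (central frame index per cluster).
#' @export
gromos_cluster <- function(ens, cutoff, cutoff_unit = c("angstrom", "nm"),
                           resno = NULL, elety = NULL) {
  cutoff_unit <- match.arg(cutoff_unit)
  if (cutoff_unit == "nm") cutoff <- cutoff * 10
  if (!isTRUE(cutoff > 0)) stop("cutoff must be > 0")
  nf <- n_frames(ens)
  if (nf < 1L) stop("empty ensemble")
  D <- pairwise_rmsd(ens, stride = 1L, resno = resno, elety = elety)$values
  gromos_cluster_from_matrix(D, cutoff)
}

# core greedy rule on a precomputed RMSD matrix (also used by the
# brute-force test oracle via an independent implementation)
gromos_cluster_from_matrix <- function(D, cutoff) {
  nf <- nrow(D)
  remaining <- rep(TRUE, nf)
  assignments <- integer(nf)
  centers <- integer(0)
  sizes <- integer(0)
  k <- 0L
  while (any(remaining)) {
    idx <- which(remaining)
    counts <- vapply(idx, function(i)
      sum(D[i, idx] <= cutoff), integer(1))   # includes self
    center <- idx[which.max(counts)]          # which.max: first max wins
    members <- idx[D[center, idx] <= cutoff]
    k <- k + 1L
    assignments[members] <- k
    centers[k] <- center
    sizes[k] <- length(members)
    remaining[members] <- FALSE
  }
  ord <- order(-sizes, centers)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  structure(list(cutoff = cutoff,
                 assignments = relabel[assignments],
                 populations = sizes[ord] / nf,
                 centers = centers[ord]),
            class = "ClusterResult")
}
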