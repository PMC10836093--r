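#' Conformer ensemble container
#'
#' A `ConformerEnsemble` holds an ordered set of frames (conformers) sharing a
#' single atom table. Coordinates are stored in Angstrom as a numeric array of
#' dimension `n_frames x n_atoms x 3`; the atom table records 1-based residue
#' numbers, residue names and atom names (PDB conventions).
#'
#' @param coords numeric array `n_frames x n_atoms x 3`, in Angstrom.
#' @param atoms data.frame with columns `resno` (integer, 1-based), `resid`
#'   (3-letter residue name) and `elety` (atom name, e.g. `"CA"`).
#' @param metadata named list of provenance fields (source, seed, dt_ps, ...).
#'
#' @return An object of class `ConformerEnsemble`.
#' @export
conformer_ensemble <- function(coords, atoms, metadata = list()) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("'coords' must be an n_frames x n_atoms x 3 array")
  if (!all(is.finite(coords)))
    stop("coordinates must be finite")
  req <- c("resno", "resid", "elety")
  if (!all(req %in% names(atoms)))
    stop("'atoms' must have columns resno, resid, elety")
  if (nrow(atoms) != dim(coords)[2])
    stop("atom table rows (", nrow(atoms), ") != atom count in coords (",
         dim(coords)[2], ")")
  structure(list(coords = coords,
                 atoms = data.frame(resno = as.integer(atoms$resno),
                                    resid = as.character(atoms$resid),
                                    elety = as.character(atoms$elety),
                                    stringsAsFactors = FALSE),
                 metadata = metadata),
            class = "ConformerEnsemble")
}

#' @export
print.ConformerEnsemble <- function(x, ...) {
  cat("ConformerEnsemble:", n_frames(x), "frames,", n_atoms(x), "atoms,",
      length(unique(x$atoms$resno)), "residues\n")
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames / atoms in an ensemble
#' @param ens a `ConformerEnsemble`.
#' @return integer count.
#' @export
n_frames <- function(ens) dim(ens$coords)[1]

#' @rdname n_frames
#' @export
n_atoms <- function(ens) dim(ens$coords)[2]

#' Extract one frame as an atom-by-3 coordinate matrix
#' @param ens a `ConformerEnsemble`.
#' @param i frame index.
#' @return numeric matrix `n_atoms x 3`.
#' @export
frame_coords <- function(ens, i) {
  stopifnot(i >= 1, i <= n_frames(ens))
  matrix(ens$coords[i, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Select atoms by residue number and/or atom name
#'
#' All geometry operations accept this selection so that Calpha-only fixtures
#' and full-backbone inputs go through the same code path.
#'
#' @param ens a `ConformerEnsemble`.
#' @param resno residue numbers to keep (default all).
#' @param elety atom names to keep (default all).
#' @return integer vector of atom indices (into the atom table).
#' @export
select_atoms <- function(ens, resno = NULL, elety = NULL) {
  keep <- rep(TRUE, n_atoms(ens))
  if (!is.null(resno)) keep <- keep & ens$atoms$resno %in% resno
  if (!is.null(elety)) keep <- keep & ens$atoms$elety %in% elety
  idx <- which(keep)
  if (length(idx) == 0L) stop("atom selection is empty")
  idx
}

#' Concatenate ensembles frame-wise
#'
#' Ensembles must share an identical atom table; used e.g. to mix hairpin and
#' extended synthetic frames into one ensemble.
#'
#' @param ... `ConformerEnsemble` objects.
#' @return a `ConformerEnsemble` with the frames of all inputs, in order.
#' @export
bind_ensembles <- function(...) {
  ens <- list(...)
  stopifnot(length(ens) >= 1L)
  ref <- ens[[1]]$atoms
  for (e in ens)
    if (!identical(e$atoms, ref))
      stop("cannot bind ensembles with differing atom tables")
  coords <- do.call(abind3, lapply(ens, `[[`, "coords"))
  conformer_ensemble(coords, ref,
                     metadata = list(source = "bind_ensembles",
                                     n_input = length(ens)))
}

# row-bind 3-d arrays along the first (frame) dimension
abind3 <- function(...) {
  arrs <- list(...)
  nf <- vapply(arrs, function(a) dim(a)[1], integer(1))
  na <- dim(arrs[[1]])[2]
  out <- array(NA_real_, dim = c(sum(nf), na, 3L))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

# standard CA atom table for a poly-alanine pseudo-chain of n residues
ca_atom_table <- function(n_res) {
  data.frame(resno = seq_len(n_res), resid = "ALA", elety = "CA",
             stringsAsFactors = FALSE)
}
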