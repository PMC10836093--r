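#' Write an ensemble as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame, chain A, 1-based residue numbering,
#' coordinates at PDB precision (3 decimals, Angstrom).
#'
#' @param ens a `ConformerEnsemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ens, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  atoms <- ens$atoms
  name4 <- ifelse(nchar(atoms$elety) < 4L,
                  sprintf("%-4s", paste0(" ", atoms$elety)),
                  sprintf("%-4s", atoms$elety))
  for (f in seq_len(n_frames(ens))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(ens, f)
    writeLines(sprintf(
      "ATOM  %5d %s%3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
      seq_len(nrow(atoms)), name4, atoms$resid, atoms$resno,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
      substr(atoms$elety, 1, 1)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file into a ConformerEnsemble
#'
#' Frames are ordered by MODEL index; residue numbering is preserved as-is.
#' Models with inconsistent atom tables raise an error citing the first
#' offending MODEL number.
#'
#' @param path PDB file path.
#' @param format input format (only `"pdb_multimodel"`).
#' @return a `ConformerEnsemble`.
#' @export
read_ensemble <- function(path, format = c("pdb_multimodel")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  # light pre-scan: per-MODEL atom counts must agree
  lines <- readLines(path)
  model_ix <- grep("^MODEL", lines)
  if (length(model_ix) > 1L) {
    end_ix <- grep("^ENDMDL", lines)
    n_atoms_per <- mapply(function(a, b)
      sum(grepl("^ATOM|^HETATM", lines[a:b])), model_ix, end_ix)
    if (length(unique(n_atoms_per)) > 1L) {
      bad <- which(n_atoms_per != n_atoms_per[1])[1]
      stop("inconsistent atom table in MODEL ", bad,
           " (", n_atoms_per[bad], " atoms vs ", n_atoms_per[1],
           " in MODEL 1)")
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3L
  coords <- array(NA_real_, dim = c(nf, na, 3L))
  for (f in seq_len(nf))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  conformer_ensemble(coords,
                     data.frame(resno = pdb$atom$resno,
                                resid = pdb$atom$resid,
                                elety = pdb$atom$elety,
                                stringsAsFactors = FALSE),
                     metadata = list(source = path))
}

#' Subsample a trajectory to a coarser time step
#'
#' Keeps frames at times `0, target_dt, 2 * target_dt, ...`; the first
#' frame is always kept and the final frame is kept when it falls on the
#' grid. `target_dt` must be an integer multiple of the source step, so for
#' an on-grid span `T` the result has `floor(T / target_dt) + 1` frames
#' (e.g. a 3 us span at a 100 ps target gives 30001 frames).
#'
#' @param x a `FeatureTrajectory`, `ConformerEnsemble`, or plain matrix of
#'   frames in rows.
#' @param target_dt desired time step (same unit as `source_dt`).
#' @param source_dt time step of `x`; taken from the object when absent.
#' @return the same type of object, reduced.
#' @export
subsample_trajectory <- function(x, target_dt, source_dt = NULL) {
  if (is.null(source_dt)) {
    source_dt <- if (inherits(x, "FeatureTrajectory")) x$dt
    else if (inherits(x, "ConformerEnsemble")) x$metadata$dt
    else stop("source_dt must be given for a plain matrix")
    if (is.null(source_dt)) stop("object carries no time step metadata")
  }
  ratio <- target_dt / source_dt
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("target_dt must be an integer multiple of the source time step")
  stride <- as.integer(round(ratio))
  if (inherits(x, "FeatureTrajectory")) {
    keep <- seq(1L, nrow(x$values), by = stride)
    x$values <- x$values[keep, , drop = FALSE]
    x$dt <- target_dt
    return(x)
  }
  if (inherits(x, "ConformerEnsemble")) {
    keep <- seq(1L, n_frames(x), by = stride)
    x$coords <- x$coords[keep, , , drop = FALSE]
    x$metadata$dt <- target_dt
    return(x)
  }
  x[seq(1L, nrow(x), by = stride), , drop = FALSE]
}

#' DSS cross-linker reference constants
#'
#' Isotope-pair mass shifts of the disuccinimidyl suberate (d0/d12)
#' cross-linker, carried for input validation and provenance only (no
#' spectral processing is performed).
#'
#' @return named list of mass constants (Da) and the spacer length (A).
#' @export
dss_constants <- function() {
  list(crosslink_shift_da = 138.0680796,
       monolink_shift_da = c(156.0786442, 155.0964278),
       isotope_pair_delta_da = 12.075321,
       spacer_arm_angstrom = 11.4)
}
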