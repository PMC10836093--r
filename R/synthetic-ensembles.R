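#' Specification for an idealized beta-hairpin Calpha ensemble
#'
#' Describes an 18-residue-style beta hairpin as two antiparallel straight
#' strands joined by a symmetric two-residue turn. The cross-strand register
#' follows the pairing rule `i <-> 2*apex + 1 - i`: residue `i` on the
#' N-terminal strand faces residue `2*apex+1-i` on the C-terminal strand at
#' distance `strand_sep`. Residues `apex` and `apex+1` form the turn itself
#' and dip below the strands so that every consecutive virtual Calpha-Calpha
#' bond measures exactly `rise` (3.8 A by default, the canonical trans
#' Calpha spacing).
#'
#' @param n_res residue count (>= 4).
#' @param apex index of the residue immediately N-terminal of the turn apex
#'   (1-based; `2 <= apex <= n_res - 2`).
#' @param strand_sep cross-strand Calpha-Calpha pairing distance, Angstrom.
#' @param rise per-residue strand rise, Angstrom.
#' @param noise_sd isotropic Gaussian coordinate noise, Angstrom (>= 0).
#' @param n_frames number of frames to generate.
#' @param seed RNG seed (one global RNG is seeded per generator call).
#'
#' @return list of class `HairpinSpec`.
#' @export
hairpin_spec <- function(n_res = 18L, apex = 9L, strand_sep = 4.8,
                         rise = 3.8, noise_sd = 0, n_frames = 1L,
                         seed = 1L) {
  spec <- list(n_res = as.integer(n_res), apex = as.integer(apex),
               strand_sep = strand_sep, rise = rise, noise_sd = noise_sd,
               n_frames = as.integer(n_frames), seed = as.integer(seed))
  class(spec) <- "HairpinSpec"
  validate_hairpin_spec(spec)
  spec
}

validate_hairpin_spec <- function(spec) {
  if (spec$n_res < 4L) stop("invalid HairpinSpec: n_res must be >= 4")
  if (spec$apex < 2L || spec$apex > spec$n_res - 2L)
    stop("invalid HairpinSpec: apex must satisfy 2 <= apex <= n_res - 2")
  if (!isTRUE(spec$strand_sep > 0))
    stop("invalid HairpinSpec: strand_sep must be > 0")
  if (!isTRUE(spec$rise > 0)) stop("invalid HairpinSpec: rise must be > 0")
  if (!isTRUE(spec$noise_sd >= 0))
    stop("invalid HairpinSpec: noise_sd must be >= 0")
  if (spec$n_frames < 1L) stop("invalid HairpinSpec: n_frames must be >= 1")
  invisible(spec)
}

# Noiseless hairpin template coordinates (n_res x 3).
#
# Strand residues i <= apex-1 sit at x = 0, their partners 2*apex+1-i at
# x = strand_sep, both at z = (apex - 1 - i) * rise, so all strand pairs are
# exactly strand_sep apart. Turn residues apex and apex+1 sit symmetrically
# at x = (strand_sep -+ bond)/2 below z = 0 with all three bridging bonds
# equal to `bond` (= rise); this requires strand_sep < 3 * bond.
hairpin_template <- function(spec) {
  n <- spec$n_res; a <- spec$apex; sep <- spec$strand_sep; rise <- spec$rise
  bond <- rise
  if (sep >= 3 * bond)
    stop("invalid HairpinSpec: strand_sep too large for a ", bond,
         " A-bonded turn (needs strand_sep < ", 3 * bond, ")")
  xt <- (sep - bond) / 2
  h <- sqrt(bond^2 - xt^2)
  xyz <- matrix(0, nrow = n, ncol = 3)
  for (i in seq_len(n)) {
    if (i <= a - 1L) {                       # N-terminal strand
      xyz[i, ] <- c(0, 0, (a - 1L - i) * rise)
    } else if (i == a) {                     # turn, N side
      xyz[i, ] <- c(xt, 0, -h)
    } else if (i == a + 1L) {                # turn, C side
      xyz[i, ] <- c(sep - xt, 0, -h)
    } else {                                 # C-terminal strand
      xyz[i, ] <- c(sep, 0, (i - (a + 2L)) * rise)
    }
  }
  xyz
}

#' Generate an idealized beta-hairpin Calpha ensemble
#'
#' Builds `n_frames` copies of the noiseless hairpin template described by
#' the spec, each perturbed by isotropic Gaussian noise of sd `noise_sd`.
#' Deterministic for a fixed spec (the seed is part of the spec).
#'
#' @param spec a [hairpin_spec()].
#' @return a [conformer_ensemble()] of Calpha pseudo-atoms.
#' @export
#' @examples
#' ens <- make_hairpin_ensemble(hairpin_spec(n_res = 18, apex = 9))
#' sqrt(sum((frame_coords(ens, 1)[9, ] - frame_coords(ens, 1)[10, ])^2))
make_hairpin_ensemble <- function(spec) {
  validate_hairpin_spec(spec)
  tmpl <- hairpin_template(spec)
  set.seed(spec$seed)
  coords <- array(NA_real_, dim = c(spec$n_frames, spec$n_res, 3L))
  for (f in seq_len(spec$n_frames)) {
    noise <- if (spec$noise_sd > 0)
      matrix(stats::rnorm(spec$n_res * 3L, sd = spec$noise_sd), ncol = 3L)
    else 0
    coords[f, , ] <- tmpl + noise
  }
  conformer_ensemble(coords, ca_atom_table(spec$n_res),
                     metadata = list(source = "make_hairpin_ensemble",
                                     apex = spec$apex,
                                     strand_sep = spec$strand_sep,
                                     noise_sd = spec$noise_sd,
                                     seed = spec$seed))
}

#' Generate a fully extended Calpha chain ensemble
#'
#' A straight-line chain with 3.8 A Calpha spacing plus optional isotropic
#' Gaussian noise; the noiseless inter-residue distance is
#' `(j - i) * 3.8` A for any residue pair `i < j`.
#'
#' @param n_res residue count (>= 2).
#' @param noise_sd isotropic Gaussian coordinate noise, Angstrom.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return a [conformer_ensemble()] of Calpha pseudo-atoms.
#' @export
make_extended_ensemble <- function(n_res = 18L, noise_sd = 0,
                                   n_frames = 1L, seed = 1L) {
  n_res <- as.integer(n_res)
  if (n_res < 2L) stop("invalid spec: n_res must be >= 2")
  if (!isTRUE(noise_sd >= 0)) stop("invalid spec: noise_sd must be >= 0")
  tmpl <- cbind(0, 0, (seq_len(n_res) - 1L) * 3.8)
  set.seed(seed)
  coords <- array(NA_real_, dim = c(n_frames, n_res, 3L))
  for (f in seq_len(n_frames)) {
    noise <- if (noise_sd > 0)
      matrix(stats::rnorm(n_res * 3L, sd = noise_sd), ncol = 3L)
    else 0
    coords[f, , ] <- tmpl + noise
  }
  conformer_ensemble(coords, ca_atom_table(n_res),
                     metadata = list(source = "make_extended_ensemble",
                                     noise_sd = noise_sd, seed = seed))
}
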