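# Unit conversions. I/O is in angstrom and electron volts; all internal
# energetics are computed in atomic units (bohr, hartree, elementary charge).

ANG_PER_BOHR <- 0.52917721
EV_PER_HARTREE <- 27.211386
KCALMOL_PER_HARTREE <- 627.509474

#' Unit conversions between angstrom/bohr and hartree/eV
#'
#' File I/O and user-facing geometry are in angstrom; energies are reported
#' in eV. All internal energetics use atomic units.
#'
#' @param x numeric vector to convert.
#' @return converted numeric vector.
#' @name units
NULL

#' @rdname units
#' @export
ang_to_bohr <- function(x) x / ANG_PER_BOHR

#' @rdname units
#' @export
bohr_to_ang <- function(x) x * ANG_PER_BOHR

#' @rdname units
#' @export
hartree_to_ev <- function(x) x * EV_PER_HARTREE

#' @rdname units
#' @export
ev_to_hartree <- function(x) x / EV_PER_HARTREE

# Component vocabulary: the solute is partitioned into BASE/RIBOSE/PHOSPHATE;
# every solvent atom is WATER.
COMPONENT_LEVELS <- c("BASE", "RIBOSE", "PHOSPHATE", "WATER")
SOLUTE_COMPONENTS <- c("BASE", "RIBOSE", "PHOSPHATE")

# TIP3P-like rigid water reference geometry (angstrom / degrees).
WATER_OH_ANG <- 0.9572
WATER_HOH_DEG <- 104.52
WATER_HH_ANG <- 2 * WATER_OH_ANG * sin(WATER_HOH_DEG / 2 * pi / 180)

# Screening length (bohr) for classical point-charge electrostatics
# (QM-MM embedding and MM-MM terms); avoids the bare-Coulomb singularity
# for close contacts during geometry relaxation.
CLASSICAL_SCREEN_BOHR <- 0.7
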