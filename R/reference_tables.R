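#' Literature reference tables for aqueous DNA nucleotide ionization
#'
#' Published QM/MM ensemble means and standard errors (40 snapshots) for
#' the four deoxyribonucleotide anions in water: vertical and adiabatic
#' ionization energies (eV) per framework, released energies (eV), and
#' component-resolved hole distributions (a.u.). Shipped as package data
#' for bookkeeping worked examples and cross-checks.
#'
#' @return list of data.frames: `vie`, `aie`, `released`,
#'   `holes_vertical`, `holes_adiabatic`.
#' @export
reference_tables <- function() {
  dir <- system.file("extdata", "reference", package = "qmmmion",
                     mustWork = TRUE)
  rd <- function(f) utils::read.csv(file.path(dir, f),
                                    stringsAsFactors = FALSE)
  list(vie = rd("vie.csv"), aie = rd("aie.csv"),
       released = rd("released.csv"),
       holes_vertical = rd("holes_vertical.csv"),
       holes_adiabatic = rd("holes_adiabatic.csv"))
}

#' Assemble released energies from reference VIE and AIE tables
#'
#' Framework bookkeeping on printed ensemble means: for each nucleotide,
#' `released[f] = VIE[f] - AIE[f]`, using the identity
#' `VIE[pol] = VIE[qmm]` for the polarized framework (the published VIE
#' tables list one column for both).
#'
#' @param tables output of [reference_tables()] (default) or a list with
#'   compatible `vie`/`aie` entries.
#' @return data.frame `nucleotide`, `framework`, `released` (eV).
#' @export
released_from_reference <- function(tables = reference_tables()) {
  vie <- tables$vie; aie <- tables$aie
  out <- aie[, c("nucleotide", "framework")]
  out$released <- vapply(seq_len(nrow(out)), function(i) {
    f <- out$framework[i]
    vf <- if (f == "pol") "qmm" else f
    v <- vie$mean[vie$nucleotide == out$nucleotide[i] & vie$framework == vf]
    a <- aie$mean[aie$nucleotide == out$nucleotide[i] &
                    aie$framework == f]
    v - a
  }, numeric(1))
  out
}

#' Build record-generator targets from the reference tables
#'
#' Maps one nucleotide's reference rows onto the quantity vocabulary of
#' [generate_records()] (VIE/AIE per framework and vertical/adiabatic
#' solute-component holes).
#'
#' @param nucleotide `"dAMP"`, `"dGMP"`, `"dCMP"` or `"dTMP"`.
#' @param tables output of [reference_tables()].
#' @return data.frame `quantity`, `mean`, `se`.
#' @export
reference_record_targets <- function(nucleotide = "dAMP",
                                     tables = reference_tables()) {
  vie <- tables$vie; aie <- tables$aie
  hv <- tables$holes_vertical; ha <- tables$holes_adiabatic
  out <- data.frame(
    quantity = c("vie_qmm", "vie_gas", "aie_qmm", "aie_pol", "aie_gas",
                 "hole_v_BASE", "hole_v_RIBOSE", "hole_v_PHOSPHATE",
                 "hole_a_BASE", "hole_a_RIBOSE", "hole_a_PHOSPHATE"),
    stringsAsFactors = FALSE)
  grab <- function(df, cond) {
    r <- df[cond, , drop = FALSE]
    stopifnot(nrow(r) == 1L)
    c(r$mean, r$se)
  }
  vals <- rbind(
    grab(vie, vie$nucleotide == nucleotide & vie$framework == "qmm"),
    grab(vie, vie$nucleotide == nucleotide & vie$framework == "gas"),
    grab(aie, aie$nucleotide == nucleotide & aie$framework == "qmm"),
    grab(aie, aie$nucleotide == nucleotide & aie$framework == "pol"),
    grab(aie, aie$nucleotide == nucleotide & aie$framework == "gas"),
    grab(hv, hv$nucleotide == nucleotide & hv$embedding == "qmm" &
           hv$component == "BASE"),
    grab(hv, hv$nucleotide == nucleotide & hv$embedding == "qmm" &
           hv$component == "RIBOSE"),
    grab(hv, hv$nucleotide == nucleotide & hv$embedding == "qmm" &
           hv$component == "PHOSPHATE"),
    grab(ha, ha$nucleotide == nucleotide & ha$component == "BASE"),
    grab(ha, ha$nucleotide == nucleotide & ha$component == "RIBOSE"),
    grab(ha, ha$nucleotide == nucleotide & ha$component == "PHOSPHATE"))
  out$mean <- vals[, 1]
  out$se <- vals[, 2]
  out
}
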