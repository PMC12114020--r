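# Per-snapshot ionization analysis: vertical and adiabatic ionization
# energies and released energies in the three frameworks (QM/MM,
# polarized-QM, gas-QM), plus component-resolved hole profiles from ESP
# charge differences.
#
# Framework bookkeeping, from four state energies per framework:
#   VIE[f]      = E_f(neutral @ anion geometry)  - E_f(anion @ anion geometry)
#   AIE[f]      = E_f(neutral @ neutral geometry) - E_f(anion @ anion geometry)
#   released[f] = E_f(neutral @ anion geometry)  - E_f(neutral @ neutral geometry)
# so released = VIE - AIE exactly when assembled from the same energies.
# The QM/MM and polarized-QM VIEs are identical because the van der Waals
# and MM terms do not depend on the electronic state at fixed geometry.

framework_energy <- function(state, framework) {
  switch(framework,
         qmm = state$e_total,
         pol = state$e_pol_or_gas_qm,
         gas = state$e_pol_or_gas_qm,
         stop("unknown framework: ", framework))
}

check_same_geometry <- function(a, b) {
  if (!identical(a$geometry_ref, b$geometry_ref))
    stop("alignment error: state results are not at the same geometry (",
         a$geometry_ref$tag, " vs ", b$geometry_ref$tag, ")")
}

#' Vertical ionization energies in the three frameworks
#'
#' The VIE is the difference between the single-point energies of the
#' neutral and anionic species at the (anion-optimized) input geometry.
#' The QM/MM value equals the polarized-QM value identically, because the
#' classical terms cancel between states at fixed geometry.
#'
#' @param anion_pol,neutral_pol POLARIZED `state_result`s at the anion
#'   geometry.
#' @param anion_gas,neutral_gas GAS `state_result`s at the same geometry,
#'   or `NULL` to skip the gas framework.
#' @return named numeric (eV): `qmm`, `pol`, `gas`.
#' @export
compute_vie <- function(anion_pol, neutral_pol, anion_gas = NULL,
                        neutral_gas = NULL) {
  check_same_geometry(anion_pol, neutral_pol)
  if (anion_pol$state_tag != "ANION" || neutral_pol$state_tag != "NEUTRAL")
    stop("domain error: expected an ANION and a NEUTRAL state result")
  gas <- NA_real_
  if (!is.null(anion_gas)) {
    check_same_geometry(anion_gas, neutral_gas)
    gas <- hartree_to_ev(framework_energy(neutral_gas, "gas") -
                           framework_energy(anion_gas, "gas"))
  }
  # the classical terms are state-independent at fixed geometry, so the
  # QM/MM VIE is assembled from the polarized-QM difference and the two
  # values are identical by construction; a drifted classical term would
  # indicate a broken engine and is rejected
  if (abs((neutral_pol$e_qm_mm_vdw + neutral_pol$e_mm) -
            (anion_pol$e_qm_mm_vdw + anion_pol$e_mm)) > 1e-12)
    stop("classical energy terms differ between states at fixed geometry")
  pol <- hartree_to_ev(neutral_pol$e_pol_or_gas_qm -
                         anion_pol$e_pol_or_gas_qm)
  c(qmm = pol, pol = pol, gas = gas)
}

#' Adiabatic ionization energies in the three frameworks
#'
#' The AIE is the difference between the neutral single-point energy at
#' the neutral-optimized geometry and the anion single-point energy at the
#' anion-optimized geometry. The gas framework uses gas single points at
#' the same two (embedding-optimized) geometries - gas energies are never
#' taken at re-optimized gas geometries.
#'
#' @param anion_pol POLARIZED anion at the anion-optimized geometry.
#' @param neutral_pol POLARIZED neutral at the neutral-optimized geometry.
#' @param anion_gas,neutral_gas GAS single points at those two geometries,
#'   or `NULL`.
#' @return named numeric (eV): `qmm`, `pol`, `gas`.
#' @export
compute_aie <- function(anion_pol, neutral_pol, anion_gas = NULL,
                        neutral_gas = NULL) {
  if (anion_pol$state_tag != "ANION" || neutral_pol$state_tag != "NEUTRAL")
    stop("domain error: expected an ANION and a NEUTRAL state result")
  gas <- NA_real_
  if (!is.null(anion_gas))
    gas <- hartree_to_ev(neutral_gas$e_pol_or_gas_qm -
                           anion_gas$e_pol_or_gas_qm)
  c(qmm = hartree_to_ev(neutral_pol$e_total - anion_pol$e_total),
    pol = hartree_to_ev(neutral_pol$e_pol_or_gas_qm -
                          anion_pol$e_pol_or_gas_qm),
    gas = gas)
}

#' Released energies in the three frameworks
#'
#' The released (relaxation) energy is the difference between the
#' single-point energies of the neutral species at the anion-optimized and
#' neutral-optimized geometries; within one framework it equals VIE - AIE.
#'
#' @param neutral_at_anion_pol,neutral_at_neutral_pol POLARIZED NEUTRAL
#'   `state_result`s at the two geometries.
#' @param neutral_at_anion_gas,neutral_at_neutral_gas GAS counterparts or
#'   `NULL`.
#' @return named numeric (eV): `qmm`, `pol`, `gas`.
#' @export
compute_released <- function(neutral_at_anion_pol, neutral_at_neutral_pol,
                             neutral_at_anion_gas = NULL,
                             neutral_at_neutral_gas = NULL) {
  states <- list(neutral_at_anion_pol, neutral_at_neutral_pol,
                 neutral_at_anion_gas, neutral_at_neutral_gas)
  for (s in states)
    if (!is.null(s) && s$state_tag != "NEUTRAL")
      stop("domain error: released energies are differences of NEUTRAL states")
  gas <- NA_real_
  if (!is.null(neutral_at_anion_gas))
    gas <- hartree_to_ev(neutral_at_anion_gas$e_pol_or_gas_qm -
                           neutral_at_neutral_gas$e_pol_or_gas_qm)
  c(qmm = hartree_to_ev(neutral_at_anion_pol$e_total -
                          neutral_at_neutral_pol$e_total),
    pol = hartree_to_ev(neutral_at_anion_pol$e_pol_or_gas_qm -
                          neutral_at_neutral_pol$e_pol_or_gas_qm),
    gas = gas)
}

#' Hole transferred during structural relaxation
#'
#' Per-component difference between the adiabatic and vertical hole
#' profiles; when both profiles total +1 the transfer sums to zero.
#'
#' @param vertical,adiabatic named per-component hole vectors.
#' @return named numeric of the same components.
#' @export
hole_transfer <- function(vertical, adiabatic) {
  if (!identical(names(vertical), names(adiabatic)))
    stop("alignment error: component vocabularies differ")
  adiabatic - vertical
}

#' Construct an ionization record
#'
#' Container for one snapshot's analysis; checks the record identities
#' (QM/MM = polarized-QM VIE; released = VIE - AIE per framework;
#' transfer = adiabatic - vertical) when the pieces are present.
#'
#' @param snapshot_id label.
#' @param vie,aie,released named numerics (`qmm`, `pol`, `gas`), eV.
#' @param hole_vertical,hole_vertical_gas,hole_adiabatic,hole_transfer
#'   named per-component hole vectors (e), or `NULL`.
#' @param diagnostics free-form list.
#' @return object of class `ionization_record`.
#' @export
ionization_record <- function(snapshot_id, vie, aie, released,
                              hole_vertical = NULL,
                              hole_vertical_gas = NULL,
                              hole_adiabatic = NULL,
                              hole_transfer = NULL,
                              diagnostics = list()) {
  if (is.null(hole_transfer) && !is.null(hole_vertical) &&
      !is.null(hole_adiabatic))
    hole_transfer <- hole_adiabatic - hole_vertical
  rec <- structure(list(snapshot_id = snapshot_id, vie = vie, aie = aie,
                        released = released,
                        hole_vertical = hole_vertical,
                        hole_vertical_gas = hole_vertical_gas,
                        hole_adiabatic = hole_adiabatic,
                        hole_transfer = hole_transfer,
                        diagnostics = diagnostics),
                   class = "ionization_record")
  validate_record(rec)
  rec
}

validate_record <- function(rec, tol_ev = 1e-9, tol_hole = 1e-6) {
  ok_num <- function(x) !is.null(x) && !anyNA(x)
  pick <- function(v, f) if (!is.null(v) && f %in% names(v)) v[[f]]
    else NA_real_
  if (ok_num(rec$vie[c("qmm", "pol")]) &&
      abs(rec$vie[["qmm"]] - rec$vie[["pol"]]) > tol_ev)
    stop("record invariant violated: VIE[QM/MM] != VIE[pol-QM]")
  for (f in c("qmm", "pol", "gas")) {
    v <- pick(rec$vie, f); a <- pick(rec$aie, f)
    r <- pick(rec$released, f)
    if (!anyNA(c(v, a, r)) && abs(r - (v - a)) > 1e-6)
      stop("record invariant violated: released != VIE - AIE for ", f)
  }
  if (ok_num(rec$hole_vertical) &&
      abs(rec$hole_vertical[["total"]] - 1) > tol_hole * 100)
    stop("record invariant violated: vertical hole total far from +1")
  invisible(rec)
}

#' @export
print.ionization_record <- function(x, ...) {
  cat("<ionization_record> ", x$snapshot_id, "\n", sep = "")
  fmt <- function(v) paste(sprintf("%s=%.2f", names(v), v), collapse = " ")
  cat("  VIE (eV):      ", fmt(x$vie), "\n")
  cat("  AIE (eV):      ", fmt(x$aie), "\n")
  cat("  released (eV): ", fmt(x$released), "\n")
  if (!is.null(x$hole_vertical))
    cat("  vertical hole: ", fmt(x$hole_vertical), "\n")
  if (!is.null(x$hole_adiabatic))
    cat("  adiabatic hole:", fmt(x$hole_adiabatic), "\n")
  invisible(x)
}

#' Full per-snapshot ionization analysis
#'
#' Runs the complete protocol on one snapshot: select the QM region at
#' `r_qm`; relax the anion (POLARIZED, `relax_scope`); vertical neutral
#' and gas single points at the anion-optimized geometry; ESP fits of
#' both states (POLARIZED charges for the QM/MM hole columns - gas
#' charges for the gas columns are controlled by `vertical_gas_holes`);
#' relax the neutral from the anion-optimized geometry; adiabatic single
#' points and ESP fits; assemble the `ionization_record`. One restraint
#' network, built on the input snapshot, is shared by every energy
#' evaluation so that all states sit on the same surface.
#'
#' @param sys a `molecular_system` snapshot.
#' @param r_qm QM-region radius, angstrom.
#' @param relax_scope `"FULL"` (all atoms; the QM/MM adiabatic path) or
#'   `"QM_ONLY"`.
#' @param esp_density,esp_scales ESP grid settings (see
#'   [build_esp_grid()]).
#' @param vertical_gas_holes also fit gas-embedding ESP charges for the
#'   gas-framework vertical hole profile.
#' @param gtol,maxit relaxation controls (see [relax_geometry()]).
#' @return an `ionization_record` with diagnostics (`n_qm_atoms`,
#'   `n_qm_waters`, ESP residuals).
#' @export
analyze_snapshot <- function(sys, r_qm = 3.4, relax_scope = "FULL",
                             esp_density = 1.0,
                             esp_scales = c(1.4, 1.6, 1.8, 2.0),
                             vertical_gas_holes = TRUE,
                             gtol = 1e-4, maxit = 500) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed for ", sys$snapshot_id, ": ",
           conditionMessage(e), call. = FALSE))
  }
  part <- stage("select", select_qm_region(sys, r_qm))
  springs <- build_springs(sys)
  # anion relaxation and vertical single points
  anion_opt <- stage("relax-anion",
                     relax_geometry(sys, part, "ANION", "POLARIZED",
                                    scope = relax_scope, springs = springs,
                                    gtol = gtol, maxit = maxit))
  sys_a <- anion_opt$system
  a_pol <- anion_opt$state
  n_pol_v <- stage("sp-vertical",
                   compute_state(sys_a, part, "NEUTRAL", "POLARIZED",
                                 springs = springs,
                                 geometry_tag = "anion-opt"))
  a_gas <- compute_state(sys_a, part, "ANION", "GAS", springs = springs,
                         geometry_tag = "anion-opt")
  n_gas_v <- compute_state(sys_a, part, "NEUTRAL", "GAS", springs = springs,
                           geometry_tag = "anion-opt")
  vie <- compute_vie(a_pol, n_pol_v, a_gas, n_gas_v)
  # ESP fits at the anion geometry (vertical holes)
  qm <- part$qm_indices
  at_a <- sys_a$atoms[qm, ]
  pos_a <- as.matrix(at_a[, c("x", "y", "z")])
  grid_a <- stage("esp-grid", build_esp_grid(pos_a, at_a$vdw_radius,
                                             esp_scales, esp_density))
  fit_state <- function(st, pos, grid) {
    v <- evaluate_potential(st$charges$charges, pos, grid$points)
    fit_esp_charges(grid$points, v, pos, st$charges$total_charge,
                    state_tag = st$state_tag, embedding = st$embedding)
  }
  esp_a_pol <- stage("esp-fit", fit_state(a_pol, pos_a, grid_a))
  esp_n_pol_v <- fit_state(n_pol_v, pos_a, grid_a)
  hv <- hole_profile(esp_n_pol_v, esp_a_pol, at_a$component)
  hv_gas <- NULL
  if (vertical_gas_holes) {
    esp_a_gas <- fit_state(a_gas, pos_a, grid_a)
    esp_n_gas <- fit_state(n_gas_v, pos_a, grid_a)
    hv_gas <- hole_profile(esp_n_gas, esp_a_gas, at_a$component)
  }
  # neutral relaxation from the anion-optimized geometry
  neutral_opt <- stage("relax-neutral",
                       relax_geometry(sys_a, part, "NEUTRAL", "POLARIZED",
                                      scope = relax_scope,
                                      springs = springs,
                                      gtol = gtol, maxit = maxit))
  sys_n <- neutral_opt$system
  n_pol_ad <- neutral_opt$state
  n_gas_ad <- compute_state(sys_n, part, "NEUTRAL", "GAS",
                            springs = springs, geometry_tag = "neutral-opt")
  aie <- compute_aie(a_pol, n_pol_ad, a_gas, n_gas_ad)
  released <- compute_released(n_pol_v, n_pol_ad, n_gas_v, n_gas_ad)
  # adiabatic hole: neutral ESP at the neutral geometry vs anion ESP
  at_n <- sys_n$atoms[qm, ]
  pos_n <- as.matrix(at_n[, c("x", "y", "z")])
  grid_n <- build_esp_grid(pos_n, at_n$vdw_radius, esp_scales, esp_density)
  esp_n_ad <- stage("esp-adiabatic", fit_state(n_pol_ad, pos_n, grid_n))
  ha <- hole_profile(esp_n_ad, esp_a_pol, at_n$component)
  ionization_record(
    snapshot_id = sys$snapshot_id,
    vie = vie, aie = aie, released = released,
    hole_vertical = hv, hole_vertical_gas = hv_gas,
    hole_adiabatic = ha,
    diagnostics = list(n_qm_atoms = length(qm),
                       n_qm_waters = part$n_qm_waters,
                       esp_residual_anion = esp_a_pol$residual_rms,
                       anion_relax_maxgrad = anion_opt$max_grad,
                       neutral_relax_maxgrad = neutral_opt$max_grad))
}
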