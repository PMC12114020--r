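# Table rendering and command-style entry points. The cmd_* functions are
# the command-line surface: each reads/writes plain-text artifacts
# (structures, partitions, curves, records, tables) and is a thin wrapper
# over the package functions; inst/cli/qmmmion.R dispatches them from a
# shell.

#' Render ensemble tables in the "mean +/- se" style
#'
#' Produces the five canonical tables from a record ensemble: VIE, AIE and
#' released energies per framework (eV, two decimals) and vertical/
#' adiabatic hole distributions per component (a.u.).
#'
#' @param records list of `ionization_record`s.
#' @param label row label (e.g. the nucleotide name).
#' @param digits decimals for the formatted cells.
#' @return list of data.frames: `energies` (rows VIE/AIE/released,
#'   columns QM/MM, pol-QM, gas-QM), `holes` (rows vertical/adiabatic per
#'   component family), plus `summary` (the unrounded
#'   [summarize_records()] output).
#' @export
report_tables <- function(records, label = "solute", digits = 2) {
  sm <- summarize_records(records)
  cell <- function(q) {
    r <- sm[sm$quantity == q, ]
    if (!nrow(r)) return(NA_character_)
    sprintf("%.*f ± %.*f", digits, r$mean, digits, r$se)
  }
  energies <- data.frame(
    quantity = c("VIE", "AIE", "released"),
    qmm = c(cell("vie.qmm"), cell("aie.qmm"), cell("released.qmm")),
    pol = c(cell("vie.pol"), cell("aie.pol"), cell("released.pol")),
    gas = c(cell("vie.gas"), cell("aie.gas"), cell("released.gas")),
    stringsAsFactors = FALSE)
  comps <- c("dRT", "BASE", "RIBOSE", "PHOSPHATE", "WATER")
  holes <- data.frame(
    component = comps,
    vertical = vapply(comps, function(cc)
      cell(paste0("hole_vertical.", cc)), ""),
    vertical_gas = vapply(comps, function(cc)
      cell(paste0("hole_vertical_gas.", cc)), ""),
    adiabatic = vapply(comps, function(cc)
      cell(paste0("hole_adiabatic.", cc)), ""),
    transfer = vapply(comps, function(cc)
      cell(paste0("hole_transfer.", cc)), ""),
    stringsAsFactors = FALSE)
  rownames(holes) <- NULL
  list(label = label, energies = energies, holes = holes, summary = sm)
}

#' Write ionization records to JSON
#'
#' @param records list of `ionization_record`s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_records_json <- function(records, path) {
  jsonlite::write_json(lapply(records, function(r) {
    r <- unclass(r)
    r <- r[!vapply(r, is.null, TRUE)]
    # named vectors must become JSON objects, not nameless arrays
    for (nm in names(r))
      if (is.numeric(r[[nm]]) && !is.null(names(r[[nm]])))
        r[[nm]] <- as.list(r[[nm]])
    r
  }), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ionization records from JSON
#'
#' @param path file written by [write_records_json()].
#' @return list of `ionization_record`s.
#' @export
read_records_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  # JSON nulls (NA fields) are dropped by unlist; restore them
  frameworks <- function(x) {
    v <- c(qmm = NA_real_, pol = NA_real_, gas = NA_real_)
    x <- unlist(x)
    v[names(x)] <- x
    v
  }
  lapply(raw, function(r)
    ionization_record(snapshot_id = r$snapshot_id,
                      vie = frameworks(r$vie), aie = frameworks(r$aie),
                      released = frameworks(r$released),
                      hole_vertical = unlist(r$hole_vertical),
                      hole_vertical_gas = unlist(r$hole_vertical_gas),
                      hole_adiabatic = unlist(r$hole_adiabatic),
                      hole_transfer = unlist(r$hole_transfer),
                      diagnostics = r$diagnostics))
}

#' Command entry points
#'
#' Thin command-style wrappers writing artifacts to an output directory:
#' `cmd_synthgen` generates snapshot structures (XYZ), `cmd_select`
#' writes a QM/MM partition (JSON), `cmd_converge` runs the region-size
#' convergence scan (CSV curve), `cmd_ionize` analyzes snapshots into
#' records (JSON), and `cmd_report` renders ensemble tables (CSV).
#' All randomness is controlled by the seed in the synthetic
#' configuration, so reruns with identical arguments produce identical
#' artifacts.
#'
#' @param out_dir output directory (created if missing).
#' @param config a [synthetic_config()].
#' @param n number of snapshots (`cmd_synthgen`, `cmd_ionize`).
#' @param r_qm region radius, angstrom.
#' @param r_values scan radii (`cmd_converge`).
#' @param threshold convergence threshold, e.
#' @param paths input structure files (`cmd_ionize`); overrides `config`.
#' @param records_path records JSON (`cmd_report`).
#' @param label table label.
#' @param ... forwarded to [analyze_snapshot()].
#' @return invisibly, the paths written.
#' @name cmd
NULL

#' @rdname cmd
#' @export
cmd_synthgen <- function(out_dir, config = synthetic_config(), n = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(n)) n <- config$n_snapshots
  paths <- character(n)
  for (k in seq_len(n)) {
    sys <- generate_snapshot(config, k)
    paths[k] <- file.path(out_dir, paste0(sys$snapshot_id, ".xyz"))
    write_structure(sys, paths[k], "xyz")
  }
  invisible(paths)
}

#' @rdname cmd
#' @export
cmd_select <- function(out_dir, path, r_qm = 3.4) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sys <- read_structure(path)
  part <- select_qm_region(sys, r_qm)
  out <- file.path(out_dir, paste0(sys$snapshot_id, "_partition.json"))
  write_partition_json(part, out)
  invisible(out)
}

#' @rdname cmd
#' @export
cmd_converge <- function(out_dir, config = synthetic_config(), n = 3,
                         r_values = seq(1.6, 4.2, by = 0.2),
                         threshold = 0.02) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  snaps <- lapply(seq_len(n), function(k) generate_snapshot(config, k))
  curve <- convergence_scan(snaps, r_values, threshold)
  out <- file.path(out_dir, "convergence_curve.csv")
  utils::write.csv(data.frame(r_qm = curve$r_values,
                              mean_solute_charge = curve$mean_solute_charge,
                              converged_r = curve$converged_r,
                              threshold = curve$threshold),
                   out, row.names = FALSE)
  invisible(out)
}

#' @rdname cmd
#' @export
cmd_ionize <- function(out_dir, config = synthetic_config(), n = 3,
                       r_qm = 3.4, paths = NULL, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  snaps <- if (is.null(paths))
    lapply(seq_len(n), function(k) generate_snapshot(config, k))
  else lapply(paths, read_structure)
  records <- lapply(snaps, analyze_snapshot, r_qm = r_qm, ...)
  out <- file.path(out_dir, "records.json")
  write_records_json(records, out)
  invisible(out)
}

#' @rdname cmd
#' @export
cmd_report <- function(out_dir, records_path, label = "solute") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_records_json(records_path)
  tabs <- report_tables(records, label)
  e_path <- file.path(out_dir, "table_energies.csv")
  h_path <- file.path(out_dir, "table_holes.csv")
  s_path <- file.path(out_dir, "summary_unrounded.csv")
  utils::write.csv(tabs$energies, e_path, row.names = FALSE)
  utils::write.csv(tabs$holes, h_path, row.names = FALSE)
  utils::write.csv(tabs$summary, s_path, row.names = FALSE)
  invisible(c(e_path, h_path, s_path))
}
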