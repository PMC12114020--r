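#' Select the QM region by the minimal water-oxygen distance criterion
#'
#' The region radius `r_qm` is the minimal distance between the oxygen atom
#' of a water molecule and any solute atom: a water joins the QM region
#' (all three atoms following its oxygen) when that minimal distance is
#' `<= r_qm` (closed threshold). The solute is always QM. Distances are
#' plain Euclidean: the droplet is finite, there are no periodic images.
#'
#' @param sys a `molecular_system`.
#' @param r_qm region radius, angstrom (> 0).
#' @return an object of class `region_partition` with fields `r_qm`,
#'   `qm_indices`, `mm_indices` (ordered atom indices) and `n_qm_waters`.
#' @export
select_qm_region <- function(sys, r_qm) {
  stopifnot(is.numeric(r_qm), length(r_qm) == 1L, r_qm > 0)
  sol <- solute_indices(sys)
  if (!length(sol)) stop("domain error: system has no solute atoms")
  at <- sys$atoms
  pos <- coords(sys)
  wo <- water_oxygen_indices(sys)
  qm_waters <- integer(0)
  if (length(wo)) {
    dmin <- apply(pos[wo, , drop = FALSE], 1L, function(p)
      sqrt(min(colSums((t(pos[sol, , drop = FALSE]) - p)^2))))
    qm_waters <- at$molecule_id[wo[dmin <= r_qm]]
  }
  qm <- which(at$component != "WATER" | at$molecule_id %in% qm_waters)
  structure(list(r_qm = r_qm,
                 qm_indices = qm,
                 mm_indices = setdiff(seq_len(nrow(at)), qm),
                 n_qm_waters = length(qm_waters)),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat("<region_partition> r_qm = ", x$r_qm, " A: ",
      length(x$qm_indices), " QM atoms (", x$n_qm_waters,
      " waters), ", length(x$mm_indices), " MM atoms\n", sep = "")
  invisible(x)
}

#' Scan the QM region over increasing radii
#'
#' Applies [select_qm_region()] at each radius of a strictly ascending list;
#' the resulting partitions are nested (QM membership is monotone in
#' `r_qm`).
#'
#' @param sys a `molecular_system`.
#' @param r_values strictly ascending radii, angstrom.
#' @return list of `region_partition` objects, one per radius.
#' @export
region_size_scan <- function(sys, r_values) {
  if (length(r_values) < 1L || any(diff(r_values) <= 0))
    stop("argument error: r_values must be strictly ascending")
  lapply(r_values, function(r) select_qm_region(sys, r))
}

#' Serialize a region partition to JSON
#'
#' @param partition a `region_partition`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_partition_json <- function(partition, path) {
  jsonlite::write_json(unclass(partition), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
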