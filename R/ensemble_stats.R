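# Ensemble statistics over snapshot records: mean, sample standard
# deviation (n-1 denominator) and the standard error of the mean
# (sd / sqrt(n)), plus the QM-region-size convergence analysis.

#' Summarize an ensemble of per-snapshot scalars
#'
#' @param samples numeric vector, length >= 2.
#' @param quantity_name label stored on the summary.
#' @return object of class `ensemble_summary`: `quantity_name`, `n`,
#'   `mean`, `sd` (sample sd, n-1 denominator), `se` (= sd / sqrt(n)).
#' @export
summarize_samples <- function(samples, quantity_name = "quantity") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("argument error: need at least 2 samples for an ensemble summary")
  s <- stats::sd(samples)
  structure(list(quantity_name = quantity_name, n = length(samples),
                 mean = mean(samples), sd = s,
                 se = s / sqrt(length(samples))),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble_summary> %s: %.4f +/- %.4f (sd %.4f, n = %d)\n",
              x$quantity_name, x$mean, x$se, x$sd, x$n))
  invisible(x)
}

#' Format a summary in the table style "mean +/- se"
#'
#' @param x an `ensemble_summary`.
#' @param digits decimals (tables use 2).
#' @param ... unused.
#' @return character scalar.
#' @export
format.ensemble_summary <- function(x, digits = 2, ...) {
  sprintf("%.*f ± %.*f", digits, x$mean, digits, x$se)
}

# flatten one record into a named numeric vector
flatten_record <- function(rec) {
  out <- c()
  for (blk in c("vie", "aie", "released")) {
    v <- rec[[blk]]
    if (!is.null(v)) out <- c(out, stats::setNames(v, paste(blk, names(v),
                                                            sep = ".")))
  }
  for (blk in c("hole_vertical", "hole_vertical_gas", "hole_adiabatic",
                "hole_transfer")) {
    v <- rec[[blk]]
    if (!is.null(v)) out <- c(out, stats::setNames(v, paste(blk, names(v),
                                                            sep = ".")))
  }
  out
}

#' Summarize an ensemble of ionization records
#'
#' Flattens each record (VIE/AIE/released per framework, hole profiles
#' per component) and computes mean, sd and se per quantity.
#'
#' @param records list of `ionization_record`s (>= 2).
#' @return data.frame with columns `quantity`, `n`, `mean`, `sd`, `se`.
#' @export
summarize_records <- function(records) {
  if (length(records) < 2L)
    stop("argument error: need at least 2 records")
  rows <- lapply(records, flatten_record)
  keys <- names(rows[[1]])
  m <- vapply(rows, function(r) r[keys], numeric(length(keys)))
  m <- matrix(m, nrow = length(keys),
              dimnames = list(keys, NULL))
  keep <- !apply(m, 1L, anyNA)
  out <- do.call(rbind, lapply(which(keep), function(i) {
    s <- summarize_samples(m[i, ], keys[i])
    data.frame(quantity = keys[i], n = s$n, mean = s$mean, sd = s$sd,
               se = s$se, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Detect the convergence radius of a scan curve
#'
#' Returns the smallest radius (from the second onward) at which the
#' absolute change from the previous radius drops below `threshold` and
#' stays below it for every larger radius in the scan, or `NA` if none.
#'
#' @param r_values ascending radii.
#' @param means per-radius mean values.
#' @param threshold convergence threshold (same units as `means`).
#' @return scalar radius or `NA`.
#' @export
detect_convergence <- function(r_values, means, threshold) {
  stopifnot(length(r_values) == length(means), threshold > 0)
  if (length(r_values) < 2L) return(NA_real_)
  ok <- abs(diff(means)) < threshold
  below_from <- rev(cumprod(rev(ok))) > 0
  idx <- which(below_from)
  if (!length(idx)) return(NA_real_)
  r_values[idx[1] + 1L]
}

#' QM-region-size convergence scan
#'
#' For each snapshot and each radius, selects the QM region, runs a
#' neutral POLARIZED single point, fits ESP charges on the QM region and
#' records the total fitted charge on the solute; solute charges are then
#' averaged over snapshots per radius and the convergence radius is the
#' smallest one from which successive changes stay below `threshold`.
#'
#' @param snapshots list of `molecular_system`s (>= 1).
#' @param r_values strictly ascending radii, angstrom.
#' @param threshold convergence threshold on the mean solute charge, e.
#' @param esp_density,esp_scales ESP grid settings.
#' @return object of class `convergence_curve`: `r_values`,
#'   `mean_solute_charge`, `per_snapshot` (matrix), `converged_r`,
#'   `threshold`.
#' @export
convergence_scan <- function(snapshots, r_values, threshold = 0.02,
                             esp_density = 1.0,
                             esp_scales = c(1.4, 1.6, 1.8, 2.0)) {
  if (!length(snapshots)) stop("argument error: no snapshots")
  if (any(diff(r_values) <= 0))
    stop("argument error: r_values must be strictly ascending")
  per <- matrix(NA_real_, length(snapshots), length(r_values))
  for (s in seq_along(snapshots)) {
    sys <- snapshots[[s]]
    springs <- build_springs(sys)
    for (k in seq_along(r_values)) {
      res <- tryCatch({
        part <- select_qm_region(sys, r_values[k])
        st <- compute_state(sys, part, "NEUTRAL", "POLARIZED",
                            springs = springs)
        at <- sys$atoms[part$qm_indices, ]
        pos <- as.matrix(at[, c("x", "y", "z")])
        grid <- build_esp_grid(pos, at$vdw_radius, esp_scales, esp_density)
        v <- evaluate_potential(st$charges$charges, pos, grid$points)
        fit <- fit_esp_charges(grid$points, v, pos,
                               st$charges$total_charge)
        sum(fit$charges[at$component != "WATER"])
      }, error = function(e)
        stop("convergence scan failed at snapshot ", sys$snapshot_id,
             ", r = ", r_values[k], ": ", conditionMessage(e),
             call. = FALSE))
      per[s, k] <- res
    }
  }
  means <- colMeans(per)
  structure(list(r_values = r_values, mean_solute_charge = means,
                 per_snapshot = per,
                 converged_r = detect_convergence(r_values, means,
                                                 threshold),
                 threshold = threshold),
            class = "convergence_curve")
}

#' @export
print.convergence_curve <- function(x, ...) {
  cat("<convergence_curve> mean solute ESP charge vs r_qm\n")
  print(data.frame(r_qm = x$r_values, mean_charge = round(
    x$mean_solute_charge, 4)))
  cat("converged_r:", x$converged_r, "(threshold", x$threshold, "e)\n")
  invisible(x)
}

#' Plot a convergence curve
#'
#' @param x a `convergence_curve`.
#' @param ... passed to [plot()].
#' @export
plot.convergence_curve <- function(x, ...) {
  plot(x$r_values, x$mean_solute_charge, type = "b",
       xlab = "r_qm (angstrom)", ylab = "mean solute ESP charge (e)", ...)
  if (!is.na(x$converged_r))
    graphics::abline(v = x$converged_r, lty = 2)
  invisible(x)
}
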