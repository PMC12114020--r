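# ESP charge fitting: Merz-Kollman-style shell grids around the van der
# Waals surface, a Coulomb potential evaluator, and a total-charge-
# constrained linear least-squares fit. Grids are deterministic
# (Fibonacci-lattice spheres), so fits are bit-stable across runs.

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (sqrt(5) + 1) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Build an ESP sampling grid on scaled van der Waals shells
#'
#' Places quasi-uniform points (Fibonacci lattice) on each scaled van der
#' Waals sphere of each atom and removes every point that falls inside the
#' innermost scaled sphere of any atom, so all surviving points lie outside
#' `min(shell_scales) * vdw_radius` of every atom.
#'
#' @param positions n x 3 matrix of atom positions, angstrom.
#' @param vdw_radii per-atom van der Waals radii, angstrom.
#' @param shell_scales ascending shell multipliers, all >= 1.
#' @param density target point density per shell, points per square
#'   angstrom.
#' @return object of class `esp_grid`: list with `points` (m x 3,
#'   angstrom), `shell_scales`, `density`.
#' @export
build_esp_grid <- function(positions, vdw_radii,
                           shell_scales = c(1.4, 1.6, 1.8, 2.0),
                           density = 1.0) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(length(vdw_radii) == n, density > 0)
  if (any(shell_scales < 1) || any(diff(shell_scales) <= 0))
    stop("shell_scales must be ascending and >= 1")
  if (n > 1L) {
    dmin <- min(stats::dist(positions))
    if (dmin < 1e-6)
      stop("geometry error: coincident atoms (separation < 1e-6 A)")
  }
  smin <- shell_scales[1]
  pts <- vector("list", n * length(shell_scales))
  k <- 0L
  for (i in seq_len(n)) {
    for (s in shell_scales) {
      rad <- s * vdw_radii[i]
      m <- max(4L, round(density * 4 * pi * rad^2))
      p <- fibonacci_sphere(m) * rad
      p <- sweep(p, 2L, positions[i, ], "+")
      keep <- rep(TRUE, nrow(p))
      for (j in seq_len(n)) {
        if (j == i) next
        d2 <- (p[, 1] - positions[j, 1])^2 + (p[, 2] - positions[j, 2])^2 +
          (p[, 3] - positions[j, 3])^2
        keep <- keep & d2 >= (smin * vdw_radii[j])^2 * (1 - 1e-12)
      }
      k <- k + 1L
      pts[[k]] <- p[keep, , drop = FALSE]
    }
  }
  points <- do.call(rbind, pts)
  if (nrow(points) < n + 1L)
    stop("geometry error: grid degenerate (", nrow(points),
         " points for ", n, " atoms); increase density or shells")
  structure(list(points = points, shell_scales = shell_scales,
                 density = density),
            class = "esp_grid")
}

#' Evaluate the point-charge electrostatic potential
#'
#' Bare Coulomb sum V(r) = sum_i q_i / |r - r_i| in atomic units; inputs
#' are in angstrom and are converted internally to bohr.
#'
#' @param charges per-atom charges, e.
#' @param positions n x 3 atom positions, angstrom.
#' @param points m x 3 evaluation points, angstrom.
#' @return per-point potential, hartree/e.
#' @export
evaluate_potential <- function(charges, positions, points) {
  positions <- as.matrix(positions); points <- as.matrix(points)
  stopifnot(length(charges) == nrow(positions))
  A <- coulomb_design(points, positions)
  drop(A %*% charges)
}

# m x n matrix of 1/r_ij in atomic units; errors on coincident point/atom.
coulomb_design <- function(points, positions) {
  m <- nrow(points); n <- nrow(positions)
  A <- matrix(0, m, n)
  for (j in seq_len(n)) {
    d2 <- (points[, 1] - positions[j, 1])^2 +
      (points[, 2] - positions[j, 2])^2 +
      (points[, 3] - positions[j, 3])^2
    if (any(d2 < 1e-12))
      stop("evaluation error: grid point coincides with atom ", j)
    A[, j] <- 1 / ang_to_bohr(sqrt(d2))
  }
  A
}

#' Fit atom-centered ESP charges under a total-charge constraint
#'
#' Minimizes the sum of squared deviations between the point-charge model
#' potential and a reference potential over the grid, subject to the exact
#' linear constraint sum(q) = `total_charge`, via the Lagrange-constrained
#' normal equations. An optional quadratic restraint toward zero charge
#' (strength `restraint`, added to the normal-equation diagonal) is off by
#' default: the default scheme is plain ESP, not RESP.
#'
#' @param points m x 3 grid points, angstrom.
#' @param reference_potential per-point reference potential, hartree/e.
#' @param positions n x 3 atom positions, angstrom.
#' @param total_charge constrained total charge, e.
#' @param restraint quadratic restraint strength (0 = pure ESP).
#' @param state_tag,embedding optional tags stored on the result
#'   (`"ANION"`/`"NEUTRAL"`, `"POLARIZED"`/`"GAS"`).
#' @return object of class `charge_set`: `charges` (e), `total_charge`,
#'   `residual_rms` (hartree/e), `state_tag`, `embedding`.
#' @export
fit_esp_charges <- function(points, reference_potential, positions,
                            total_charge, restraint = 0,
                            state_tag = NA_character_,
                            embedding = NA_character_) {
  points <- as.matrix(points); positions <- as.matrix(positions)
  n <- nrow(positions)
  if (nrow(points) < n + 1L)
    stop("need at least n_atoms + 1 grid points (", nrow(points),
         " for ", n, " atoms)")
  stopifnot(length(reference_potential) == nrow(points))
  A <- coulomb_design(points, positions)
  M <- crossprod(A)
  diag(M) <- diag(M) + restraint
  K <- rbind(cbind(M, rep(1, n)), c(rep(1, n), 0))
  rhs <- c(crossprod(A, reference_potential), total_charge)
  if (rcond(K) < 1e-14)
    stop("conditioning error: ESP design matrix is rank-deficient after ",
         "the charge constraint; add grid points or a small restraint")
  sol <- solve(K, rhs)
  q <- sol[seq_len(n)]
  resid <- drop(A %*% q) - reference_potential
  charge_set(q, total_charge, sqrt(mean(resid^2)), state_tag, embedding)
}

charge_set <- function(charges, total_charge, residual_rms = NA_real_,
                       state_tag = NA_character_,
                       embedding = NA_character_) {
  structure(list(charges = as.numeric(charges),
                 total_charge = total_charge,
                 residual_rms = residual_rms,
                 state_tag = state_tag, embedding = embedding),
            class = "charge_set")
}

#' @export
print.charge_set <- function(x, ...) {
  cat("<charge_set> ", length(x$charges), " charges, total ",
      format(sum(x$charges), digits = 10), " e",
      if (!is.na(x$state_tag)) paste0(" [", x$state_tag, "/", x$embedding, "]"),
      "\n", sep = "")
  invisible(x)
}

#' Sum per-atom values by component
#'
#' Groups a per-atom vector by component label and sums; all four component
#' levels are always present in the result (zero when absent), so grand
#' totals are preserved exactly.
#'
#' @param values per-atom scalars.
#' @param components per-atom component labels.
#' @return named numeric over `BASE`, `RIBOSE`, `PHOSPHATE`, `WATER`.
#' @export
aggregate_by_component <- function(values, components) {
  if (length(values) != length(components))
    stop("alignment error: ", length(values), " values for ",
         length(components), " component labels")
  f <- factor(as.character(components), levels = COMPONENT_LEVELS)
  if (anyNA(f)) stop("unknown component label(s)")
  out <- tapply(values, f, sum, default = 0)
  out[is.na(out)] <- 0
  stats::setNames(as.numeric(out), COMPONENT_LEVELS)
}

#' Component-resolved hole profile between two charge states
#'
#' The per-atom hole is `q_neutral - q_anion`; component values are sums of
#' member atoms. The profile reports the four components, the solute total
#' `dRT` (BASE + RIBOSE + PHOSPHATE), and the grand `total`
#' (= neutral total - anion total, +1 for anion -> neutral ionization).
#'
#' @param neutral,anion `charge_set` objects on the same atom ordering.
#' @param components per-atom component labels.
#' @return named numeric: `BASE`, `RIBOSE`, `PHOSPHATE`, `WATER`, `dRT`,
#'   `total`.
#' @export
hole_profile <- function(neutral, anion, components) {
  if (length(neutral$charges) != length(anion$charges))
    stop("alignment error: charge sets have ", length(neutral$charges),
         " vs ", length(anion$charges), " atoms")
  hole <- neutral$charges - anion$charges
  comp <- aggregate_by_component(hole, components)
  c(comp, dRT = sum(comp[SOLUTE_COMPONENTS]), total = sum(hole))
}

#' Write an ESP grid as an XYZ point cloud for inspection
#'
#' @param grid an `esp_grid`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_grid_xyz <- function(grid, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("%d", nrow(grid$points)), "esp grid points"), con)
  writeLines(sprintf("X %14.6f %14.6f %14.6f", grid$points[, 1],
                     grid$points[, 2], grid$points[, 3]), con)
  invisible(path)
}
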