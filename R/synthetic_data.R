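# Synthetic study inputs: deterministic water-droplet snapshots around a
# labeled solute (standing in for classical MD sampling) and record-level
# ensembles with prescribed mean/standard-error structure (standing in for
# full per-snapshot analyses).

#' Synthetic-data configuration
#'
#' The defaults are the study conditions of the emulated protocol: a
#' 30.0 angstrom water sphere at liquid-water number density, 40 snapshots
#' taken at 25 ps intervals from the final 1000 ps of a trajectory
#' (labels S1025-S2000), and a small thermal positional jitter.
#'
#' @param seed integer master seed; per-snapshot streams are derived from
#'   `(seed, index)`.
#' @param sphere_radius droplet radius, angstrom.
#' @param water_number_density molecules per cubic angstrom (0.0334 is
#'   liquid water).
#' @param solute_template one of `"dAMP"`, `"dGMP"`, `"dCMP"`, `"dTMP"`,
#'   `"TOY"`.
#' @param thermal_sigma per-atom positional jitter (sd), angstrom.
#' @param n_snapshots snapshots in the ensemble.
#' @param extraction_start_ps,extraction_window_ps,extraction_interval_ps
#'   trajectory-style extraction: snapshots at
#'   `start + k * interval, k = 1..window/interval`, labeled `S<time>`.
#' @param orientation_wobble sd of the random tilt applied to the
#'   inward-pointing water dipole orientation (dimensionless direction
#'   noise); the inward bias emulates the ordered solvation response
#'   around an anionic solute.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, sphere_radius = 30.0,
                             water_number_density = 0.0334,
                             solute_template = "dAMP",
                             thermal_sigma = 0.05,
                             n_snapshots = 40L,
                             extraction_start_ps = 1000,
                             extraction_window_ps = 1000,
                             extraction_interval_ps = 25,
                             orientation_wobble = 0.25) {
  stopifnot(water_number_density > 0, sphere_radius > 0,
            extraction_interval_ps > 0, thermal_sigma >= 0)
  structure(list(seed = as.integer(seed), sphere_radius = sphere_radius,
                 water_number_density = water_number_density,
                 solute_template = solute_template,
                 thermal_sigma = thermal_sigma,
                 n_snapshots = as.integer(n_snapshots),
                 extraction_start_ps = extraction_start_ps,
                 extraction_window_ps = extraction_window_ps,
                 extraction_interval_ps = extraction_interval_ps,
                 orientation_wobble = orientation_wobble),
            class = "synthetic_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

snapshot_seed <- function(seed, index) {
  (as.numeric(seed) * 1000003 + as.numeric(index) * 7919) %% 2147483629
}

#' Generate one droplet snapshot
#'
#' Places the solute template at the center and fills the sphere with
#' waters by rejection sampling: oxygen sites are uniform in the sphere,
#' rejected closer than 2.4 angstrom to any solute atom or 2.5 angstrom
#' to an already-placed oxygen. The target count is
#' `density * 4/3 pi (R^3 - r_excl^3)`, where `r_excl` (stored as an
#' attribute) is the exclusion radius equivalent to the solute's
#' 2.4-angstrom contact volume, estimated by seeded hit-or-miss
#' integration. Each water's dipole is biased toward the center
#' (hydrogens inward, as around an anion) plus random wobble, and applies
#' per-atom thermal jitter. Fully deterministic given `(seed, index)`.
#'
#' @param config a [synthetic_config()].
#' @param index snapshot index (>= 1).
#' @param snapshot_id optional label; default `S<index>`.
#' @return a `molecular_system`.
#' @export
generate_snapshot <- function(config, index = 1L, snapshot_id = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(snapshot_id)) snapshot_id <- paste0("S", index)
  with_seed(snapshot_seed(config$seed, index), {
    sol <- solute_template(config$solute_template)
    spos <- as.matrix(sol[, c("x", "y", "z")])
    R <- config$sphere_radius
    extent <- max(sqrt(rowSums(spos^2)))
    if (R <= extent + 2.4 + 1.0)
      stop("generation error: sphere_radius ", R,
           " too small for the solute (needs > ", round(extent + 3.4, 2),
           ")")
    # accessible volume (sphere minus the 2.4 A solute contact region),
    # estimated by seeded hit-or-miss sampling; the equivalent exclusion
    # radius r_excl satisfies V_acc = 4/3 pi (R^3 - r_excl^3)
    mc <- 20000L
    u <- stats::runif(mc)
    z <- stats::runif(mc, -1, 1)
    phi <- stats::runif(mc, 0, 2 * pi)
    rad <- R * u^(1 / 3)
    sfac <- sqrt(1 - z^2)
    probe <- cbind(rad * sfac * cos(phi), rad * sfac * sin(phi), rad * z)
    free_frac <- mean(vapply(seq_len(mc), function(b)
      min(colSums((t(spos) - probe[b, ])^2)) >= 2.4^2, TRUE))
    vol <- free_frac * 4 / 3 * pi * R^3
    r_excl <- (R^3 - vol * 3 / (4 * pi))^(1 / 3)
    n_target <- round(config$water_number_density * vol)
    opos <- matrix(0, 0, 3)
    attempts <- 0L
    max_attempts <- 200L * max(n_target, 1L)
    while (nrow(opos) < n_target && attempts < max_attempts) {
      batch <- min(2048L, max_attempts - attempts)
      u <- stats::runif(batch)
      rad <- R * u^(1 / 3)
      z <- stats::runif(batch, -1, 1)
      phi <- stats::runif(batch, 0, 2 * pi)
      s <- sqrt(1 - z^2)
      cand <- cbind(rad * s * cos(phi), rad * s * sin(phi), rad * z)
      for (b in seq_len(batch)) {
        if (nrow(opos) >= n_target) break
        p <- cand[b, ]
        if (min(colSums((t(spos) - p)^2)) < 2.4^2) next
        if (nrow(opos) &&
            min(colSums((t(opos) - p)^2)) < 2.5^2) next
        opos <- rbind(opos, p)
      }
      attempts <- attempts + batch
    }
    if (nrow(opos) < n_target)
      stop("generation error: placed ", nrow(opos), " of ", n_target,
           " waters; density infeasible for this radius")
    # orient each water: dipole bisector toward the center plus wobble
    waters <- vector("list", nrow(opos))
    d_bis <- WATER_OH_ANG * cos(WATER_HOH_DEG / 2 * pi / 180)
    d_half <- WATER_OH_ANG * sin(WATER_HOH_DEG / 2 * pi / 180)
    for (w in seq_len(nrow(opos))) {
      o <- opos[w, ]
      u <- -o / sqrt(sum(o^2)) + config$orientation_wobble * stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      a <- stats::rnorm(3)
      a <- a - sum(a * u) * u
      a <- a / sqrt(sum(a^2))
      h1 <- o + d_bis * u + d_half * a
      h2 <- o + d_bis * u - d_half * a
      waters[[w]] <- data.frame(
        element = c("O", "H", "H"),
        x = c(o[1], h1[1], h2[1]), y = c(o[2], h1[2], h2[2]),
        z = c(o[3], h1[3], h2[3]),
        component = "WATER", molecule_id = 1L + w,
        stringsAsFactors = FALSE)
    }
    atoms <- rbind(sol[, c("element", "x", "y", "z", "component",
                           "molecule_id")],
                   do.call(rbind, waters))
    if (config$thermal_sigma > 0) {
      atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, config$thermal_sigma)
      atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, config$thermal_sigma)
      atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, config$thermal_sigma)
    }
    sysm <- molecular_system(atoms, snapshot_id = snapshot_id,
                             solute_total_charge = -1,
                             sphere_radius = config$sphere_radius)
    attr(sysm, "n_water_target") <- n_target
    attr(sysm, "r_excl") <- r_excl
    sysm
  })
}

#' Extract a trajectory-style snapshot ensemble
#'
#' Returns `floor(window / interval)` snapshots labeled
#' `S<start + k * interval>`; a warning is raised when the interval does
#' not divide the window exactly.
#'
#' @param config a [synthetic_config()].
#' @return list of `molecular_system` objects.
#' @export
extract_snapshots <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  ratio <- config$extraction_window_ps / config$extraction_interval_ps
  n <- floor(ratio)
  if (n < 1L) stop("extraction window shorter than the interval")
  if (abs(ratio - n) > 1e-9)
    warning("extraction interval does not divide the window; taking ",
            n, " snapshots")
  lapply(seq_len(n), function(k)
    generate_snapshot(config, k,
                      snapshot_id = paste0(
                        "S", format(config$extraction_start_ps +
                                      k * config$extraction_interval_ps,
                                    scientific = FALSE, trim = TRUE))))
}

#' Generate record-level ensembles with prescribed mean/SE structure
#'
#' Draws `n` per-snapshot values for each target quantity from a normal
#' law with mean `mean` and standard deviation `se * sqrt(n)` (so that the
#' ensemble standard error reproduces `se` in expectation), then assembles
#' per-snapshot ionization records that satisfy the record identities by
#' construction: the QM/MM and polarized-QM VIEs are identical, released
#' energies are `VIE - AIE` per framework, and each hole profile's WATER
#' entry closes the sum to +1.
#'
#' Recognised quantity names: `vie_qmm`, `vie_gas`, `aie_qmm`, `aie_pol`,
#' `aie_gas`, `hole_v_BASE`, `hole_v_RIBOSE`, `hole_v_PHOSPHATE`,
#' `hole_a_BASE`, `hole_a_RIBOSE`, `hole_a_PHOSPHATE`.
#'
#' @param targets data.frame with columns `quantity`, `mean`, `se`.
#' @param n ensemble size (>= 2).
#' @param seed integer seed.
#' @return list of `ionization_record` objects of length `n`.
#' @export
generate_records <- function(targets, n = 40L, seed = 1L) {
  stopifnot(is.data.frame(targets),
            all(c("quantity", "mean", "se") %in% names(targets)),
            n >= 2L, all(targets$se >= 0))
  draws <- with_seed(seed, {
    m <- vapply(seq_len(nrow(targets)), function(i)
      stats::rnorm(n, targets$mean[i], targets$se[i] * sqrt(n)),
      numeric(n))
    colnames(m) <- targets$quantity
    m
  })
  get_q <- function(k, nm)
    if (nm %in% colnames(draws)) unname(draws[k, nm]) else NA_real_
  lapply(seq_len(n), function(k) {
    vie <- c(qmm = get_q(k, "vie_qmm"), pol = get_q(k, "vie_qmm"),
             gas = get_q(k, "vie_gas"))
    aie <- c(qmm = get_q(k, "aie_qmm"), pol = get_q(k, "aie_pol"),
             gas = get_q(k, "aie_gas"))
    hv <- c(BASE = get_q(k, "hole_v_BASE"),
            RIBOSE = get_q(k, "hole_v_RIBOSE"),
            PHOSPHATE = get_q(k, "hole_v_PHOSPHATE"))
    ha <- c(BASE = get_q(k, "hole_a_BASE"),
            RIBOSE = get_q(k, "hole_a_RIBOSE"),
            PHOSPHATE = get_q(k, "hole_a_PHOSPHATE"))
    close_profile <- function(h) {
      if (anyNA(h)) return(NULL)
      h <- c(h, WATER = 1 - sum(h))
      c(h, dRT = sum(h[SOLUTE_COMPONENTS]), total = sum(h[COMPONENT_LEVELS]))
    }
    ionization_record(snapshot_id = paste0("R", k),
                      vie = vie, aie = aie,
                      released = vie - aie,
                      hole_vertical = close_profile(hv),
                      hole_adiabatic = close_profile(ha))
  })
}
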