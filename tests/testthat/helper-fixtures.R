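# Shared fixtures, built in code. Expensive ones are computed lazily and
# cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# one intact water molecule as a 5-column XYZ text block
single_water_xyz <- function() {
  c("3",
    "snapshot_id=W1 solute_charge=0 sphere_radius=10",
    "O   0.000000   0.000000   0.000000 WATER",
    "H   0.760000   0.590000   0.000000 WATER",
    "H  -0.760000   0.590000   0.000000 WATER")
}

# minimal hand-built solute + waters system; water O positions given,
# H atoms attached at the reference internal geometry
make_droplet <- function(solute_df, water_o, sphere_radius = 30,
                         solute_charge = -1, snapshot_id = "T1") {
  rows <- solute_df
  rows$molecule_id <- 1L
  if (!is.null(water_o) && nrow(water_o)) {
    for (w in seq_len(nrow(water_o))) {
      o <- as.numeric(water_o[w, ])
      rows <- rbind(rows, data.frame(
        element = c("O", "H", "H"),
        x = o[1] + c(0, 0.7568, -0.7568),
        y = o[2] + c(0, 0.5862, 0.5862),
        z = o[3],
        component = "WATER", molecule_id = 1L + w,
        stringsAsFactors = FALSE))
    }
  }
  molecular_system(rows, snapshot_id = snapshot_id,
                   solute_total_charge = solute_charge,
                   sphere_radius = sphere_radius)
}

one_atom_solute <- function(element = "C", component = "BASE") {
  data.frame(element = element, x = 0, y = 0, z = 0,
             component = component, stringsAsFactors = FALSE)
}

# deterministic random droplet for oracle tests: k waters uniform in a
# shell around a small random solute; no contact constraints, so it also
# exercises awkward geometries
random_droplet <- function(seed, n_water = 12, radius = 8) {
  set.seed(seed)
  ns <- sample(2:4, 1)
  sol <- data.frame(
    element = sample(c("C", "N", "O", "P"), ns, replace = TRUE),
    x = stats::runif(ns, -1, 1), y = stats::runif(ns, -1, 1),
    z = stats::runif(ns, -1, 1),
    component = sample(c("BASE", "RIBOSE", "PHOSPHATE"), ns,
                       replace = TRUE),
    stringsAsFactors = FALSE)
  wo <- matrix(stats::runif(3 * n_water, -radius, radius), ncol = 3)
  keep <- sqrt(rowSums(wo^2)) > 2.2
  make_droplet(sol, as.data.frame(wo[keep, , drop = FALSE]),
               sphere_radius = 2 * radius,
               snapshot_id = paste0("RD", seed))
}

# small TOY droplet ensemble used by several engine tests
toy_config <- function(seed = 101, radius = 6.0)
  synthetic_config(seed = seed, sphere_radius = radius,
                   solute_template = "TOY", n_snapshots = 3)

toy_snapshot <- function(index = 1, seed = 101)
  cached(paste0("toy", seed, "_", index),
         generate_snapshot(toy_config(seed), index))

# a fully analyzed TOY record (expensive: two relaxations)
toy_record <- function(index = 1, seed = 101)
  cached(paste0("toyrec", seed, "_", index),
         analyze_snapshot(toy_snapshot(index, seed), r_qm = 3.4))

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)

# O(N_solute x N_water) reference implementation of the region criterion
brute_force_qm_waters <- function(sys, r_qm) {
  at <- sys$atoms
  pos <- as.matrix(at[, c("x", "y", "z")])
  sol <- which(at$component != "WATER")
  keep <- integer(0)
  for (i in which(at$component == "WATER" & at$element == "O")) {
    dmin <- Inf
    for (j in sol)
      dmin <- min(dmin, sqrt(sum((pos[i, ] - pos[j, ])^2)))
    if (dmin <= r_qm) keep <- c(keep, at$molecule_id[i])
  }
  keep
}
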