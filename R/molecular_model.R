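#' Molecular system: a labeled solute in a water droplet
#'
#' A `molecular_system` holds one snapshot: an ordered atom table (element,
#' position in angstrom, component label, molecule id, per-atom parameters),
#' a snapshot label, the solute total charge (e) and the droplet radius
#' (angstrom). The solute atoms are labeled `BASE`, `RIBOSE` or `PHOSPHATE`
#' and share a single molecule id; every water is three atoms (one O, two H)
#' under its own molecule id with component `WATER`.
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z`,
#'   `component`, `molecule_id`; per-atom parameter columns (`vdw_radius`,
#'   `mm_charge`, `chi`, `eta`, `lj_eps`, `lj_sigma`) are filled from the
#'   shipped engine table when absent.
#' @param snapshot_id character snapshot label, e.g. `"S1025"`.
#' @param solute_total_charge total solute charge in e (-1 for a
#'   deoxyribonucleotide anion).
#' @param sphere_radius droplet radius in angstrom.
#' @param validate check invariants (water grouping, single solute molecule,
#'   containment) and fail on violation.
#' @return an object of class `molecular_system`.
#' @export
molecular_system <- function(atoms, snapshot_id = "S0",
                             solute_total_charge = -1,
                             sphere_radius = 30.0, validate = TRUE) {
  stopifnot(is.data.frame(atoms))
  needed <- c("element", "x", "y", "z", "component", "molecule_id")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  atoms$component <- as.character(atoms$component)
  bad <- setdiff(unique(atoms$component), COMPONENT_LEVELS)
  if (length(bad))
    stop("unknown component label(s): ", paste(bad, collapse = ", "))
  par_cols <- c("vdw_radius", "mm_charge", "chi", "eta", "lj_eps", "lj_sigma")
  if (!all(par_cols %in% names(atoms))) {
    pars <- element_params(atoms$element, atoms$component)
    for (cc in par_cols) if (!cc %in% names(atoms)) atoms[[cc]] <- pars[[cc]]
  }
  rownames(atoms) <- NULL
  sys <- structure(list(atoms = atoms,
                        snapshot_id = as.character(snapshot_id),
                        solute_total_charge = solute_total_charge,
                        sphere_radius = sphere_radius),
                   class = "molecular_system")
  if (validate) validate_system(sys)
  sys
}

#' Validate a molecular system's invariants
#'
#' Checks that positive radii/hardness, water grouping (3 atoms: 1 O + 2 H
#' per WATER molecule id), a single solute molecule id, and containment of
#' all atoms within `sphere_radius + tol` of the solute centroid hold.
#'
#' @param sys a `molecular_system`.
#' @param tol containment slack in angstrom.
#' @return the system, invisibly; errors on violation.
#' @export
validate_system <- function(sys, tol = 2.0) {
  at <- sys$atoms
  if (!all(at$vdw_radius > 0)) stop("vdw_radius must be positive")
  if (!all(at$eta > 0)) stop("eta must be positive")
  w <- at$component == "WATER"
  if (any(w)) {
    for (mid in unique(at$molecule_id[w])) {
      grp <- at[at$molecule_id == mid, ]
      if (nrow(grp) != 3L || sum(grp$element == "O") != 1L ||
          sum(grp$element == "H") != 2L)
        stop("water molecule ", mid, " is not one O and two H (",
             nrow(grp), " atoms)")
      if (any(grp$component != "WATER"))
        stop("molecule ", mid, " mixes WATER and solute components")
    }
  }
  if (any(!w)) {
    if (length(unique(at$molecule_id[!w])) != 1L)
      stop("solute components must share a single molecule_id")
    if (any(at$molecule_id[!w] %in% at$molecule_id[w]))
      stop("solute molecule_id collides with a water molecule_id")
    cen <- colMeans(at[!w, c("x", "y", "z")])
    d <- sqrt((at$x - cen[1])^2 + (at$y - cen[2])^2 + (at$z - cen[3])^2)
    if (any(d > sys$sphere_radius + tol))
      stop("atom(s) lie beyond sphere_radius + ", tol, " A of the solute centroid")
  }
  invisible(sys)
}

#' @export
print.molecular_system <- function(x, ...) {
  at <- x$atoms
  nw <- length(unique(at$molecule_id[at$component == "WATER"]))
  cat("<molecular_system> snapshot ", x$snapshot_id, "\n",
      "  atoms: ", nrow(at), " (solute ", sum(at$component != "WATER"),
      ", waters ", nw, ")\n",
      "  solute charge: ", x$solute_total_charge,
      " e; sphere radius: ", x$sphere_radius, " A\n", sep = "")
  invisible(x)
}

# index helpers
solute_indices <- function(sys) which(sys$atoms$component != "WATER")
water_oxygen_indices <- function(sys)
  which(sys$atoms$component == "WATER" & sys$atoms$element == "O")

coords <- function(sys, idx = NULL) {
  m <- as.matrix(sys$atoms[, c("x", "y", "z")])
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m
}

set_coords <- function(sys, xyz) {
  sys$atoms$x <- xyz[, 1]; sys$atoms$y <- xyz[, 2]; sys$atoms$z <- xyz[, 3]
  sys
}

# ---------------------------------------------------------------------------
# Structure I/O.
#
# XYZ dialect: "element x y z component" rows; the comment line carries
#   snapshot_id, solute charge and sphere radius as key=value tokens.
# PDB: columns 1-54 honored (occupancy/B-factor ignored); waters recognised
#   by residue name (HOH/WAT/TIP3), solute components assigned through a
#   residue/atom-name component map.
# ---------------------------------------------------------------------------

#' Read a molecular structure
#'
#' Reads an XYZ (extended 5-column dialect: `element x y z component`) or a
#' PDB file into a [molecular_system()]. Waters are grouped from residue ids
#' (PDB) or by O-H distance < 1.2 angstrom (XYZ); solute atoms of a PDB are
#' assigned to components through a component map (see
#' [load_component_map()]).
#'
#' @param path input file.
#' @param format `"xyz"` or `"pdb"`; default guesses from the extension.
#' @param component_map component map list for PDB input; default is the
#'   shipped nucleotide map.
#' @param solute_total_charge,sphere_radius system metadata; for XYZ these
#'   default to values stored on the comment line when present.
#' @return a `molecular_system`.
#' @export
read_structure <- function(path, format = c("auto", "xyz", "pdb"),
                           component_map = NULL,
                           solute_total_charge = NULL, sphere_radius = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "xyz")
    read_xyz(path, solute_total_charge, sphere_radius)
  else
    read_pdb(path, component_map, solute_total_charge, sphere_radius)
}

read_xyz <- function(path, solute_total_charge = NULL, sphere_radius = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("XYZ parse error: file too short")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("XYZ parse error at line 1: atom count expected")
  if (length(lines) < 2L + n)
    stop("XYZ parse error: ", n, " atoms declared, ",
         length(lines) - 2L, " rows present")
  meta <- parse_kv(lines[2])
  snapshot_id <- if (!is.null(meta$snapshot_id)) meta$snapshot_id else "S0"
  if (is.null(solute_total_charge))
    solute_total_charge <- if (!is.null(meta$solute_charge))
      as.numeric(meta$solute_charge) else -1
  if (is.null(sphere_radius))
    sphere_radius <- if (!is.null(meta$sphere_radius))
      as.numeric(meta$sphere_radius) else 30.0
  rows <- lines[3:(2 + n)]
  tok <- strsplit(trimws(rows), "\\s+")
  at <- lapply(seq_along(tok), function(i) {
    t <- tok[[i]]
    if (length(t) < 5L)
      stop("XYZ parse error at line ", i + 2L,
           ": expected 'element x y z component'")
    xyz <- suppressWarnings(as.numeric(t[2:4]))
    if (anyNA(xyz)) stop("XYZ parse error at line ", i + 2L,
                         ": non-numeric coordinate")
    list(element = t[1], x = xyz[1], y = xyz[2], z = xyz[3], component = t[5])
  })
  atoms <- data.frame(element = vapply(at, `[[`, "", "element"),
                      x = vapply(at, `[[`, 0, "x"),
                      y = vapply(at, `[[`, 0, "y"),
                      z = vapply(at, `[[`, 0, "z"),
                      component = vapply(at, `[[`, "", "component"),
                      stringsAsFactors = FALSE)
  bad <- setdiff(unique(atoms$component), COMPONENT_LEVELS)
  if (length(bad))
    stop("labeling error: unknown component token(s): ",
         paste(bad, collapse = ", "))
  atoms$molecule_id <- assign_molecule_ids_xyz(atoms)
  molecular_system(atoms, snapshot_id, solute_total_charge, sphere_radius)
}

# Waters in an XYZ have no residue ids: each O claims the H atoms within
# 1.2 A; anything left over is an integrity error.
assign_molecule_ids_xyz <- function(atoms) {
  mid <- integer(nrow(atoms))
  mid[atoms$component != "WATER"] <- 1L
  widx <- which(atoms$component == "WATER")
  if (!length(widx)) return(mid)
  wo <- widx[atoms$element[widx] == "O"]
  wh <- widx[atoms$element[widx] == "H"]
  if (length(widx) != length(wo) + length(wh))
    stop("integrity error: WATER atoms must be O or H")
  taken <- rep(FALSE, length(wh))
  next_id <- 2L
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  for (o in wo) {
    d2 <- colSums((t(pos[wh, , drop = FALSE]) - pos[o, ])^2)
    cand <- which(!taken & d2 < 1.2^2)
    if (length(cand) < 2L)
      stop("integrity error: water O at row ", o,
           " has ", length(cand), " unassigned H within 1.2 A (need 2)")
    cand <- cand[order(d2[cand])][1:2]
    taken[cand] <- TRUE
    mid[c(o, wh[cand])] <- next_id
    next_id <- next_id + 1L
  }
  if (!all(taken))
    stop("integrity error: ", sum(!taken),
         " water H atom(s) not within 1.2 A of any O")
  mid
}

parse_kv <- function(line) {
  toks <- regmatches(line, gregexpr("[A-Za-z_]+=[^ ]+", line))[[1]]
  out <- list()
  for (t in toks) {
    kv <- strsplit(t, "=", fixed = TRUE)[[1]]
    out[[kv[1]]] <- kv[2]
  }
  out
}

#' Load a residue/atom-name component map
#'
#' Component maps assign PDB solute atoms to `BASE`/`RIBOSE`/`PHOSPHATE`.
#' The shipped map covers the four 2'-deoxyribonucleoside 5'-monophosphates
#' (residues DA/DG/DC/DT and base-only ADE/GUA/CYT/THY), plus the internal
#' `BAS`/`RIB`/`PHO` residues this package writes. The bridging O5' oxygen
#' is assigned to the phosphate group and O3' to the ribose.
#'
#' @param path YAML file; `NULL` loads the shipped nucleotide map.
#' @return list with `water_residues` and `residues` entries.
#' @export
load_component_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "component_maps", "nucleotides.yaml",
                        package = "qmmmion", mustWork = TRUE)
  yaml::read_yaml(path)
}

read_pdb <- function(path, component_map = NULL,
                     solute_total_charge = NULL, sphere_radius = NULL) {
  if (is.null(component_map)) component_map <- load_component_map()
  lines <- readLines(path)
  rec <- lines[substr(lines, 1, 6) %in% c("ATOM  ", "HETATM")]
  if (!length(rec)) stop("PDB parse error: no ATOM/HETATM records")
  name <- trimws(substr(rec, 13, 16))
  resname <- trimws(substr(rec, 18, 20))
  resseq <- suppressWarnings(as.integer(trimws(substr(rec, 23, 26))))
  x <- suppressWarnings(as.numeric(substr(rec, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(rec, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(rec, 47, 54)))
  bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(resseq))
  if (length(bad))
    stop("PDB parse error at record ", bad[1], ": malformed coordinates")
  element <- pdb_element(name)
  water <- resname %in% component_map$water_residues
  component <- character(length(rec))
  component[water] <- "WATER"
  for (i in which(!water)) {
    rmap <- component_map$residues[[resname[i]]]
    if (is.null(rmap))
      stop("labeling error: residue '", resname[i], "' not in component map")
    comp <- rmap[[name[i]]]
    if (is.null(comp)) comp <- rmap[["*"]]
    if (is.null(comp))
      stop("labeling error: atom '", name[i], "' of residue '",
           resname[i], "' not in component map")
    component[i] <- comp
  }
  mid <- integer(length(rec))
  mid[!water] <- 1L
  if (any(water))
    mid[water] <- 1L + as.integer(factor(resseq[water],
                                         levels = unique(resseq[water])))
  atoms <- data.frame(element = element, x = x, y = y, z = z,
                      component = component, molecule_id = mid,
                      stringsAsFactors = FALSE)
  if (is.null(solute_total_charge)) solute_total_charge <- -1
  if (is.null(sphere_radius)) sphere_radius <- 30.0
  molecular_system(atoms, snapshot_id = sub("\\.pdb$", "", basename(path),
                                            ignore.case = TRUE),
                   solute_total_charge, sphere_radius)
}

pdb_element <- function(name) {
  sym <- sub("^[0-9']*", "", name)
  two <- toupper(substr(sym, 1, 2))
  ifelse(two %in% c("CL", "BR", "NA", "MG", "FE", "ZN"),
         paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))),
         substr(sym, 1, 1))
}

#' Write a molecular structure
#'
#' Writes a system as extended XYZ (component token in the fifth column,
#' metadata on the comment line) or PDB (waters as `WAT`, solute atoms under
#' residues `BAS`/`RIB`/`PHO` so labels survive a round trip).
#'
#' @param sys a `molecular_system`.
#' @param path output file.
#' @param format `"xyz"` or `"pdb"`; default guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_structure <- function(sys, path, format = c("auto", "xyz", "pdb")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  at <- sys$atoms
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("I/O error: cannot open '", path, "' for writing"))
  on.exit(close(con))
  if (format == "xyz") {
    writeLines(c(sprintf("%d", nrow(at)),
                 sprintf("snapshot_id=%s solute_charge=%g sphere_radius=%g",
                         sys$snapshot_id, sys$solute_total_charge,
                         sys$sphere_radius)), con)
    writeLines(sprintf("%-2s %14.6f %14.6f %14.6f %s",
                       at$element, at$x, at$y, at$z, at$component), con)
  } else {
    resname <- c(BASE = "BAS", RIBOSE = "RIB", PHOSPHATE = "PHO",
                 WATER = "WAT")[at$component]
    counter <- stats::ave(seq_len(nrow(at)), at$molecule_id, at$element,
                          FUN = seq_along)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(at)),
      substr(paste0(at$element, counter), 1, 4),
      resname, at$molecule_id, at$x, at$y, at$z, at$element), con)
    writeLines("END", con)
  }
  invisible(path)
}
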