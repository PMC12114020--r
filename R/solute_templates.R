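# Idealized solute templates: planar-ring nucleotide geometries
# (base + deoxyribose + 5'-phosphate) built from regular polygons with
# standard-ish bond lengths, and a small TOY solute carrying all three
# solute components. These are synthetic idealizations intended to give
# the engine the right composition (nitrogen-rich base, C/O sugar,
# P-centered phosphate) and a bonded, connected geometry - not accurate
# nucleotide conformers.

polygon_ring <- function(n, edge, center = c(0, 0, 0), phase = 0) {
  R <- edge / (2 * sin(pi / n))
  th <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + R * cos(th), center[2] + R * sin(th), center[3])
}

# radial exocyclic position: ring atom pushed outward from ring center
radial_out <- function(pos, center, dist) {
  u <- pos - center
  u <- u / sqrt(sum(u^2))
  pos + dist * u
}

# remaining 3 vertices of a regular pentagon sharing edge A-B, placed on
# the side away from `away`
pentagon_complete <- function(A, B, away) {
  M <- (A + B) / 2
  e <- B - A; s <- sqrt(sum(e^2)); e <- e / s
  nrm <- M - away
  nrm <- nrm - sum(nrm * e) * e
  nrm <- nrm / sqrt(sum(nrm^2))
  apo <- s / (2 * tan(pi / 5))
  R <- s / (2 * sin(pi / 5))
  cen <- M + apo * nrm
  ang <- function(p) atan2(sum((p - cen) * nrm), sum((p - cen) * e))
  a0 <- ang(A); b0 <- ang(B)
  step <- 2 * pi / 5
  dir <- if (sin(b0 - a0) > 0) 1 else -1
  t(vapply(1:3, function(k) {
    th <- b0 + dir * step * k
    cen + R * (cos(th) * e + sin(th) * nrm)
  }, numeric(3)))
}

atom_row <- function(element, pos, component) {
  data.frame(element = element, x = pos[1], y = pos[2], z = pos[3],
             component = component, stringsAsFactors = FALSE)
}

build_base <- function(kind, center) {
  hex <- polygon_ring(6, 1.39, center)
  cen <- center
  rows <- list()
  if (kind %in% c("dAMP", "dGMP")) {
    # purine: hexagon N1 C2 N3 C4 C5 C6 fused to pentagon C4-C5-N7-C8-N9
    el <- c("N", "C", "N", "C", "C", "C")
    nm <- c("N1", "C2", "N3", "C4", "C5", "C6")
    for (i in 1:6) rows[[nm[i]]] <- atom_row(el[i], hex[i, ], "BASE")
    pent <- pentagon_complete(hex[5, ], hex[4, ], cen)  # from C5 to C4
    rows[["N7"]] <- atom_row("N", pent[1, ], "BASE")
    rows[["C8"]] <- atom_row("C", pent[2, ], "BASE")
    rows[["N9"]] <- atom_row("N", pent[3, ], "BASE")
    rows[["H8"]] <- atom_row("H", radial_out(pent[2, ], cen, 1.08), "BASE")
    if (kind == "dAMP") {
      rows[["N6"]] <- atom_row("N", radial_out(hex[6, ], cen, 1.34), "BASE")
      rows[["H2"]] <- atom_row("H", radial_out(hex[2, ], cen, 1.08), "BASE")
    } else {
      rows[["O6"]] <- atom_row("O", radial_out(hex[6, ], cen, 1.23), "BASE")
      rows[["N2"]] <- atom_row("N", radial_out(hex[2, ], cen, 1.34), "BASE")
      rows[["H1"]] <- atom_row("H", radial_out(hex[1, ], cen, 1.01), "BASE")
    }
    attach_atom <- "N9"
  } else {
    # pyrimidine: hexagon N1 C2 N3 C4 C5 C6
    el <- c("N", "C", "N", "C", "C", "C")
    nm <- c("N1", "C2", "N3", "C4", "C5", "C6")
    for (i in 1:6) rows[[nm[i]]] <- atom_row(el[i], hex[i, ], "BASE")
    rows[["O2"]] <- atom_row("O", radial_out(hex[2, ], cen, 1.23), "BASE")
    rows[["H6"]] <- atom_row("H", radial_out(hex[6, ], cen, 1.08), "BASE")
    if (kind == "dCMP") {
      rows[["N4"]] <- atom_row("N", radial_out(hex[4, ], cen, 1.34), "BASE")
      rows[["H5"]] <- atom_row("H", radial_out(hex[5, ], cen, 1.08), "BASE")
    } else {
      rows[["O4"]] <- atom_row("O", radial_out(hex[4, ], cen, 1.23), "BASE")
      rows[["C7"]] <- atom_row("C", radial_out(hex[5, ], cen, 1.50), "BASE")
      rows[["H3"]] <- atom_row("H", radial_out(hex[3, ], cen, 1.01), "BASE")
    }
    attach_atom <- "N1"
  }
  list(rows = rows, attach = attach_atom, center = cen)
}

#' Build a solute template
#'
#' Constructs the idealized geometry of one of the four
#' deoxyribonucleotide 5'-monophosphate anions (`dAMP`, `dGMP`, `dCMP`,
#' `dTMP`) or a small `TOY` solute, centered on its centroid, with
#' component labels and engine parameters attached.
#'
#' @param template `"dAMP"`, `"dGMP"`, `"dCMP"`, `"dTMP"` or `"TOY"`.
#' @return data.frame of atoms (`element`, `x`, `y`, `z`, `component`,
#'   `molecule_id`).
#' @export
solute_template <- function(template = c("dAMP", "dGMP", "dCMP", "dTMP",
                                         "TOY")) {
  template <- match.arg(template)
  if (template == "TOY") {
    df <- rbind(
      atom_row("P", c(-1.45, 0.30, 0.00), "PHOSPHATE"),
      atom_row("O", c(-1.95, -1.05, 0.25), "PHOSPHATE"),
      atom_row("O", c(-1.80, 1.35, -0.85), "PHOSPHATE"),
      atom_row("C", c(0.05, 0.25, 0.10), "RIBOSE"),
      atom_row("O", c(0.75, 1.45, 0.00), "RIBOSE"),
      atom_row("C", c(0.85, -0.95, -0.15), "BASE"),
      atom_row("N", c(2.10, -0.60, 0.30), "BASE"),
      atom_row("C", c(1.95, 0.80, 0.45), "BASE"))
  } else {
    base <- build_base(template, center = c(2.4, 0.6, 0))
    rows <- base$rows
    # deoxyribose 5-ring: O4' C1' C2' C3' C4'; C1' must sit ~1.47 A from
    # the base attachment nitrogen
    att <- unlist(rows[[base$attach]][1, c("x", "y", "z")])
    u_out <- att - base$center
    u_out <- u_out / sqrt(sum(u_out^2))
    ring_center <- att + 2.1 * u_out + c(0, 0, 0.9)
    phase <- atan2(att[2] - ring_center[2], att[1] - ring_center[1])
    pent <- polygon_ring(5, 1.45, ring_center, phase = phase)
    rnm <- c("C1p", "O4p", "C4p", "C3p", "C2p")
    rel <- c("C", "O", "C", "C", "C")
    sug <- list()
    for (i in 1:5) sug[[rnm[i]]] <- atom_row(rel[i], pent[i, ], "RIBOSE")
    # pull C1' toward the attachment nitrogen to make the glycosidic bond
    c1 <- pent[1, ]
    u <- att - c1; d <- sqrt(sum(u^2))
    if (d > 2.2) sug[["C1p"]][1, c("x", "y", "z")] <-
      as.list(c1 + (d - 1.47) * u / d)
    sug[["O3p"]] <- atom_row("O", radial_out(pent[4, ], ring_center, 1.43),
                             "RIBOSE")
    sug[["H1p"]] <- atom_row("H",
                             unlist(sug[["C1p"]][1, c("x", "y", "z")]) +
                               c(0, 0, 1.09), "RIBOSE")
    sug[["H3p"]] <- atom_row("H", pent[4, ] + c(0, 0, -1.09), "RIBOSE")
    # C5' exocyclic on C4', then bridging O5' and the phosphate
    c5 <- radial_out(pent[3, ], ring_center, 1.52)
    sug[["C5p"]] <- atom_row("C", c5, "RIBOSE")
    dir5 <- c5 - ring_center; dir5 <- dir5 / sqrt(sum(dir5^2))
    o5 <- c5 + 1.43 * dir5
    p <- o5 + 1.60 * dir5
    pho <- list(O5p = atom_row("O", o5, "PHOSPHATE"),
                P = atom_row("P", p, "PHOSPHATE"))
    # three terminal oxygens, tetrahedral-ish around P
    perp1 <- c(-dir5[2], dir5[1], 0)
    perp1 <- perp1 / sqrt(sum(perp1^2))
    perp2 <- c(dir5[2] * perp1[3] - dir5[3] * perp1[2],
               dir5[3] * perp1[1] - dir5[1] * perp1[3],
               dir5[1] * perp1[2] - dir5[2] * perp1[1])
    for (k in 1:3) {
      ang <- 2 * pi * (k - 1) / 3
      u <- 0.5 * dir5 + 0.866 * (cos(ang) * perp1 + sin(ang) * perp2)
      pho[[paste0("OP", k)]] <- atom_row("O", p + 1.50 * u, "PHOSPHATE")
    }
    df <- do.call(rbind, c(rows, sug, pho))
  }
  df$molecule_id <- 1L
  xyz <- as.matrix(df[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2L, colMeans(xyz))
  df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]
  rownames(df) <- NULL
  df
}
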