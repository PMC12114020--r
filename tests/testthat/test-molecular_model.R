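test_that("a single intact water parses from 5-column XYZ", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(single_water_xyz(), path)
  sys <- read_structure(path, "xyz", solute_total_charge = 0)
  expect_equal(nrow(sys$atoms), 3L)
  expect_true(all(sys$atoms$component == "WATER"))
  expect_equal(length(unique(sys$atoms$molecule_id)), 1L)
  expect_equal(sys$snapshot_id, "W1")
})

test_that("write/read round trip preserves counts, labels and coordinates", {
  sys <- toy_snapshot(1)
  for (fmt in c("xyz", "pdb")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_structure(sys, path, fmt)
    back <- read_structure(path, fmt,
                           solute_total_charge = sys$solute_total_charge,
                           sphere_radius = sys$sphere_radius)
    expect_equal(nrow(back$atoms), nrow(sys$atoms))
    expect_equal(back$atoms$element, sys$atoms$element)
    expect_equal(back$atoms$component, sys$atoms$component)
    tol <- if (fmt == "xyz") 1e-4 else 1.1e-3
    expect_close(as.matrix(back$atoms[, c("x", "y", "z")]),
                 as.matrix(sys$atoms[, c("x", "y", "z")]), tol)
    # molecule grouping is preserved up to relabeling
    expect_equal(length(unique(back$atoms$molecule_id)),
                 length(unique(sys$atoms$molecule_id)))
  }
})

test_that("XYZ round trip preserves metadata on the comment line", {
  sys <- toy_snapshot(1)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_structure(sys, path)
  back <- read_structure(path)
  expect_equal(back$snapshot_id, sys$snapshot_id)
  expect_equal(back$solute_total_charge, sys$solute_total_charge)
  expect_equal(back$sphere_radius, sys$sphere_radius)
})

test_that("PDB with ADE + 5 WAT residues partitions molecules correctly", {
  lines <- c(
    sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            1:4, c("N9", "C8", "N7", "C5"), "ADE", 1,
            c(0, 1.3, 2.0, 1.2), c(0, 0.3, -0.7, -1.9), c(0, 0, 0, 0)))
  n <- 4L
  for (w in 1:5) {
    o <- c(4 + w * 2, 0, 0)
    lines <- c(lines, sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      n + 1:3, c("O", "H1", "H2"), "WAT", 1 + w,
      o[1] + c(0, 0.76, -0.76), o[2] + c(0, 0.59, 0.59), rep(o[3], 3)))
    n <- n + 3L
  }
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), path)
  sys <- read_structure(path, "pdb", sphere_radius = 40)
  # brute-force residue scan: 5 water residues x 3 atoms, 1 solute molecule
  expect_equal(sum(sys$atoms$component == "WATER"), 15L)
  wat_ids <- unique(sys$atoms$molecule_id[sys$atoms$component == "WATER"])
  sol_ids <- unique(sys$atoms$molecule_id[sys$atoms$component != "WATER"])
  expect_equal(length(wat_ids), 5L)
  expect_equal(length(sol_ids), 1L)
  expect_false(sol_ids %in% wat_ids)
  expect_true(all(sys$atoms$component[1:4] == "BASE"))
})

test_that("solute-only systems write one row per atom", {
  sys <- make_droplet(solute_template("TOY")[, c("element", "x", "y", "z",
                                                 "component")],
                      water_o = NULL, sphere_radius = 10)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_structure(sys, path)
  lines <- readLines(path)
  expect_equal(as.integer(lines[1]), 8L)
  expect_equal(length(lines), 2L + 8L)
  # 1 solute atom + 2 waters: 7 rows, 3 molecules
  sys2 <- make_droplet(one_atom_solute(),
                       data.frame(x = c(3, -3), y = 0, z = 0),
                       sphere_radius = 10)
  path2 <- withr::local_tempfile(fileext = ".xyz")
  write_structure(sys2, path2)
  back <- read_structure(path2)
  expect_equal(nrow(back$atoms), 7L)
  expect_equal(length(unique(back$atoms$molecule_id)), 3L)
})

test_that("malformed and inconsistent inputs fail with informative errors", {
  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "comment", "O 0 0 0 WATER", "H x 0 0 WATER"), bad)
  expect_error(read_structure(bad), "line 4")
  # water with only one H is an integrity error
  lone <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "c", "O 0 0 0 WATER", "H 0.76 0.59 0 WATER"), lone)
  expect_error(read_structure(lone, solute_total_charge = 0), "integrity")
  # unknown component token
  tok <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "c", "C 0 0 0 SUGAR"), tok)
  expect_error(read_structure(tok), "component token")
})

test_that("component sets partition the atom list", {
  sys <- toy_snapshot(1)
  comp <- sys$atoms$component
  expect_true(all(comp %in% c("BASE", "RIBOSE", "PHOSPHATE", "WATER")))
  expect_equal(sum(comp != "WATER") + sum(comp == "WATER"), nrow(sys$atoms))
})

test_that("validation rejects broken water groups and stray atoms", {
  at <- data.frame(element = c("C", "O", "H"), x = c(0, 3, 3.76),
                   y = c(0, 0, 0.59), z = 0,
                   component = c("BASE", "WATER", "WATER"),
                   molecule_id = c(1L, 2L, 2L), stringsAsFactors = FALSE)
  expect_error(molecular_system(at, sphere_radius = 10), "water molecule")
  at2 <- one_atom_solute()
  at2$molecule_id <- 1L
  at2 <- rbind(at2, within(at2, x <- 50))
  expect_error(molecular_system(at2, sphere_radius = 10), "beyond")
})
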