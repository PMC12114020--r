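test_that("symmetric two-site solutions split the charge evenly", {
  pos <- rbind(c(0, 0, 0), c(2, 0, 0))
  s <- eem_solve(c(0.4, 0.4), c(0.8, 0.8), pos, -1)
  expect_close(s$charges, c(-0.5, -0.5), 1e-12)
  s0 <- eem_solve(c(0.4, 0.4), c(0.8, 0.8), pos, 0)
  expect_close(s0$charges, c(0, 0), 1e-12)
})

test_that("three-site charges match an independent constrained minimizer", {
  chi <- c(0.3, 0.5, 0.4); eta <- c(0.7, 1.1, 0.9)
  pos <- rbind(c(0, 0, 0), c(1.4, 0.2, -0.1), c(0.5, 1.2, 0.9))
  vext <- c(0.02, -0.05, 0.01)
  got <- eem_solve(chi, eta, pos, -1, vext)
  # oracle: eliminate the constraint (q3 = Q - q1 - q2) and minimize the
  # explicit energy numerically
  energy <- function(q12) {
    q <- c(q12, -1 - sum(q12))
    pb <- qmmmion::ang_to_bohr(pos)
    e <- sum(chi * q) + 0.5 * sum(eta * q^2) + sum(q * vext)
    for (i in 1:2) for (j in (i + 1):3) {
      r <- sqrt(sum((pb[i, ] - pb[j, ])^2))
      s <- 2 / (eta[i] + eta[j])
      e <- e + q[i] * q[j] / sqrt(r^2 + s^2)
    }
    e
  }
  opt <- optim(c(-0.3, -0.3), energy, method = "BFGS",
               control = list(reltol = 1e-15))
  oracle <- c(opt$par, -1 - sum(opt$par))
  expect_close(got$charges, oracle, 1e-6)
  expect_lt(abs(got$energy - energy(opt$par[1:2])), 1e-8)
})

test_that("a uniform external potential shifts the energy by c * Q", {
  sys <- toy_snapshot(1)
  part <- select_qm_region(sys, 3.4)
  springs <- build_springs(sys)
  base <- compute_state(sys, part, "ANION", "GAS", springs = springs)
  cshift <- 0.037
  shifted <- compute_state(sys, part, "ANION", "GAS", springs = springs,
                           extra_potential = rep(cshift,
                                                 length(part$qm_indices)))
  expect_close(shifted$charges$charges, base$charges$charges, 1e-9)
  expect_equal(shifted$e_pol_or_gas_qm - base$e_pol_or_gas_qm,
               cshift * sys$solute_total_charge, tolerance = 1e-10)
})

test_that("decomposition closes and classical terms are state-independent", {
  sys <- toy_snapshot(2)
  part <- select_qm_region(sys, 3.4)
  springs <- build_springs(sys)
  for (state in c("ANION", "NEUTRAL")) {
    st <- compute_state(sys, part, state, "POLARIZED", springs = springs)
    expect_lt(abs(st$e_total - (st$e_pol_or_gas_qm + st$e_qm_mm_vdw +
                                  st$e_mm)), 1e-10)
  }
  a <- compute_state(sys, part, "ANION", "POLARIZED", springs = springs)
  n <- compute_state(sys, part, "NEUTRAL", "POLARIZED", springs = springs)
  expect_identical(a$e_qm_mm_vdw, n$e_qm_mm_vdw)
  expect_identical(a$e_mm, n$e_mm)
})

test_that("empty MM region makes POLARIZED and GAS coincide", {
  sys <- make_droplet(solute_template("TOY")[, c("element", "x", "y", "z",
                                                 "component")],
                      water_o = NULL, sphere_radius = 10)
  part <- select_qm_region(sys, 3.4)
  pol <- compute_state(sys, part, "ANION", "POLARIZED")
  gas <- compute_state(sys, part, "ANION", "GAS")
  expect_equal(pol$e_pol_or_gas_qm, gas$e_pol_or_gas_qm, tolerance = 1e-12)
  expect_equal(pol$e_total, gas$e_total, tolerance = 1e-12)
})

test_that("energy is invariant under rigid translation and rotation", {
  sys <- toy_snapshot(1)
  part <- select_qm_region(sys, 3.4)
  ctx <- qmmmion:::engine_context(sys, part)
  X <- ang_to_bohr(qmmmion:::coords(sys))
  e0 <- qmmmion:::engine_eval(ctx, X, -1, "POLARIZED")$e_total
  Xt <- X + matrix(c(5, -3, 2), nrow(X), 3, byrow = TRUE)
  th <- 0.9
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_lt(abs(qmmmion:::engine_eval(ctx, Xt, -1, "POLARIZED")$e_total - e0),
            1e-9)
  expect_lt(abs(qmmmion:::engine_eval(ctx, X %*% Rz, -1,
                                      "POLARIZED")$e_total - e0), 1e-9)
})

test_that("analytic gradients match central finite differences", {
  sys <- toy_snapshot(3)
  part <- select_qm_region(sys, 3.0)
  ctx <- qmmmion:::engine_context(sys, part)
  X <- ang_to_bohr(qmmmion:::coords(sys))
  set.seed(4)
  idx <- cbind(sample(nrow(X), 5), sample(3, 5, replace = TRUE))
  h <- 1e-5
  for (emb in c("POLARIZED", "GAS")) {
    g <- qmmmion:::engine_eval(ctx, X, -1, emb, gradient = TRUE)$gradient
    for (k in seq_len(nrow(idx))) {
      Xp <- X; Xp[idx[k, 1], idx[k, 2]] <- Xp[idx[k, 1], idx[k, 2]] + h
      Xm <- X; Xm[idx[k, 1], idx[k, 2]] <- Xm[idx[k, 1], idx[k, 2]] - h
      gnum <- (qmmmion:::engine_eval(ctx, Xp, -1, emb)$e_total -
                 qmmmion:::engine_eval(ctx, Xm, -1, emb)$e_total) / (2 * h)
      expect_lt(abs(gnum - g[idx[k, 1], idx[k, 2]]), 1e-8)
    }
  }
})

test_that("a displaced harmonic dimer relaxes to its rest length", {
  sol <- data.frame(element = c("C", "C"), x = c(0, 1.5), y = 0, z = 0,
                    component = "BASE", stringsAsFactors = FALSE)
  sys0 <- make_droplet(sol, NULL, sphere_radius = 10, solute_charge = 0)
  springs <- build_springs(sys0)          # rest length = 1.5 A
  expect_equal(nrow(springs), 1L)
  d <- 0.3
  sys <- sys0
  sys$atoms$x[2] <- 1.5 + d
  part <- select_qm_region(sys, 3.4)
  e_start <- compute_state(sys, part, "ANION", "POLARIZED",
                           springs = springs)$e_total
  rel <- relax_geometry(sys, part, "ANION", "POLARIZED", springs = springs)
  r_final <- abs(diff(rel$system$atoms$x))
  expect_equal(r_final, 1.5, tolerance = 1e-3)
  drop_expected <- 0.5 * springs$k[1] * ang_to_bohr(d)^2
  expect_equal(e_start - rel$state$e_total, drop_expected,
               tolerance = 1e-6)
  # starting at the minimum stays at the minimum
  rel0 <- relax_geometry(sys0, part, "ANION", "POLARIZED",
                         springs = springs)
  expect_close(as.matrix(rel0$system$atoms[, c("x", "y", "z")]),
               as.matrix(sys0$atoms[, c("x", "y", "z")]), 1e-5)
})

test_that("FULL relaxation reaches at least as low as QM_ONLY", {
  sys <- toy_snapshot(2)
  part <- select_qm_region(sys, 3.0)
  springs <- build_springs(sys)
  full <- relax_geometry(sys, part, "ANION", "POLARIZED", scope = "FULL",
                         springs = springs)
  qm_only <- relax_geometry(sys, part, "ANION", "POLARIZED",
                            scope = "QM_ONLY", springs = springs)
  expect_lte(full$state$e_total, qm_only$state$e_total + 1e-8)
  # QM_ONLY must not move MM atoms
  mm <- part$mm_indices
  expect_close(as.matrix(qm_only$system$atoms[mm, c("x", "y", "z")]),
               as.matrix(sys$atoms[mm, c("x", "y", "z")]), 1e-12)
})
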