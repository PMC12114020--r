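test_that("single-atom shell grid has the area-scaled point count", {
  grid <- build_esp_grid(matrix(0, 1, 3), 1.5, shell_scales = 1.4,
                         density = 1.0)
  r <- sqrt(rowSums(grid$points^2))
  expect_close(r, 2.1, 1e-9)
  expect_lt(abs(nrow(grid$points) - 4 * pi * 2.1^2) / (4 * pi * 2.1^2), 0.1)
})

test_that("distant atoms keep all their shell points; close ones exclude", {
  pos2 <- rbind(c(0, 0, 0), c(10, 0, 0))
  g2 <- build_esp_grid(pos2, c(1.5, 1.5), shell_scales = 1.4)
  g1 <- build_esp_grid(matrix(0, 1, 3), 1.5, shell_scales = 1.4)
  expect_equal(nrow(g2$points), 2L * nrow(g1$points))
  # brute-force point-in-sphere filter agrees for a close pair
  posc <- rbind(c(0, 0, 0), c(1.2, 0, 0))
  gc <- build_esp_grid(posc, c(1.5, 1.5), shell_scales = 1.4)
  for (j in 1:2) {
    d <- sqrt(colSums((t(gc$points) - posc[j, ])^2))
    expect_true(all(d >= 1.4 * 1.5 - 1e-9))
  }
  expect_error(build_esp_grid(rbind(c(0, 0, 0), c(0, 0, 0)), c(1, 1)),
               "coincident")
})

test_that("Coulomb potential obeys unit case, nullity and antisymmetry", {
  b <- bohr_to_ang(1)
  expect_equal(evaluate_potential(1, matrix(0, 1, 3),
                                  matrix(c(b, 0, 0), 1, 3)), 1,
               tolerance = 1e-12)
  pts <- matrix(rnorm(30), 10, 3) + 5
  expect_equal(evaluate_potential(c(0, 0), rbind(c(0, 0, 0), c(1, 0, 0)),
                                  pts), rep(0, 10))
  v <- evaluate_potential(c(0.4, -0.4),
                          rbind(c(0.5, 0, 0), c(-0.5, 0, 0)),
                          matrix(c(0, 1.3, 0), 1, 3))
  expect_lt(abs(v), 1e-14)
})

test_that("null reference potential fits all-zero charges", {
  pos <- rbind(c(0, 0, 0), c(2, 0, 0))
  grid <- build_esp_grid(pos, c(1.5, 1.5))
  fit <- fit_esp_charges(grid$points, rep(0, nrow(grid$points)), pos, 0)
  expect_close(fit$charges, c(0, 0), 1e-10)
  one <- build_esp_grid(matrix(0, 1, 3), 1.5)
  f1 <- fit_esp_charges(one$points, rep(0, nrow(one$points)),
                        matrix(0, 1, 3), -1)
  expect_equal(f1$charges, -1, tolerance = 1e-12)
})

test_that("planted charges are recovered through the full grid pipeline", {
  pos <- rbind(c(0, 0, 0), c(1.0, 0, 0))
  planted <- c(0.4, -0.4)
  grid <- build_esp_grid(pos, c(1.5, 1.5))
  v <- evaluate_potential(planted, pos, grid$points)
  fit <- fit_esp_charges(grid$points, v, pos, 0)
  expect_close(fit$charges, planted, 1e-6)
  expect_lt(fit$residual_rms, 1e-10)
})

test_that("fit is linear and the constraint is exact on random systems", {
  set.seed(7)
  for (k in 1:5) {
    n <- sample(3:8, 1)
    pos <- matrix(rnorm(3 * n, sd = 3), n, 3)
    while (min(dist(pos)) < 1.6) pos <- matrix(rnorm(3 * n, sd = 3), n, 3)
    vdw <- runif(n, 1.2, 1.8)
    grid <- build_esp_grid(pos, vdw)
    q1 <- runif(n, -0.5, 0.5); q2 <- runif(n, -0.5, 0.5)
    v1 <- evaluate_potential(q1, pos, grid$points)
    v2 <- evaluate_potential(q2, pos, grid$points)
    f1 <- fit_esp_charges(grid$points, v1, pos, sum(q1))
    f2 <- fit_esp_charges(grid$points, v2, pos, sum(q2))
    f12 <- fit_esp_charges(grid$points, v1 + v2, pos, sum(q1) + sum(q2))
    expect_close(f12$charges, f1$charges + f2$charges, 1e-8)
    expect_lt(abs(sum(f1$charges) - sum(q1)), 1e-8)
  }
})

test_that("component aggregation matches a group-by oracle and keeps totals", {
  set.seed(11)
  comps <- sample(c("BASE", "RIBOSE", "PHOSPHATE", "WATER"), 30,
                  replace = TRUE)
  vals <- rnorm(30)
  agg <- aggregate_by_component(vals, comps)
  oracle <- tapply(vals, factor(comps, levels = names(agg)), sum,
                   default = 0)
  expect_close(agg, as.numeric(oracle), 1e-12)
  expect_equal(sum(agg), sum(vals), tolerance = 1e-12)
  expect_equal(unname(aggregate_by_component(rep(0, 4),
                                             rep("BASE", 4))["BASE"]), 0)
  expect_equal(unname(aggregate_by_component(rep(2.5, 3),
                                             rep("RIBOSE", 3))["RIBOSE"]),
               7.5)
  expect_error(aggregate_by_component(1:3, c("BASE", "WATER")),
               "alignment")
})

test_that("hole profiles difference, aggregate and conserve charge", {
  comps <- c("BASE", "BASE", "RIBOSE", "PHOSPHATE", "WATER", "WATER")
  qa <- c(-0.5, -0.3, -0.1, -0.1, 0.0, 0.0)
  qn <- c(0.3, 0.1, 0.0, -0.1, 0.35, 0.35)
  h <- hole_profile(charge_set(qn, 1), charge_set(qa, -1), comps)
  expect_equal(unname(h["BASE"]), 1.2)
  expect_equal(unname(h["dRT"]),
               unname(h["BASE"] + h["RIBOSE"] + h["PHOSPHATE"]))
  expect_equal(unname(h["total"]), sum(qn) - sum(qa), tolerance = 1e-12)
  expect_equal(unname(h["total"]), 1 - (-1))
  # single-atom difference on a BASE atom
  h1 <- hole_profile(charge_set(1, 1), charge_set(0, 0), "BASE")
  expect_equal(unname(h1[c("BASE", "RIBOSE", "PHOSPHATE", "WATER")]),
               c(1, 0, 0, 0))
  expect_error(hole_profile(charge_set(c(0, 0), 0), charge_set(0, 0),
                            c("BASE", "BASE")), "alignment")
})
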