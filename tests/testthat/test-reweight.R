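test_that("exponential unbiasing weights follow exp(+U/kT)", {
  mk <- function(u) dihedral_trajectory(
    matrix(0, length(u), 1, dimnames = list(NULL, "phi")),
    bias_energy = u)

  w <- compute_weights(mk(rep(4.2, 5)), 300)
  expect_equal(w$w, rep(0.2, 5))
  expect_equal(sum(w$w), 1, tolerance = 1e-12)

  w2 <- compute_weights(mk(c(0, kT300 * log(3))), 300)
  expect_equal(w2$w, c(0.25, 0.75), tolerance = 1e-12)

  unbiased <- dihedral_trajectory(
    matrix(0, 2, 1, dimnames = list(NULL, "phi")))
  expect_error(compute_weights(unbiased), "no bias_energy")
})

test_that("weighted expectations use four contiguous blocks", {
  uw <- uniform_weights(8)
  expect_equal(weighted_expectation(rep(3.5, 8), uw),
               list(mean = 3.5, block_error = 0,
                    block_means = rep(3.5, 4)),
               tolerance = 1e-12)
  withr::with_seed(2, v <- stats::rnorm(8))
  expect_equal(weighted_expectation(v, uw)$mean, mean(v),
               tolerance = 1e-12)

  # linear ramp: block means enumerated by hand
  v <- 1:8
  e <- weighted_expectation(v, uw)
  expect_equal(e$block_means, c(1.5, 3.5, 5.5, 7.5))
  expect_equal(e$block_error, stats::sd(c(1.5, 3.5, 5.5, 7.5)))

  expect_warning(e3 <- weighted_expectation(1:3, uniform_weights(3)),
                 "block error undefined")
  expect_true(is.na(e3$block_error))
})

test_that("free-energy maps anchor the visited minimum at zero", {
  # flat ensemble: G deviates from 0 only by sampling noise
  withr::with_seed(3, ang <- cbind(phi = stats::runif(20000, -180, 180),
                                   psi = stats::runif(20000, -180, 180)))
  tr <- dihedral_trajectory(ang)
  fem <- free_energy_map(tr, uniform_weights(20000), c("phi", "psi"),
                         n_bins = 6)
  expect_true(all(fem$visited))
  expect_lt(max(abs(fem$grid)), 1.0)

  # two visited bins at P = 0.8 / 0.2: the closed-form ln ratio
  tr2 <- dihedral_trajectory(cbind(phi = c(-175, 5),
                                   psi = c(-175, 5)))
  w2 <- frame_weights(c(0.8, 0.2))
  fem2 <- free_energy_map(tr2, w2, c("phi", "psi"))
  expect_equal(min(fem2$grid, na.rm = TRUE), 0)
  expect_equal(max(fem2$grid, na.rm = TRUE), kT300 * log(4),
               tolerance = 1e-12)
  expect_equal(sum(fem2$visited), 2)
  expect_true(all(is.na(fem2$grid[!fem2$visited])))
  expect_gte(sum(fem2$grid == 0, na.rm = TRUE), 1)

  expect_error(free_energy_map(tr2, w2, c("phi", "nope")),
               "not present")
})

test_that("reweighted LEUS populations agree with the quadrature oracle", {
  s <- two_well()
  dg_ref <- quad_gap(s)
  b <- le_build(s, bias_potential(c("phi", "psi")), t_le = 5e4,
                sampler_config(seed = 31))
  tr <- us_sample(s, b, t_us = 4e5,
                  sampler_config(seed = 32, record_every = 10))
  w <- compute_weights(tr)
  e <- weighted_expectation(as.numeric(tr$angles[, "phi"] > 0), w)
  dg <- -kT300 * log(e$mean / (1 - e$mean))
  dgb <- -kT300 * log(e$block_means / (1 - e$block_means))
  expect_lt(abs(dg - dg_ref), 3 * max(stats::sd(dgb), 0.05))

  fem <- free_energy_map(tr, w, c("phi", "psi"))
  expect_identical(min(fem$grid, na.rm = TRUE), 0)
})

test_that("Hamiltonian reweighting matches direct perturbed sampling", {
  s <- analytic_surface(wells = data.frame(center_phi = c(-60, 60),
                                           center_psi = 0,
                                           depth = c(-6, -6), width = 40))
  tr <- sample_dihedrals(s, sampler_config(n_steps = 3e5, seed = 41,
                                           record_every = 4))
  # null perturbation: uniform weights
  w0 <- hamiltonian_reweight(tr, data.frame(angle = character(),
                                            dk = numeric(),
                                            theta0 = numeric(),
                                            m = numeric()))
  expect_equal(w0$w, rep(1 / n_frames(tr), n_frames(tr)),
               tolerance = 1e-12)

  pert <- data.frame(angle = "phi", dk = 1.2, theta0 = 0, m = 1)
  fw <- hamiltonian_reweight(tr, pert)
  direct <- sample_dihedrals(
    analytic_surface(wells = s$wells,
                     torsions = data.frame(angle = "phi", k = 1.2,
                                           theta0 = 0, m = 1)),
    sampler_config(n_steps = 3e5, seed = 42, record_every = 4))
  tv <- 0.5 * sum(abs(hist36(tr$angles[, "phi"], fw$w) -
                        hist36(direct$angles[, "phi"])))
  expect_lt(tv, 0.05)

  # a term peaking on the phi > 0 basin depletes it monotonically in dk
  minor_pop <- vapply(c(0, 1, 2, 4), function(dk) {
    fw <- suppressWarnings(hamiltonian_reweight(
      tr, data.frame(angle = "phi", dk = dk, theta0 = 60, m = 1)))
    sum(fw$w[tr$angles[, "phi"] > 0])
  }, numeric(1))
  expect_true(all(diff(minor_pop) < 0))

  # ESS collapse is warned about, never silent: one frame soaks up all
  # the weight
  skew <- dihedral_trajectory(
    matrix(c(rep(0, 99), 180), ncol = 1,
           dimnames = list(NULL, "phi")))
  expect_warning(
    hamiltonian_reweight(skew, data.frame(angle = "phi", dk = 10,
                                          theta0 = 0, m = 1)),
    "unreliable")
})

test_that("parameter search recovers planted dihedral terms", {
  wells <- data.frame(center_phi = c(-65, -140, -70),
                      center_psi = c(-20, 155, 140),
                      depth = c(-8, -8, -8), width = 25)
  s <- analytic_surface(c("phi_P", "psi_P"), wells = wells)
  base <- sample_dihedrals(s, sampler_config(n_steps = 3e5, seed = 51,
                                             record_every = 6))
  uw <- uniform_weights(n_frames(base))

  # identity optimum: targets equal to the ensemble's own values
  own <- list(
    J = data.frame(relation = "3JHNHA", angle = "phi_P",
                   target_Hz = ensemble_j(base, uw, "3JHNHA")$mean),
    propensity = as.list(ensemble_propensities(
      base, uw, c("phi_P", "psi_P"))[c("alpha", "beta", "PII")]),
    pair = c("phi_P", "psi_P"))
  space <- data.frame(angle = "phi_P", m = 2, theta0 = -60,
                      dk_min = 0, dk_max = 4)
  res0 <- parameter_search(base, own, space, n_iter = 30,
                           n_refine = 20, seed = 1)
  expect_equal(res0$perturbation$dk, 0)
  expect_equal(res0$objective, 0, tolerance = 1e-12)

  # empty search space returns the null perturbation
  res_e <- parameter_search(base, own,
                            space[integer(0), , drop = FALSE])
  expect_equal(nrow(res_e$perturbation), 0)

  # planted single-term perturbation recovered within 20%
  dk_true <- 1.5
  planted <- sample_dihedrals(
    analytic_surface(c("phi_P", "psi_P"), wells = wells,
                     torsions = data.frame(angle = "phi_P",
                                           k = dk_true, theta0 = -60,
                                           m = 2)),
    sampler_config(n_steps = 3e5, seed = 52, record_every = 6))
  puw <- uniform_weights(n_frames(planted))
  targets <- list(
    J = data.frame(relation = "3JHNHA", angle = "phi_P",
                   target_Hz = ensemble_j(planted, puw, "3JHNHA")$mean),
    propensity = as.list(ensemble_propensities(
      planted, puw, c("phi_P", "psi_P"))[c("alpha", "beta", "PII")]),
    pair = c("phi_P", "psi_P"))
  res <- parameter_search(base, targets, space, n_iter = 150,
                          n_refine = 80, seed = 2)
  expect_lt(abs(res$perturbation$dk - dk_true) / dk_true, 0.2)
  expect_true(all(diff(res$trace) <= 0))
})
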