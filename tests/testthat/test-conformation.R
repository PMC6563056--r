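test_that("hydrogen-bond detection applies both geometric gates", {
  # linear D-H...A at 0.20 nm, 180 degrees: detected
  mk <- function(d_ha) cartesian_frame(data.frame(
    name = c("D1", "HD1", "A1"), element = c("N", "H", "O"),
    x = c(0, 0.10, 0.10 + d_ha), y = 0, z = 0))
  don <- data.frame(donor = "D1", hydrogen = "HD1")
  w1 <- uniform_weights(1)
  hit <- detect_hbonds(list(mk(0.20)), w1, don, "A1", min_report = 0)
  expect_equal(hit$occurrence_pct, 100)

  # distance gate: 0.26 nm fails regardless of angle
  miss <- detect_hbonds(list(mk(0.26)), w1, don, "A1", min_report = 0)
  expect_equal(miss$occurrence_pct, 0)

  # angle gate: bend the acceptor to 120 degrees at 0.2 nm
  bent <- cartesian_frame(data.frame(
    name = c("D1", "HD1", "A1"), element = c("N", "H", "O"),
    x = c(0, 0.10, 0.10 + 0.2 * cos(pi / 3)),
    y = c(0, 0, 0.2 * sin(pi / 3)), z = 0))
  expect_equal(detect_hbonds(list(bent), w1, don, "A1",
                             min_report = 0)$occurrence_pct, 0)

  expect_error(detect_hbonds(list(mk(0.2)), w1,
                             data.frame(donor = "D1", hydrogen = "HX"),
                             "A1"), "HX")
})

test_that("occurrences match an exhaustive brute-force double loop", {
  withr::with_seed(11, {
    frames <- lapply(1:100, function(i) random_hbond_frame())
    w <- stats::runif(100); w <- w / sum(w)
  })
  don <- data.frame(donor = paste0("D", 1:3),
                    hydrogen = paste0("HD", 1:3))
  acc <- paste0("A", 1:4)
  fast <- detect_hbonds(frames, frame_weights(w), don, acc,
                        min_report = 0)
  slow <- brute_hbond_occurrence(frames, w, don, acc)
  key <- function(d) paste(d$donor, d$acceptor)
  slow <- slow[match(key(fast), key(slow)), ]
  expect_equal(fast$occurrence_pct, slow$occurrence_pct,
               tolerance = 1e-12)
  expect_gt(max(fast$occurrence_pct), 0)  # the comparison is non-trivial
})

test_that("backbone classification partitions the Ramachandran map", {
  expect_identical(classify_backbone(-60, -45), "alpha")
  expect_identical(classify_backbone(-140, 150), "beta")
  expect_identical(classify_backbone(-60, 120), "PII")
  expect_identical(classify_backbone(100, 100), "UC")

  # exhaustive disjointness/exhaustiveness on a fine grid
  g <- expand.grid(phi = seq(-177.5, 177.5, by = 5),
                   psi = seq(-177.5, 177.5, by = 5))
  lab <- classify_backbone(g$phi, g$psi)
  expect_true(all(lab %in% c("alpha", "beta", "PII", "UC")))

  withr::with_seed(12, {
    tr <- dihedral_trajectory(cbind(phi_P = stats::runif(500, -180, 180),
                                    psi_P = stats::runif(500, -180, 180)))
    w <- frame_weights(stats::runif(500))
  })
  p <- ensemble_propensities(tr, w, c("phi_P", "psi_P"))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p >= 0))
})

test_that("phi-bin preferences are weighted width fractions", {
  tr1 <- dihedral_trajectory(cbind(phi_P = rep(-120, 10)))
  expect_equal(unname(phi_bin_preferences(tr1, uniform_weights(10),
                                          "phi_P")),
               c(100, 0, 0))

  # exactly uniform grid of angles: fractions proportional to widths
  tru <- dihedral_trajectory(cbind(phi_P = seq(-179.75, 179.75,
                                               by = 0.5)))
  pu <- phi_bin_preferences(tru, uniform_weights(720), "phi_P")
  expect_equal(unname(pu), 100 * c(80, 100, 180) / 360,
               tolerance = 1e-9)
  expect_equal(sum(pu), 100, tolerance = 1e-9)
})

test_that("greedy clustering partitions frames with ordered sizes", {
  base_a <- build_model_frame(c(chi_S = 60))
  base_b <- build_model_frame(c(chi_S = 180))
  fit_sel <- c("N", "CA", "C", "C1", "O1", "O5")

  # identical frames collapse to one cluster
  same <- rep(list(base_a), 6)
  r1 <- cluster_conformations(same, fit_sel, cutoff = 0.1)
  expect_equal(length(r1$clusters), 1)
  expect_equal(r1$sizes, 6)

  # two well-separated geometry groups at a 0.1 nm cutoff
  withr::with_seed(13, {
    grp <- c(jittered_frames(base_a, 7, 0.004),
             jittered_frames(base_b, 5, 0.004))
  })
  r2 <- cluster_conformations(grp, fit_sel, cutoff = 0.1)
  expect_equal(length(r2$clusters), 2)
  expect_equal(sort(r2$sizes, decreasing = TRUE), r2$sizes)
  expect_setequal(unlist(r2$clusters), seq_along(grp))
  expect_equal(r2$sizes, c(7, 5))

  # cutoff above the diameter: everything is one cluster
  r3 <- cluster_conformations(grp, fit_sel,
                              cutoff = max(r2$rmsd) + 0.01)
  expect_equal(length(r3$clusters), 1)

  expect_error(cluster_conformations(grp, "NOPE"), "unknown")
})

test_that("coverage curves count clusters per restricted prefix", {
  base_a <- build_model_frame(c(chi_S = 60))
  base_b <- build_model_frame(c(chi_S = 180))
  fit_sel <- c("N", "CA", "C", "C1", "O1", "O5")
  frames <- c(rep(list(base_a), 4), rep(list(base_b), 4))
  times <- 1:8
  res <- cluster_conformations(frames, fit_sel, cutoff = 0.05)
  expect_equal(length(res$clusters), 2)

  cc <- coverage_curves(res, times, coverage_levels = c(0.99, 0.50))
  # prefix of only group A: one cluster suffices at every level
  expect_equal(cc$n_clusters_0.99[cc$time_ps == 4], 1)
  # full trajectory, two equal clusters: 50% needs 1, 99% needs 2
  expect_equal(cc$n_clusters_0.5[cc$time_ps == 8], 1)
  expect_equal(cc$n_clusters_0.99[cc$time_ps == 8], 2)
  # curves non-decreasing in level at fixed time
  expect_true(all(cc$n_clusters_0.99 >= cc$n_clusters_0.5))

  single <- cluster_conformations(rep(list(base_a), 5), fit_sel)
  cs <- coverage_curves(single, 1:5)
  expect_true(all(cs[, -1] == 1))
})

test_that("rotational correlation times recover a known diffusion", {
  # constant vector: non-decaying ACF flagged unresolvable
  cv <- matrix(rep(c(1, 2, 3), each = 200), 200, 3)
  rt0 <- rotational_tau(cv, dt_ps = 1)
  expect_false(rt0$resolvable)
  expect_true(is.na(rt0$tau_ps))

  # i.i.d. isotropic vectors: ACF(0) = 1, ACF(t > 0) near zero
  withr::with_seed(14, v <- matrix(stats::rnorm(3000), 1000, 3))
  rt1 <- rotational_tau(v, dt_ps = 1, max_lag = 20)
  expect_equal(rt1$acf[1], 1)
  expect_lt(max(abs(rt1$acf[-1])), 3 / sqrt(500))

  # known rotational diffusion constant: tau = 1 / (6 D_r)
  d_r <- 0.02
  vv <- simulate_rotational_diffusion(20000, 0.1, d_r, seed = 15)
  rt2 <- rotational_tau(vv, dt_ps = 0.1)
  expect_true(rt2$resolvable)
  expect_lt(abs(rt2$tau_ps - 1 / (6 * d_r)) / (1 / (6 * d_r)), 0.2)
})
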