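test_that("Karplus closed forms match analytic values", {
  # evaluate the bare a cos^2 + b cos + c forms via zero-offset relations
  hnha <- karplus_relation(a = 6.51, b = -1.76, c = 1.60, offset = 0)
  expect_equal(karplus_j(90, hnha), 1.60, tolerance = 1e-12)
  expect_equal(karplus_j(180, hnha), 6.51 + 1.76 + 1.60,
               tolerance = 1e-12)
  hnh2 <- karplus_relation(a = 9.6, b = -1.51, c = 0.99, offset = 0)
  expect_equal(karplus_j(180, hnh2), 9.6 + 1.51 + 0.99,
               tolerance = 1e-12)

  # presets shift the raw structural dihedral by their offset
  expect_equal(karplus_j(-60, "3JHNHA"),
               6.51 * 0.25 + (-1.76) * (-0.5) + 1.60,
               tolerance = 1e-12)  # theta = -120
  expect_equal(karplus_j(-60 + 360, "3JHNHA"),
               karplus_j(-60, "3JHNHA"), tolerance = 1e-12)
})

test_that("ensemble J averages per-frame Karplus values", {
  mk <- function(phi) dihedral_trajectory(
    matrix(phi, ncol = 1, dimnames = list(NULL, "phi_P")))

  # delta ensemble equals the pointwise value
  tr <- mk(rep(-60, 8))
  e <- ensemble_j(tr, uniform_weights(8), "3JHNHA")
  expect_equal(e$mean, 4.1075, tolerance = 1e-12)
  expect_equal(e$block_error, 0)

  # 50/50 mixture of Karplus angles 0 and 180 (raw = theta + 60)
  tr2 <- mk(rep(c(60, -120), each = 4))
  e2 <- ensemble_j(tr2, uniform_weights(8), "3JHNHA")
  j0 <- 6.51 - 1.76 + 1.60
  j180 <- 6.51 + 1.76 + 1.60
  expect_equal(e2$mean, (j0 + j180) / 2, tolerance = 1e-12)

  # every ensemble average lies inside the closed-form range
  withr::with_seed(6, {
    for (preset in c("3JHNHA", "3JHNH2", "3JHAHB_Thr", "3JHAHB2_Ser",
                     "3JHAHB3_Ser")) {
      rng <- karplus_range(preset)
      ang <- karplus_relation(preset)$angle
      tr3 <- dihedral_trajectory(
        matrix(stats::runif(200, -180, 180), ncol = 1,
               dimnames = list(NULL, ang)))
      w <- frame_weights(stats::runif(200))
      e3 <- ensemble_j(tr3, w, preset)
      expect_gte(e3$mean, rng[1] - 1e-12)
      expect_lte(e3$mean, rng[2] + 1e-12)
    }
  })

  expect_error(ensemble_j(mk(0), uniform_weights(1), "3JHNH2"),
               "not present")
})

test_that("virtual sites are placed with the documented geometry", {
  # ideal CH1: three neighbours in perfect tetrahedral directions
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1)) / sqrt(3)
  atoms <- data.frame(
    name = c("CA", "N", "C", "CB"), element = c("C", "N", "C", "C"),
    x = c(0, 0.147 * tet[1, 1], 0.153 * tet[2, 1], 0.153 * tet[3, 1]),
    y = c(0, 0.147 * tet[1, 2], 0.153 * tet[2, 2], 0.153 * tet[3, 2]),
    z = c(0, 0.147 * tet[1, 3], 0.153 * tet[2, 3], 0.153 * tet[3, 3]))
  fr <- cartesian_frame(atoms, bonds = rbind(c(1, 2), c(1, 3), c(1, 4)),
                        united = c(CA = "CH1"))
  v <- place_virtual_sites(fr)
  expect_true("HA" %in% v$atoms$name)
  expect_equal(frame_distance(v, "CA", "HA"), 0.10, tolerance = 1e-12)
  for (nb in c("N", "C", "CB")) {
    u1 <- atom_xyz(v, nb) - atom_xyz(v, "CA")
    u2 <- atom_xyz(v, "HA") - atom_xyz(v, "CA")
    ang <- acos(sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2))) * 180 / pi
    expect_equal(ang, 109.47, tolerance = 0.1)
  }

  # prochiral CH2: two mirror sites; neighbour swap only relabels
  atoms2 <- data.frame(name = c("CB", "CA", "O1"),
                       element = c("C", "C", "O"),
                       x = c(0, 0.153, -0.05),
                       y = c(0, 0, 0.14), z = c(0, 0, 0.02))
  fr2 <- cartesian_frame(atoms2, bonds = rbind(c(1, 2), c(1, 3)),
                         united = c(CB = "CH2"))
  v2 <- place_virtual_sites(fr2)
  h1 <- atom_xyz(v2, "HB1"); h2 <- atom_xyz(v2, "HB2")
  cb <- atom_xyz(v2, "CB")
  expect_equal(sqrt(sum((h1 - cb)^2)), 0.10, tolerance = 1e-12)
  ang_hch <- acos(sum((h1 - cb) * (h2 - cb)) / 0.01) * 180 / pi
  expect_equal(ang_hch, 109.47, tolerance = 0.1)
  # swap neighbour (bond) order: same two positions, swapped labels
  fr2s <- fr2; fr2s$bonds <- rbind(c(1, 3), c(1, 2))
  v2s <- place_virtual_sites(fr2s)
  expect_equal(atom_xyz(v2s, "HB1"), h2, tolerance = 1e-12)
  expect_equal(atom_xyz(v2s, "HB2"), h1, tolerance = 1e-12)

  # CH3 pseudo-site vs an explicit three-proton rotor oracle
  atoms3 <- data.frame(name = c("CG", "CB"), element = c("C", "C"),
                       x = c(0, -0.153), y = c(0, 0), z = c(0, 0))
  fr3 <- cartesian_frame(atoms3, bonds = rbind(c(1, 2)),
                         united = c(CG = "CH3"))
  v3 <- place_virtual_sites(fr3)
  expect_true("QG" %in% v3$atoms$name)
  rotor_r6 <- function(probe) {
    # explicit H's at 0.1 nm, tetrahedral to the CB-CG axis, swept 360
    d6 <- c()
    for (phi in seq(0, 359, by = 1)) {
      for (k in 0:2) {
        a <- deg <- (phi + 120 * k) * pi / 180
        hx <- 0.1 * cos((180 - 109.47) * pi / 180)
        hr <- 0.1 * sin((180 - 109.47) * pi / 180)
        h <- c(hx, hr * cos(a), hr * sin(a))
        d6 <- c(d6, sum((h - probe)^2)^(-3))
      }
    }
    mean(d6)^(-1 / 6)
  }
  # the r^-6 rotor average sits closer than the carbon (nearer protons
  # dominate); the +0.03 nm correction keeps the pseudo distance a
  # conservative upper estimate, within twice the correction of the
  # explicit rotor
  for (dprobe in c(0.35, 0.6, 1.0)) {
    probe <- c(dprobe, 0.1, -0.05)
    oracle <- rotor_r6(probe)
    pseudo <- sqrt(sum(probe^2)) + 0.03
    expect_gte(pseudo, oracle)
    expect_lt(abs(pseudo - oracle), 0.06)
  }

  bad <- cartesian_frame(atoms2, bonds = rbind(c(1, 2)),
                         united = c(CB = "CH2"))
  expect_error(place_virtual_sites(bad), "CB")
})

test_that("r^-6 averaging obeys its closed form and bounds", {
  uw <- uniform_weights(5)
  expect_equal(noe_average(rep(2.7, 5), uw)$mean, 2.7,
               tolerance = 1e-12)

  e <- noe_average(rep(c(2, 4), c(4, 4)), uniform_weights(8))
  expect_equal(e$mean, (0.5 * (2^-6 + 4^-6))^(-1 / 6),
               tolerance = 1e-12)

  withr::with_seed(7, {
    for (i in 1:200) {
      r <- stats::runif(20, 1.5, 6)
      w <- frame_weights(stats::runif(20))
      m <- noe_average(r, w)$mean
      expect_gte(m, min(r) - 1e-9)
      expect_lte(m, sum(w$w * r) + 1e-9)
    }
  })
  # adding a frame below the current average strictly decreases it
  r0 <- rep(4, 10)
  m0 <- noe_average(r0, uniform_weights(10))$mean
  m1 <- noe_average(c(r0, 2), uniform_weights(11))$mean
  expect_lt(m1, m0)

  expect_error(noe_average(c(2, -1), uniform_weights(2)),
               "nonpositive")
})

test_that("NOE reports score one-sided violations at the 1 A threshold", {
  r <- noe_records(c("a", "b", "c"), bound_A = c(2.5, 2.8, 3.0),
                   avg_A = c(3.5, 4.0, 2.4))
  expect_equal(r$violation_A, c(1.0, 1.2, 0))
  expect_identical(r$significant, c(TRUE, TRUE, FALSE))

  # frame-based report equals a manual r^-6 over site distances
  frames <- lapply(c(-170, -60, 60, 150), function(ps)
    place_virtual_sites(build_model_frame(c(psi_P = ps))))
  w <- uniform_weights(4)
  bounds <- data.frame(pair = "d(HT,H)", atom1 = "HT", atom2 = "H",
                       bound_A = 2.5)
  rep1 <- noe_report(frames, w, bounds)
  dman <- vapply(frames, site_distance, numeric(1), "HT", "H")
  expect_equal(rep1$avg_A, mean(dman^-6)^(-1 / 6), tolerance = 1e-12)
  expect_equal(rep1$violation_A,
               max(0, rep1$avg_A - 2.5), tolerance = 1e-12)

  # virtual sites are placed automatically when missing
  raw <- lapply(c(-170, -60, 60, 150), function(ps)
    build_model_frame(c(psi_P = ps)))
  expect_equal(noe_report(raw, w, bounds)$avg_A, rep1$avg_A,
               tolerance = 1e-12)

  expect_error(noe_report(frames, w,
                          data.frame(pair = "x", atom1 = "HZ9",
                                     atom2 = "H", bound_A = 2)),
               "HZ9")
})

test_that("distance distributions are unit-mass weighted histograms", {
  w <- uniform_weights(6)
  d1 <- distance_distribution(rep(3.1, 6), w, bin_width = 0.5)
  expect_equal(sum(d1$density), 1, tolerance = 1e-12)
  expect_equal(max(d1$density), 1)

  withr::with_seed(8, r <- stats::runif(50, 2, 6))
  ww <- frame_weights(stats::runif(50))
  d2 <- distance_distribution(r, ww, bin_width = 0.25)
  expect_equal(sum(d2$density), 1, tolerance = 1e-12)
  expect_equal(d2$mean, sum(ww$w * r), tolerance = 1e-12)
})
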