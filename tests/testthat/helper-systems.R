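# Shared toy systems and independent oracles used across the suite.

kT300 <- glycoleus::KB_KJMOL * 300

# deep two-well surface on the diagonal; quadrature gap solved to 3 kJ/mol
two_well <- function(delta_g = 3) two_basin_surface(delta_g)

# single asymmetric well for argmin-style checks
one_well <- function(center = c(60, 60), depth = -15, width = 25) {
  analytic_surface(wells = data.frame(center_phi = center[1],
                                      center_psi = center[2],
                                      depth = depth, width = width))
}

# independent half-plane free-energy gap from quadrature probabilities
quad_gap <- function(surface, temperature = 300) {
  q <- surface_quadrature(surface, temperature)
  minor <- sum(q$P[q$phi > 0, ])
  -glycoleus::KB_KJMOL * temperature * log(minor / (1 - minor))
}

# weighted 36-bin histogram of one angle, normalised
hist36 <- function(x, w = rep(1 / length(x), length(x))) {
  i <- floor((x + 180) / 10) + 1
  v <- numeric(36)
  for (k in seq_along(x)) v[i[k]] <- v[i[k]] + w[k]
  v / sum(v)
}

# random Cartesian frames holding donors (D*, HD*) and acceptors (A*)
# scattered in a box, for hydrogen-bond oracle comparisons
random_hbond_frame <- function(n_donors = 3, n_acceptors = 4,
                               box = 0.8) {
  nm <- character(0); el <- character(0); xyz <- NULL
  for (i in seq_len(n_donors)) {
    d <- stats::runif(3, 0, box)
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    h <- d + 0.1 * u
    nm <- c(nm, paste0("D", i), paste0("HD", i))
    el <- c(el, "N", "H")
    xyz <- rbind(xyz, d, h)
  }
  for (i in seq_len(n_acceptors)) {
    nm <- c(nm, paste0("A", i)); el <- c(el, "O")
    xyz <- rbind(xyz, stats::runif(3, 0, box))
  }
  cartesian_frame(data.frame(name = nm, element = el,
                             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

# brute-force hydrogen-bond occurrence: exhaustive double loop with
# geometry recomputed from scratch (independent of detect_hbonds)
brute_hbond_occurrence <- function(frames, w, donors, acceptors,
                                   dmax = 0.25, amin = 135) {
  out <- NULL
  for (di in seq_len(nrow(donors))) {
    for (a in acceptors) {
      occ <- 0
      for (f in seq_along(frames)) {
        fr <- frames[[f]]
        ph <- atom_xyz(fr, donors$hydrogen[di])
        pa <- atom_xyz(fr, a)
        pd <- atom_xyz(fr, donors$donor[di])
        dha <- sqrt(sum((ph - pa)^2))
        v1 <- pd - ph; v2 <- pa - ph
        ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                  sqrt(sum(v1^2) * sum(v2^2))))) *
          180 / pi
        if (dha < dmax && ang > amin) occ <- occ + w[f]
      }
      out <- rbind(out, data.frame(donor = donors$donor[di],
                                   hydrogen = donors$hydrogen[di],
                                   acceptor = a,
                                   occurrence_pct = occ * 100))
    }
  }
  out
}

# frames for clustering: base geometry jittered within a group,
# displaced between groups
jittered_frames <- function(base, n, sd_nm, shift = c(0, 0, 0)) {
  lapply(seq_len(n), function(i) {
    fr <- base
    fr$atoms$x <- fr$atoms$x + shift[1] + stats::rnorm(nrow(fr$atoms), sd = sd_nm)
    fr$atoms$y <- fr$atoms$y + shift[2] + stats::rnorm(nrow(fr$atoms), sd = sd_nm)
    fr$atoms$z <- fr$atoms$z + shift[3] + stats::rnorm(nrow(fr$atoms), sd = sd_nm)
    fr
  })
}
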