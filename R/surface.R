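#' Analytic periodic dihedral energy surfaces
#'
#' An `analytic_surface` is a smooth, exactly 360-degree-periodic energy
#' function over one named pair of dihedral angles. It is a sum of
#' wrapped 2D Gaussian wells (nearest-image distance in each dimension),
#' optional cosine torsion terms of the form `k * (1 + cos(m*theta -
#' theta0))` acting on a single angle, and a constant offset. These
#' surfaces stand in for the molecular Hamiltonian in all synthetic
#' sampling: they are integrable by simple quadrature, which makes exact
#' reference populations available for any surface.
#'
#' @param pair character(2), the names of the two angles, e.g.
#'   `c("phi_P", "psi_P")`.
#' @param wells data.frame with columns `center_phi`, `center_psi`
#'   (degrees), `depth` (kJ/mol, negative for attractive wells), `width`
#'   (degrees, Gaussian standard deviation). May have zero rows.
#' @param torsions data.frame with columns `angle` (one of `pair`), `k`
#'   (kJ/mol), `theta0` (degrees), `m` (positive integer multiplicity),
#'   contributing `k * (1 + cos(m*theta - theta0))`. May be `NULL`.
#' @param offset constant energy offset in kJ/mol.
#' @return An object of class `analytic_surface`.
#' @examples
#' s <- analytic_surface(
#'   pair = c("phi", "psi"),
#'   wells = data.frame(center_phi = c(-60, 60), center_psi = c(-60, 60),
#'                      depth = c(-20, -17), width = 30))
#' surface_energy(s, -60, -60)
#' @export
analytic_surface <- function(pair = c("phi", "psi"),
                             wells = data.frame(),
                             torsions = NULL,
                             offset = 0) {
  stopifnot(is.character(pair), length(pair) == 2, pair[1] != pair[2])
  if (nrow(wells) > 0) {
    need <- c("center_phi", "center_psi", "depth", "width")
    if (!all(need %in% names(wells)))
      stop("wells must have columns ", paste(need, collapse = ", "))
    stopifnot(all(is.finite(as.matrix(wells[need]))), all(wells$width > 0))
  }
  if (!is.null(torsions) && nrow(torsions) > 0) {
    need <- c("angle", "k", "theta0", "m")
    if (!all(need %in% names(torsions)))
      stop("torsions must have columns ", paste(need, collapse = ", "))
    if (!all(torsions$angle %in% pair))
      stop("torsion angles must belong to the surface's pair")
    stopifnot(all(torsions$m >= 1), all(torsions$m == round(torsions$m)))
  }
  structure(list(pair = pair, wells = wells, torsions = torsions,
                 offset = offset),
            class = "analytic_surface")
}

#' Evaluate an analytic surface
#'
#' Vectorised evaluation of the surface energy at arbitrary angle pairs.
#' The result is exactly periodic: `surface_energy(s, phi + 360, psi)`
#' equals `surface_energy(s, phi, psi)`.
#'
#' @param surface an [analytic_surface()].
#' @param phi,psi numeric vectors of angles in degrees (recycled to a
#'   common length).
#' @return Numeric vector of energies in kJ/mol.
#' @export
surface_energy <- function(surface, phi, psi) {
  stopifnot(inherits(surface, "analytic_surface"))
  n <- max(length(phi), length(psi))
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  e <- rep(surface$offset, n)
  w <- surface$wells
  if (!is.null(w) && nrow(w) > 0) {
    for (t in seq_len(nrow(w))) {
      dphi <- angle_diff(phi, w$center_phi[t])
      dpsi <- angle_diff(psi, w$center_psi[t])
      e <- e + w$depth[t] * exp(-(dphi^2 + dpsi^2) / (2 * w$width[t]^2))
    }
  }
  tor <- surface$torsions
  if (!is.null(tor) && nrow(tor) > 0) {
    for (t in seq_len(nrow(tor))) {
      th <- if (tor$angle[t] == surface$pair[1]) phi else psi
      e <- e + tor$k[t] * (1 + cos(deg2rad(tor$m[t] * th - tor$theta0[t])))
    }
  }
  e
}

#' Sampler configuration
#'
#' Parameters of the Metropolis chain used for all synthetic sampling.
#' Proposals perturb every angle independently by a uniform deviate in
#' `[-step_size, step_size]` degrees, with periodic wrapping.
#'
#' @param temperature simulation temperature in K (default 300).
#' @param n_steps number of Metropolis steps.
#' @param step_size maximal per-angle proposal perturbation in degrees,
#'   in (0, 180].
#' @param seed integer RNG seed; identical seeds give bit-identical
#'   trajectories.
#' @param record_every save one frame every this many steps.
#' @param dt_ps nominal time per step in ps, used only to label frames
#'   with strictly increasing times.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(temperature = 300, n_steps = 10000,
                           step_size = 30, seed = 1, record_every = 10,
                           dt_ps = 0.002) {
  stopifnot(temperature > 0, n_steps >= 0,
            step_size > 0, step_size <= 180,
            record_every >= 1, dt_ps > 0)
  structure(list(temperature = temperature, n_steps = as.integer(n_steps),
                 step_size = step_size, seed = as.integer(seed),
                 record_every = as.integer(record_every), dt_ps = dt_ps),
            class = "sampler_config")
}

# Flatten one-or-more surfaces / biases into the matrices the C++ chain
# expects.  Returns angle names, pair index matrix, well/torsion term
# matrices, offset, and bias descriptors.
.chain_setup <- function(surfaces, biases) {
  if (inherits(surfaces, "analytic_surface")) surfaces <- list(surfaces)
  if (!is.null(biases) && inherits(biases, "bias_potential"))
    biases <- list(biases)
  angle_names <- unique(unlist(lapply(surfaces, function(s) s$pair)))
  if (!is.null(biases)) {
    bpairs <- lapply(biases, function(b) b$pair)
    all_b <- unlist(bpairs)
    if (anyDuplicated(all_b))
      stop("bias potentials must act on disjoint angle pairs")
    if (!all(all_b %in% angle_names))
      stop("bias angle pair not present among the sampled angles: ",
           paste(setdiff(all_b, angle_names), collapse = ", "))
  }
  pairs <- t(vapply(surfaces, function(s)
    match(s$pair, angle_names) - 1L, integer(2)))
  terms <- matrix(0, 0, 5)
  tors <- matrix(0, 0, 4)
  offset <- 0
  for (i in seq_along(surfaces)) {
    s <- surfaces[[i]]
    offset <- offset + s$offset
    if (!is.null(s$wells) && nrow(s$wells) > 0)
      terms <- rbind(terms, cbind(i - 1L, s$wells$center_phi,
                                  s$wells$center_psi, s$wells$depth,
                                  s$wells$width))
    if (!is.null(s$torsions) && nrow(s$torsions) > 0)
      tors <- rbind(tors, cbind(
        match(s$torsions$angle, angle_names) - 1L,
        s$torsions$k, s$torsions$theta0, s$torsions$m))
  }
  bias_pair <- matrix(0L, 0, 2)
  bias_w <- list()
  bias_sigma <- numeric(0)
  if (!is.null(biases)) {
    bias_pair <- t(vapply(biases, function(b)
      match(b$pair, angle_names) - 1L, integer(2)))
    bias_w <- lapply(biases, function(b) b$weights)
    bias_sigma <- vapply(biases, function(b) b$sigma, numeric(1))
  }
  list(angle_names = angle_names, pairs = pairs, terms = terms,
       tors = tors, offset = offset, bias_pair = bias_pair,
       bias_w = bias_w, bias_sigma = bias_sigma)
}

#' Sample dihedral ensembles by Metropolis Monte Carlo
#'
#' Runs a Metropolis chain targeting `exp(-[U_surface + U_bias] / kB T)`
#' over the union of the angle pairs of the supplied surfaces. When one
#' or more frozen bias potentials are supplied their total energy is
#' recorded per saved frame (the quantity needed for exponential
#' reweighting back to the unbiased ensemble).
#'
#' @param surface an [analytic_surface()] or a list of them on disjoint
#'   or distinct angle pairs; their energies add.
#' @param config a [sampler_config()].
#' @param bias optional [bias_potential()] or list of them on disjoint
#'   angle pairs; evaluated but never modified.
#' @param init optional named numeric vector of starting angles in
#'   degrees; defaults to 0 for every angle.
#' @return A [dihedral_trajectory()] with `bias_energy` present iff
#'   `bias` was given.
#' @seealso [le_build()], [us_sample()], [compute_weights()]
#' @export
sample_dihedrals <- function(surface, config, bias = NULL, init = NULL) {
  stopifnot(inherits(config, "sampler_config"))
  setup <- .chain_setup(surface, bias)
  n_ang <- length(setup$angle_names)
  x0 <- rep(0, n_ang)
  names(x0) <- setup$angle_names
  if (!is.null(init)) x0[names(init)] <- init

  res <- withr::with_seed(config$seed, cpp_run_chain(
    init = unname(x0),
    pairs = setup$pairs, terms = setup$terms, tors = setup$tors,
    offset = setup$offset,
    n_steps = config$n_steps, step_size = config$step_size,
    temperature = config$temperature, record_every = config$record_every,
    bias_pair = setup$bias_pair, bias_w = setup$bias_w,
    bias_sigma = setup$bias_sigma,
    le_index = -1L, increment_c = 0, deposit_every = 0L))

  frames <- res$frames
  colnames(frames) <- setup$angle_names
  times <- seq_len(nrow(frames)) * config$record_every * config$dt_ps
  dihedral_trajectory(frames, times = times,
                      bias_energy = if (length(setup$bias_w)) res$bias_energy)
}

#' Two-basin toy surface with a prescribed free-energy gap
#'
#' Builds the standard two-well test surface: Gaussian wells at
#' `centers` (default (-60, -60) and (+60, +60)) of width `width`,
#' the first at `depth`, the second solved by quadrature bisection so
#' that the free-energy difference between the `phi > 0` and `phi < 0`
#' half-planes is exactly `delta_g` at `temperature`. Because the gap
#' is defined on populations (not well depths), the entropic
#' contribution of the basin shapes is accounted for automatically.
#'
#' @param delta_g target half-plane free-energy difference in kJ/mol
#'   (default 3).
#' @param temperature temperature in K.
#' @param depth depth of the major well in kJ/mol (negative).
#' @param width well width in degrees.
#' @param centers 2x2 matrix of well centres (rows), degrees.
#' @param pair angle names.
#' @param grid quadrature grid spacing in degrees.
#' @return An [analytic_surface()]; its quadrature half-plane gap
#'   equals `delta_g` to the accuracy of the grid.
#' @export
two_basin_surface <- function(delta_g = 3, temperature = 300,
                              depth = -20, width = 30,
                              centers = rbind(c(-60, -60), c(60, 60)),
                              pair = c("phi", "psi"), grid = 1) {
  stopifnot(depth < 0, delta_g >= 0)
  kt <- KB_KJMOL * temperature
  gap <- function(d2) {
    s <- analytic_surface(pair, wells = data.frame(
      center_phi = centers[, 1], center_psi = centers[, 2],
      depth = c(depth, d2), width = width))
    q <- surface_quadrature(s, temperature, grid)
    minor <- sum(q$P[q$phi > 0, ])
    -kt * log(minor / (1 - minor)) - delta_g
  }
  d2 <- stats::uniroot(gap, lower = depth, upper = -1e-3,
                       tol = 1e-8)$root
  analytic_surface(pair, wells = data.frame(
    center_phi = centers[, 1], center_psi = centers[, 2],
    depth = c(depth, d2), width = width))
}

#' Quadrature reference populations for a surface
#'
#' Computes the Boltzmann probability of every cell of a regular angle
#' grid by direct quadrature, `P(phi, psi) proportional to exp(-U / kB T)`.
#' This is the independent reference against which sampled and
#' reweighted ensembles are validated; it never involves the sampler.
#'
#' @param surface an [analytic_surface()].
#' @param temperature temperature in K.
#' @param grid grid spacing in degrees (default 1).
#' @return A list with `phi`, `psi` (cell-centre vectors), matrix `P`
#'   (normalised probabilities, `phi` indexing rows), and matrix `G`
#'   (free energies in kJ/mol anchored at 0 at the global minimum).
#' @examples
#' s <- analytic_surface(wells = data.frame(center_phi = c(-60, 60),
#'   center_psi = c(-60, 60), depth = c(-20, -17), width = 30))
#' q <- surface_quadrature(s)
#' # free-energy difference between the phi<0 and phi>0 half-planes:
#' -KB_KJMOL * 300 * log(sum(q$P[q$phi > 0, ]) / sum(q$P[q$phi < 0, ]))
#' @export
surface_quadrature <- function(surface, temperature = 300, grid = 1) {
  stopifnot(inherits(surface, "analytic_surface"), grid > 0)
  centers <- seq(-180 + grid / 2, 180 - grid / 2, by = grid)
  u <- outer(centers, centers,
             function(p, q) surface_energy(surface, p, q))
  kt <- KB_KJMOL * temperature
  p <- exp(-(u - min(u)) / kt)
  p <- p / sum(p)
  g <- -kt * log(p)
  g <- g - min(g)
  list(phi = centers, psi = centers, P = p, G = g,
       temperature = temperature)
}
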