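#' Frame weights for ensemble reweighting
#'
#' Normalised per-frame weights turning a (possibly biased) ensemble
#' into unbiased expectations. Objects carry the Kish effective sample
#' size `ess = 1 / sum(w^2)` and the temperature at which they were
#' computed.
#'
#' @param w numeric vector of non-negative unnormalised weights.
#' @param temperature temperature in K.
#' @return An object of class `frame_weights`: list with `w` (summing
#'   to 1), `ess`, `temperature`.
#' @export
frame_weights <- function(w, temperature = 300) {
  stopifnot(all(is.finite(w)), all(w >= 0), sum(w) > 0, temperature > 0)
  w <- w / sum(w)
  structure(list(w = w, ess = 1 / sum(w^2), temperature = temperature),
            class = "frame_weights")
}

#' @export
print.frame_weights <- function(x, ...) {
  cat("Frame weights: n =", length(x$w),
      " ESS =", format(x$ess, digits = 4),
      " T =", x$temperature, "K\n")
  invisible(x)
}

#' @rdname frame_weights
#' @param n number of frames.
#' @export
uniform_weights <- function(n, temperature = 300) {
  frame_weights(rep(1, n), temperature)
}

#' Exponential reweighting of a biased ensemble
#'
#' Computes the unbiasing weights `w_i` proportional to
#' `exp(+U_bias_i / kB T)` from the per-frame bias energies recorded
#' during umbrella sampling, so that weighted averages over the biased
#' trajectory estimate unbiased ensemble expectations. The maximal bias
#' energy is subtracted before exponentiation to guard against
#' overflow.
#'
#' @param traj a [dihedral_trajectory()] carrying `bias_energy`.
#' @param temperature temperature in K (default 300).
#' @return A [frame_weights()] object.
#' @export
compute_weights <- function(traj, temperature = 300) {
  stopifnot(inherits(traj, "dihedral_trajectory"))
  if (is.null(traj$bias_energy))
    stop("trajectory carries no bias_energy; reweighting requires a ",
         "biased ensemble (use uniform_weights() for unbiased runs)")
  u <- traj$bias_energy
  kt <- KB_KJMOL * temperature
  frame_weights(exp((u - max(u)) / kt), temperature)
}

#' Weighted ensemble average with four-block error
#'
#' The ensemble mean is `sum(w_i * v_i)`. The uncertainty is the
#' standard deviation of the four per-block weighted means obtained by
#' splitting the trajectory into four equal contiguous blocks (weights
#' renormalised within each block) — a simple autocorrelation-robust
#' error estimate.
#'
#' @param values numeric vector of per-frame values.
#' @param weights a [frame_weights()] of matching length.
#' @return List with `mean`, `block_error` (`NA` when fewer than 4
#'   frames, reported with a warning) and `block_means`.
#' @export
weighted_expectation <- function(values, weights) {
  stopifnot(inherits(weights, "frame_weights"),
            length(values) == length(weights$w))
  w <- weights$w
  m <- sum(w * values)
  n <- length(values)
  if (n < 4) {
    warning("fewer than 4 frames: block error undefined")
    return(list(mean = m, block_error = NA_real_, block_means = NULL))
  }
  blocks <- .four_blocks(n)
  bm <- vapply(1:4, function(b) {
    i <- blocks == b
    sum(w[i] * values[i]) / sum(w[i])
  }, numeric(1))
  list(mean = m, block_error = stats::sd(bm), block_means = bm)
}

# contiguous assignment of n frames to 4 (nearly) equal blocks
.four_blocks <- function(n) {
  as.integer(cut(seq_len(n), breaks = 4, labels = FALSE))
}

#' Two-dimensional free-energy map from a weighted ensemble
#'
#' Bins a named angle pair into an `n_bins x n_bins` weighted histogram
#' P (bin j covers \[-180 + j*delta, -180 + (j+1)*delta)) and converts it
#' to free energies `G = -kB T ln P`. The global minimum over visited
#' bins is anchored at exactly 0 kJ/mol; bins never visited carry `NA`
#' and a `FALSE` entry in the visited mask, never 0.
#'
#' @param traj a [dihedral_trajectory()].
#' @param weights a [frame_weights()] of matching length.
#' @param pair character(2): the angle pair (must be in `traj`). First
#'   name indexes rows of the grid.
#' @param n_bins bins per dimension (default 36, i.e. 10 degrees).
#' @param contour_spacing contour spacing for plotting, kJ/mol
#'   (default 5).
#' @return An object of class `free_energy_map`: list with `grid`
#'   (kJ/mol, `NA` for unvisited), `P`, `visited`, `pair`, `bin_width`,
#'   `centers`, `temperature`, `contour_spacing`.
#' @export
free_energy_map <- function(traj, weights, pair, n_bins = 36,
                            contour_spacing = 5) {
  stopifnot(inherits(traj, "dihedral_trajectory"),
            inherits(weights, "frame_weights"),
            length(weights$w) == n_frames(traj),
            length(pair) == 2)
  if (n_frames(traj) == 0) stop("empty trajectory")
  if (!all(pair %in% colnames(traj$angles)))
    stop("pair not present in trajectory: ",
         paste(setdiff(pair, colnames(traj$angles)), collapse = ", "))
  h <- .weighted_hist2d(traj$angles[, pair[1]], traj$angles[, pair[2]],
                        weights$w, n_bins)
  kt <- KB_KJMOL * weights$temperature
  visited <- h > 0
  g <- matrix(NA_real_, n_bins, n_bins)
  g[visited] <- -kt * log(h[visited])
  g <- g - min(g, na.rm = TRUE)
  delta <- 360 / n_bins
  structure(list(grid = g, P = h, visited = visited, pair = pair,
                 bin_width = delta,
                 centers = seq(-180 + delta / 2, 180 - delta / 2,
                               by = delta),
                 temperature = weights$temperature,
                 contour_spacing = contour_spacing),
            class = "free_energy_map")
}

.bin_of <- function(x, n_bins) {
  j <- floor((wrap_angle(x) + 180) / (360 / n_bins)) + 1
  pmin(pmax(j, 1), n_bins)
}

.weighted_hist2d <- function(x, y, w, n_bins) {
  i <- .bin_of(x, n_bins)
  j <- .bin_of(y, n_bins)
  h <- matrix(0, n_bins, n_bins)
  for (k in seq_along(w)) h[i[k], j[k]] <- h[i[k], j[k]] + w[k]
  h
}

#' @export
print.free_energy_map <- function(x, ...) {
  cat("Free-energy map G(", paste(x$pair, collapse = ", "), ") — ",
      nrow(x$grid), "x", ncol(x$grid), " bins of ", x$bin_width,
      " deg\n", sep = "")
  cat("  visited bins:", sum(x$visited), "/", length(x$visited),
      "  max G:", format(max(x$grid, na.rm = TRUE), digits = 4),
      "kJ/mol\n")
  invisible(x)
}

#' @export
plot.free_energy_map <- function(x, ...) {
  z <- x$grid
  z[!x$visited] <- max(z, na.rm = TRUE) + 2 * x$contour_spacing
  graphics::image(x$centers, x$centers, z,
                  xlab = x$pair[1], ylab = x$pair[2],
                  col = grDevices::hcl.colors(32, "viridis",
                                              rev = TRUE), ...)
  graphics::contour(x$centers, x$centers, x$grid,
                    levels = seq(0, max(x$grid, na.rm = TRUE),
                                 by = x$contour_spacing),
                    add = TRUE)
  invisible(x)
}

#' Write / read a free-energy map as matrix text
#'
#' Header lines carry the pair, bin count, temperature and contour
#' spacing; unvisited bins are written as the sentinel `NA`.
#'
#' @param fem a [free_energy_map()].
#' @param path file path.
#' @export
write_free_energy_map <- function(fem, path) {
  stopifnot(inherits(fem, "free_energy_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# pair\t", paste(fem$pair, collapse = "\t")),
    paste0("# n_bins\t", nrow(fem$grid)),
    paste0("# temperature\t", fem$temperature),
    paste0("# contour_spacing\t", fem$contour_spacing)), con)
  utils::write.table(fem$grid, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, na = "NA")
  invisible(path)
}

#' Binned occurrence map for coloured Karplus-curve plots
#'
#' Weighted occurrences of an angle pair on a fine grid (default
#' 6-degree spacing) expressed as `ln P`; negative values are set to
#' zero. This is the colouring export used to indicate preferred
#' sampling along a Karplus curve; it is distinct from (and never feeds
#' back into) the free-energy map.
#'
#' @inheritParams free_energy_map
#' @param bin_width grid spacing in degrees (default 6).
#' @return Matrix of clamped `ln P` values (rows index `pair[1]`).
#' @export
occurrence_map <- function(traj, weights, pair, bin_width = 6) {
  stopifnot(360 %% bin_width == 0)
  n_bins <- as.integer(360 / bin_width)
  h <- .weighted_hist2d(traj$angles[, pair[1]], traj$angles[, pair[2]],
                        weights$w * n_frames(traj), n_bins)
  lp <- matrix(0, n_bins, n_bins)
  lp[h > 0] <- pmax(log(h[h > 0]), 0)
  lp
}

#' Hamiltonian reweighting under a dihedral-term perturbation
#'
#' Computes weights turning an existing ensemble into the ensemble of a
#' perturbed Hamiltonian whose dihedral terms changed by
#' `delta U(theta) = sum_terms dk * (1 + cos(m*theta - theta0))`:
#' `w_i` proportional to `exp(-delta U(theta_i) / kB T)`, composed with
#' the umbrella-unbiasing factor `exp(+U_bias_i / kB T)` when the
#' trajectory carries bias energies.
#'
#' @param traj a [dihedral_trajectory()].
#' @param perturbation data.frame with columns `angle` (name in
#'   `traj`), `dk` (kJ/mol), `theta0` (degrees), `m` (multiplicity).
#'   Zero rows mean a null perturbation.
#' @param temperature temperature in K.
#' @param ess_floor warn when the Kish effective sample size falls
#'   below this (default 50).
#' @return A [frame_weights()] object.
#' @export
hamiltonian_reweight <- function(traj, perturbation, temperature = 300,
                                 ess_floor = 50) {
  stopifnot(inherits(traj, "dihedral_trajectory"))
  du <- perturbation_energy(perturbation, traj)
  kt <- KB_KJMOL * temperature
  logw <- -du / kt
  if (!is.null(traj$bias_energy))
    logw <- logw + traj$bias_energy / kt
  fw <- frame_weights(exp(logw - max(logw)), temperature)
  if (fw$ess < ess_floor)
    warning(sprintf(
      "effective sample size %.1f below floor %g: reweighting unreliable",
      fw$ess, ess_floor))
  fw
}

#' Per-frame perturbation energy of a dihedral-term change
#'
#' @param perturbation data.frame as in [hamiltonian_reweight()].
#' @param traj a [dihedral_trajectory()].
#' @return Numeric vector of `delta U` in kJ/mol (zero for a null
#'   perturbation).
#' @export
perturbation_energy <- function(perturbation, traj) {
  du <- numeric(n_frames(traj))
  if (is.null(perturbation) || nrow(perturbation) == 0) return(du)
  need <- c("angle", "dk", "theta0", "m")
  if (!all(need %in% names(perturbation)))
    stop("perturbation needs columns ", paste(need, collapse = ", "))
  stopifnot(all(perturbation$m >= 1),
            all(perturbation$m == round(perturbation$m)))
  for (t in seq_len(nrow(perturbation))) {
    a <- perturbation$angle[t]
    if (!a %in% colnames(traj$angles))
      stop("perturbed angle not in trajectory: ", a)
    th <- traj$angles[, a]
    du <- du + perturbation$dk[t] *
      (1 + cos(deg2rad(perturbation$m[t] * th - perturbation$theta0[t])))
  }
  du
}

#' Monte Carlo search for dihedral parameters matching target observables
#'
#' Searches the bounded space of dihedral-term force-constant changes
#' for the perturbation whose Hamiltonian-reweighted ensemble best
#' matches target J couplings and secondary-structure propensities.
#' The objective is the sum of squared J deviations (Hz^2) plus
#' `lambda` times the sum of squared propensity deviations
#' (`lambda = 100` by default). Candidates whose reweighted effective
#' sample size collapses below `ess_floor` are scored infeasible
#' (+Inf), never silently accepted.
#'
#' The search is a seeded random exploration of the box: `n_iter`
#' uniform draws refined by `n_refine` Gaussian perturbations around the
#' incumbent best (standard deviation one tenth of the box width).
#'
#' @param traj a [dihedral_trajectory()].
#' @param targets list with optional elements `J` (data.frame with
#'   columns `angle`, `relation` — a [karplus_relation()] preset name —
#'   and `target_Hz`) and `propensity` (named fractions for labels among
#'   `alpha`, `beta`, `PII`, `UC`, with `pair` attribute or a separate
#'   `pair` element naming the backbone angle pair).
#' @param search_space data.frame with columns `angle`, `m`, `theta0`,
#'   `dk_min`, `dk_max`; one row per searched term. Zero rows return
#'   the null perturbation.
#' @param temperature temperature in K.
#' @param lambda propensity weight in the objective (default 100).
#' @param n_iter,n_refine search effort (defaults 200 and 100).
#' @param seed integer seed for the search.
#' @param ess_floor feasibility floor on the Kish ESS (default 50).
#' @param regions propensity region definitions, see
#'   [propensity_regions()].
#' @return List with `perturbation` (best data.frame with filled `dk`),
#'   `objective`, and `trace` (objective of the incumbent best per
#'   evaluation).
#' @export
parameter_search <- function(traj, targets, search_space,
                             temperature = 300, lambda = 100,
                             n_iter = 200, n_refine = 100, seed = 1,
                             ess_floor = 50,
                             regions = propensity_regions()) {
  stopifnot(is.list(targets))
  null_pert <- if (nrow(search_space) == 0) {
    data.frame(angle = character(), dk = numeric(),
               theta0 = numeric(), m = numeric())
  } else {
    data.frame(angle = search_space$angle, dk = 0,
               theta0 = search_space$theta0, m = search_space$m)
  }

  score <- function(dk) {
    pert <- null_pert
    if (nrow(pert) > 0) pert$dk <- dk
    fw <- suppressWarnings(
      hamiltonian_reweight(traj, pert, temperature, ess_floor = 0))
    if (fw$ess < ess_floor) return(Inf)
    obj <- 0
    if (!is.null(targets$J)) {
      for (r in seq_len(nrow(targets$J))) {
        rel <- karplus_relation(targets$J$relation[r])
        jc <- ensemble_j(traj, fw, rel, angle = targets$J$angle[r])
        obj <- obj + (jc$mean - targets$J$target_Hz[r])^2
      }
    }
    if (!is.null(targets$propensity)) {
      pair <- targets$pair
      if (is.null(pair)) stop("targets$pair required with propensities")
      prop <- ensemble_propensities(traj, fw, pair, regions)
      for (lab in names(targets$propensity))
        obj <- obj + lambda * (prop[[lab]] - targets$propensity[[lab]])^2
    }
    obj
  }

  if (nrow(search_space) == 0) {
    obj0 <- score(numeric(0))
    return(list(perturbation = null_pert, objective = obj0,
                trace = obj0))
  }

  lo <- search_space$dk_min
  hi <- search_space$dk_max
  stopifnot(all(is.finite(lo)), all(is.finite(hi)), all(hi >= lo))
  width <- hi - lo

  withr::with_seed(seed, {
    best_dk <- rep(0, nrow(search_space))
    best_obj <- score(pmin(pmax(best_dk, lo), hi))
    trace <- best_obj
    for (i in seq_len(n_iter)) {
      cand <- lo + stats::runif(length(lo)) * width
      o <- score(cand)
      if (o < best_obj) { best_obj <- o; best_dk <- cand }
      trace <- c(trace, best_obj)
    }
    for (i in seq_len(n_refine)) {
      cand <- pmin(pmax(best_dk + stats::rnorm(length(lo),
                                               sd = width / 10),
                        lo), hi)
      o <- score(cand)
      if (o < best_obj) { best_obj <- o; best_dk <- cand }
      trace <- c(trace, best_obj)
    }
  })
  best <- null_pert
  best$dk <- best_dk
  list(perturbation = best, objective = best_obj, trace = trace)
}
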