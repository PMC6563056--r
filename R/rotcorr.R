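#' Rotational correlation time from a vector autocorrelation
#'
#' Computes the autocorrelation of the Legendre polynomial (order 1 or
#' 2; default 2, the NMR-relevant order) of the angle between `v(t0)`
#' and `v(t0 + t)`, averaged over all time origins, and fits
#' `A * exp(-t / tau) + c` by Levenberg-Marquardt least squares. For a
#' vector undergoing isotropic rotational diffusion with constant
#' `D_r`, the order-2 correlation time is `1 / (6 D_r)`.
#'
#' @param v numeric `n x 3` matrix: one vector per uniformly spaced
#'   frame (need not be normalised). At least 100 frames.
#' @param dt_ps time spacing between frames in ps.
#' @param order Legendre order, 1 or 2 (default 2).
#' @param max_lag maximal lag in frames (default `n %/% 5`).
#' @return List with `tau_ps`, `A`, `c`, `resolvable` (FALSE for a
#'   non-decaying autocorrelation, in which case `tau_ps` is `NA`),
#'   `lags_ps` and `acf`.
#' @export
rotational_tau <- function(v, dt_ps, order = 2, max_lag = NULL) {
  v <- as.matrix(v)
  stopifnot(ncol(v) == 3, order %in% c(1, 2), dt_ps > 0)
  n <- nrow(v)
  if (n < 100) stop("need at least 100 frames")
  v <- v / sqrt(rowSums(v^2))
  if (is.null(max_lag)) max_lag <- n %/% 5
  pl <- if (order == 1) function(x) x else function(x) (3 * x^2 - 1) / 2
  lags <- 0:max_lag
  acf <- vapply(lags, function(l) {
    if (l == 0) return(1)
    ct <- rowSums(v[1:(n - l), , drop = FALSE] *
                    v[(1 + l):n, , drop = FALSE])
    mean(pl(pmin(pmax(ct, -1), 1)))
  }, numeric(1))
  lags_ps <- lags * dt_ps

  base <- list(lags_ps = lags_ps, acf = acf)
  if (diff(range(acf)) < 1e-8)
    return(c(list(tau_ps = NA_real_, A = NA_real_, c = NA_real_,
                  resolvable = FALSE), base))
  # crude initial tau: first crossing of 1/e above the tail level
  tail_c <- mean(acf[lags > max_lag * 0.8])
  target <- tail_c + (1 - tail_c) / exp(1)
  idx <- which(acf <= target)[1]
  tau0 <- if (is.na(idx)) max(lags_ps) / 3 else max(lags_ps[idx], dt_ps)
  fit <- tryCatch(
    minpack.lm::nlsLM(acf ~ A * exp(-lags_ps / tau) + c0,
                      start = list(A = 1 - tail_c, tau = tau0,
                                   c0 = tail_c),
                      lower = c(-2, 1e-8, -1), upper = c(2, Inf, 1)),
    error = function(e) NULL)
  if (is.null(fit))
    return(c(list(tau_ps = NA_real_, A = NA_real_, c = NA_real_,
                  resolvable = FALSE), base))
  cf <- stats::coef(fit)
  c(list(tau_ps = unname(cf["tau"]), A = unname(cf["A"]),
         c = unname(cf["c0"]), resolvable = TRUE), base)
}

#' Vector series from an ensemble of frames
#'
#' Builds the per-frame vector from the centroid of one atom group to
#' the centroid of another — e.g. from the C-alpha atom to the centre
#' of the sugar moiety, or from backbone N to C. Use
#' [cross_series()] for the third, perpendicular vector.
#'
#' @param frames list of [cartesian_frame()] objects.
#' @param from,to character vectors of atom names; multi-atom groups
#'   use the unweighted centroid.
#' @return Numeric `n x 3` matrix.
#' @export
vector_series <- function(frames, from, to) {
  centroid <- function(f, atoms) {
    colMeans(do.call(rbind, lapply(atoms, function(a) atom_xyz(f, a))))
  }
  t(vapply(frames, function(f) centroid(f, to) - centroid(f, from),
           numeric(3)))
}

#' @rdname vector_series
#' @param v1,v2 `n x 3` matrices.
#' @return `cross_series()`: the row-wise cross product `v1 x v2`.
#' @export
cross_series <- function(v1, v2) {
  cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
        v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
        v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
}

#' Synthetic isotropic rotational diffusion
#'
#' Generates a unit-vector series undergoing isotropic rotational
#' diffusion with rotational diffusion constant `d_r`: at every step
#' the vector is rotated about a random axis by Gaussian angular
#' increments of variance `2 d_r dt` per Cartesian component. The
#' order-2 Legendre autocorrelation of the result decays with time
#' constant `1 / (6 d_r)` — the known-process reference used to
#' validate [rotational_tau()].
#'
#' @param n_steps number of frames.
#' @param dt_ps time step in ps.
#' @param d_r rotational diffusion constant in rad^2/ps.
#' @param seed integer seed.
#' @return Numeric `n_steps x 3` matrix of unit vectors.
#' @export
simulate_rotational_diffusion <- function(n_steps, dt_ps, d_r,
                                          seed = 1) {
  stopifnot(n_steps >= 1, dt_ps > 0, d_r > 0)
  withr::with_seed(seed, {
    v <- matrix(0, n_steps, 3)
    x <- c(1, 0, 0)
    sd_step <- sqrt(2 * d_r * dt_ps)
    for (i in seq_len(n_steps)) {
      w <- stats::rnorm(3, sd = sd_step)
      th <- sqrt(sum(w^2))
      if (th > 0) {
        k <- w / th
        # Rodrigues rotation of x about axis k by angle th
        x <- x * cos(th) +
          c(k[2] * x[3] - k[3] * x[2],
            k[3] * x[1] - k[1] * x[3],
            k[1] * x[2] - k[2] * x[1]) * sin(th) +
          k * sum(k * x) * (1 - cos(th))
        x <- x / sqrt(sum(x^2))
      }
      v[i, ] <- x
    }
    v
  })
}
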