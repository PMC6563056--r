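#' Local-elevation bias potentials on a dihedral pair
#'
#' A `bias_potential` is a 2D periodic grid of basis-function weights
#' over one pair of dihedral angles. The bias energy at `(phi, psi)` is
#' the weighted sum of wrapped Gaussian basis functions of standard
#' deviation `sigma` centred at the bin centres. The grid follows the
#' standard local-elevation discretisation: `n_bins` bins per dimension
#' (default 36), basis width `sigma = 360 / n_bins` degrees, and a force
#' constant increment `increment_c` (default 0.005 kJ/mol) added to the
#' occupied bin at every deposition event during build-up.
#'
#' @param pair character(2) naming the biased angle pair.
#' @param n_bins bins per dimension (default 36).
#' @param increment_c deposition increment in kJ/mol (default 0.005).
#' @param weights optional `n_bins x n_bins` matrix of accumulated
#'   weights (kJ/mol); defaults to all zero (an empty prototype).
#' @param visit_counts optional integer matrix of deposition counts.
#' @return An object of class `bias_potential`. `sigma` is always
#'   `360 / n_bins` and is stored for reference.
#' @seealso [le_build()], [bias_energy()], [us_sample()]
#' @export
bias_potential <- function(pair, n_bins = 36, increment_c = 0.005,
                           weights = NULL, visit_counts = NULL) {
  stopifnot(is.character(pair), length(pair) == 2, pair[1] != pair[2],
            n_bins >= 2, increment_c > 0)
  n_bins <- as.integer(n_bins)
  if (is.null(weights)) weights <- matrix(0, n_bins, n_bins)
  weights <- as.matrix(weights)
  stopifnot(nrow(weights) == n_bins, ncol(weights) == n_bins,
            all(weights >= 0))
  if (is.null(visit_counts)) visit_counts <- matrix(0L, n_bins, n_bins)
  structure(list(pair = pair, n_bins = n_bins, sigma = 360 / n_bins,
                 increment_c = increment_c, weights = weights,
                 visit_counts = visit_counts),
            class = "bias_potential")
}

#' @export
print.bias_potential <- function(x, ...) {
  cat("Local-elevation bias on (", paste(x$pair, collapse = ", "), ")\n",
      sep = "")
  cat("  grid:", x$n_bins, "x", x$n_bins,
      " sigma:", format(x$sigma), "deg",
      " increment:", x$increment_c, "kJ/mol\n")
  cat("  depositions:", sum(x$visit_counts),
      " total weight:", format(sum(x$weights)), "kJ/mol\n")
  invisible(x)
}

#' Evaluate a bias potential
#'
#' Smooth, strictly periodic, non-negative interpolation of the grid:
#' the weighted sum of wrapped Gaussian basis functions (width `sigma`)
#' centred at the bin centres.
#'
#' @param bias a [bias_potential()].
#' @param phi,psi numeric vectors of angles in degrees (recycled).
#' @return Numeric vector of bias energies in kJ/mol (all >= 0).
#' @export
bias_energy <- function(bias, phi, psi) {
  stopifnot(inherits(bias, "bias_potential"))
  n <- max(length(phi), length(psi))
  cpp_bias_energy(bias$weights, bias$sigma,
                  rep_len(as.numeric(phi), n),
                  rep_len(as.numeric(psi), n))
}

#' Build a local-elevation bias by adaptive deposition
#'
#' Runs the Metropolis sampler on `surface` under an evolving bias: at
#' every deposition event (default: every step) the increment
#' `proto$increment_c` is added to the basis weight of the currently
#' occupied bin, progressively filling the wells of the underlying
#' surface. The returned potential is frozen (build-up bookkeeping is
#' complete); `t_LE = 0` returns the prototype unchanged.
#'
#' @param surface an [analytic_surface()] (or list; see
#'   [sample_dihedrals()]) that must cover the prototype's angle pair.
#' @param proto a zero-weight [bias_potential()] prototype.
#' @param t_le number of build-up steps.
#' @param config a [sampler_config()]; `n_steps` is ignored in favour of
#'   `t_le`.
#' @param deposit_every deposition cadence in steps (default 1).
#' @param frozen optional list of already-frozen [bias_potential()]s on
#'   other pairs, applied during the build.
#' @return The built [bias_potential()] with accumulated `weights` and
#'   `visit_counts`. The sum of weights equals
#'   (number of depositions) x `increment_c` exactly.
#' @export
le_build <- function(surface, proto, t_le, config,
                     deposit_every = 1, frozen = NULL) {
  stopifnot(inherits(proto, "bias_potential"),
            inherits(config, "sampler_config"), t_le >= 0)
  if (any(proto$weights != 0))
    stop("prototype bias must have zero weights")
  if (t_le == 0) return(proto)

  biases <- c(list(proto), if (!is.null(frozen)) {
    if (inherits(frozen, "bias_potential")) list(frozen) else frozen
  })
  setup <- .chain_setup(surface, biases)
  x0 <- rep(0, length(setup$angle_names))

  res <- withr::with_seed(config$seed, cpp_run_chain(
    init = x0,
    pairs = setup$pairs, terms = setup$terms, tors = setup$tors,
    offset = setup$offset,
    n_steps = as.integer(t_le), step_size = config$step_size,
    temperature = config$temperature, record_every = 0L,
    bias_pair = setup$bias_pair, bias_w = setup$bias_w,
    bias_sigma = setup$bias_sigma,
    le_index = 0L, increment_c = proto$increment_c,
    deposit_every = as.integer(deposit_every)))

  bias_potential(proto$pair, n_bins = proto$n_bins,
                 increment_c = proto$increment_c,
                 weights = res$weights, visit_counts = res$visits)
}

#' Umbrella sampling under frozen bias potentials
#'
#' Runs production sampling with one or two frozen bias potentials on
#' disjoint angle pairs. The per-frame `bias_energy` recorded in the
#' returned trajectory is the sum of all supplied biases, each evaluated
#' on its own pair — exactly the quantity required for exponential
#' reweighting to the unbiased ensemble. Bias weights are never
#' modified.
#'
#' @param surface an [analytic_surface()] or list of them.
#' @param biases a [bias_potential()] or list of one or two on disjoint
#'   pairs.
#' @param t_us number of sampling steps.
#' @param config a [sampler_config()]; `n_steps` is ignored in favour of
#'   `t_us`.
#' @return A [dihedral_trajectory()] with `bias_energy` present.
#' @export
us_sample <- function(surface, biases, t_us, config) {
  stopifnot(inherits(config, "sampler_config"), t_us > 0)
  cfg <- config
  cfg$n_steps <- as.integer(t_us)
  if (inherits(biases, "bias_potential")) biases <- list(biases)
  traj <- sample_dihedrals(surface, cfg, bias = biases)
  traj
}

#' Read and write bias potentials as plain text
#'
#' Serialisation is a commented header (angle pair, `n_bins`, `sigma`,
#' `increment_c`, number of depositions) followed by the weight matrix;
#' the round trip is lossless.
#'
#' @param bias a [bias_potential()].
#' @param path file path.
#' @return `read_bias()` returns a [bias_potential()];
#'   `write_bias()` returns `path` invisibly.
#' @export
write_bias <- function(bias, path) {
  stopifnot(inherits(bias, "bias_potential"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# angle_pair\t", paste(bias$pair, collapse = "\t")),
    paste0("# n_bins\t", bias$n_bins),
    paste0("# sigma\t", format(bias$sigma, digits = 17)),
    paste0("# increment_c\t", format(bias$increment_c, digits = 17)),
    paste0("# n_depositions\t", sum(bias$visit_counts))), con)
  utils::write.table(format(bias$weights, digits = 17), con,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bias
#' @export
read_bias <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  get <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key))]
    if (length(ln) != 1) stop("missing header field: ", key)
    strsplit(sub(paste0("# ", key, "\t"), "", ln), "\t")[[1]]
  }
  pair <- get("angle_pair")
  n_bins <- as.integer(get("n_bins"))
  increment_c <- as.numeric(get("increment_c"))
  w <- as.matrix(utils::read.table(path, comment.char = "#", sep = "\t"))
  dimnames(w) <- NULL
  bias_potential(pair, n_bins = n_bins, increment_c = increment_c,
                 weights = w)
}
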