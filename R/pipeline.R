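#' Pipeline configuration
#'
#' Assembles (and validates) the configuration driving
#' [run_pipeline()]: the toy system's energy surfaces, the LEUS
#' schedule, the observable definitions and a single global seed from
#' which every stochastic stage derives its own seed by a fixed
#' counter scheme (`seed + stage counter`), so stages are
#' independently re-runnable.
#'
#' @param name system identifier used in outputs.
#' @param surfaces list of [analytic_surface()] objects (one per
#'   biased pair). Angle names that match the model template's
#'   settable dihedrals (`phi_P`, `psi_P`, `chi_S`, `phi_S`, `psi_S`,
#'   `theta`) enable the Cartesian stages.
#' @param template model geometry template for Cartesian analyses, or
#'   `NULL` to skip them (see [build_model_frame()]).
#' @param t_le local-elevation build steps per bias.
#' @param t_us umbrella-sampling steps.
#' @param t_unbiased plain sampling steps for the unbiased comparison.
#' @param record_every frame recording stride (steps).
#' @param step_size Metropolis step size (degrees).
#' @param temperature temperature in K.
#' @param n_bins,increment_c local-elevation grid settings (defaults
#'   36 bins, 0.005 kJ/mol).
#' @param karplus data.frame with columns `relation` (preset name) and
#'   `angle`, or `NULL`.
#' @param noe_bounds data.frame (`pair`, `atom1`, `atom2`, `bound_A`)
#'   or `NULL`.
#' @param donors,acceptors hydrogen-bond definitions (see
#'   [detect_hbonds()]) or `NULL`.
#' @param cluster_fit atom names for the clustering fit selection.
#' @param max_cartesian_frames cap on frames materialised as Cartesian
#'   geometry (subsampled evenly; default 200).
#' @param seed global integer seed.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(name, surfaces, template = "galnac_ser",
                            t_le = 20000, t_us = 100000,
                            t_unbiased = 20000,
                            record_every = 10, step_size = 30,
                            temperature = 300, n_bins = 36,
                            increment_c = 0.005,
                            karplus = NULL, noe_bounds = NULL,
                            donors = NULL, acceptors = NULL,
                            cluster_fit = c("N", "CA", "C", "C1",
                                            "O1", "O5"),
                            max_cartesian_frames = 200,
                            seed = 1, out_dir = NULL) {
  if (inherits(surfaces, "analytic_surface")) surfaces <- list(surfaces)
  stopifnot(length(surfaces) >= 1,
            all(vapply(surfaces, inherits, logical(1),
                       "analytic_surface")),
            t_le >= 0, t_us > 0, t_unbiased >= 0)
  structure(list(name = name, surfaces = surfaces, template = template,
                 t_le = t_le, t_us = t_us, t_unbiased = t_unbiased,
                 record_every = record_every, step_size = step_size,
                 temperature = temperature, n_bins = n_bins,
                 increment_c = increment_c, karplus = karplus,
                 noe_bounds = noe_bounds, donors = donors,
                 acceptors = acceptors, cluster_fit = cluster_fit,
                 max_cartesian_frames = max_cartesian_frames,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file mirrors the arguments of [pipeline_config()]; surfaces are
#' given as a list with `pair`, `wells` (list of rows with
#' `center_phi`, `center_psi`, `depth`, `width`) and optional
#' `offset`. Referenced files (e.g. an `noe_bounds` path) must exist
#' at validation time.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  surfaces <- lapply(y$surfaces, function(s)
    analytic_surface(pair = unlist(s$pair),
                     wells = do.call(rbind, lapply(s$wells,
                                                   as.data.frame)),
                     offset = if (is.null(s$offset)) 0 else s$offset))
  noe <- y$noe_bounds
  if (is.character(noe)) {
    if (!file.exists(noe)) stop("noe_bounds file not found: ", noe)
    noe <- utils::read.table(noe, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  } else if (!is.null(noe)) {
    noe <- do.call(rbind, lapply(noe, as.data.frame))
  }
  args <- y[setdiff(names(y), c("surfaces", "noe_bounds", "karplus",
                                "donors"))]
  args$surfaces <- surfaces
  args$noe_bounds <- noe
  if (!is.null(y$karplus))
    args$karplus <- do.call(rbind, lapply(y$karplus, as.data.frame))
  if (!is.null(y$donors))
    args$donors <- do.call(rbind, lapply(y$donors, as.data.frame))
  do.call(pipeline_config, args)
}

#' Run the full LEUS analysis pipeline on a toy system
#'
#' Chains every stage end to end: unbiased sampling, local-elevation
#' build-up per angle pair, frozen-bias umbrella sampling, exponential
#' reweighting, free-energy maps, J couplings with propensities, NOE
#' distances, hydrogen bonds, conformational clustering with coverage
#' curves, and rotational correlation times. Deterministic for a fixed
#' seed; when `out_dir` is set, all intermediate artifacts are written
#' as plain text together with their MD5 checksums, and every table in
#' the report can be regenerated from them without re-sampling.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `run_report`: a list of per-stage tables
#'   (`j_table`, `propensities`, `phi_preferences`, `noe`, `hbonds`,
#'   `maps`, `coverage`, `rotation`, `flags`, ...).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed0 <- config$seed
  stage_seed <- function(k) seed0 + k
  flags <- character()

  # 1. unbiased reference sampling
  unbiased <- NULL
  if (config$t_unbiased > 0)
    unbiased <- sample_dihedrals(
      config$surfaces,
      sampler_config(config$temperature, config$t_unbiased,
                     config$step_size, seed = stage_seed(1),
                     record_every = config$record_every))

  # 2. LE build per pair (earlier biases frozen during later builds)
  biases <- list()
  for (i in seq_along(config$surfaces)) {
    proto <- bias_potential(config$surfaces[[i]]$pair,
                            n_bins = config$n_bins,
                            increment_c = config$increment_c)
    biases[[i]] <- le_build(
      config$surfaces, proto, config$t_le,
      sampler_config(config$temperature, 1,
                     config$step_size, seed = stage_seed(10 + i)),
      frozen = if (i > 1) biases[seq_len(i - 1)])
  }
  if (config$t_le == 0)
    flags <- c(flags,
               "t_le = 0: umbrella phase ran with a zero bias (unflattened sampling)")

  # 3. umbrella sampling with all biases frozen
  traj <- us_sample(config$surfaces, biases, config$t_us,
                    sampler_config(config$temperature, 1,
                                   config$step_size,
                                   seed = stage_seed(20),
                                   record_every = config$record_every))
  weights <- compute_weights(traj, config$temperature)

  # 4. free-energy maps per pair
  maps <- lapply(config$surfaces, function(s)
    free_energy_map(traj, weights, s$pair, n_bins = config$n_bins))
  names(maps) <- vapply(config$surfaces, function(s)
    paste(s$pair, collapse = "_"), character(1))

  # 5. J couplings and backbone statistics
  j_table <- NULL
  if (!is.null(config$karplus)) {
    j_table <- do.call(rbind, lapply(seq_len(nrow(config$karplus)),
                                     function(r) {
      rel <- karplus_relation(config$karplus$relation[r])
      e <- ensemble_j(traj, weights, rel,
                      angle = config$karplus$angle[r])
      data.frame(relation = config$karplus$relation[r],
                 angle = config$karplus$angle[r],
                 J_Hz = e$mean, block_error_Hz = e$block_error)
    }))
  }
  propens <- NULL
  phi_pref <- NULL
  bb <- c("phi_P", "psi_P")
  if (all(bb %in% colnames(traj$angles))) {
    propens <- ensemble_propensities(traj, weights, bb)
    phi_pref <- phi_bin_preferences(traj, weights, "phi_P")
  }

  # 6. Cartesian stages on a subsample of frames
  noe <- hbonds <- coverage <- rotation <- clust <- NULL
  frames <- NULL
  if (!is.null(config$template)) {
    settable <- names(model_template_angles(config$template))
    avail <- intersect(settable, colnames(traj$angles))
    nf <- n_frames(traj)
    stride <- max(1, ceiling(nf / config$max_cartesian_frames))
    sub <- seq(1, nf, by = stride)
    frames <- lapply(sub, function(i)
      build_model_frame(traj$angles[i, avail], config$template))
    sub_w <- frame_weights(weights$w[sub], config$temperature)
    sub_t <- traj$times[sub]

    if (!is.null(config$noe_bounds))
      noe <- noe_report(frames, sub_w, config$noe_bounds)
    if (!is.null(config$donors) && !is.null(config$acceptors))
      hbonds <- detect_hbonds(frames, sub_w, config$donors,
                              config$acceptors)
    clust <- cluster_conformations(frames, config$cluster_fit)
    coverage <- coverage_curves(clust, sub_t)
    v1 <- vector_series(frames, "CA",
                        intersect(c("C1", "O5", "C2", "C5", "O1"),
                                  frames[[1]]$atoms$name))
    v2 <- vector_series(frames, "N", "C")
    dt <- if (length(sub_t) > 1) diff(sub_t)[1] else 1
    rotation <- list(
      sugar = rotational_tau(v1, dt),
      backbone = rotational_tau(v2, dt),
      normal = rotational_tau(cross_series(v1, v2), dt))
  }

  report <- structure(list(
    name = config$name, seed = seed0,
    trajectory = traj, unbiased = unbiased, biases = biases,
    weights = weights, maps = maps, j_table = j_table,
    propensities = propens, phi_preferences = phi_pref,
    noe = noe, hbonds = hbonds, clustering = clust,
    coverage = coverage, rotation = rotation, frames = frames,
    flags = flags), class = "run_report")

  if (!is.null(config$out_dir)) .write_report(report, config)
  report
}

.write_report <- function(report, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  write_trajectory(report$trajectory, p("us_trajectory.tsv"))
  for (i in seq_along(report$biases))
    write_bias(report$biases[[i]],
               p(sprintf("bias_%s.leus",
                         paste(report$biases[[i]]$pair,
                               collapse = "_"))))
  for (nm in names(report$maps))
    write_free_energy_map(report$maps[[nm]],
                          p(sprintf("fem_%s.txt", nm)))
  if (!is.null(report$j_table))
    utils::write.table(report$j_table, p("j_couplings.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$noe))
    utils::write.table(as.data.frame(report$noe), p("noe_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$hbonds))
    utils::write.table(report$hbonds, p("hbonds.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(report$coverage))
    utils::write.table(report$coverage, p("coverage_curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$frames))
    write_frames(report$frames, p("frames.pdb"))
  files <- setdiff(list.files(config$out_dir, full.names = TRUE),
                   p("checksums.txt"))
  sums <- tools::md5sum(files)
  writeLines(paste(sums, basename(names(sums)), sep = "  "),
             p("checksums.txt"))
  invisible(NULL)
}

#' @export
print.run_report <- function(x, ...) {
  cat("LEUS pipeline report —", x$name, "(seed", paste0(x$seed, ")\n"))
  cat(" US frames:", n_frames(x$trajectory),
      " ESS:", format(x$weights$ess, digits = 4), "\n")
  if (!is.null(x$propensities)) {
    cat(" propensities:",
        paste(sprintf("%s=%.2f", names(x$propensities),
                      x$propensities), collapse = " "), "\n")
  }
  if (!is.null(x$j_table)) {
    cat(" J couplings:\n")
    print(x$j_table, row.names = FALSE)
  }
  if (!is.null(x$noe)) {
    cat(" NOE report:\n")
    print(x$noe)
  }
  for (f in x$flags) cat(" flag:", f, "\n")
  invisible(x)
}
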