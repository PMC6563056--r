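#' Conformational clustering by greedy largest neighborhood
#'
#' Computes the pairwise RMSD matrix of an ensemble after least-squares
#' superposition of every pair on the fit selection (via
#' [bio3d::fit.xyz()]), then clusters with the greedy
#' largest-neighborhood algorithm: the frame with the most neighbours
#' within `cutoff` becomes the medoid of the first cluster, that
#' cluster is removed, and the procedure repeats on the remainder.
#' Ties are broken by the lowest frame index. Clusters partition all
#' frames and their sizes are non-increasing in rank order.
#'
#' @param frames list of [cartesian_frame()] objects with identical
#'   atom sets.
#' @param fit_selection character vector of atom names used for the
#'   superposition (e.g. peptide backbone plus sugar ring atoms).
#' @param calc_selection atom names over which the RMSD is computed;
#'   defaults to all atoms ("all-atom RMSD after fitting").
#' @param cutoff similarity cutoff in nm (default 0.1).
#' @return An object of class `cluster_result`: list with `clusters`
#'   (list of member index vectors), `medoids`, `membership` (integer
#'   vector), `sizes`, `cutoff`, and the `rmsd` matrix (nm).
#' @export
cluster_conformations <- function(frames, fit_selection,
                                  calc_selection = NULL, cutoff = 0.1) {
  stopifnot(is.list(frames), length(frames) >= 1, cutoff > 0)
  nm <- frames[[1]]$atoms$name
  fit_idx <- match(fit_selection, nm)
  if (length(fit_idx) == 0 || anyNA(fit_idx))
    stop("fit selection resolves to zero or unknown atoms")
  if (is.null(calc_selection)) calc_selection <- nm
  calc_idx <- match(calc_selection, nm)
  if (length(calc_idx) == 0 || anyNA(calc_idx))
    stop("calc selection resolves to zero or unknown atoms")

  n <- length(frames)
  xyz <- do.call(rbind, lapply(frames, function(f)
    as.vector(t(as.matrix(f$atoms[c("x", "y", "z")])))))
  fit_x <- bio3d::atom2xyz(fit_idx)
  calc_x <- bio3d::atom2xyz(calc_idx)

  rmsd <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    fitted <- bio3d::fit.xyz(fixed = xyz[i, ],
                             mobile = xyz[(i + 1):n, , drop = FALSE],
                             fixed.inds = fit_x, mobile.inds = fit_x)
    for (jj in seq_len(nrow(fitted))) {
      dif <- matrix(fitted[jj, calc_x] - xyz[i, calc_x],
                    ncol = 3, byrow = TRUE)
      r <- sqrt(mean(rowSums(dif^2)))
      rmsd[i, i + jj] <- rmsd[i + jj, i] <- r
    }
  }

  adjacent <- rmsd <= cutoff
  remaining <- rep(TRUE, n)
  clusters <- list()
  medoids <- integer()
  membership <- integer(n)
  while (any(remaining)) {
    counts <- colSums(adjacent[remaining, , drop = FALSE]) * remaining
    center <- which.max(counts)  # which.max takes the lowest index on ties
    members <- which(remaining & adjacent[center, ])
    k <- length(clusters) + 1
    clusters[[k]] <- members
    medoids[k] <- center
    membership[members] <- k
    remaining[members] <- FALSE
  }
  structure(list(clusters = clusters, medoids = medoids,
                 membership = membership,
                 sizes = lengths(clusters),
                 cutoff = cutoff, rmsd = rmsd),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Conformational clustering:", length(x$clusters), "clusters of",
      length(x$membership), "frames at cutoff", x$cutoff, "nm\n")
  cat("  sizes:", paste(utils::head(x$sizes, 10), collapse = ", "),
      if (length(x$sizes) > 10) "..." else "", "\n")
  invisible(x)
}

#' Cluster coverage curves over time
#'
#' For each evaluation time point, cluster memberships are restricted
#' to the frames sampled up to that point, ranked by restricted size,
#' and the minimal number of clusters whose cumulative restricted size
#' reaches each coverage level is reported. Levelling-off of these
#' curves indicates that no new conformations are being sampled.
#'
#' @param result a [cluster_result()] from the full trajectory.
#' @param times numeric frame times (ps), aligned with the clustered
#'   frames.
#' @param coverage_levels fractions of the prefix trajectory to cover
#'   (default `c(0.99, 0.95, 0.75, 0.50)`).
#' @param eval_times time points at which to evaluate; defaults to
#'   `times`. Points with an empty prefix are skipped.
#' @return data.frame with columns `time_ps` and one `n_clusters_<level>`
#'   column per level.
#' @export
coverage_curves <- function(result, times,
                            coverage_levels = c(0.99, 0.95, 0.75, 0.50),
                            eval_times = NULL) {
  stopifnot(inherits(result, "cluster_result"),
            length(times) == length(result$membership))
  if (is.null(eval_times)) eval_times <- times
  rows <- lapply(eval_times, function(t) {
    pre <- times <= t
    nt <- sum(pre)
    if (nt == 0) return(NULL)
    sizes <- sort(tabulate(result$membership[pre]), decreasing = TRUE)
    sizes <- sizes[sizes > 0]
    counts <- vapply(coverage_levels, function(lev) {
      which(cumsum(sizes) >= lev * nt)[1]
    }, numeric(1))
    c(t, counts)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- as.data.frame(rows)
  names(out) <- c("time_ps", paste0("n_clusters_", coverage_levels))
  out
}
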