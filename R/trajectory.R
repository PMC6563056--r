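#' Dihedral trajectories
#'
#' The central ensemble record: per-frame values of named periodic
#' dihedral angles (degrees, canonical range \[-180, 180)), strictly
#' increasing frame times in ps, and — iff the ensemble was generated
#' under a bias — the total biasing energy of every frame in kJ/mol.
#'
#' @param angles numeric matrix, one row per frame, with column names
#'   naming the angles (e.g. `phi_S`, `psi_S`, `phi_P`, `psi_P`). Angles
#'   outside the canonical range are wrapped with a note.
#' @param times numeric vector of frame times in ps, strictly
#'   increasing; defaults to `1:n`.
#' @param bias_energy optional numeric vector (kJ/mol), one value per
#'   frame. Present iff the trajectory was produced under a bias.
#' @return An object of class `dihedral_trajectory`: a list with
#'   elements `angles`, `times` and (optionally) `bias_energy`.
#' @export
dihedral_trajectory <- function(angles, times = NULL, bias_energy = NULL) {
  angles <- as.matrix(angles)
  if (is.null(colnames(angles)))
    stop("angle columns must be named")
  if (anyDuplicated(colnames(angles)))
    stop("duplicate angle names")
  if (!all(is.finite(angles))) stop("non-finite angle values")
  if (any(angles < -180 | angles >= 180)) {
    message("wrapping input angles into [-180, 180)")
    angles <- apply(angles, 2, wrap_angle)
  }
  n <- nrow(angles)
  if (is.null(times)) times <- seq_len(n)
  stopifnot(length(times) == n)
  if (n > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (!is.null(bias_energy)) {
    stopifnot(length(bias_energy) == n, all(is.finite(bias_energy)))
  }
  structure(list(angles = angles, times = as.numeric(times),
                 bias_energy = bias_energy),
            class = "dihedral_trajectory")
}

#' @export
print.dihedral_trajectory <- function(x, ...) {
  cat("Dihedral trajectory:", nrow(x$angles), "frames,",
      ncol(x$angles), "angles\n")
  cat("  angles:", paste(colnames(x$angles), collapse = ", "), "\n")
  cat("  time:", format(x$times[1]), "..",
      format(x$times[length(x$times)]), "ps\n")
  cat("  bias energy:",
      if (is.null(x$bias_energy)) "absent (unbiased ensemble)"
      else "present (biased ensemble)", "\n")
  invisible(x)
}

#' @export
summary.dihedral_trajectory <- function(object, ...) {
  s <- apply(object$angles, 2, function(a)
    c(min = min(a), mean = mean(a), max = max(a)))
  print(round(t(s), 2))
  invisible(t(s))
}

#' Number of frames in a trajectory
#' @param traj a [dihedral_trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$angles)

#' Read and write dihedral trajectories as tab-separated text
#'
#' The on-disk format is a header row `time_ps <angle names...>
#' [bias_kJmol]` followed by one frame per line. Reading and writing
#' round-trip the canonical form losslessly; a missing `bias_kJmol`
#' column yields a trajectory without bias energies (never zero-filled).
#' Input angles outside \[-180, 180) are wrapped with a note.
#'
#' @param path file path.
#' @return `read_trajectory()` returns a [dihedral_trajectory()];
#'   `write_trajectory()` returns `path` invisibly.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  if (names(df)[1] != "time_ps")
    stop("first column must be time_ps, got: ", names(df)[1])
  has_bias <- names(df)[ncol(df)] == "bias_kJmol"
  acol <- setdiff(names(df), c("time_ps", "bias_kJmol"))
  if (length(acol) == 0) stop("no angle columns found")
  dihedral_trajectory(
    as.matrix(df[acol]),
    times = df$time_ps,
    bias_energy = if (has_bias) df$bias_kJmol)
}

#' @rdname read_trajectory
#' @param traj a [dihedral_trajectory()].
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "dihedral_trajectory"))
  df <- data.frame(time_ps = traj$times, check.names = FALSE)
  df <- cbind(df, as.data.frame(traj$angles))
  if (!is.null(traj$bias_energy)) df$bias_kJmol <- traj$bias_energy
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
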