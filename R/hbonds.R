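#' Geometric hydrogen-bond criterion
#'
#' A donor-hydrogen...acceptor contact counts as a hydrogen bond when
#' the hydrogen-acceptor distance is smaller than `max_ha_nm` (default
#' 0.25 nm) and the donor-hydrogen-acceptor angle is larger than
#' `min_dha_deg` (default 135 degrees).
#'
#' @param max_ha_nm maximal H...A distance in nm.
#' @param min_dha_deg minimal D-H...A angle in degrees.
#' @return An object of class `hbond_criterion`.
#' @export
hbond_criterion <- function(max_ha_nm = 0.25, min_dha_deg = 135) {
  stopifnot(max_ha_nm > 0, min_dha_deg > 0, min_dha_deg <= 180)
  structure(list(max_ha_nm = max_ha_nm, min_dha_deg = min_dha_deg),
            class = "hbond_criterion")
}

# is D-H...A hydrogen-bonded in this frame?
.is_hbond <- function(frame, donor, hydrogen, acceptor, criterion) {
  ph <- atom_xyz(frame, hydrogen)
  pa <- atom_xyz(frame, acceptor)
  d_ha <- sqrt(sum((ph - pa)^2))
  if (d_ha >= criterion$max_ha_nm) return(FALSE)
  pd <- atom_xyz(frame, donor)
  v1 <- pd - ph
  v2 <- pa - ph
  ang <- rad2deg(acos(pmin(pmax(
    sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)), -1), 1)))
  ang > criterion$min_dha_deg
}

#' Weighted hydrogen-bond occurrences over an ensemble
#'
#' Applies the geometric criterion to every donor/acceptor combination
#' in every frame and reports the weighted occurrence percentage per
#' pair. Donor-acceptor pairs within the same functional group
#' (hydrogen bonded to the acceptor) are skipped.
#'
#' @param frames list of [cartesian_frame()] objects.
#' @param weights a [frame_weights()] with one weight per frame.
#' @param donors data.frame with columns `donor` and `hydrogen` (atom
#'   names; the hydrogen must exist in the frames).
#' @param acceptors character vector of acceptor atom names.
#' @param criterion an [hbond_criterion()].
#' @param min_report report filter in percent (default 2); pairs below
#'   it are dropped from the result (set 0 to keep all). The filter
#'   changes only what is reported, never what is computed.
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor`,
#'   `occurrence_pct`, sorted by decreasing occurrence.
#' @export
detect_hbonds <- function(frames, weights, donors, acceptors,
                          criterion = hbond_criterion(),
                          min_report = 2) {
  stopifnot(is.list(frames), inherits(weights, "frame_weights"),
            length(frames) == length(weights$w),
            all(c("donor", "hydrogen") %in% names(donors)))
  nm <- frames[[1]]$atoms$name
  missing_h <- setdiff(donors$hydrogen, nm)
  if (length(missing_h) > 0)
    stop("donor hydrogen(s) not present in frames: ",
         paste(missing_h, collapse = ", "))
  missing_a <- setdiff(acceptors, nm)
  if (length(missing_a) > 0)
    stop("acceptor(s) not present in frames: ",
         paste(missing_a, collapse = ", "))

  out <- NULL
  for (di in seq_len(nrow(donors))) {
    for (a in acceptors) {
      if (a == donors$donor[di]) next
      occ <- sum(weights$w * vapply(frames, .is_hbond, logical(1),
                                    donors$donor[di],
                                    donors$hydrogen[di], a,
                                    criterion)) * 100
      out <- rbind(out, data.frame(donor = donors$donor[di],
                                   hydrogen = donors$hydrogen[di],
                                   acceptor = a,
                                   occurrence_pct = occ))
    }
  }
  out <- out[order(-out$occurrence_pct), , drop = FALSE]
  rownames(out) <- NULL
  out[out$occurrence_pct >= min_report, , drop = FALSE]
}
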