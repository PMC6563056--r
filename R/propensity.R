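#' Secondary-structure propensity regions of the Ramachandran map
#'
#' Named phi/psi boxes assigning every backbone conformation to exactly
#' one of `alpha`, `beta`, `PII` (polyproline II) or `UC`
#' (unclassified). The shipped defaults are a package choice consistent
#' with the conventional locations of the three regions:
#' \itemize{
#'   \item beta: phi in \[-180, -100) and psi in \[50, 180) or
#'     \[-180, -150);
#'   \item PII: phi in \[-100, -20) and psi in \[50, 180);
#'   \item alpha: phi in \[-160, -20) and psi in \[-120, 50), minus any
#'     overlap with beta/PII (none with these defaults);
#'   \item UC: everything else.
#' }
#' All edges are half-open, so the boxes are pairwise disjoint and the
#' four labels exhaustively partition the map: propensities over any
#' weighted ensemble sum to exactly 1.
#'
#' @param boxes optional replacement list; each element is a list with
#'   `label`, `phi = c(min, max)` and a list `psi` of one or more
#'   `c(min, max)` intervals. Earlier entries win on overlap.
#' @return An object of class `propensity_regions`.
#' @export
propensity_regions <- function(boxes = NULL) {
  if (is.null(boxes)) {
    boxes <- list(
      list(label = "beta", phi = c(-180, -100),
           psi = list(c(50, 180), c(-180, -150))),
      list(label = "PII", phi = c(-100, -20),
           psi = list(c(50, 180))),
      list(label = "alpha", phi = c(-160, -20),
           psi = list(c(-120, 50))))
  }
  structure(list(boxes = boxes), class = "propensity_regions")
}

#' Classify a backbone conformation
#'
#' Half-open box membership test; deterministic, first matching box
#' wins, no box means `UC`.
#'
#' @param phi,psi backbone dihedrals in degrees (vectors recycled).
#' @param regions a [propensity_regions()].
#' @return Character vector of labels in
#'   `c("alpha", "beta", "PII", "UC")`.
#' @examples
#' classify_backbone(-60, -45)    # alpha
#' classify_backbone(-140, 150)   # beta
#' @export
classify_backbone <- function(phi, psi, regions = propensity_regions()) {
  n <- max(length(phi), length(psi))
  phi <- wrap_angle(rep_len(phi, n))
  psi <- wrap_angle(rep_len(psi, n))
  lab <- rep("UC", n)
  unset <- rep(TRUE, n)
  for (b in regions$boxes) {
    inphi <- phi >= b$phi[1] & phi < b$phi[2]
    inpsi <- rep(FALSE, n)
    for (iv in b$psi) inpsi <- inpsi | (psi >= iv[1] & psi < iv[2])
    hit <- unset & inphi & inpsi
    lab[hit] <- b$label
    unset[hit] <- FALSE
  }
  lab
}

#' Weighted secondary-structure propensities of an ensemble
#'
#' @param traj a [dihedral_trajectory()].
#' @param weights a [frame_weights()] of matching length.
#' @param pair character(2): the backbone angle pair, e.g.
#'   `c("phi_P", "psi_P")`.
#' @param regions a [propensity_regions()].
#' @return Named numeric vector of fractions over
#'   `alpha`, `beta`, `PII`, `UC`, summing to 1.
#' @export
ensemble_propensities <- function(traj, weights, pair,
                                  regions = propensity_regions()) {
  stopifnot(all(pair %in% colnames(traj$angles)))
  lab <- classify_backbone(traj$angles[, pair[1]],
                           traj$angles[, pair[2]], regions)
  out <- c(alpha = 0, beta = 0, PII = 0, UC = 0)
  for (l in names(out)) out[l] <- sum(weights$w[lab == l])
  out
}

#' Weighted fractions of an angle over named bins
#'
#' Bins one dihedral by a strictly increasing edge vector spanning
#' \[-180, 180\] and reports weighted percentages summing to 100.
#'
#' @param traj a [dihedral_trajectory()].
#' @param weights a [frame_weights()] of matching length.
#' @param angle angle column name.
#' @param edges increasing numeric vector of bin edges from -180 to
#'   180; default `c(-180, -100, 0, 180)`.
#' @return Named numeric vector of percentages (one per bin).
#' @export
phi_bin_preferences <- function(traj, weights, angle,
                                edges = c(-180, -100, 0, 180)) {
  stopifnot(angle %in% colnames(traj$angles),
            all(diff(edges) > 0), edges[1] == -180,
            edges[length(edges)] == 180)
  x <- traj$angles[, angle]
  idx <- pmin(findInterval(x, edges, rightmost.closed = TRUE),
              length(edges) - 1)
  out <- vapply(seq_len(length(edges) - 1),
                function(b) 100 * sum(weights$w[idx == b]), numeric(1))
  names(out) <- paste0("[", edges[-length(edges)], ",",
                       edges[-1], ")")
  out
}
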