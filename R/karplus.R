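#' Karplus relations for three-bond J couplings
#'
#' A Karplus relation links a three-bond scalar coupling to its
#' intervening dihedral via `J(theta) = a*cos^2(theta) + b*cos(theta) +
#' c`, where `theta` is the raw structural dihedral (A-B-C-D) shifted by
#' a relation-specific offset. Five presets ship with the package,
#' covering the couplings relevant to GalNAc-Ser/Thr glycopeptides:
#'
#' \describe{
#'   \item{`3JHNHA`}{backbone HN-Halpha: a=6.51, b=-1.76, c=1.60 Hz,
#'     dihedral (CX-N-CA-C) = phi_P, offset -60 deg.}
#'   \item{`3JHNH2`}{GalNAc N-acetyl HN2-H2: a=9.6, b=-1.51, c=0.99 Hz,
#'     dihedral (C7-N2-C2-C1), offset +60 deg.}
#'   \item{`3JHAHB_Thr`}{Halpha-Hbeta of Thr: a=9.5, b=-1.6, c=1.80 Hz,
#'     dihedral (N-CA-CB-O1) = chi_S, offset -120 deg.}
#'   \item{`3JHAHB2_Ser`}{Halpha-Hbeta2 of Ser: same coefficients,
#'     offset 0 deg.}
#'   \item{`3JHAHB3_Ser`}{Halpha-Hbeta3 of Ser: same coefficients,
#'     offset -120 deg.}
#' }
#'
#' The Ser Hbeta2/Hbeta3 assignment follows the prochiral labelling
#' convention of [place_virtual_sites()]; swap the two presets to apply
#' the opposite experimental stereo-assignment.
#'
#' @param name one of the preset names above, or `NULL` to build a
#'   custom relation from the remaining arguments.
#' @param a,b,c Karplus coefficients in Hz.
#' @param atoms character(4): the dihedral's atom quadruple.
#' @param offset degrees added to the raw dihedral before evaluating
#'   the closed form.
#' @param angle default trajectory angle name carrying the raw
#'   dihedral.
#' @return An object of class `karplus_relation`.
#' @examples
#' karplus_j(90, karplus_relation("3JHNHA"))   # 1.60 Hz
#' karplus_j(180, karplus_relation("3JHNHA"))  # 9.87 Hz
#' @export
karplus_relation <- function(name = NULL, a = NULL, b = NULL, c = NULL,
                             atoms = NULL, offset = 0, angle = NULL) {
  presets <- list(
    "3JHNHA" = list(a = 6.51, b = -1.76, c = 1.60,
                    atoms = c("CX", "N", "CA", "C"), offset = -60,
                    angle = "phi_P"),
    "3JHNH2" = list(a = 9.6, b = -1.51, c = 0.99,
                    atoms = c("C7", "N2", "C2", "C1"), offset = 60,
                    angle = "theta"),
    "3JHAHB_Thr" = list(a = 9.5, b = -1.6, c = 1.80,
                        atoms = c("N", "CA", "CB", "O1"), offset = -120,
                        angle = "chi_S"),
    "3JHAHB2_Ser" = list(a = 9.5, b = -1.6, c = 1.80,
                         atoms = c("N", "CA", "CB", "O1"), offset = 0,
                         angle = "chi_S"),
    "3JHAHB3_Ser" = list(a = 9.5, b = -1.6, c = 1.80,
                         atoms = c("N", "CA", "CB", "O1"), offset = -120,
                         angle = "chi_S"))
  if (!is.null(name)) {
    if (inherits(name, "karplus_relation")) return(name)
    if (!name %in% names(presets))
      stop("unknown Karplus preset: ", name, " (available: ",
           paste(names(presets), collapse = ", "), ")")
    p <- presets[[name]]
    return(structure(c(p, list(name = name)),
                     class = "karplus_relation"))
  }
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  structure(list(a = a, b = b, c = c, atoms = atoms, offset = offset,
                 angle = angle, name = "custom"),
            class = "karplus_relation")
}

#' @export
print.karplus_relation <- function(x, ...) {
  cat(sprintf(
    "Karplus relation %s: J = %.2f cos^2(t) %+.2f cos(t) %+.2f Hz, ",
    x$name, x$a, x$b, x$c))
  cat(sprintf("t = (%s) %+g deg\n",
              paste(x$atoms, collapse = "-"), x$offset))
  invisible(x)
}

#' Evaluate a Karplus relation
#'
#' Applies the relation's offset to the raw structural dihedral, then
#' evaluates the closed form.
#'
#' @param theta raw dihedral angle(s) in degrees (the A-B-C-D value,
#'   before the offset).
#' @param relation a [karplus_relation()] or preset name.
#' @return Coupling constant(s) in Hz.
#' @export
karplus_j <- function(theta, relation) {
  relation <- karplus_relation(relation)
  ct <- cos(deg2rad(theta + relation$offset))
  relation$a * ct^2 + relation$b * ct + relation$c
}

#' Attainable range of a Karplus relation
#'
#' Closed-form minimum and maximum of `a*x^2 + b*x + c` over
#' `x = cos(theta)` in `[-1, 1]`; every ensemble-averaged J necessarily
#' lies inside this interval.
#'
#' @param relation a [karplus_relation()] or preset name.
#' @return Numeric `c(min, max)` in Hz.
#' @export
karplus_range <- function(relation) {
  relation <- karplus_relation(relation)
  f <- function(x) relation$a * x^2 + relation$b * x + relation$c
  xs <- c(-1, 1)
  if (relation$a != 0) {
    xv <- -relation$b / (2 * relation$a)
    if (xv >= -1 && xv <= 1) xs <- c(xs, xv)
  }
  range(f(xs))
}

#' Ensemble-averaged J coupling
#'
#' The Karplus relation is evaluated per frame and the resulting J
#' series is averaged with [weighted_expectation()] — never the Karplus
#' of the mean angle, which the nonlinearity would bias.
#'
#' @param traj a [dihedral_trajectory()].
#' @param weights a [frame_weights()] of matching length.
#' @param relation a [karplus_relation()] or preset name.
#' @param angle trajectory angle column holding the raw dihedral;
#'   defaults to the relation's conventional angle.
#' @return List with `mean` (Hz), `block_error`, `block_means`.
#' @export
ensemble_j <- function(traj, weights, relation, angle = NULL) {
  relation <- karplus_relation(relation)
  if (is.null(angle)) angle <- relation$angle
  if (is.null(angle) || !angle %in% colnames(traj$angles))
    stop("dihedral angle not present in trajectory: ", angle)
  j <- karplus_j(traj$angles[, angle], relation)
  weighted_expectation(j, weights)
}
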