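#' Cartesian frames of model glycopeptides
#'
#' A `cartesian_frame` holds atom names, elements and positions (nm)
#' for one structure, together with its bond list and the united-atom
#' classification of carbons that carry no explicit hydrogens
#' (`"CH1"`, `"CH2"` or `"CH3"`). It is the source object for
#' distances, angles, hydrogen bonds, virtual-site construction, NOE
#' distances and RMSD clustering.
#'
#' @param atoms data.frame with columns `name` (unique), `element`,
#'   `x`, `y`, `z` (nm).
#' @param bonds two-column matrix of atom indices.
#' @param united named character vector mapping united-atom carbon
#'   names to their class, e.g. `c(CA = "CH1", CB = "CH2")`.
#' @return An object of class `cartesian_frame`.
#' @export
cartesian_frame <- function(atoms, bonds = NULL, united = character()) {
  stopifnot(is.data.frame(atoms),
            all(c("name", "element", "x", "y", "z") %in% names(atoms)))
  if (anyDuplicated(atoms$name))
    stop("atom names must be unique within a frame")
  if (!all(is.finite(as.matrix(atoms[c("x", "y", "z")]))))
    stop("non-finite atom positions")
  if (is.null(bonds)) bonds <- matrix(integer(), 0, 2)
  if (length(united) > 0) {
    stopifnot(!is.null(names(united)),
              all(names(united) %in% atoms$name),
              all(united %in% c("CH1", "CH2", "CH3")))
  }
  structure(list(atoms = atoms, bonds = bonds, united = united),
            class = "cartesian_frame")
}

#' @export
print.cartesian_frame <- function(x, ...) {
  cat("Cartesian frame:", nrow(x$atoms), "atoms,",
      nrow(x$bonds), "bonds,", length(x$united), "united-atom carbons\n")
  invisible(x)
}

#' Position of a named atom
#' @param frame a [cartesian_frame()].
#' @param name atom name.
#' @return Numeric length-3 position in nm.
#' @export
atom_xyz <- function(frame, name) {
  i <- match(name, frame$atoms$name)
  if (is.na(i)) stop("no such atom: ", name)
  as.numeric(frame$atoms[i, c("x", "y", "z")])
}

#' Interatomic distance within a frame
#' @inheritParams atom_xyz
#' @param a,b atom names.
#' @param unit `"nm"` (default) or `"A"`.
#' @return Distance.
#' @export
frame_distance <- function(frame, a, b, unit = c("nm", "A")) {
  unit <- match.arg(unit)
  d <- sqrt(sum((atom_xyz(frame, a) - atom_xyz(frame, b))^2))
  if (unit == "A") d * 10 else d
}

#' Dihedral angle of four named atoms in a frame
#' @inheritParams atom_xyz
#' @param atoms character(4) atom names.
#' @return Angle in degrees in \[-180, 180).
#' @export
frame_dihedral <- function(frame, atoms) {
  stopifnot(length(atoms) == 4)
  p <- lapply(atoms, function(a) atom_xyz(frame, a))
  measure_dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
}

# idealised internal-coordinate geometry (nm / degrees)
.BL <- c(CC = 0.153, CN = 0.147, CO = 0.143, C_dbl_O = 0.123, XH = 0.100)

# Z-matrix templates for reduced model glycopeptides.  Each row places
# one atom from a bond length, a bond angle and a torsion; torsions
# named after a settable dihedral get that request (+ branch offset).
.model_templates <- function(template) {
  # columns: name element bond_ref len angle_ref ang dih_ref base off
  ser <- list(
    list("CX",  "C", NA,   NA,    NA,   NA,    NA,   "",      0),
    list("OX",  "O", "CX", 0.123, NA,   NA,    NA,   "",      0),
    list("N",   "N", "CX", 0.147, "OX", 122,   NA,   "",      0),
    list("CA",  "C", "N",  0.147, "CX", 122,   "OX", "",      0),
    list("H",   "H", "N",  0.100, "CX", 119,   "OX", "",    180),
    list("CXM", "C", "CX", 0.153, "N",  115,   "CA", "",    180),
    list("C",   "C", "CA", 0.153, "N",  109.5, "CX", "phi_P", 0),
    list("CB",  "C", "CA", 0.153, "N",  109.5, "CX", "phi_P", 120),
    list("O",   "O", "C",  0.123, "CA", 121,   "N",  "psi_P", 180),
    list("NT",  "N", "C",  0.147, "CA", 115,   "N",  "psi_P", 0),
    list("HT",  "H", "NT", 0.100, "C",  119,   "O",  "",    180),
    list("CT",  "C", "NT", 0.147, "C",  122,   "O",  "",      0),
    list("O1",  "O", "CB", 0.143, "CA", 109.5, "N",  "chi_S", 0),
    list("C1",  "C", "O1", 0.143, "CB", 113,   "CA", "psi_S", 0),
    list("O5",  "O", "C1", 0.143, "O1", 109.5, "CB", "phi_S", 0),
    list("C2",  "C", "C1", 0.153, "O1", 109.5, "CB", "phi_S", 120),
    list("C5",  "C", "O5", 0.143, "C1", 113,   "O1", "",     60),
    list("C3",  "C", "C2", 0.153, "C1", 109.5, "O1", "",     60),
    list("N2",  "N", "C2", 0.147, "C1", 109.5, "O1", "",    -60),
    list("C7",  "C", "N2", 0.147, "C2", 122,   "C1", "theta", 0),
    list("O7",  "O", "C7", 0.123, "N2", 122,   "C2", "",    180),
    list("HN2", "H", "N2", 0.100, "C7", 118,   "O7", "",    180))
  thr_extra <- list(
    list("CG",  "C", "CB", 0.153, "CA", 109.5, "N",  "chi_S", -120))
  settable <- c(phi_P = -120, psi_P = 150, chi_S = 60,
                phi_S = 60, psi_S = 120, theta = 180)
  if (template == "galnac_ser") {
    rows <- ser
    united <- c(CA = "CH1", CB = "CH2", C1 = "CH1", C2 = "CH1",
                CXM = "CH3", CT = "CH3")
  } else if (template == "galnac_thr") {
    rows <- c(ser, thr_extra)
    united <- c(CA = "CH1", CB = "CH1", C1 = "CH1", C2 = "CH1",
                CXM = "CH3", CT = "CH3", CG = "CH3")
  } else {
    stop("unknown template: ", template,
         " (available: galnac_ser, galnac_thr)")
  }
  list(rows = rows, united = united, defaults = settable)
}

#' Names of the settable dihedrals of a model template
#' @param template `"galnac_ser"` or `"galnac_thr"`.
#' @return Named numeric vector of default angles (degrees).
#' @export
model_template_angles <- function(template = "galnac_ser") {
  .model_templates(template)$defaults
}

# NeRF placement of atom D bonded to C, with bond angle B-C-D and
# torsion A-B-C-D
.place_atom <- function(a, b, c, len, ang, tors) {
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  ang <- deg2rad(ang)
  tors <- -deg2rad(tors)  # right-handed torsion convention
  d2 <- len * c(-cos(ang), sin(ang) * cos(tors), sin(ang) * sin(tors))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build a model glycopeptide frame with prescribed dihedrals
#'
#' Places the atoms of a reduced glycopeptide — peptide backbone with
#' N-acetyl/N-methyl caps plus the anomeric fragment of the GalNAc ring
#' (C1, O1, O5, C2, N2, C7, O7, ...) — from idealised internal
#' coordinates (bond lengths 0.153 nm C-C, 0.147 nm C-N, 0.143 nm C-O,
#' 0.123 nm C=O, 0.100 nm X-H; tetrahedral/planar angles), with the
#' requested values of the settable dihedrals `phi_P`, `psi_P`,
#' `chi_S`, `phi_S`, `psi_S` and `theta`. Construction is fully
#' deterministic and the measured dihedrals of the output reproduce the
#' request to well below 1e-6 degrees.
#'
#' @param dihedrals named numeric vector in degrees; any subset of the
#'   settable angles (unset ones take template defaults). Unknown names
#'   are rejected.
#' @param template `"galnac_ser"` (prochiral CH2 at C-beta) or
#'   `"galnac_thr"` (CH1 at C-beta plus a C-gamma methyl).
#' @return A [cartesian_frame()] whose united-atom carbons carry no
#'   explicit hydrogens.
#' @examples
#' fr <- build_model_frame(c(phi_P = -60, psi_P = -45))
#' frame_dihedral(fr, c("CX", "N", "CA", "C"))   # -60
#' frame_dihedral(fr, c("N", "CA", "C", "NT"))   # -45
#' @export
build_model_frame <- function(dihedrals = c(),
                              template = "galnac_ser") {
  tpl <- .model_templates(template)
  angles <- tpl$defaults
  if (length(dihedrals) > 0) {
    unknown <- setdiff(names(dihedrals), names(angles))
    if (length(unknown) > 0)
      stop("unknown dihedral(s) for template ", template, ": ",
           paste(unknown, collapse = ", "))
    angles[names(dihedrals)] <- dihedrals
  }
  rows <- tpl$rows
  nm <- vapply(rows, `[[`, character(1), 1)
  pos <- matrix(NA_real_, length(rows), 3)
  rownames(pos) <- nm
  # first three atoms define the frame
  pos[1, ] <- c(0, 0, 0)
  pos[2, ] <- c(rows[[2]][[4]], 0, 0)
  b3 <- match(rows[[3]][[3]], nm)   # bonded reference
  r3 <- match(rows[[3]][[5]], nm)   # angle reference
  a3 <- deg2rad(rows[[3]][[6]])
  u <- pos[r3, ] - pos[b3, ]
  u <- u / sqrt(sum(u^2))
  pos[3, ] <- pos[b3, ] + rows[[3]][[4]] *
    (cos(a3) * u + sin(a3) * c(0, 1, 0))

  for (i in 4:length(rows)) {
    r <- rows[[i]]
    tors <- if (nzchar(r[[8]])) angles[[r[[8]]]] + r[[9]] else r[[9]]
    pos[i, ] <- .place_atom(pos[match(r[[7]], nm), ],
                            pos[match(r[[5]], nm), ],
                            pos[match(r[[3]], nm), ],
                            r[[4]], r[[6]], tors)
  }
  bonds <- do.call(rbind, lapply(seq_along(rows)[-1], function(i)
    c(match(rows[[i]][[3]], nm), i)))
  atoms <- data.frame(name = nm,
                      element = vapply(rows, `[[`, character(1), 2),
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      row.names = NULL)
  cartesian_frame(atoms, bonds = bonds, united = tpl$united)
}

#' Names of heavy atoms bonded to a given atom
#' @param frame a [cartesian_frame()].
#' @param name atom name.
#' @return Character vector of bonded non-hydrogen atom names.
#' @export
heavy_neighbors <- function(frame, name) {
  i <- match(name, frame$atoms$name)
  j <- c(frame$bonds[frame$bonds[, 1] == i, 2],
         frame$bonds[frame$bonds[, 2] == i, 1])
  nb <- frame$atoms$name[j]
  nb[frame$atoms$element[j] != "H"]
}

#' Read model frames from a PDB file
#'
#' Uses [bio3d::read.pdb()]; multi-MODEL files yield one frame per
#' model, in file order. Atom names are preserved verbatim, coordinates
#' converted from Angstrom to nm. Bonds are inferred from interatomic
#' distances (heavy-heavy < 0.18 nm, X-H < 0.125 nm), since PDB CONECT
#' records are not required for these small models.
#'
#' @param path PDB file path.
#' @param united optional named character vector of united-atom flags
#'   applied to every frame (see [cartesian_frame()]).
#' @return List of [cartesian_frame()] objects.
#' @export
read_frames <- function(path, united = character()) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  names <- pdb$atom$elety
  if (anyDuplicated(names))
    stop("duplicate atom names within a model: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  elem <- ifelse(nzchar(trimws(pdb$atom$elesy)) &
                   !is.na(pdb$atom$elesy),
                 trimws(pdb$atom$elesy),
                 substr(trimws(names), 1, 1))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  lapply(seq_len(nrow(xyz)), function(m) {
    co <- matrix(xyz[m, ], ncol = 3, byrow = TRUE) / 10  # A -> nm
    atoms <- data.frame(name = names, element = elem,
                        x = co[, 1], y = co[, 2], z = co[, 3])
    fr <- cartesian_frame(atoms, united = united)
    fr$bonds <- .infer_bonds(fr)
    fr
  })
}

.infer_bonds <- function(frame) {
  co <- as.matrix(frame$atoms[c("x", "y", "z")])
  n <- nrow(co)
  d <- as.matrix(stats::dist(co))
  ish <- frame$atoms$element == "H"
  out <- matrix(integer(), 0, 2)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cut <- if (ish[i] || ish[j]) 0.125 else 0.18
    if (d[i, j] < cut && !(ish[i] && ish[j]))
      out <- rbind(out, c(i, j))
  }
  out
}

#' Write model frames to a PDB file
#'
#' One MODEL per frame via [bio3d::write.pdb()]; coordinates converted
#' from nm to Angstrom. United-atom carbons simply have no H records.
#'
#' @param frames a [cartesian_frame()] or list of them (identical atom
#'   order).
#' @param path output file path.
#' @export
write_frames <- function(frames, path) {
  if (inherits(frames, "cartesian_frame")) frames <- list(frames)
  a1 <- frames[[1]]$atoms
  xyz <- do.call(rbind, lapply(frames, function(f)
    as.vector(t(as.matrix(f$atoms[c("x", "y", "z")]) * 10))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   elety = a1$name,
                   resid = rep("MOL", nrow(a1)),
                   resno = rep(1, nrow(a1)),
                   elesy = a1$element)
  invisible(path)
}
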