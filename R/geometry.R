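#' Atom group
#'
#' A set of atoms (coordinates in nm, masses in amu) whose centre of mass
#' serves as one point of a collective variable.
#'
#' @param coords Numeric matrix, one row per atom, three columns (nm).
#' @param masses Numeric vector of atomic masses (amu, > 0), one per atom.
#' @param label Optional identifier.
#' @return An object of class `"atom_group"`.
#' @export
atom_group <- function(coords, masses, label = "") {
  coords <- as.matrix(coords)
  stopifnot(is.numeric(coords), ncol(coords) == 3L, nrow(coords) >= 1L,
            all(is.finite(coords)),
            is.numeric(masses), length(masses) == nrow(coords),
            all(is.finite(masses)), all(masses > 0))
  structure(list(coords = coords, masses = as.numeric(masses),
                 label = as.character(label)),
            class = "atom_group")
}

#' Centre of mass of an atom group
#'
#' @param group An [atom_group()].
#' @return Length-3 numeric vector: the mass-weighted mean position (nm).
#' @export
center_of_mass <- function(group) {
  stopifnot(inherits(group, "atom_group"))
  tot <- sum(group$masses)
  if (tot <= 0) stop("atom group has zero total mass")
  as.numeric(colSums(group$coords * group$masses) / tot)
}

#' Geometric collective variable over atom-group centres of mass
#'
#' @param kind One of `"dihedral"` (4 groups), `"planar_angle"` (3 groups)
#'   or `"distance"` (2 groups).
#' @param groups List of [atom_group()] objects; the count must match
#'   `kind`.
#' @param label Identifier (conventionally `D*` for dihedrals, `P*` for
#'   planar angles, `R*` for distances).
#' @return An object of class `"collective_variable"`.
#' @export
collective_variable <- function(kind = c("dihedral", "planar_angle",
                                         "distance"),
                                groups, label = "") {
  kind <- match.arg(kind)
  need <- c(dihedral = 4L, planar_angle = 3L, distance = 2L)[[kind]]
  stopifnot(is.list(groups),
            all(vapply(groups, inherits, logical(1), "atom_group")))
  if (length(groups) != need) {
    stop(sprintf("a %s needs %d atom groups, got %d", kind, need,
                 length(groups)))
  }
  structure(list(kind = kind, groups = groups, label = as.character(label)),
            class = "collective_variable")
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.vnorm <- function(v) sqrt(sum(v * v))

# Signed dihedral (degrees) over four points, atan2 convention, (-180, 180].
.dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  scale <- max(.vnorm(b1), .vnorm(b2), .vnorm(b3))
  if (.vnorm(n1) <= 1e-12 * scale^2 || .vnorm(n2) <= 1e-12 * scale^2) {
    stop("undefined geometry: three consecutive centres of mass are colinear")
  }
  y <- sum(.cross3(n1, n2) * b2) / .vnorm(b2)
  x <- sum(n1 * n2)
  deg <- atan2(y, x) * 180 / pi
  if (deg <= -180) deg <- deg + 360
  deg
}

.planar_angle3 <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  nu <- .vnorm(u)
  nv <- .vnorm(v)
  if (nu == 0 || nv == 0) stop("undefined geometry: coincident centres of mass")
  acos(pmin(pmax(sum(u * v) / (nu * nv), -1), 1)) * 180 / pi
}

#' Evaluate a collective variable
#'
#' Distances are Euclidean norms between centres of mass (nm); planar angles
#' come from the arccosine of the normalised dot product, in `[0, 180]`
#' degrees; dihedrals use the signed atan2 convention in `(-180, 180]`
#' degrees.
#'
#' @param cv A [collective_variable()].
#' @return Scalar value: nm for distances, degrees for angles.
#' @export
eval_cv <- function(cv) {
  stopifnot(inherits(cv, "collective_variable"))
  coms <- lapply(cv$groups, center_of_mass)
  switch(cv$kind,
    distance = .vnorm(coms[[1]] - coms[[2]]),
    planar_angle = .planar_angle3(coms[[1]], coms[[2]], coms[[3]]),
    dihedral = .dihedral4(coms[[1]], coms[[2]], coms[[3]], coms[[4]])
  )
}

# Kabsch optimal rotation taking centred P onto centred Q.
.kabsch_rotation <- function(P, Q) {
  H <- crossprod(P, Q)            # t(P) %*% Q
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

#' Root-mean-square deviation between two coordinate sets
#'
#' With `superpose = TRUE` the first set is optimally rigid-body aligned
#' onto the second (Kabsch superposition) before the deviation is computed;
#' this is the criterion used to judge completeness of a steered
#' conformational transition (e.g. backbone RMSD below 0.25 nm against a
#' reference closed state).
#'
#' @param coords_a,coords_b Numeric matrices of equal dimension, one row per
#'   atom, three columns (nm).
#' @param superpose Optimally align `coords_a` onto `coords_b` first.
#' @return RMSD in the coordinate units (nm).
#' @export
backbone_rmsd <- function(coords_a, coords_b, superpose = TRUE) {
  A <- as.matrix(coords_a)
  B <- as.matrix(coords_b)
  if (!all(dim(A) == dim(B)) || ncol(A) != 3L) {
    stop("coordinate sets must be n x 3 matrices of equal size")
  }
  if (superpose) {
    ca <- colMeans(A)
    cb <- colMeans(B)
    Ac <- sweep(A, 2, ca)
    Bc <- sweep(B, 2, cb)
    R <- .kabsch_rotation(Ac, Bc)
    A <- Ac %*% t(R)
    B <- Bc
  }
  sqrt(mean(rowSums((A - B)^2)))
}

# Atomic masses (amu) by element symbol for PDB-derived groups.
.ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                   P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38,
                   MG = 24.305, CA = 40.078, K = 39.098, CL = 35.45,
                   "NA" = 22.990)

element_mass <- function(symbol) {
  symbol <- toupper(trimws(symbol))
  m <- unname(.ELEMENT_MASS[symbol])
  if (anyNA(m)) {
    warning("unknown element symbol(s): ",
            paste(unique(symbol[is.na(m)]), collapse = ", "),
            "; using the mass of carbon")
    m[is.na(m)] <- .ELEMENT_MASS[["C"]]
  }
  m
}

.BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Build an atom group from a PDB structure
#'
#' Selects ATOM records by chain, residue-number range and atom names, and
#' attaches element masses. Coordinates are converted from Angstrom (PDB
#' convention) to nm. Alternate locations are resolved by keeping the
#' first-listed conformer.
#'
#' @param pdb A `bio3d` pdb object ([bio3d::read.pdb()]) or a path to a PDB
#'   file.
#' @param chain Optional chain identifier(s).
#' @param resno Optional residue-number range `c(lo, hi)` (1-based, as in
#'   the PDB) or explicit residue numbers.
#' @param elety Optional atom-name selection (e.g. `"CA"`); `backbone =
#'   TRUE` is shorthand for N, CA, C, O.
#' @param backbone Restrict to peptide-backbone heavy atoms.
#' @param label Group label.
#' @return An [atom_group()] with coordinates in nm.
#' @export
atom_group_from_pdb <- function(pdb, chain = NULL, resno = NULL,
                                elety = NULL, backbone = FALSE, label = "") {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  at <- pdb$atom
  keep <- at$type == "ATOM"
  # first-listed conformer wins for alternate locations
  keep <- keep & (is.na(at$alt) | at$alt %in% c("", "A"))
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(resno)) {
    rng <- if (length(resno) == 2L) seq(resno[1], resno[2]) else resno
    keep <- keep & at$resno %in% rng
  }
  if (backbone) elety <- .BACKBONE_ATOMS
  if (!is.null(elety)) keep <- keep & at$elety %in% elety
  at <- at[keep, , drop = FALSE]
  if (!nrow(at)) stop("PDB selection matched no atoms")
  sym <- at$elesy
  if (is.null(sym) || all(is.na(sym)) || all(sym == "")) {
    sym <- substr(trimws(at$elety), 1L, 1L)
  }
  atom_group(cbind(at$x, at$y, at$z) / 10, element_mass(sym), label = label)
}

#' Read a collective-variable configuration file
#'
#' The YAML layout is a top-level `cvs` list; each entry has `label`,
#' `kind` (`dihedral` / `planar_angle` / `distance`) and a `groups` list of
#' selections (`chain`, `resno: [lo, hi]`, optional `backbone: true` or
#' `elety`). Group definitions are deliberately configuration-driven: the
#' shipped example file uses serum-albumin domain ranges as placeholders and
#' users substitute their own authoritative selections.
#'
#' @param path Path to the YAML file.
#' @return The parsed configuration list.
#' @export
read_cv_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$cvs)) stop("CV configuration must contain a 'cvs' list")
  cfg
}

#' Build collective variables from a PDB structure and a configuration
#'
#' @param pdb A `bio3d` pdb object or PDB file path.
#' @param config A configuration list from [read_cv_config()] (or a path to
#'   one).
#' @return Named list of [collective_variable()] objects.
#' @export
cvs_from_pdb <- function(pdb, config) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  if (is.character(config)) config <- read_cv_config(config)
  out <- lapply(config$cvs, function(cv) {
    groups <- lapply(cv$groups, function(g) {
      atom_group_from_pdb(pdb, chain = g$chain,
                          resno = unlist(g$resno),
                          elety = g$elety,
                          backbone = isTRUE(g$backbone),
                          label = g$label %||% "")
    })
    collective_variable(cv$kind, groups, label = cv$label %||% "")
  })
  names(out) <- vapply(config$cvs, function(cv) cv$label %||% "",
                       character(1))
  out
}

#' Evaluate all configured collective variables on a structure
#'
#' @inheritParams cvs_from_pdb
#' @return Data frame with columns `label`, `kind`, `value`, `unit`.
#' @export
eval_cv_set <- function(pdb, config) {
  cvs <- cvs_from_pdb(pdb, config)
  data.frame(
    label = names(cvs),
    kind = vapply(cvs, `[[`, character(1), "kind"),
    value = vapply(cvs, eval_cv, numeric(1)),
    unit = ifelse(vapply(cvs, `[[`, character(1), "kind") == "distance",
                  "nm", "degrees"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
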