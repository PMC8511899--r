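# Canonical pyranose ring atom order
.RING_ATOMS <- c("C1", "C2", "C3", "C4", "C5", "O5")

# First side-chain heavy atom beyond CB, per residue type (chi1 partner)
.GAMMA_ATOM <- c(ARG = "CG", ASN = "CG", ASP = "CG", CYS = "SG",
                 GLN = "CG", GLU = "CG", HIS = "CG", ILE = "CG1",
                 LEU = "CG", LYS = "CG", MET = "CG", MSE = "CG",
                 PHE = "CG", PRO = "CG", SER = "OG", THR = "OG1",
                 TRP = "CG", TYR = "CG", VAL = "CG1")

#' Extract pyranose ring coordinates from a structure
#'
#' @param struct A `structure3d` object.
#' @param resno Residue number of the sugar.
#' @param chain Optional chain id.
#' @return 6 x 3 coordinate matrix with rows `C1, C2, C3, C4, C5, O5`.
#' @export
ring_coords <- function(struct, resno, chain = NULL) {
  sel <- select_atoms(struct, resno = resno, chain = chain)
  sel$elety <- .norm_sugar_atom(sel$elety)
  idx <- match(.RING_ATOMS, sel$elety)
  if (anyNA(idx)) {
    stop("residue ", resno, " lacks ring atom(s): ",
         paste(.RING_ATOMS[is.na(idx)], collapse = ", "))
  }
  m <- .xyz(sel[idx, , drop = FALSE])
  rownames(m) <- .RING_ATOMS
  m
}

#' Least-squares mean plane of a pyranose ring
#'
#' Fits the plane minimizing squared atomic distances through the six
#' ring atoms (singular value decomposition of the centered
#' coordinates) and returns signed displacements of each atom along the
#' plane normal. The displacements of a least-squares plane sum to zero
#' by construction.
#'
#' @param ring Either a 6 x 3 matrix in `C1..C5, O5` order (see
#'   [ring_coords()]) or a `structure3d` with `resno` given.
#' @param resno,chain Sugar residue locator when `ring` is a structure.
#' @return A `ring_plane`: list with `centroid`, unit `normal` and named
#'   `displacements` (angstroms).
#' @examples
#' s <- make_ring_fixture("4C1")
#' ring_mean_plane(ring_coords(s, resno = 1))$displacements
#' @export
ring_mean_plane <- function(ring, resno = NULL, chain = NULL) {
  if (inherits(ring, "structure3d")) {
    stopifnot(!is.null(resno))
    ring <- ring_coords(ring, resno, chain)
  }
  stopifnot(is.matrix(ring), nrow(ring) == 6L, ncol(ring) == 3L)
  if (anyDuplicated(round(ring, 6))) stop("coincident ring atoms")
  centroid <- colMeans(ring)
  m <- sweep(ring, 2, centroid)
  sv <- svd(m)
  if (sv$d[2L] < 1e-8 * sv$d[1L]) {
    stop("degenerate (collinear) ring atoms; no plane defined")
  }
  normal <- sv$v[, 3L]
  disp <- as.numeric(m %*% normal)
  names(disp) <- rownames(ring) %||% .RING_ATOMS
  structure(list(centroid = centroid, normal = normal,
                 displacements = disp),
            class = "ring_plane")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify the ring face presented toward a reference point
#'
#' Orients the mean-plane normal toward the reference point (by default
#' the tunnel roof) and reads the signs of the C1, C3 and C5
#' displacements: all positive is the alpha face (C1/C3/C5 pointing
#' toward the reference), all negative the beta face, anything mixed or
#' flat is indeterminate. Reflecting the reference point through the
#' plane therefore swaps alpha and beta. The default reference used by
#' the pipeline is the centroid of the lid-loop residues Y38/Y39, the
#' roof of the catalytic tunnel, which reproduces the conserved
#' `+1 = alpha / -1 = beta` pattern at the catalytic subsites.
#'
#' @param ring A `ring_plane`, a 6 x 3 coordinate matrix, or a
#'   `structure3d` with `resno`.
#' @param reference_point Numeric 3-vector; must not lie within 0.1
#'   angstrom of the plane.
#' @param resno,chain Sugar residue locator when `ring` is a structure.
#' @param tol Displacements below `tol` (angstroms) count as "in
#'   plane".
#' @return `"alpha"`, `"beta"` or `"indeterminate"`.
#' @export
classify_face <- function(ring, reference_point, resno = NULL,
                          chain = NULL, tol = 1e-6) {
  if (!inherits(ring, "ring_plane")) {
    ring <- ring_mean_plane(ring, resno = resno, chain = chain)
  }
  stopifnot(is.numeric(reference_point), length(reference_point) == 3L)
  h <- sum((reference_point - ring$centroid) * ring$normal)
  if (abs(h) < 0.1) {
    stop("reference point lies within 0.1 angstrom of the ring plane")
  }
  disp <- ring$displacements
  if (h < 0) disp <- -disp
  d135 <- disp[c("C1", "C3", "C5")]
  if (all(d135 > tol)) return("alpha")
  if (all(d135 < -tol)) return("beta")
  "indeterminate"
}

#' Tunnel-roof reference point (lid-loop centroid)
#'
#' Centroid of all atoms of the lid-loop residues, the default
#' reference for [classify_face()].
#'
#' @param struct A `structure3d` object.
#' @param resno Lid-loop residue numbers (default Y38/Y39).
#' @param chain Optional chain id.
#' @return Numeric 3-vector.
#' @export
roof_reference <- function(struct, resno = c(38, 39), chain = NULL) {
  sel <- select_atoms(struct, resno = resno, chain = chain, hetero = FALSE)
  if (nrow(sel) == 0L) stop("lid-loop residues not found")
  colMeans(.xyz(sel))
}

#' Cremer-Pople puckering parameters of a six-membered ring
#'
#' Auxiliary output for conformer inspection: total puckering amplitude
#' `Q` (angstroms) and polar angles `theta`, `phi` (degrees) computed
#' from the Cremer-Pople mean plane. An ideal chair has `theta` near 0
#' or 180 degrees. Face calls in this package use the least-squares
#' plane, not these parameters.
#'
#' @inheritParams ring_mean_plane
#' @return List with `Q`, `theta`, `phi` and the Cremer-Pople `z`
#'   displacements.
#' @export
ring_pucker_cp <- function(ring, resno = NULL, chain = NULL) {
  if (inherits(ring, "structure3d")) {
    stopifnot(!is.null(resno))
    ring <- ring_coords(ring, resno, chain)
  }
  stopifnot(is.matrix(ring), nrow(ring) == 6L)
  n <- 6L
  j <- seq_len(n) - 1L
  r <- sweep(ring, 2, colMeans(ring))
  rp <- colSums(r * sin(2 * pi * j / n))
  rpp <- colSums(r * cos(2 * pi * j / n))
  nrm <- c(rp[2] * rpp[3] - rp[3] * rpp[2],
           rp[3] * rpp[1] - rp[1] * rpp[3],
           rp[1] * rpp[2] - rp[2] * rpp[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  z <- as.numeric(r %*% nrm)
  q2c <- sqrt(2 / n) * sum(z * cos(4 * pi * j / n))
  q2s <- -sqrt(2 / n) * sum(z * sin(4 * pi * j / n))
  q3 <- sqrt(1 / n) * sum(z * (-1)^j)
  q2 <- sqrt(q2c^2 + q2s^2)
  Q <- sqrt(q2^2 + q3^2)
  theta <- atan2(q2, q3) * 180 / pi
  phi <- (atan2(q2s, q2c) * 180 / pi) %% 360
  list(Q = Q, theta = theta, phi = phi, z = z)
}

#' Torsion (dihedral) angle of four points
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors.
#' @return Angle in degrees in `(-180, 180]`.
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  # IUPAC sign convention (matches crystallographic chi/phi/psi tools)
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Rotamer bin of a chi1 angle
#'
#' Bins: `g+` for (0, 120], `t` for (120, 180] and (-180, -120],
#' `g-` for (-120, 0].
#'
#' @param chi Angle(s) in degrees.
#' @return Character vector of bins.
#' @export
rotamer_bin <- function(chi) {
  vapply(chi, function(a) {
    if (is.na(a)) return(NA_character_)
    if (a > 0 && a <= 120) "g+"
    else if (a > -120 && a <= 0) "g-"
    else "t"
  }, character(1))
}

#' Side-chain chi1 torsion and rotamer state
#'
#' Dihedral N-CA-CB-gamma for a protein residue. Residues lacking any
#' of the four atoms (glycine, alanine, or unresolved density) get the
#' state `"unresolved"` with `chi1 = NA`.
#'
#' @param struct A `structure3d` object.
#' @param resno Residue number.
#' @param chain Optional chain id.
#' @return One-row data frame: `resno`, `resid`, `chi1` (degrees),
#'   `bin` (`g+`, `t`, `g-` or `unresolved`).
#' @export
chi1 <- function(struct, resno, chain = NULL) {
  sel <- select_atoms(struct, resno = resno, chain = chain, hetero = FALSE)
  if (nrow(sel) == 0L) {
    return(data.frame(resno = resno, resid = NA_character_,
                      chi1 = NA_real_, bin = "unresolved",
                      stringsAsFactors = FALSE))
  }
  resid <- sel$resid[[1L]]
  gamma <- .GAMMA_ATOM[resid]
  names(gamma) <- NULL
  need <- c("N", "CA", "CB", gamma)
  if (is.na(gamma) || !all(need %in% sel$elety)) {
    return(data.frame(resno = resno, resid = resid, chi1 = NA_real_,
                      bin = "unresolved", stringsAsFactors = FALSE))
  }
  p <- lapply(need, function(a) {
    as.numeric(sel[match(a, sel$elety), c("x", "y", "z")])
  })
  ang <- torsion_angle(p[[1L]], p[[2L]], p[[3L]], p[[4L]])
  data.frame(resno = resno, resid = resid, chi1 = ang,
             bin = rotamer_bin(ang), stringsAsFactors = FALSE)
}

#' Chi1 rotamer transitions across a structure series
#'
#' Computes the chi1 rotamer bin of each residue in every structure of
#' a labeled series and flags, relative to the first structure (the
#' reference, by convention the lowest-pH form), whether the bin
#' changed or the residue is unresolved.
#'
#' @param structs Named list of `structure3d` objects; the first is the
#'   reference.
#' @param residues Residue ids (`"K42"`) or integer residue numbers.
#' @param chain Optional chain id.
#' @return Data frame with one row per residue x structure: `residue`,
#'   `resno`, `label`, `chi1`, `bin`, `changed` (`NA` for the
#'   reference row). Residues unresolved everywhere are dropped with a
#'   warning.
#' @export
rotamer_transitions <- function(structs, residues, chain = NULL) {
  stopifnot(is.list(structs), length(structs) >= 2L,
            !is.null(names(structs)))
  labels <- names(structs)
  ids <- if (is.character(residues)) residues else as.character(residues)
  nums <- if (is.character(residues)) region_resno(residues) else
    as.integer(residues)

  rows <- list()
  skipped <- character(0)
  for (k in seq_along(nums)) {
    states <- lapply(structs, chi1, resno = nums[[k]], chain = chain)
    bins <- vapply(states, function(s) s$bin, character(1))
    if (all(bins == "unresolved")) {
      skipped <- c(skipped, ids[[k]])
      next
    }
    ref_bin <- bins[[1L]]
    for (j in seq_along(labels)) {
      changed <- if (j == 1L) NA else
        (bins[[j]] == "unresolved" || ref_bin == "unresolved" ||
           bins[[j]] != ref_bin)
      rows[[length(rows) + 1L]] <- data.frame(
        residue = ids[[k]], resno = nums[[k]], label = labels[[j]],
        chi1 = states[[j]]$chi1, bin = bins[[j]], changed = changed,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(skipped)) {
    warning("residue(s) unresolved in every structure: ",
            paste(skipped, collapse = ", "))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(residue = character(0), resno = integer(0),
               label = character(0), chi1 = numeric(0), bin = character(0),
               changed = logical(0))
  rownames(out) <- NULL
  out
}
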