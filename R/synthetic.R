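# Fixture generators. Everything here is synthetic by construction: the
# requested B-factors, conformers and contact distances are the ground
# truth that the analysis modules are tested against. Fixtures are
# round-tripped through PDB text so tests exercise the real parser path.

.fixture_structure <- function(atoms, cell = NULL,
                               space_group = NA_character_,
                               z_prime = NA_real_, round_trip = TRUE,
                               check_clashes = TRUE) {
  atoms$eleno <- seq_len(nrow(atoms))
  atoms$o <- atoms$o %||% 1
  st <- structure(list(atoms = atoms, cell = cell,
                       space_group = space_group, z_prime = z_prime),
                  class = "structure3d")
  validate_structure(st)
  if (check_clashes) .check_clashes(st)
  if (round_trip) st <- parse_structure(write_structure(st),
                                        z_prime = z_prime)
  st
}

.check_clashes <- function(struct, min_dist = 1.0) {
  m <- .xyz(struct$atoms)
  if (nrow(m) < 2L) return(invisible(TRUE))
  d <- as.matrix(stats::dist(m))
  diag(d) <- Inf
  if (min(d) < min_dist) {
    stop("geometric clash: atoms closer than ", min_dist, " angstrom")
  }
  invisible(TRUE)
}

.atom_row <- function(type, elety, resid, chain, resno, xyz, b = 10,
                      o = 1, elesy = NULL) {
  data.frame(type = type, eleno = NA_integer_, elety = elety,
             resid = resid, chain = chain, resno = as.integer(resno),
             x = round(xyz[[1]], 3), y = round(xyz[[2]], 3),
             z = round(xyz[[3]], 3), o = o, b = b,
             elesy = elesy %||% .guess_element(elety),
             stringsAsFactors = FALSE)
}

#' Poly-alanine fixture with a prescribed B-factor profile
#'
#' Builds a chain of alanine-like residues (atoms N, CA, C, O, CB) laid
#' out along a gentle helix, with every atom of residue *i* carrying
#' exactly `b_profile[i]` as its B-factor. Used as the oracle for the
#' flexibility statistics: means and scaled values computed from the
#' structure must equal what the profile dictates.
#'
#' @param n_residues Number of residues.
#' @param b_profile Per-residue B target: a constant, or a vector
#'   recycled to `n_residues` (ramps, two-block profiles, ...).
#' @param chain Chain id.
#' @param resno_start First author residue number.
#' @param jitter_sd Gaussian coordinate jitter in angstroms (B values
#'   stay exact).
#' @param seed Seed for the jitter.
#' @param cell,space_group Optional crystal metadata.
#' @return A `structure3d`, round-tripped through PDB text.
#' @export
make_bfactor_fixture <- function(n_residues, b_profile = 10,
                                 chain = "A", resno_start = 1L,
                                 jitter_sd = 0, seed = NULL,
                                 cell = NULL,
                                 space_group = NA_character_) {
  stopifnot(n_residues >= 1L)
  b <- rep_len(b_profile, n_residues)
  if (any(b < 0)) stop("B-factors must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  offsets <- list(N = c(-0.8, 1.1, 0.2), CA = c(0, 0, 0),
                  C = c(1.2, 0.6, -0.3), O = c(1.5, 1.7, -0.5),
                  CB = c(0.4, -1.3, 0.9))
  rows <- list()
  for (i in seq_len(n_residues)) {
    base <- c(3.8 * i, 2.0 * sin(i * 0.8), 2.0 * cos(i * 0.8))
    for (a in names(offsets)) {
      xyz <- base + offsets[[a]]
      if (jitter_sd > 0) xyz <- xyz + stats::rnorm(3, sd = jitter_sd)
      rows[[length(rows) + 1L]] <- .atom_row(
        "ATOM", a, "ALA", chain, resno_start + i - 1L, xyz, b = b[[i]]
      )
    }
  }
  # jittered chains are statistical fixtures, not contact geometry;
  # no clash guarantee is made or enforced for them
  .fixture_structure(do.call(rbind, rows), cell = cell,
                     space_group = space_group,
                     check_clashes = jitter_sd == 0)
}

# Ideal-geometry pyranose ring template: hexagon of radius r with
# alternating +/- z displacements of the requested conformer.
.ring_template <- function(conformer) {
  conformer <- match.arg(conformer,
                         c("4C1", "1C4", "planar", "half-chair"))
  r <- 1.456
  dz <- switch(conformer,
               "4C1" = c(0.25, -0.25, 0.25, -0.25, 0.25, -0.25),
               "1C4" = -c(0.25, -0.25, 0.25, -0.25, 0.25, -0.25),
               "planar" = rep(0, 6),
               "half-chair" = c(0.25, -0.25, 0.25, 0.25, -0.25, -0.25))
  # ring path C1 -> C2 -> ... -> O5 around the hexagon
  ang <- c(0, -60, -120, 180, 120, 60) * pi / 180
  m <- cbind(r * cos(ang), r * sin(ang), dz)
  rownames(m) <- .RING_ATOMS
  round(m, 3)
}

.radial_unit <- function(p) {
  u <- c(p[[1]], p[[2]], 0)
  u / sqrt(sum(u^2))
}

# Full sugar residue atom set from a (possibly translated) ring template
.sugar_atoms <- function(ring, resid, chain, resno, b = 20,
                         atoms = c("O2", "O3", "O4", "C6", "O6A",
                                   "O6B")) {
  rows <- lapply(rownames(ring), function(a) {
    .atom_row("HETATM", a, resid, chain, resno, ring[a, ], b = b)
  })
  add <- function(name, xyz) {
    rows[[length(rows) + 1L]] <<- .atom_row("HETATM", name, resid,
                                            resno = resno,
                                            chain = chain, xyz = xyz,
                                            b = b)
  }
  center <- colMeans(ring[, 1:2])
  rad <- function(atom) {
    p <- ring[atom, ]
    u <- c(p[[1]] - center[[1]], p[[2]] - center[[2]], 0)
    u / sqrt(sum(u^2))
  }
  if ("O2" %in% atoms) add("O2", ring["C2", ] + 1.43 * rad("C2"))
  if ("O3" %in% atoms) add("O3", ring["C3", ] + 1.43 * rad("C3"))
  if ("O4" %in% atoms) add("O4", ring["C4", ] + 1.43 * rad("C4"))
  if ("C6" %in% atoms) {
    c6 <- ring["C5", ] + 1.5 * rad("C5")
    add("C6", c6)
    if ("O6A" %in% atoms) add("O6A", c6 + c(0.85 * rad("C5")[1:2], 1.0))
    if ("O6B" %in% atoms) add("O6B", c6 + c(0.85 * rad("C5")[1:2], -1.0))
  }
  df <- do.call(rbind, rows)
  df$x <- round(df$x, 3); df$y <- round(df$y, 3); df$z <- round(df$z, 3)
  df
}

#' Single-sugar ring fixture with a known conformer and face
#'
#' Builds one pyranose residue with ideal alternating-chair geometry
#' (`4C1`: C1/C3/C5 displaced +0.25 angstrom from the mean plane and
#' C2/C4/O5 -0.25; `1C4` is its mirror; `planar` and `half-chair` give
#' flat and mixed-sign displacement patterns), plus hydroxyl and
#' carboxylate substituents. The attribute `face_reference` is a point
#' on the C1/C3/C5 side of the plane (`NULL` for the planar
#' conformer), so `classify_face(..., attr(s, "face_reference"))`
#' returns `"alpha"` by construction for both chairs.
#'
#' @param conformer One of `"4C1"`, `"1C4"`, `"planar"`,
#'   `"half-chair"`.
#' @param resid Sugar component code (`BEM`, `NAG`, `BDP`, `LGU`).
#' @param chain,resno Residue identifiers.
#' @param b B-factor for all atoms.
#' @return A `structure3d` with attributes `face_reference` and
#'   `conformer`.
#' @export
make_ring_fixture <- function(conformer = "4C1", resid = "BEM",
                              chain = "B", resno = 1L, b = 20) {
  if (!resid %in% .SUGARS) stop("unknown sugar component: ", resid)
  ring <- .ring_template(conformer)
  st <- .fixture_structure(.sugar_atoms(ring, resid, chain, resno,
                                        b = b))
  face_ref <- switch(conformer,
                     "4C1" = c(0, 0, 5),
                     "1C4" = c(0, 0, -5),
                     "half-chair" = c(0, 0, 5),
                     NULL)
  attr(st, "face_reference") <- face_ref
  attr(st, "conformer") <- conformer
  st
}

#' Linear glycan-chain fixture with known connectivity
#'
#' Chains `n_sugars` ideal rings through 4-to-1 glycosidic linkages
#' (C1 of each successive ring placed 1.43 angstrom from the O4 of the
#' previous one). The first residue keeps a free anomeric C1 and is
#' therefore the reducing end. The attribute `triad_point` marks a
#' point next to the glycosidic oxygen between residues 1 and 2, so
#' subsite assignment against it must give residue 1 subsite `+1`,
#' residue 2 `-1`, residue 3 `-2`, and so on.
#'
#' @param n_sugars Number of sugar units (>= 1).
#' @param resid Sugar component code.
#' @param chain Chain id.
#' @param start_resno Residue number of the reducing-end sugar;
#'   successive units count up by 100 (deposition style).
#' @return A `structure3d` with attribute `triad_point`.
#' @export
make_glycan_fixture <- function(n_sugars = 3L, resid = "BEM",
                                chain = "B", start_resno = 601L) {
  stopifnot(n_sugars >= 1L)
  tmpl <- .ring_template("4C1")
  rows <- list()
  ring <- tmpl
  scissile_o <- NULL
  for (i in seq_len(n_sugars)) {
    resno <- start_resno + (i - 1L) * 100L
    # interior units keep O4 as the linkage oxygen; terminal non-reducing
    # unit keeps it too (free 4-OH)
    rows[[i]] <- .sugar_atoms(ring, resid, chain, resno,
                              atoms = c("O2", "O3", "O4", "C6", "O6A",
                                        "O6B"))
    o4 <- ring["C4", ] + 1.43 * c(.radial_unit_at(ring, "C4"), 0)
    if (i == 1L) scissile_o <- o4
    # next ring: its C1 sits 1.43 A beyond this O4, along -x
    shift <- (o4 + c(-1.43, 0, 0)) - tmpl["C1", ]
    ring <- sweep(tmpl, 2, -shift)
    ring <- round(ring, 3)
  }
  st <- .fixture_structure(do.call(rbind, rows))
  attr(st, "triad_point") <- round(scissile_o + c(0, 3, 0), 3)
  st
}

.radial_unit_at <- function(ring, atom) {
  center <- colMeans(ring[, 1:2])
  u <- c(ring[atom, 1] - center[[1]], ring[atom, 2] - center[[2]])
  u / sqrt(sum(u^2))
}

# Minimal side-chain "ladder" templates: the donor atom sits first and
# the remaining atoms are stacked away from the contact axis.
.DONOR_RESIDUES <- list(
  ARG = c("NH1", "NH2", "NE", "CZ", "CD", "CG", "CB", "CA", "C", "O",
          "N"),
  LYS = c("NZ", "CE", "CD", "CG", "CB", "CA", "C", "O", "N"),
  TYR = c("OH", "CZ", "CE1", "CD1", "CG", "CB", "CA", "C", "O", "N"),
  SER = c("OG", "CB", "CA", "C", "O", "N"),
  ASN = c("ND2", "CG", "OD1", "CB", "CA", "C", "O", "N"),
  HIS = c("NE2", "CD2", "CG", "CB", "CA", "C", "O", "N")
)

#' Protein-sugar contact fixture with exact construction distances
#'
#' For every requested contact, places one protein residue and one
#' minimal sugar residue so that the named donor atom lies exactly the
#' requested distance from the named acceptor atom (to the PDB format's
#' 0.001 angstrom precision). Contacts are laid out in well-separated
#' blocks so each produces exactly its own interaction and nothing
#' else; the construction distances are the oracle for the detection
#' code.
#'
#' @param contacts List of contact specs, each a list or vector with
#'   `donor` (`"ARG:NH1"` style; residues ARG, LYS, TYR, SER, ASN,
#'   HIS), `acceptor` (sugar atom name: `O2`, `O3`, `O4`, `O6A`,
#'   `O6B`), and `dist` in angstroms (> 1.5).
#' @param resid Sugar component code.
#' @return A `structure3d`; attribute `contact_specs` echoes the
#'   requested contacts.
#' @examples
#' s <- make_contact_fixture(list(
#'   list(donor = "ARG:NH1", acceptor = "O6B", dist = 2.9)))
#' find_salt_bridges(s)$distance
#' @export
make_contact_fixture <- function(contacts, resid = "BEM") {
  stopifnot(is.list(contacts), length(contacts) >= 1L)
  rows <- list()
  for (k in seq_along(contacts)) {
    sp <- contacts[[k]]
    dn <- strsplit(sp$donor %||% sp[["donor"]], ":", fixed = TRUE)[[1L]]
    if (length(dn) != 2L || !dn[[1L]] %in% names(.DONOR_RESIDUES)) {
      stop("donor must be RES:ATOM with RES one of ",
           paste(names(.DONOR_RESIDUES), collapse = ", "))
    }
    acceptor <- sp$acceptor
    d <- as.numeric(sp$dist)
    if (d <= 1.5) stop("contact distance must exceed 1.5 angstrom")

    base_z <- 25 * (k - 1L)
    need <- if (acceptor %in% c("O6A", "O6B")) c("C6", acceptor) else
      acceptor
    ring <- .ring_template("4C1")
    ring[, 3] <- ring[, 3] + base_z
    sugar <- .sugar_atoms(ring, resid, "B", 600L + k,
                          atoms = unique(c(need)))
    acc <- sugar[sugar$elety == acceptor, , drop = FALSE]
    if (nrow(acc) != 1L) stop("unknown acceptor atom: ", acceptor)
    acc_xyz <- c(acc$x, acc$y, acc$z)

    res <- dn[[1L]]; donor_atom <- dn[[2L]]
    atoms <- .DONOR_RESIDUES[[res]]
    if (!donor_atom %in% atoms) {
      stop("atom ", donor_atom, " not in template for ", res)
    }
    atoms <- c(donor_atom, setdiff(atoms, donor_atom))
    prot <- do.call(rbind, lapply(seq_along(atoms), function(j) {
      xyz <- acc_xyz + c(0.3 * ((j - 1) %% 2), 0.3 * ((j - 1) %/% 3),
                         round(d, 3) + 2.0 * (j - 1))
      .atom_row("ATOM", atoms[[j]], res, "A", 10L + k, xyz, b = 15)
    }))
    rows[[length(rows) + 1L]] <- sugar
    rows[[length(rows) + 1L]] <- prot
  }
  st <- .fixture_structure(do.call(rbind, rows))
  attr(st, "contact_specs") <- contacts
  st
}

#' Apply a rigid-body transform to a structure
#'
#' Rotates and translates all atom coordinates. Useful for testing
#' frame-invariance of geometric analyses.
#'
#' @param struct A `structure3d`.
#' @param rotation 3 x 3 rotation matrix (default identity).
#' @param translation Numeric 3-vector (default zero).
#' @return The transformed structure (cell metadata unchanged).
#' @export
transform_structure <- function(struct, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  stopifnot(inherits(struct, "structure3d"))
  m <- .xyz(struct$atoms) %*% t(rotation)
  m <- sweep(m, 2, -translation)
  struct$atoms$x <- m[, 1]
  struct$atoms$y <- m[, 2]
  struct$atoms$z <- m[, 3]
  struct
}
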