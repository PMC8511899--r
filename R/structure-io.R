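#' @importFrom stats setNames
NULL

# Canonical amino-acid three-letter codes (protein detection)
.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE")

# Backbone heavy-atom set; side chain is everything else in a protein residue
.BACKBONE <- c("N", "CA", "C", "O")

# Sugar chemical-component codes handled by the geometry/interaction layers
.SUGARS <- c("BEM", "NAG", "BDP", "LGU")

.WATERS <- c("HOH", "WAT", "DOD")

#' Parse a PDB-format macromolecular structure
#'
#' Reads fixed-column PDB content (ATOM, HETATM, CRYST1) into a
#' `structure3d` object: an atom table plus unit-cell metadata. Alternate
#' locations other than blank or `"A"` are dropped, the deposition-standard
#' convention for single-conformer analysis. Record parsing is delegated to
#' [bio3d::read.pdb()]; the unit cell and space group are read from the
#' CRYST1 record, which bio3d discards.
#'
#' @param text PDB content: a single string (with embedded newlines), a
#'   character vector of lines, or a path to a file.
#' @param z_prime Molecules per asymmetric unit, if known. Not encoded in
#'   coordinate files; defaults to `NA`.
#' @return An object of class `structure3d` with components:
#'   \describe{
#'     \item{atoms}{data frame with columns `type`, `eleno`, `elety`,
#'       `resid`, `chain`, `resno`, `x`, `y`, `z`, `o`, `b`, `elesy`.}
#'     \item{cell}{named numeric `(a, b, c, alpha, beta, gamma)` in
#'       angstroms/degrees, or `NULL` when the file carries no cell.}
#'     \item{space_group}{Hermann-Mauguin symbol or `NA`.}
#'     \item{z_prime}{molecules per asymmetric unit or `NA`.}
#'   }
#' @examples
#' s <- make_bfactor_fixture(n_residues = 3, b_profile = 10)
#' txt <- write_structure(s)
#' s2 <- parse_structure(txt)
#' nrow(s2$atoms)
#' @export
parse_structure <- function(text, z_prime = NA_real_) {
  lines <- .as_pdb_lines(text)
  if (length(lines) == 0L || !any(grepl("^(ATOM  |HETATM)", lines))) {
    stop("no ATOM or HETATM records in input")
  }
  .validate_pdb_lines(lines)

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, verbose = FALSE)

  at <- pdb$atom
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  atoms <- data.frame(
    type  = at$type,
    eleno = at$eleno,
    elety = at$elety,
    resid = at$resid,
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    elesy = ifelse(is.na(at$elesy), .guess_element(at$elety), at$elesy),
    stringsAsFactors = FALSE
  )
  rownames(atoms) <- NULL

  cryst <- grep("^CRYST1", lines, value = TRUE)
  cell <- NULL
  space_group <- NA_character_
  if (length(cryst) >= 1L) {
    cc <- .parse_cryst1(cryst[[1L]])
    cell <- cc$cell
    space_group <- cc$space_group
  }

  out <- structure(
    list(atoms = atoms, cell = cell, space_group = space_group,
         z_prime = z_prime),
    class = "structure3d"
  )
  validate_structure(out)
  out
}

#' Read a PDB file from disk
#'
#' Convenience wrapper around [parse_structure()].
#'
#' @param path Path to a PDB-format file.
#' @inheritParams parse_structure
#' @return A `structure3d` object.
#' @export
read_structure <- function(path, z_prime = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  parse_structure(readLines(path, warn = FALSE), z_prime = z_prime)
}

.as_pdb_lines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    return(readLines(text, warn = FALSE))
  }
  unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
}

.validate_pdb_lines <- function(lines) {
  idx <- grep("^(ATOM  |HETATM)", lines)
  for (i in idx) {
    ln <- lines[[i]]
    if (nchar(ln) < 54L) {
      stop("malformed ATOM/HETATM record (line ", i, "): too short")
    }
    num <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)
    )))
    if (anyNA(num)) {
      stop("malformed ATOM/HETATM record (line ", i,
           "): non-numeric coordinate field")
    }
  }
  invisible(TRUE)
}

.parse_cryst1 <- function(line) {
  line <- formatC(line, width = 70, flag = "-")
  vals <- suppressWarnings(as.numeric(c(
    substr(line, 7, 15), substr(line, 16, 24), substr(line, 25, 33),
    substr(line, 34, 40), substr(line, 41, 47), substr(line, 48, 54)
  )))
  sg <- trimws(substr(line, 56, 66))
  if (anyNA(vals)) stop("malformed CRYST1 record")
  # the placeholder cell 1 1 1 90 90 90 means "no cell"
  if (all(vals[1:3] == 1) && all(vals[4:6] == 90)) {
    return(list(cell = NULL, space_group = NA_character_))
  }
  list(cell = setNames(vals, c("a", "b", "c", "alpha", "beta", "gamma")),
       space_group = if (nzchar(sg)) sg else NA_character_)
}

.guess_element <- function(elety) {
  sym <- sub("^[0-9]*", "", elety)
  toupper(substr(sym, 1, 1))
}

#' Validate a structure3d object
#'
#' Checks the atom- and cell-level invariants: finite coordinates,
#' non-negative B-factors, occupancies in `[0, 1]`, positive cell lengths
#' and angles in `(0, 180)` degrees.
#'
#' @param struct A `structure3d` object.
#' @return The structure, invisibly; errors on violation.
#' @export
validate_structure <- function(struct) {
  stopifnot(inherits(struct, "structure3d"))
  at <- struct$atoms
  if (!all(is.finite(c(at$x, at$y, at$z)))) {
    stop("non-finite atom coordinates")
  }
  if (any(at$b < 0)) stop("negative B-factor")
  if (any(at$o < 0 | at$o > 1)) stop("occupancy outside [0, 1]")
  dup <- duplicated(at[, c("chain", "resno", "resid", "elety")])
  if (any(dup)) {
    stop("duplicate atom name within residue: ",
         paste(unique(at$elety[dup]), collapse = ", "))
  }
  if (!is.null(struct$cell)) {
    cl <- struct$cell
    if (any(cl[1:3] <= 0)) stop("non-positive cell length")
    if (any(cl[4:6] <= 0 | cl[4:6] >= 180)) {
      stop("cell angle outside (0, 180) degrees")
    }
  }
  if (!is.na(struct$z_prime) && struct$z_prime < 1) {
    stop("z_prime must be >= 1")
  }
  invisible(struct)
}

#' Write a structure to PDB format
#'
#' Serializes a `structure3d` back to fixed-column PDB text (CRYST1 when a
#' cell is present, then ATOM/HETATM records via [bio3d::write.pdb()]).
#' Coordinates keep 3 decimals and B-factors 2 decimals, the format's
#' precision, so `parse_structure(write_structure(s))` reproduces them
#' exactly at that precision.
#'
#' @param struct A `structure3d` object.
#' @param file Optional output path. When `NULL` the PDB text is returned
#'   as a single string.
#' @return The file path (invisibly) when `file` is given, otherwise the
#'   PDB text.
#' @export
write_structure <- function(struct, file = NULL) {
  validate_structure(struct)
  at <- struct$atoms
  if (any(nchar(at$elety) > 4L)) stop("atom name exceeds 4 characters")
  if (any(nchar(at$resid) > 3L)) stop("residue name exceeds 3 characters")
  if (any(nchar(at$chain) > 1L)) stop("chain id exceeds 1 character")

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = tf, xyz = xyz, type = at$type, resno = at$resno,
    resid = at$resid, eleno = at$eleno, elety = at$elety,
    chain = at$chain, o = at$o, b = at$b, elesy = at$elesy
  )
  body <- readLines(tf, warn = FALSE)
  header <- character(0)
  if (!is.null(struct$cell)) {
    cl <- struct$cell
    sg <- if (is.na(struct$space_group)) "P 1" else struct$space_group
    header <- sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
      cl[["a"]], cl[["b"]], cl[["c"]],
      cl[["alpha"]], cl[["beta"]], cl[["gamma"]], sg
    )
  }
  out <- c(header, body)
  if (is.null(file)) {
    return(paste(out, collapse = "\n"))
  }
  writeLines(out, file)
  invisible(file)
}

#' Select atoms from a structure
#'
#' Conjunctive filtering of the atom table. Every supplied clause must
#' match; an unknown chain or residue yields an empty selection rather
#' than an error. The result is ordered by (chain, residue number, atom
#' name), so repeated selection is idempotent and adding a clause can
#' only shrink the result.
#'
#' @param struct A `structure3d` object.
#' @param chain Chain identifier(s).
#' @param resno Residue number(s) (author numbering).
#' @param resid Residue name(s), e.g. `"BEM"`.
#' @param elety Atom name(s), e.g. `c("N", "CA", "C", "O")`.
#' @param hetero `NA` (default, both), `TRUE` (HETATM only) or `FALSE`
#'   (ATOM only).
#' @param backbone If `TRUE`, restrict to the backbone set
#'   `{N, CA, C, O}`.
#' @return The matching rows of the atom table, stably ordered.
#' @examples
#' s <- make_bfactor_fixture(n_residues = 2, b_profile = 10)
#' select_atoms(s, resno = 1, backbone = TRUE)$elety
#' @export
select_atoms <- function(struct, chain = NULL, resno = NULL, resid = NULL,
                         elety = NULL, hetero = NA, backbone = FALSE) {
  stopifnot(inherits(struct, "structure3d"))
  at <- struct$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(resno)) keep <- keep & at$resno %in% resno
  if (!is.null(resid)) keep <- keep & at$resid %in% resid
  if (!is.null(elety)) keep <- keep & at$elety %in% elety
  if (isTRUE(backbone)) keep <- keep & at$elety %in% .BACKBONE
  if (!is.na(hetero)) {
    keep <- keep & ((at$type == "HETATM") == hetero)
  }
  res <- at[keep, , drop = FALSE]
  res <- res[order(res$chain, res$resno, res$elety), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' @export
print.structure3d <- function(x, ...) {
  at <- x$atoms
  prot <- sum(!at$type == "HETATM")
  cat("structure3d: ", nrow(at), " atoms (", prot, " ATOM, ",
      nrow(at) - prot, " HETATM), ",
      length(unique(paste(at$chain, at$resno))), " residues\n", sep = "")
  if (!is.null(x$cell)) {
    cat("  cell: ", paste(sprintf("%.3f", x$cell[1:3]), collapse = " "),
        " / ", paste(sprintf("%.2f", x$cell[4:6]), collapse = " "),
        "  SG: ", x$space_group, "\n", sep = "")
  }
  invisible(x)
}

# TRUE for atoms belonging to standard amino-acid residues
.is_protein <- function(atoms) {
  atoms$resid %in% .AA3 & atoms$type == "ATOM"
}

.is_water <- function(atoms) atoms$resid %in% .WATERS

.xyz <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}
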