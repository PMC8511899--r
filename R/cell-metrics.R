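# General-position multiplicities of the space groups encountered in
# the pH series (plus P1 baseline)
.SG_MULTIPLICITY <- c("P 1" = 1, "P 21 21 21" = 4, "P 21 21 2" = 4,
                      "C 2 2 21" = 8, "P 31 2 1" = 6)

#' Space-group general-position multiplicity
#'
#' Asymmetric units per unit cell for the supported Hermann-Mauguin
#' symbols; spacing and subscript formatting are normalized
#' (`"P212121"` and `"P 21 21 21"` are the same group).
#'
#' @param symbol Hermann-Mauguin space-group symbol.
#' @return Integer multiplicity.
#' @export
sg_multiplicity <- function(symbol) {
  key <- gsub(" ", "", names(.SG_MULTIPLICITY))
  hit <- match(gsub(" ", "", toupper(symbol)), toupper(key))
  if (is.na(hit)) {
    stop("unknown space group: ", symbol, " (supported: ",
         paste(names(.SG_MULTIPLICITY), collapse = ", "), ")")
  }
  unname(.SG_MULTIPLICITY[[hit]])
}

#' Unit-cell volume from cell parameters
#'
#' General triclinic formula
#' \deqn{V = abc\sqrt{1 - \cos^2\alpha - \cos^2\beta - \cos^2\gamma
#'   + 2\cos\alpha\cos\beta\cos\gamma}}
#' which reduces to `a*b*c` for orthorhombic cells.
#'
#' @param a,b,c Cell lengths in angstroms (positive).
#' @param alpha,beta,gamma Cell angles in degrees, in (0, 180).
#' @return Volume in cubic angstroms.
#' @examples
#' unit_cell_volume(49.131, 94.737, 160.499, 90, 90, 90)
#' @export
unit_cell_volume <- function(a, b, c, alpha = 90, beta = 90,
                             gamma = 90) {
  if (any(c(a, b, c) <= 0)) stop("cell lengths must be positive")
  ang <- c(alpha, beta, gamma)
  if (any(ang <= 0 | ang >= 180)) {
    stop("cell angles must lie in (0, 180) degrees")
  }
  ca <- cos(alpha * pi / 180)
  cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180)
  disc <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (disc <= 0) stop("impossible cell: negative volume discriminant")
  a * b * c * sqrt(disc)
}

#' Matthews coefficient
#'
#' Crystal volume per dalton of macromolecule:
#' `VM = V / (multiplicity * z_prime * mw)`.
#'
#' @param volume Unit-cell volume, cubic angstroms.
#' @param multiplicity Asymmetric units per cell (space-group general
#'   positions).
#' @param z_prime Molecules per asymmetric unit.
#' @param mw Molecular weight of one molecule, daltons.
#' @return VM in cubic angstroms per dalton.
#' @export
matthews <- function(volume, multiplicity, z_prime, mw) {
  stopifnot(volume > 0, multiplicity > 0, z_prime > 0, mw > 0)
  volume / (multiplicity * z_prime * mw)
}

#' Solvent content from the Matthews coefficient
#'
#' `(1 - 1.23 / VM) * 100`, using Matthews' classic protein partial
#' specific volume constant 1.23, clipped to `[0, 100]` percent. A VM
#' at or below 1.23 (denser than pure protein) returns 0 with a
#' warning.
#'
#' @param vm Matthews coefficient, cubic angstroms per dalton.
#' @return Solvent content in percent.
#' @examples
#' solvent_content(2.46)  # 50%
#' @export
solvent_content <- function(vm) {
  stopifnot(vm > 0)
  if (vm <= 1.23) {
    warning("VM <= 1.23 A^3/Da implies no solvent; returning 0%")
    return(0)
  }
  min((1 - 1.23 / vm) * 100, 100)
}

#' Protein molecular weight from sequence or structure
#'
#' Average molecular weight of the polypeptide, via [seqinr::pmw()].
#' When given a structure, the sequence is taken from the CA atoms of
#' one chain.
#'
#' @param x One-letter sequence string, a character vector of
#'   one-letter codes, or a `structure3d` object.
#' @param chain Chain to use when `x` is a structure (default: first
#'   protein chain).
#' @return Molecular weight in daltons.
#' @export
protein_mw <- function(x, chain = NULL) {
  if (inherits(x, "structure3d")) {
    ca <- select_atoms(x, elety = "CA", hetero = FALSE)
    if (is.null(chain)) chain <- ca$chain[[1L]]
    ca <- ca[ca$chain == chain, , drop = FALSE]
    aa1 <- .AA1[ca$resid]
    x <- aa1[!is.na(aa1)]
  }
  if (length(x) == 1L && nchar(x) > 1L) {
    x <- strsplit(x, "")[[1L]]
  }
  seqinr::pmw(toupper(x))
}

#' Cell metrics bundle: volume, Matthews coefficient, solvent content
#'
#' Computes the crystal-packing summary a structure table reports from
#' the unit cell, space group, copies per asymmetric unit and molecular
#' weight; alternatively extracts cell and sequence from a parsed
#' structure.
#'
#' @param cell Named numeric `(a, b, c, alpha, beta, gamma)`, or a
#'   `structure3d` carrying a cell.
#' @param space_group Hermann-Mauguin symbol (taken from the structure
#'   if omitted).
#' @param z_prime Molecules per asymmetric unit.
#' @param mw Molecular weight per molecule in daltons (computed from
#'   the structure's sequence if omitted and a structure is given).
#' @return List with `volume`, `multiplicity`, `vm` and `solvent`.
#' @export
cell_metrics <- function(cell, space_group = NULL, z_prime = 1,
                         mw = NULL) {
  if (inherits(cell, "structure3d")) {
    struct <- cell
    if (is.null(struct$cell)) stop("structure carries no unit cell")
    if (is.null(space_group)) space_group <- struct$space_group
    if (!is.na(struct$z_prime)) z_prime <- struct$z_prime
    if (is.null(mw)) mw <- protein_mw(struct)
    cell <- struct$cell
  }
  if (is.null(mw)) stop("molecular weight required")
  vol <- unit_cell_volume(cell[["a"]], cell[["b"]], cell[["c"]],
                          cell[["alpha"]], cell[["beta"]],
                          cell[["gamma"]])
  mult <- sg_multiplicity(space_group)
  vm <- matthews(vol, mult, z_prime, mw)
  list(volume = vol, multiplicity = mult, vm = vm,
       solvent = solvent_content(vm))
}
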