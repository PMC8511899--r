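# Shared test helpers: tiny hand-written PDB text, structure editing,
# rotation matrices, and a chi1 residue constructor with a known torsion.

tiny_pdb_text <- paste(
  c("CRYST1   49.131   94.737  160.499  90.00  90.00  90.00 P 21 21 21",
    "ATOM      1  N   ALA A  22      11.104   6.134  -6.504  1.00 10.00           N",
    "ATOM      2  CA  ALA A  22      11.639   6.071  -5.147  1.00 12.50           C",
    "ATOM      3  C   ALA A  22      12.345   7.364  -4.803  1.00 15.00           C",
    "END"),
  collapse = "\n")

# Append atoms of one protein residue at explicit coordinates, then
# round-trip through PDB text so the edit goes through the parser path.
add_protein_residue <- function(st, resid, resno, atoms, chain = "A",
                                b = 15) {
  rows <- do.call(rbind, lapply(names(atoms), function(a) {
    xyz <- atoms[[a]]
    data.frame(type = "ATOM", eleno = NA_integer_, elety = a,
               resid = resid, chain = chain, resno = as.integer(resno),
               x = round(xyz[[1]], 3), y = round(xyz[[2]], 3),
               z = round(xyz[[3]], 3), o = 1, b = b,
               elesy = toupper(substr(sub("^[0-9]*", "", a), 1, 1)),
               stringsAsFactors = FALSE)
  }))
  st$atoms <- rbind(st$atoms, rows)
  st$atoms$eleno <- seq_len(nrow(st$atoms))
  parse_structure(write_structure(st))
}

rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, -s, 0, s, c, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Residue whose chi1 (N-CA-CB-CG dihedral, IUPAC sign) equals `chi`
# degrees by construction: CB axis along z, N in the x-z plane.
chi_residue_atoms <- function(chi, base = c(0, 0, 0)) {
  phi <- chi * pi / 180
  list(N = base + c(1.45, 0, -1.0),
       CA = base,
       CB = base + c(0, 0, 1.53),
       CG = base + c(1.45 * cos(phi), 1.45 * sin(phi), 2.3),
       C = base + c(-1.3, 0.8, -0.4),
       O = base + c(-1.5, 2.0, -0.6))
}
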