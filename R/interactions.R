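# One-letter amino-acid codes, for composing residue ids like "Y38"
.AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
          GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
          LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
          SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
          MSE = "M")

# Uronic-acid carboxylate oxygen aliases (O61/O62 deposition variants)
.SUGAR_ATOM_ALIASES <- c(O61 = "O6A", O62 = "O6B")

.norm_sugar_atom <- function(elety) {
  hit <- match(elety, names(.SUGAR_ATOM_ALIASES))
  ifelse(is.na(hit), elety, .SUGAR_ATOM_ALIASES[hit])
}

# Protein nitrogen atoms that are cationic at working pH (salt-bridge donors)
.CATIONIC_N <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ")

# Carboxylate oxygens on ligands (uronic acid C6 carboxylate; Asp/Glu
# for generality)
.CARBOXYLATE_O <- c("O6A", "O6B", "OD1", "OD2", "OE1", "OE2")

.pairwise_dist <- function(a, b) {
  ax <- .xyz(a); bx <- .xyz(b)
  dx <- outer(ax[, 1], bx[, 1], "-")
  dy <- outer(ax[, 2], bx[, 2], "-")
  dz <- outer(ax[, 3], bx[, 3], "-")
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Sugar (glycan) residues of a structure
#'
#' HETATM residues whose chemical component code is one of the handled
#' sugars (BEM, NAG, BDP, LGU).
#'
#' @param struct A `structure3d` object.
#' @return Atom table of the glycan residues, with carboxylate oxygen
#'   aliases normalized (O61/O62 to O6A/O6B).
#' @export
ligand_atoms <- function(struct) {
  at <- struct$atoms
  lig <- at[at$resid %in% .SUGARS, , drop = FALSE]
  lig$elety <- .norm_sugar_atom(lig$elety)
  rownames(lig) <- NULL
  lig
}

#' Assign lyase subsites to a bound glycan chain
#'
#' Infers the glycosidic connectivity of the bound sugar residues
#' (an exocyclic oxygen of one sugar within `link_cutoff` of the
#' anomeric C1 of the next), orders the chain from its reducing end (the
#' unique sugar whose C1 is not engaged in a linkage; the reducing end
#' exits the tunnel first), locates the scissile glycosidic oxygen as
#' the linkage oxygen nearest the catalytic-residue centroid, and
#' numbers subsites so that `+1` and `-1` flank the scissile bond with
#' positive subsites on the reducing (exit) side.
#'
#' @param struct A `structure3d` object.
#' @param catalytic Residue ids of the catalytic set used to locate the
#'   scissile bond (default `c("N167","H168","Y222")`); their side-chain
#'   centroid is the reference point.
#' @param catalytic_point Optional explicit 3-vector overriding the
#'   centroid (useful for synthetic fixtures without a full protein).
#' @param link_cutoff Maximum O-C1 distance treated as a glycosidic
#'   bond, in angstroms.
#' @return A `subsite_assignment`: data frame (`chain`, `resno`,
#'   `resid`, `subsite`) with attribute `scissile` (list with the
#'   glycosidic oxygen atom row and the flanking residue numbers), or a
#'   zero-row frame when the structure holds no glycan.
#' @examples
#' s <- make_glycan_fixture(n_sugars = 3)
#' assign_subsites(s, catalytic_point = attr(s, "triad_point"))
#' @export
assign_subsites <- function(struct, catalytic = c("N167", "H168", "Y222"),
                            catalytic_point = NULL, link_cutoff = 1.8) {
  lig <- ligand_atoms(struct)
  empty <- data.frame(chain = character(0), resno = integer(0),
                      resid = character(0), subsite = integer(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("subsite_assignment", "data.frame")
  if (nrow(lig) == 0L) return(empty)

  key <- unique(lig[, c("chain", "resno", "resid")])
  rownames(key) <- NULL
  n <- nrow(key)
  res_atoms <- lapply(seq_len(n), function(i) {
    lig[lig$chain == key$chain[i] & lig$resno == key$resno[i], ,
        drop = FALSE]
  })

  if (is.null(catalytic_point)) {
    nums <- region_resno(catalytic)
    prot <- struct$atoms[.is_protein(struct$atoms), , drop = FALSE]
    side <- prot[prot$resno %in% nums & !prot$elety %in% .BACKBONE, ,
                 drop = FALSE]
    if (nrow(side) == 0L) {
      stop("catalytic residues not found; supply catalytic_point")
    }
    catalytic_point <- colMeans(.xyz(side))
  }

  if (n == 1L) {
    out <- cbind(key, subsite = 1L)
    class(out) <- c("subsite_assignment", "data.frame")
    attr(out, "scissile") <- NULL
    return(out)
  }

  # glycosidic links: exocyclic O of residue i near anomeric C1 of j
  links <- list()
  for (i in seq_len(n)) {
    oi <- res_atoms[[i]][res_atoms[[i]]$elesy == "O", , drop = FALSE]
    if (nrow(oi) == 0L) next
    for (j in seq_len(n)) {
      if (i == j) next
      cj <- res_atoms[[j]][res_atoms[[j]]$elety == "C1", , drop = FALSE]
      if (nrow(cj) == 0L) next
      d <- .pairwise_dist(oi, cj)
      hit <- which(d <= link_cutoff, arr.ind = TRUE)
      if (nrow(hit)) {
        k <- hit[1L, ]
        links[[length(links) + 1L]] <- list(
          o_res = i, c_res = j, o_atom = oi[k[[1L]], , drop = FALSE],
          dist = d[k[[1L]], k[[2L]]]
        )
      }
    }
  }
  if (length(links) == 0L) {
    stop("ligand residues are not glycosidically connected")
  }

  adj <- matrix(FALSE, n, n)
  for (lk in links) adj[lk$o_res, lk$c_res] <- adj[lk$c_res, lk$o_res] <- TRUE
  deg <- rowSums(adj)
  if (any(deg > 2L) || sum(deg == 1L) != 2L || sum(deg) != 2L * (n - 1L)) {
    stop("glycan is branched or disconnected; cannot assign subsites")
  }

  # reducing end: C1 not used as the carbon partner of any linkage
  c1_used <- unique(vapply(links, function(l) l$c_res, integer(1)))
  red <- setdiff(which(deg == 1L), c1_used)
  if (length(red) != 1L) {
    stop("cannot identify a unique reducing end")
  }
  path <- red
  while (length(path) < n) {
    nxt <- setdiff(which(adj[path[length(path)], ]), path)
    path <- c(path, nxt[[1L]])
  }

  # scissile bond: linkage oxygen nearest the catalytic reference point
  link_of <- function(i, j) {
    for (lk in links) {
      if ((lk$o_res == i && lk$c_res == j) ||
          (lk$o_res == j && lk$c_res == i)) return(lk)
    }
    NULL
  }
  bond_links <- lapply(seq_len(n - 1L),
                       function(k) link_of(path[k], path[k + 1L]))
  dists <- vapply(bond_links, function(lk) {
    sqrt(sum((as.numeric(lk$o_atom[1, c("x", "y", "z")]) -
                catalytic_point)^2))
  }, numeric(1))
  k <- which.min(dists)

  subsite <- integer(n)
  subsite[path[seq_len(k)]] <- k - seq_len(k) + 1L          # +k ... +1
  subsite[path[seq(k + 1L, n)]] <- -(seq(k + 1L, n) - k)    # -1 ... -(n-k)

  out <- cbind(key, subsite = subsite)
  out <- out[order(-out$subsite), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("subsite_assignment", "data.frame")
  attr(out, "scissile") <- list(
    o_atom = bond_links[[k]]$o_atom,
    flanking = c(key$resno[path[k]], key$resno[path[k + 1L]])
  )
  out
}

.interaction_records <- function(prot_sel, lig_sel, kind, cutoff) {
  if (nrow(prot_sel) == 0L || nrow(lig_sel) == 0L) {
    return(.empty_records())
  }
  d <- .pairwise_dist(prot_sel, lig_sel)
  hit <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(.empty_records())
  data.frame(
    donor_chain = prot_sel$chain[hit[, 1]],
    donor_resid = prot_sel$resid[hit[, 1]],
    donor_resno = prot_sel$resno[hit[, 1]],
    donor_atom = prot_sel$elety[hit[, 1]],
    acceptor_chain = lig_sel$chain[hit[, 2]],
    acceptor_resid = lig_sel$resid[hit[, 2]],
    acceptor_resno = lig_sel$resno[hit[, 2]],
    acceptor_atom = lig_sel$elety[hit[, 2]],
    kind = kind,
    distance = d[hit],
    stringsAsFactors = FALSE
  )
}

.empty_records <- function() {
  data.frame(donor_chain = character(0), donor_resid = character(0),
             donor_resno = integer(0), donor_atom = character(0),
             acceptor_chain = character(0), acceptor_resid = character(0),
             acceptor_resno = integer(0), acceptor_atom = character(0),
             kind = character(0), distance = numeric(0),
             stringsAsFactors = FALSE)
}

.salt_bridge_typed <- function(atoms) {
  ok <- rep(FALSE, nrow(atoms))
  for (res in names(.CATIONIC_N)) {
    ok <- ok | (atoms$resid == res & atoms$elety %in% .CATIONIC_N[[res]])
  }
  ok
}

#' Protein-ligand salt bridges
#'
#' Pairs of a cationic side-chain nitrogen (Arg NH1/NH2/NE, Lys NZ) and
#' a ligand carboxylate oxygen (uronic O6A/O6B, or Asp/Glu-type
#' carboxylate oxygens) within the cutoff. Histidine contacts are
#' deliberately classified as hydrogen bonds, matching the convention of
#' the interaction tables this reproduces.
#'
#' @param struct A `structure3d` object.
#' @param cutoff Heavy-atom distance cutoff in angstroms (default 4.0).
#' @param ligand Optional ligand atom table (default [ligand_atoms()]).
#' @param protein Optional protein atom table.
#' @return Data frame of interaction records (donor = protein atom,
#'   acceptor = ligand atom, `kind = "SALT BRIDGE"`, `distance`).
#' @export
find_salt_bridges <- function(struct, cutoff = 4.0, ligand = NULL,
                              protein = NULL) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (is.null(ligand)) ligand <- ligand_atoms(struct)
  if (is.null(protein)) {
    protein <- struct$atoms[.is_protein(struct$atoms), , drop = FALSE]
  }
  prot <- protein[.salt_bridge_typed(protein), , drop = FALSE]
  lig <- ligand[ligand$elety %in% .CARBOXYLATE_O, , drop = FALSE]
  .interaction_records(prot, lig, "SALT BRIDGE", cutoff)
}

#' Protein-ligand hydrogen bonds
#'
#' All pairs of a polar protein nitrogen/oxygen and a ligand
#' nitrogen/oxygen within the heavy-atom cutoff. No donor-hydrogen
#' angle term is applied: the crystallographic models this targets are
#' hydrogen-free at 2.2-2.6 angstrom resolution, so the criterion is
#' distance-only, with the cutoff bracketing the longest tabulated
#' hydrogen bond (3.6 angstroms). Pairs typed as salt bridges (cationic
#' N against carboxylate O) are excluded. The record lists the protein
#' atom as donor and the sugar atom as acceptor, following the
#' convention of the tables being reproduced.
#'
#' @inheritParams find_salt_bridges
#' @param cutoff Heavy-atom distance cutoff in angstroms (default 3.6).
#' @return Data frame of interaction records (`kind = "H-BOND"`).
#' @export
find_hbonds <- function(struct, cutoff = 3.6, ligand = NULL,
                        protein = NULL) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (is.null(ligand)) ligand <- ligand_atoms(struct)
  if (is.null(protein)) {
    protein <- struct$atoms[.is_protein(struct$atoms), , drop = FALSE]
  }
  prot <- protein[protein$elesy %in% c("N", "O"), , drop = FALSE]
  lig <- ligand[ligand$elesy %in% c("N", "O"), , drop = FALSE]
  rec <- .interaction_records(prot, lig, "H-BOND", cutoff)
  sb_type <- .salt_bridge_typed(
    data.frame(resid = rec$donor_resid, elety = rec$donor_atom,
               stringsAsFactors = FALSE)) &
    rec$acceptor_atom %in% .CARBOXYLATE_O
  rec[!sb_type, , drop = FALSE]
}

#' Full enzyme-substrate interaction table with subsite and region labels
#'
#' Enumerates hydrogen bonds and salt bridges between the protein and
#' the bound glycan, attaches each ligand partner's subsite (a
#' glycosidic oxygen belonging to a linkage is labelled with both
#' flanking subsites, e.g. `"-1,+1"`), labels every protein residue with
#' its site and surface from the region map, sorts records entry ->
#' tunnel -> exit by donor residue number, and counts hydrogen bonds and
#' salt bridges restricted to the catalytic `[-1, +1]` subsites.
#'
#' @param struct A `structure3d` object.
#' @param region_map A `region_map` (default [default_region_map()]).
#' @param hbond_cutoff,saltbridge_cutoff Distance cutoffs in angstroms.
#' @param ... Passed to [assign_subsites()] (e.g. `catalytic_point`).
#' @return List with `records` (ordered data frame adding `site`,
#'   `surface`, `subsite`) and `counts`
#'   (`c(h_bond = n, salt_bridge = m)` over the `[-1, +1]` subsites).
#' @export
interaction_table <- function(struct, region_map = default_region_map(),
                              hbond_cutoff = 3.6, saltbridge_cutoff = 4.0,
                              ...) {
  sub <- assign_subsites(struct, ...)
  sb <- find_salt_bridges(struct, cutoff = saltbridge_cutoff)
  hb <- find_hbonds(struct, cutoff = hbond_cutoff)
  rec <- rbind(sb, hb)
  if (nrow(rec) == 0L || nrow(sub) == 0L) {
    rec <- .empty_records()
    rec$site <- rec$surface <- rec$subsite <- character(0)
    return(list(records = rec,
                counts = c(h_bond = 0L, salt_bridge = 0L)))
  }

  scis <- attr(sub, "scissile")
  sub_of <- function(resno) sub$subsite[match(resno, sub$resno)]
  fmt <- function(s) sprintf("%+d", s)
  subsite <- character(nrow(rec))
  catalytic_only <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    s <- sub_of(rec$acceptor_resno[[i]])
    bridging <- !is.null(scis) &&
      rec$acceptor_resno[[i]] == scis$o_atom$resno[[1L]] &&
      rec$acceptor_atom[[i]] == scis$o_atom$elety[[1L]]
    if (bridging) {
      both <- sort(vapply(scis$flanking, sub_of, numeric(1)))
      subsite[[i]] <- paste(fmt(both), collapse = ",")
      catalytic_only[[i]] <- all(abs(both) == 1L)
    } else {
      subsite[[i]] <- fmt(s)
      catalytic_only[[i]] <- abs(s) == 1L
    }
  }
  rec$subsite <- subsite

  aa1 <- .AA1[rec$donor_resid]
  donor_id <- paste0(ifelse(is.na(aa1), "X", aa1), rec$donor_resno)
  rec$site <- vapply(donor_id, function(id) site_of(region_map, id),
                     character(1))
  rec$surface <- vapply(donor_id, function(id) {
    sf <- surface_of(region_map, id)
    if (length(sf)) paste(sf, collapse = "/") else NA_character_
  }, character(1))

  site_rank <- match(rec$site, c("entry", "tunnel", "exit"))
  site_rank[is.na(site_rank)] <- 4L
  ord <- order(site_rank, rec$donor_resno, rec$kind, rec$distance)
  rec <- rec[ord, , drop = FALSE]
  rownames(rec) <- NULL

  cat_rec <- rec[catalytic_only[ord], , drop = FALSE]
  counts <- c(h_bond = sum(cat_rec$kind == "H-BOND"),
              salt_bridge = sum(cat_rec$kind == "SALT BRIDGE"))
  list(records = rec, counts = counts)
}
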