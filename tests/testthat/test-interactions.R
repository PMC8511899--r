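test_that("hydrogen bonds are found at construction distance and not beyond cutoff", {
  s <- make_contact_fixture(list(list(donor = "SER:OG", acceptor = "O3",
                                      dist = 2.9)))
  hb <- find_hbonds(s)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$donor_atom, "OG")
  expect_equal(hb$acceptor_atom, "O3")
  expect_equal(hb$distance, 2.9, tolerance = 0.01)

  far <- make_contact_fixture(list(list(donor = "TYR:OH",
                                        acceptor = "O3", dist = 3.7)))
  expect_equal(nrow(find_hbonds(far, cutoff = 3.6)), 0L)
  expect_error(find_hbonds(s, cutoff = -1), "positive")
})

test_that("salt bridges pair cationic nitrogens with carboxylate oxygens only", {
  s <- make_contact_fixture(list(list(donor = "ARG:NH1",
                                      acceptor = "O6B", dist = 2.9),
                                 list(donor = "LYS:NZ",
                                      acceptor = "O6A", dist = 3.0)))
  sb <- find_salt_bridges(s)
  expect_equal(nrow(sb), 2L)
  expect_setequal(sb$donor_atom, c("NH1", "NZ"))
  expect_equal(sort(sb$distance), c(2.9, 3.0), tolerance = 0.01)
  # a hydroxyl contact is never typed as a salt bridge
  hydroxyl <- make_contact_fixture(list(list(donor = "TYR:OH",
                                             acceptor = "O3",
                                             dist = 2.8)))
  expect_equal(nrow(find_salt_bridges(hydroxyl)), 0L)
})

test_that("salt-bridge and hydrogen-bond sets never share an atom pair", {
  s <- make_contact_fixture(list(list(donor = "ARG:NH1",
                                      acceptor = "O6B", dist = 2.9),
                                 list(donor = "SER:OG",
                                      acceptor = "O2", dist = 3.0)))
  sb <- find_salt_bridges(s)
  hb <- find_hbonds(s)
  key <- function(df) paste(df$donor_resno, df$donor_atom,
                            df$acceptor_resno, df$acceptor_atom)
  expect_length(intersect(key(sb), key(hb)), 0L)
  expect_equal(nrow(sb), 1L)
  expect_equal(nrow(hb), 1L)
})

test_that("a batch of random contact specs is recovered to 0.01 angstrom", {
  set.seed(21)
  donors <- c("SER:OG", "TYR:OH", "ASN:ND2", "HIS:NE2")
  specs <- lapply(1:10, function(i) {
    list(donor = sample(donors, 1),
         acceptor = sample(c("O2", "O3", "O4"), 1),
         dist = round(runif(1, 2.7, 3.5), 3))
  })
  s <- make_contact_fixture(specs)
  hb <- find_hbonds(s)
  expect_equal(nrow(hb), 10L)
  want <- vapply(specs, function(sp) sp$dist, numeric(1))
  got <- hb$distance[order(hb$acceptor_resno)]
  expect_equal(got, want, tolerance = 0.01)
})

test_that("increasing the cutoff never removes interaction records", {
  set.seed(33)
  specs <- lapply(1:6, function(i) {
    list(donor = "SER:OG", acceptor = "O3",
         dist = round(runif(1, 2.6, 4.4), 3))
  })
  s <- make_contact_fixture(specs)
  cuts <- c(2.8, 3.2, 3.6, 4.0, 4.5)
  ns <- vapply(cuts, function(ct) nrow(find_hbonds(s, cutoff = ct)),
               integer(1))
  expect_true(all(diff(ns) >= 0))
})

test_that("interaction records are invariant under rigid-body motion", {
  s <- make_contact_fixture(list(list(donor = "ARG:NH1",
                                      acceptor = "O6B", dist = 2.9),
                                 list(donor = "TYR:OH", acceptor = "O3",
                                      dist = 3.1)))
  r <- transform_structure(s, random_rotation(8), c(12, -7, 31))
  for (f in list(find_hbonds, find_salt_bridges)) {
    a <- f(s); b <- f(r)
    expect_equal(nrow(a), nrow(b))
    expect_equal(a$distance, b$distance, tolerance = 1e-6)
  }
})

test_that("subsites number outward from the scissile bond, reducing end positive", {
  g <- make_glycan_fixture(3)
  sub <- assign_subsites(g, catalytic_point = attr(g, "triad_point"))
  expect_equal(sub$subsite[match(c(601, 701, 801), sub$resno)],
               c(1L, -1L, -2L))
  scis <- attr(sub, "scissile")
  expect_setequal(scis$flanking, c(601, 701))

  g4 <- make_glycan_fixture(4)
  sub4 <- assign_subsites(g4, catalytic_point = attr(g4, "triad_point"))
  expect_equal(sort(sub4$subsite), c(-3L, -2L, -1L, 1L))
})

test_that("a single sugar sits at subsite +1 and apo structures give none", {
  ring <- make_ring_fixture("4C1", resno = 601L)
  sub <- assign_subsites(ring, catalytic_point = c(0, 5, 0))
  expect_equal(sub$subsite, 1L)
  apo <- make_bfactor_fixture(5, b_profile = 10)
  expect_equal(nrow(assign_subsites(apo, catalytic_point = c(0, 0, 0))),
               0L)
})

test_that("disconnected ligand residues are rejected", {
  g <- make_glycan_fixture(2)
  far <- g$atoms$resno == 701
  g$atoms$x[far] <- g$atoms$x[far] - 40
  expect_error(assign_subsites(g, catalytic_point = c(0, 3, 0)),
               "connected|disconnected")
})

test_that("the interaction table carries subsites, regions and [-1,+1] counts", {
  g <- make_glycan_fixture(3)
  triad <- attr(g, "triad_point")
  lig <- ligand_atoms(g)
  at_of <- function(resno, name) {
    r <- lig[lig$resno == resno & lig$elety == name, ]
    c(r$x, r$y, r$z)
  }
  # R312 (entry/F2) salt-bridges the +1 sugar's carboxylate; S99
  # (unmapped) H-bonds the -1 sugar's O6A; Y38 (tunnel) H-bonds the -2
  # sugar (excluded from the catalytic-subsite counts)
  g <- add_protein_residue(g, "ARG", 312,
    list(NH1 = at_of(601, "O6B") + c(0, 0, -2.9),
         CZ = at_of(601, "O6B") + c(0, 0, -5.0),
         CA = at_of(601, "O6B") + c(0, 0, -8.0)))
  g <- add_protein_residue(g, "SER", 99,
    list(OG = at_of(701, "O6A") + c(0, 0, 3.0),
         CB = at_of(701, "O6A") + c(0, 0, 5.2),
         CA = at_of(701, "O6A") + c(0, 0, 7.4)))
  g <- add_protein_residue(g, "TYR", 38,
    list(OH = at_of(801, "O3") + c(0, 0, 3.1),
         CZ = at_of(801, "O3") + c(0, 0, 5.3),
         CA = at_of(801, "O3") + c(0, 0, 7.5)))
  tb <- interaction_table(g, catalytic_point = triad)
  rec <- tb$records
  expect_equal(nrow(rec), 3L)
  expect_equal(tb$counts, c(h_bond = 1L, salt_bridge = 1L))
  r312 <- rec[rec$donor_resno == 312, ]
  expect_equal(r312$kind, "SALT BRIDGE")
  expect_equal(r312$site, "entry")
  expect_equal(r312$surface, "F2")
  expect_equal(r312$subsite, "+1")
  expect_equal(rec$subsite[rec$donor_resno == 38], "-2")
  # ordering: entry before tunnel before unmapped
  expect_equal(rec$donor_resno, c(312, 38, 99))
})

test_that("an apo structure yields an empty interaction table", {
  apo <- make_bfactor_fixture(5, b_profile = 10)
  tb <- interaction_table(apo, catalytic_point = c(0, 0, 0))
  expect_equal(nrow(tb$records), 0L)
  expect_equal(tb$counts, c(h_bond = 0L, salt_bridge = 0L))
})
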