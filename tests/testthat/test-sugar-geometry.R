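test_that("a planar hexagon has zero displacements; chairs alternate at 0.25", {
  flat <- make_ring_fixture("planar")
  pl <- ring_mean_plane(ring_coords(flat, 1))
  expect_equal(unname(pl$displacements), rep(0, 6), tolerance = 1e-3)
  expect_equal(sum(pl$displacements), 0, tolerance = 1e-6)
  expect_equal(sqrt(sum(pl$normal^2)), 1, tolerance = 1e-12)

  chair <- make_ring_fixture("4C1")
  d <- ring_mean_plane(ring_coords(chair, 1))$displacements
  expect_equal(abs(unname(d)), rep(0.25, 6), tolerance = 0.01)
  s135 <- sign(d[c("C1", "C3", "C5")])
  s240 <- sign(d[c("C2", "C4", "O5")])
  expect_true(all(s135 == s135[[1]]))
  expect_true(all(s240 == -s135[[1]]))
})

test_that("1C4 is the mirror of 4C1 relative to a common reference", {
  a <- make_ring_fixture("4C1")
  b <- make_ring_fixture("1C4")
  ref <- c(0, 0, 5)
  expect_equal(classify_face(ring_coords(a, 1), ref), "alpha")
  expect_equal(classify_face(ring_coords(b, 1), ref), "beta")
  # each chair seen from its own C1/C3/C5 side is alpha
  expect_equal(classify_face(ring_coords(b, 1),
                             attr(b, "face_reference")), "alpha")
})

test_that("reflecting the reference through the plane swaps alpha and beta", {
  set.seed(14)
  for (conf in c("4C1", "1C4")) {
    s <- make_ring_fixture(conf)
    ring <- ring_coords(s, 1)
    pl <- ring_mean_plane(ring)
    ref <- pl$centroid + 4 * pl$normal + c(0.3, -0.2, 0.1)
    h <- sum((ref - pl$centroid) * pl$normal)
    mirrored <- ref - 2 * h * pl$normal
    f1 <- classify_face(pl, ref)
    f2 <- classify_face(pl, mirrored)
    expect_setequal(c(f1, f2), c("alpha", "beta"))
  }
})

test_that("face calls are invariant under joint rigid motion", {
  s <- make_ring_fixture("4C1")
  ring <- ring_coords(s, 1)
  ref <- attr(s, "face_reference")
  f0 <- classify_face(ring, ref)
  for (seed in 1:4) {
    R <- random_rotation(seed)
    t <- c(7, -3, 11) * seed
    ring2 <- sweep(ring %*% t(R), 2, -t)
    ref2 <- as.numeric(R %*% ref) + t
    expect_equal(classify_face(ring2, ref2), f0)
  }
})

test_that("degenerate rings and in-plane references are rejected", {
  line <- cbind(seq(0, 5, 1), 0, 0)
  expect_error(ring_mean_plane(line), "collinear|degenerate")
  s <- make_ring_fixture("4C1")
  pl <- ring_mean_plane(ring_coords(s, 1))
  expect_error(classify_face(pl, pl$centroid + 0.01 * pl$normal),
               "0.1 angstrom")
})

test_that("non-chair puckers are indeterminate; chairs never are", {
  hc <- make_ring_fixture("half-chair")
  expect_equal(classify_face(ring_coords(hc, 1), c(0, 0, 5)),
               "indeterminate")
  flat <- make_ring_fixture("planar")
  expect_equal(classify_face(ring_coords(flat, 1), c(0, 0, 5)),
               "indeterminate")
  for (conf in c("4C1", "1C4")) {
    f <- classify_face(ring_coords(make_ring_fixture(conf), 1),
                       c(1, 2, 6))
    expect_true(f %in% c("alpha", "beta"))
  }
})

test_that("Cremer-Pople parameters mark ideal chairs as poles", {
  th4 <- ring_pucker_cp(ring_coords(make_ring_fixture("4C1"), 1))
  th1 <- ring_pucker_cp(ring_coords(make_ring_fixture("1C4"), 1))
  expect_true(min(th4$theta, 180 - th4$theta) < 5)
  expect_true(min(th1$theta, 180 - th1$theta) < 5)
  expect_equal(abs(th4$theta - th1$theta), 180, tolerance = 5)
  expect_gt(th4$Q, 0.4)
  flat <- ring_pucker_cp(ring_coords(make_ring_fixture("planar"), 1))
  expect_lt(flat$Q, 0.01)
})

test_that("torsion angles agree with an independent implementation", {
  set.seed(2)
  for (i in 1:20) {
    p <- matrix(rnorm(12, sd = 3), 4, 3)
    mine <- torsion_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    ref <- bio3d::torsion.xyz(as.numeric(t(p)), atm.inc = 4)
    ref <- ref[!is.na(ref)][[1]]
    delta <- abs(mine - ref) %% 360
    expect_lt(min(delta, 360 - delta), 1e-6)
  }
})

test_that("chi1 is computed and binned from constructed side chains", {
  s <- make_bfactor_fixture(1, b_profile = 10)  # carrier structure
  for (case in list(list(chi = 180, bin = "t"),
                    list(chi = -60, bin = "g-"),
                    list(chi = 60, bin = "g+"),
                    list(chi = -150, bin = "t"))) {
    st <- add_protein_residue(s, "ARG", 50,
                              chi_residue_atoms(case$chi, c(30, 0, 0)))
    got <- chi1(st, 50)
    expect_equal(got$chi1, case$chi, tolerance = 0.05)
    expect_equal(got$bin, case$bin)
  }
})

test_that("rotamer bin edges follow the g+/t/g- convention", {
  expect_equal(rotamer_bin(c(120, 121, 180, -180.0 + 1e-9, -120, -119.9,
                             0, 1e-9)),
               c("g+", "t", "t", "t", "t", "g-", "g-", "g+"))
})

test_that("residues without a gamma atom are unresolved", {
  s <- make_bfactor_fixture(1, b_profile = 10)
  st <- add_protein_residue(s, "GLY", 60,
                            list(N = c(30, 0, -1), CA = c(30, 0, 0),
                                 C = c(31, 1, 0), O = c(31, 2.4, 0)))
  expect_equal(chi1(st, 60)$bin, "unresolved")
  expect_equal(chi1(st, 999)$bin, "unresolved")
})

test_that("rotamer transitions flag exactly the changed residues", {
  base <- make_bfactor_fixture(1, b_profile = 10)
  mk <- function(chis) {
    st <- base
    for (i in seq_along(chis)) {
      st <- add_protein_residue(st, "ARG", 100 + i,
                                chi_residue_atoms(chis[[i]],
                                                  c(30 + 10 * i, 0, 0)))
    }
    st
  }
  ref <- mk(c(-60, 180, 60))
  same <- mk(c(-60, 180, 60))
  one_flip <- mk(c(-60, 60, 60))   # residue 102 rotated by 120 degrees

  tr_same <- rotamer_transitions(list(pH5 = ref, pH7 = same), 101:103)
  expect_false(any(tr_same$changed[tr_same$label == "pH7"]))

  tr_flip <- rotamer_transitions(list(pH5 = ref, pH7 = one_flip),
                                 101:103)
  ch <- tr_flip[tr_flip$label == "pH7", ]
  expect_equal(ch$resno[ch$changed], 102L)
  expect_equal(sum(ch$changed), 1L)
})

test_that("missing density marks a residue changed-by-unresolved", {
  base <- make_bfactor_fixture(1, b_profile = 10)
  ref <- add_protein_residue(base, "LYS", 42,
                             list(N = c(30, 0, -1), CA = c(30, 0, 0),
                                  CB = c(30, 0, 1.53),
                                  CG = c(31.45, 0, 2.3)))
  partial <- add_protein_residue(base, "LYS", 42,
                                 list(N = c(30, 0, -1),
                                      CA = c(30, 0, 0),
                                      CB = c(30, 0, 1.53)))
  tr <- rotamer_transitions(list(pH5 = ref, pH7 = partial), c("K42"))
  row <- tr[tr$label == "pH7", ]
  expect_equal(row$bin, "unresolved")
  expect_true(row$changed)
  expect_warning(
    rotamer_transitions(list(pH5 = ref, pH7 = partial), c("K42", "K99")),
    "unresolved")
})
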