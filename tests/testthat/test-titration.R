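kB <- 1.9872e-3

test_that("the transition free energy follows the closed form", {
  expect_equal(transition_free_energy(7, 7), 0)
  expect_equal(transition_free_energy(8, 7), kB * 300 * log(10),
               tolerance = 1e-12)
  expect_equal(transition_free_energy(8, 7), 1.3727, tolerance = 1e-4)
  # a constant electrostatic offset moves the zero crossing by
  # -delta / (kB T ln 10)
  delta <- 0.8
  pH0 <- 7 - delta / (kB * 300 * log(10))
  expect_equal(transition_free_energy(pH0, 7, dG_elec = delta), 0,
               tolerance = 1e-12)
  expect_error(transition_free_energy(7, 7, temperature = -1),
               "positive")
})

test_that("doubling the temperature doubles the pH slope of the free energy", {
  slope <- function(temp) {
    transition_free_energy(8, 7, temperature = temp) -
      transition_free_energy(7, 7, temperature = temp)
  }
  expect_equal(slope(600), 2 * slope(300), tolerance = 1e-12)
})

test_that("Metropolis acceptance matches exp(-dG/kBT) and accepts dG <= 0", {
  # site at pH = pKa + 1, starting deprotonated: the protonation
  # proposal costs kB T ln 10, so acceptance must be 1/10
  sys <- titration_system(pKa_ref = 7, protonated = FALSE)
  n <- 2e4
  set.seed(101)
  acc <- 0L
  for (i in seq_len(n)) {
    sys$protonated[1] <- FALSE
    sys <- mc_step(sys, pH = 8)
    acc <- acc + sys$protonated[1]
  }
  p <- 0.1
  expect_lt(abs(acc / n - p), 3 * sqrt(p * (1 - p) / n))

  # dG = 0 (pH = pKa) is always accepted: the state alternates
  sys <- titration_system(pKa_ref = 7, protonated = FALSE)
  flips <- 0L
  for (i in seq_len(200)) {
    before <- sys$protonated[1]
    sys <- mc_step(sys, pH = 7)
    flips <- flips + (sys$protonated[1] != before)
  }
  expect_equal(flips, 200L)
})

test_that("a null-model site titrates along Henderson-Hasselbalch", {
  grid <- seq(5, 9, 0.5)
  run <- run_titration(titration_system(pKa_ref = 7), grid,
                       n_sweeps = 10000, seed = 7)
  hh <- 1 / (1 + 10^(grid - 7))
  n_kept <- run$n_sweeps - run$burn_in
  sigma <- sqrt(hh * (1 - hh) / n_kept)
  expect_true(all(abs(run$fractions[, 1] - hh) <= 3 * sigma))
  expect_equal(unname(run$fractions[grid == 7, 1]), 0.5,
               tolerance = 0.05)
})

test_that("pKa is recovered to 0.05 and an offset of kBTln10 shifts it by -1", {
  grid <- seq(5, 9, 0.5)
  run <- run_titration(titration_system(pKa_ref = 7), grid,
                       n_sweeps = 10000, seed = 7)
  est <- estimate_pka(grid, run$fractions[, 1])
  expect_equal(est$pKa, 7, tolerance = 0.05)
  expect_equal(est$hill, 1, tolerance = 0.1)

  grid2 <- seq(4, 8, 0.5)
  shifted <- run_titration(
    titration_system(pKa_ref = 7, elec_offset = kB * 300 * log(10)),
    grid2, n_sweeps = 10000, seed = 7)
  est2 <- estimate_pka(grid2, shifted$fractions[, 1])
  expect_equal(est2$pKa - est$pKa, -1, tolerance = 0.05)
})

test_that("independent sites each follow their own titration curve", {
  grid <- seq(4.5, 9.5, 0.5)
  sys <- titration_system(pKa_ref = c(6, 8))
  run <- run_titration(sys, grid, n_sweeps = 8000, seed = 13)
  for (k in 1:2) {
    est <- estimate_pka(grid, run$fractions[, k])
    expect_equal(est$pKa, c(6, 8)[k], tolerance = 0.08)
  }
})

test_that("a coupled two-site system samples the Boltzmann distribution", {
  J <- 1.0
  sys <- titration_system(pKa_ref = c(6.5, 7.5), coupling =
                            matrix(c(0, J, J, 0), 2, 2))
  pH <- 7
  e_site <- kB * 300 * log(10) * (pH - c(6.5, 7.5))
  states <- list(c(FALSE, FALSE), c(TRUE, FALSE), c(FALSE, TRUE),
                 c(TRUE, TRUE))
  energy <- vapply(states, function(s) {
    sum(e_site[s]) + if (all(s)) J else 0
  }, numeric(1))
  p_exp <- exp(-energy / (kB * 300))
  p_exp <- p_exp / sum(p_exp)

  set.seed(29)
  n <- 20000
  counts <- integer(4)
  for (i in seq_len(n)) {
    for (s in 1:2) sys <- mc_step(sys, pH)
    if (i > 1000) {
      idx <- 1L + sys$protonated[1] + 2L * sys$protonated[2]
      counts[idx] <- counts[idx] + 1L
    }
  }
  gof <- suppressWarnings(stats::chisq.test(counts, p = p_exp))
  expect_gt(gof$p.value, 0.01)
})

test_that("runs are bit-reproducible for a fixed seed", {
  sys <- titration_system(pKa_ref = c(6, 8))
  a <- run_titration(sys, c(6, 7, 8), n_sweeps = 2000, seed = 5)
  b <- run_titration(sys, c(6, 7, 8), n_sweeps = 2000, seed = 5)
  c <- run_titration(sys, c(6, 7, 8), n_sweeps = 2000, seed = 6)
  expect_identical(a$fractions, b$fractions)
  expect_false(identical(a$fractions, c$fractions))
})

test_that("degenerate inputs are rejected", {
  sys <- titration_system(pKa_ref = 7)
  expect_error(run_titration(sys, numeric(0)), "empty pH grid")
  expect_error(run_titration(sys, 7, n_sweeps = 10, burn_in = 10),
               "burn_in")
  expect_error(estimate_pka(c(5, 6, 7), c(0.9, 0.8, 0.7)),
               "never crosses")
})
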