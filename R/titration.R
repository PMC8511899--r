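# Boltzmann constant in kcal/(mol K)
.KB <- 1.9872e-3

#' Transition free energy for a protonation-state flip
#'
#' The pH-dependent free energy driving constant-pH Monte Carlo:
#' \deqn{\Delta G = k_B T (\mathrm{pH} - pK_{a,ref}) \ln 10
#'   + \Delta G_{elec} - \Delta G_{elec,ref}}
#' evaluated for the protonation move (deprotonated to protonated);
#' the deprotonation move is its negation. With this orientation a
#' single site with a null electrostatic term titrates along the
#' Henderson-Hasselbalch curve \eqn{f_{prot} = 1/(1+10^{pH - pK_a})},
#' and a constant electrostatic offset \eqn{\delta} shifts the apparent
#' pKa by \eqn{-\delta/(k_B T \ln 10)}.
#'
#' @param pH Solution pH of the calculation.
#' @param pKa_ref Reference-compound pKa of the titratable site.
#' @param dG_elec Electrostatic component of the transition free energy
#'   for the site in its environment, kcal/mol.
#' @param dG_elec_ref Electrostatic component for the reference
#'   compound, kcal/mol.
#' @param temperature Kelvin; must be positive.
#' @return Free energy in kcal/mol.
#' @examples
#' transition_free_energy(8, 7)            # ~ +1.3727 kcal/mol at 300 K
#' @export
transition_free_energy <- function(pH, pKa_ref, dG_elec = 0,
                                   dG_elec_ref = 0, temperature = 300) {
  if (temperature <= 0) stop("temperature must be positive")
  .KB * temperature * (pH - pKa_ref) * log(10) + dG_elec - dG_elec_ref
}

#' Create a titration system
#'
#' A set of titratable sites with reference pKa values and a pluggable
#' electrostatic term: per-site constant offsets
#' \eqn{\delta_i = \Delta G_{elec,i} - \Delta G_{elec,ref,i}} plus an
#' optional symmetric site-site coupling matrix `J` (kcal/mol) adding
#' \eqn{J_{ij}} when sites i and j are simultaneously protonated — a
#' Coulombic toy standing in for conformation-dependent electrostatics.
#'
#' @param pKa_ref Numeric vector of reference pKa values (one per
#'   site).
#' @param ids Site labels (default `site1...`).
#' @param elec_offset Per-site constant electrostatic offset,
#'   kcal/mol (recycled).
#' @param coupling Optional n x n symmetric matrix of pairwise
#'   protonated-protonated interaction energies, kcal/mol.
#' @param protonated Initial state vector (default all protonated).
#' @param temperature Kelvin.
#' @return A `titration_system` object.
#' @export
titration_system <- function(pKa_ref, ids = NULL, elec_offset = 0,
                             coupling = NULL, protonated = TRUE,
                             temperature = 300) {
  n <- length(pKa_ref)
  stopifnot(n >= 1L, all(is.finite(pKa_ref)), temperature > 0)
  if (is.null(ids)) ids <- paste0("site", seq_len(n))
  elec_offset <- rep_len(elec_offset, n)
  protonated <- rep_len(as.logical(protonated), n)
  if (!is.null(coupling)) {
    stopifnot(is.matrix(coupling), nrow(coupling) == n,
              ncol(coupling) == n, isTRUE(all.equal(coupling,
                                                    t(coupling))))
    diag(coupling) <- 0
  }
  structure(list(ids = ids, pKa_ref = pKa_ref,
                 elec_offset = elec_offset, coupling = coupling,
                 protonated = protonated, temperature = temperature),
            class = "titration_system")
}

# Free-energy change of flipping site i at the given pH
.flip_dG <- function(sys, i, pH) {
  delta <- sys$elec_offset[[i]]
  if (!is.null(sys$coupling)) {
    delta <- delta + sum(sys$coupling[i, sys$protonated])
  }
  dG_prot <- transition_free_energy(pH, sys$pKa_ref[[i]], delta, 0,
                                    sys$temperature)
  if (sys$protonated[[i]]) -dG_prot else dG_prot
}

#' One Metropolis Monte Carlo protonation move
#'
#' Picks a site uniformly at random, proposes flipping its protonation
#' state, and accepts with probability
#' \eqn{\min(1, e^{-\Delta G / k_B T})}; a zero or negative
#' \eqn{\Delta G} is always accepted. Uses R's RNG stream, so seeding
#' with [set.seed()] makes trajectories reproducible.
#'
#' @param sys A `titration_system`.
#' @param pH Calculation pH.
#' @return The (possibly updated) system.
#' @export
mc_step <- function(sys, pH) {
  i <- sample.int(length(sys$protonated), 1L)
  dG <- .flip_dG(sys, i, pH)
  if (dG <= 0 || stats::runif(1) < exp(-dG / (.KB * sys$temperature))) {
    sys$protonated[[i]] <- !sys$protonated[[i]]
  }
  sys
}

#' Constant-pH Monte Carlo titration over a pH grid
#'
#' For each pH in the grid, runs `n_sweeps` Monte Carlo sweeps (one
#' sweep = one attempted flip per site) from the system's initial
#' state, discards `burn_in` sweeps, and records each site's protonated
#' fraction over the retained sweeps. Fully deterministic for a fixed
#' seed.
#'
#' @param sys A `titration_system`.
#' @param pH_grid Numeric vector of pH values (non-empty).
#' @param n_sweeps MC sweeps per pH.
#' @param burn_in Sweeps discarded before sampling (default 10% of
#'   `n_sweeps`).
#' @param seed RNG seed.
#' @return A `titration_run`: list with `fractions` (matrix pH x site),
#'   `pH_grid`, `n_sweeps`, `burn_in`, `seed`, `temperature`.
#' @examples
#' sys <- titration_system(pKa_ref = 7)
#' run <- run_titration(sys, pH_grid = c(6, 7, 8), n_sweeps = 2000,
#'                      seed = 1)
#' run$fractions
#' @export
run_titration <- function(sys, pH_grid, n_sweeps = 10000,
                          burn_in = floor(n_sweeps / 10), seed = 1) {
  stopifnot(inherits(sys, "titration_system"))
  if (length(pH_grid) == 0L) stop("empty pH grid")
  if (!(n_sweeps > burn_in && burn_in >= 0)) {
    stop("need n_sweeps > burn_in >= 0")
  }
  n_sites <- length(sys$protonated)
  set.seed(seed)
  frac <- matrix(NA_real_, length(pH_grid), n_sites,
                 dimnames = list(as.character(pH_grid), sys$ids))
  init <- sys$protonated
  for (g in seq_along(pH_grid)) {
    pH <- pH_grid[[g]]
    sys$protonated <- init
    acc <- numeric(n_sites)
    kept <- 0L
    for (sweep in seq_len(n_sweeps)) {
      for (s in seq_len(n_sites)) sys <- mc_step(sys, pH)
      if (sweep > burn_in) {
        acc <- acc + sys$protonated
        kept <- kept + 1L
      }
    }
    frac[g, ] <- acc / kept
  }
  structure(list(fractions = frac, pH_grid = pH_grid,
                 n_sweeps = n_sweeps, burn_in = burn_in, seed = seed,
                 temperature = sys$temperature),
            class = "titration_run")
}

#' @export
print.titration_run <- function(x, ...) {
  cat("titration_run: ", length(x$pH_grid), " pH points, ",
      ncol(x$fractions), " site(s), ", x$n_sweeps, " sweeps (burn-in ",
      x$burn_in, "), seed ", x$seed, "\n", sep = "")
  print(round(x$fractions, 3))
  invisible(x)
}

#' Estimate pKa (and Hill coefficient) from a titration curve
#'
#' Fits the Hill form
#' \eqn{f(pH) = 1/(1 + 10^{n (pH - pK_a)})} to a protonated-fraction
#' curve by nonlinear least squares, started from the linear
#' interpolation of the half-protonation point. The curve must bracket
#' a fraction of 0.5.
#'
#' @param pH Numeric vector of pH values.
#' @param fraction Protonated fraction at each pH.
#' @return List with `pKa` and `hill`.
#' @examples
#' ph <- seq(5, 9, 0.5)
#' estimate_pka(ph, 1 / (1 + 10^(ph - 7)))$pKa
#' @export
estimate_pka <- function(pH, fraction) {
  stopifnot(length(pH) == length(fraction), length(pH) >= 3L)
  ord <- order(pH)
  pH <- pH[ord]; fraction <- fraction[ord]
  if (min(fraction) > 0.5 || max(fraction) < 0.5) {
    stop("curve never crosses fraction 0.5; cannot locate pKa")
  }
  start_pka <- stats::approx(fraction, pH, xout = 0.5, ties = mean)$y
  df <- data.frame(pH = pH, f = fraction)
  fit <- stats::nls(f ~ 1 / (1 + 10^(n * (pH - pKa))), data = df,
                    start = list(pKa = start_pka, n = 1),
                    control = stats::nls.control(warnOnly = TRUE))
  est <- stats::coef(fit)
  list(pKa = unname(est[["pKa"]]), hill = unname(est[["n"]]))
}
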