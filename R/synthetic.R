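# Synthetic-data generators.  One-dimensional harmonic ensembles are the
# oracle family: the configurational partition function of u_k(x) =
# Kspr_k (x - c_k)^2 / 2 is sqrt(2 pi / Kspr_k), so the dimensionless free
# energies are known in closed form, and overlap between states is tunable
# through spring constants and centers.  All generators are pure functions
# of their parameters plus an explicit seed.

#' Harmonic lambda-path dataset with analytic free energies
#'
#' Draws `n_per_state` samples from each of K one-dimensional harmonic
#' states (Gaussians with variance 1/spring) and cross-evaluates every
#' sample's reduced potential at all K states, producing the exact input an
#' MBAR/BAR estimator expects together with the analytic answer
#' f_k = 0.5 * ln(spring_k / spring_1).
#'
#' @param spring_constants per-state spring constants (kT per squared unit
#'   of the coordinate), all > 0; length defines K.
#' @param centers per-state potential centers (default all 0).
#' @param n_per_state samples per state (scalar or length K).
#' @param seed integer RNG seed (mandatory; no hidden global state is used).
#' @param time_spacing_ps nominal time between successive samples of one
#'   state, in ps; sample times start at 0.
#' @param temperature temperature recorded on the dataset (kelvin).
#' @return List with `rps` (a [reduced_potential_set()]) and `analytic_f`
#'   (length K, normalized to `analytic_f[1] == 0`, units of kT).
#' @examples
#' d <- make_harmonic_dataset(c(1, 4), n_per_state = 100, seed = 7)
#' d$analytic_f[2] # log(2)
#' @export
make_harmonic_dataset <- function(spring_constants, centers = NULL,
                                  n_per_state = 500L, seed,
                                  time_spacing_ps = 10,
                                  temperature = 300) {
  spring_constants <- as.numeric(spring_constants)
  K <- length(spring_constants)
  if (K < 2L || any(!is.finite(spring_constants)) ||
      any(spring_constants <= 0)) {
    fep_abort("`spring_constants` must be >= 2 positive numbers",
              "fepddg_input_error")
  }
  if (is.null(centers)) centers <- rep(0, K)
  centers <- as.numeric(centers)
  if (length(centers) != K) {
    fep_abort("`centers` must match the number of states", "fepddg_input_error")
  }
  if (missing(seed)) fep_abort("`seed` is required", "fepddg_input_error")
  n_per_state <- rep_len(as.integer(n_per_state), K)
  if (any(n_per_state < 1L)) {
    fep_abort("`n_per_state` must be >= 1", "fepddg_input_error")
  }
  set.seed(as.integer(seed))
  x <- unlist(lapply(seq_len(K), function(k) {
    stats::rnorm(n_per_state[k], mean = centers[k],
                 sd = 1 / sqrt(spring_constants[k]))
  }))
  origin <- rep(seq_len(K), n_per_state)
  times <- unlist(lapply(n_per_state, function(nk) {
    (seq_len(nk) - 1) * time_spacing_ps
  }))
  # u[n, l] = Kspr_l (x_n - c_l)^2 / 2
  u <- 0.5 * sweep(outer(x, centers, "-")^2, 2L, spring_constants, "*")
  rps <- reduced_potential_set(u, origin,
                               lambda_values = seq(0, 1, length.out = K),
                               times = times, replicate = 1L,
                               temperature = temperature)
  analytic_f <- 0.5 * log(spring_constants / spring_constants[1L])
  list(rps = rps, analytic_f = analytic_f)
}

#' Planted-truth two-leg thermodynamic cycle scenario
#'
#' Builds replicate harmonic-path datasets for the two legs of a cycle with
#' known leg free energies, so end-to-end DDG assembly can be validated
#' against ground truth.  Each leg is a geometric interpolation of spring
#' constants from 1 to exp(2 * dG_leg / kT), whose analytic end-to-end free
#' energy equals the planted value; replicates differ by derived sub-seeds,
#' and optional Gaussian jitter of the per-replicate planted value emulates
#' additional between-run spread.
#'
#' @param dG_leg1_kcal,dG_leg2_kcal planted leg free energies in kcal/mol
#'   (leg 1 = drug-free mutation or wild-type binding; leg 2 = drug-bound
#'   mutation or mutant binding).
#' @param cycle `"mutation"` or `"annihilation"` (labels only).
#' @param n_replicates independent replicates per leg (default 3).
#' @param n_states lambda states per leg (default 11).
#' @param n_per_state samples per state per replicate (default 400).
#' @param noise_sd_kcal SD of per-replicate jitter on the planted leg value
#'   (kcal/mol, default 0: spread comes from sampling alone).
#' @param seed integer RNG seed.
#' @param temperature kelvin.
#' @return List with `leg1`, `leg2` (lists of `n_replicates`
#'   [reduced_potential_set()]s), `truth` (list: `dG1_kcal`, `dG2_kcal`,
#'   `ddG_kcal`, `leg_labels`, per-replicate planted values) and
#'   `analytic_f` per leg and replicate.
#' @export
make_cycle_scenario <- function(dG_leg1_kcal, dG_leg2_kcal,
                                cycle = c("mutation", "annihilation"),
                                n_replicates = 3L, n_states = 11L,
                                n_per_state = 400L, noise_sd_kcal = 0,
                                seed, temperature = 300) {
  cycle <- match.arg(cycle)
  if (missing(seed)) fep_abort("`seed` is required", "fepddg_input_error")
  if (n_replicates < 1L) fep_abort("`n_replicates` must be >= 1",
                                   "fepddg_input_error")
  set.seed(as.integer(seed))
  sub_seeds <- matrix(sample.int(2147483646L, 2L * n_replicates),
                      nrow = 2L)
  jitter <- matrix(stats::rnorm(2L * n_replicates, 0, noise_sd_kcal),
                   nrow = 2L)
  planted <- c(dG_leg1_kcal, dG_leg2_kcal)
  build_leg <- function(leg) {
    lapply(seq_len(n_replicates), function(r) {
      dG_r <- planted[leg] + jitter[leg, r]
      df_kT <- kcal_to_kT(dG_r, temperature)
      k_end <- exp(2 * df_kT)
      if (!is.finite(k_end) || k_end <= 0) {
        fep_abort("planted leg free energy implies a non-positive spring constant",
                  "fepddg_input_error")
      }
      springs <- exp(seq(0, 2 * df_kT, length.out = n_states))
      make_harmonic_dataset(springs, n_per_state = n_per_state,
                            seed = sub_seeds[leg, r],
                            temperature = temperature)
    })
  }
  leg1 <- build_leg(1L)
  leg2 <- build_leg(2L)
  leg_labels <- if (cycle == "mutation") {
    c("mutation_free", "mutation_bound")
  } else {
    c("bind_wt", "bind_mut")
  }
  list(
    leg1 = lapply(leg1, `[[`, "rps"),
    leg2 = lapply(leg2, `[[`, "rps"),
    analytic_f = list(leg1 = lapply(leg1, `[[`, "analytic_f"),
                      leg2 = lapply(leg2, `[[`, "analytic_f")),
    truth = list(cycle = cycle, leg_labels = leg_labels,
                 dG1_kcal = dG_leg1_kcal, dG2_kcal = dG_leg2_kcal,
                 ddG_kcal = dG_leg2_kcal - dG_leg1_kcal,
                 planted_per_replicate = list(leg1 = planted[1L] + jitter[1L, ],
                                              leg2 = planted[2L] + jitter[2L, ])))
}

#' Synthetic center-of-mass distance trajectories
#'
#' Emulates the two qualitative regimes of an alchemical series: `"bound"`
#' trajectories fluctuate stationarily around the bound-pocket distance at
#' every lambda, while `"escape"` trajectories acquire a mean displacement
#' that grows with the lambda index beyond `escape_onset`, so late windows
#' exceed any threshold learned from the unperturbed runs (the end-point
#' problem of annihilation schemes).
#'
#' @param mode `"bound"` or `"escape"`.
#' @param n_lambda number of lambda windows (indices 0..n_lambda-1).
#' @param n_replicates replicates per window.
#' @param n_times frames per trajectory.
#' @param time_spacing_ps frame spacing in ps (times start at 0).
#' @param d0 bound-state mean COM distance in nm.
#' @param sigma frame-to-frame fluctuation SD in nm.
#' @param drift per-window mean displacement step beyond the onset (nm).
#' @param escape_onset first 0-based lambda index that escapes (default:
#'   the last 7 windows escape).
#' @param seed integer RNG seed.
#' @return List of [com_trajectory()] objects, ordered by lambda then
#'   replicate.
#' @export
make_com_trajectories <- function(mode = c("bound", "escape"),
                                  n_lambda = 27L, n_replicates = 3L,
                                  n_times = 300L, time_spacing_ps = 10,
                                  d0 = 0.5, sigma = 0.02, drift = 0.3,
                                  escape_onset = NULL, seed) {
  mode <- match.arg(mode)
  if (missing(seed)) fep_abort("`seed` is required", "fepddg_input_error")
  if (is.null(escape_onset)) escape_onset <- n_lambda - 7L
  set.seed(as.integer(seed))
  times <- (seq_len(n_times) - 1) * time_spacing_ps
  out <- vector("list", n_lambda * n_replicates)
  i <- 0L
  for (lam in 0:(n_lambda - 1L)) {
    mu <- d0
    if (mode == "escape" && lam >= escape_onset) {
      mu <- d0 + drift * (lam - escape_onset + 1L)
    }
    for (r in seq_len(n_replicates)) {
      i <- i + 1L
      d <- pmax(stats::rnorm(n_times, mu, sigma), 0)
      out[[i]] <- com_trajectory(lam, r, times, d)
    }
  }
  out
}
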