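#' Exponential-averaging (Zwanzig) free energy estimator
#'
#' One-sided free energy perturbation: Delta f = -ln < exp(-w) > over forward
#' reduced work samples w, evaluated with a log-sum-exp so large work values
#' do not overflow.  Mainly useful as a cheap initializer and an independent
#' cross-check for BAR/MBAR.
#'
#' @param work_values numeric vector of forward reduced work samples (kT).
#' @return Scalar Delta f in kT.
#' @examples
#' exp_estimator(c(0, 0, 0)) # 0
#' @export
exp_estimator <- function(work_values) {
  work_values <- as.numeric(work_values)
  if (length(work_values) < 1L) {
    fep_abort("`work_values` is empty", "fepddg_input_error")
  }
  if (anyNA(work_values) || any(!is.finite(work_values))) {
    fep_abort("`work_values` must be finite", "fepddg_input_error")
  }
  -(.logsumexp(-work_values) - log(length(work_values)))
}

#' Bennett acceptance ratio (BAR) estimator for a single state pair
#'
#' Solves the Bennett self-consistent equation for the free energy difference
#' between two states from forward work samples (drawn in state 0, evaluated
#' as u1 - u0) and reverse work samples (drawn in state 1, evaluated as
#' u0 - u1), and reports the standard asymptotic-variance uncertainty.
#' BAR is the two-state special case of MBAR; on identical samples the two
#' agree to solver tolerance.
#'
#' @param work_fwd forward reduced work samples (kT), drawn in state 0.
#' @param work_rev reverse reduced work samples (kT), drawn in state 1.
#' @param tolerance root-finding tolerance on Delta f (kT).
#' @param max_bracket maximum number of bracket doublings while searching for
#'   a sign change before giving up.
#' @return List with `delta_f` (kT), `stderr` (kT), `estimator = "BAR"` and
#'   `converged`.
#' @references Bennett, J. Comput. Phys. 22, 245-268 (1976).
#' @export
bar_estimate <- function(work_fwd, work_rev, tolerance = 1e-12,
                         max_bracket = 60L) {
  work_fwd <- as.numeric(work_fwd)
  work_rev <- as.numeric(work_rev)
  if (length(work_fwd) < 1L || length(work_rev) < 1L) {
    fep_abort("both work directions must be non-empty", "fepddg_input_error")
  }
  if (any(!is.finite(c(work_fwd, work_rev)))) {
    fep_abort("work samples must be finite", "fepddg_input_error")
  }
  nF <- length(work_fwd)
  nR <- length(work_rev)
  M <- log(nF) - log(nR)
  # Maximum-likelihood form: the root of fn() in Delta f.  fn is monotone
  # increasing, so a sign-changing bracket guarantees a unique root.
  fn <- function(df) {
    .logsumexp(-.log1pexp(M + work_fwd - df)) -
      .logsumexp(-.log1pexp(-M + work_rev + df))
  }
  guess <- 0.5 * (exp_estimator(work_fwd) - exp_estimator(work_rev))
  lo <- guess - 1
  hi <- guess + 1
  width <- 1
  it <- 0L
  while (fn(lo) > 0 && it < max_bracket) {
    width <- width * 2
    lo <- lo - width
    it <- it + 1L
  }
  while (fn(hi) < 0 && it < max_bracket) {
    width <- width * 2
    hi <- hi + width
    it <- it + 1L
  }
  if (fn(lo) > 0 || fn(hi) < 0) {
    fep_abort("BAR self-consistent equation has no root in expanded bracket",
              "fepddg_convergence_error")
  }
  df <- stats::uniroot(fn, c(lo, hi), tol = tolerance)$root
  # Bennett asymptotic variance from the Fermi-function overlap integrals
  fF <- stats::plogis(-(M + work_fwd - df))
  fR <- stats::plogis(-(-M + work_rev + df))
  var_df <- (mean(fF^2) / mean(fF)^2 - 1) / nF +
    (mean(fR^2) / mean(fR)^2 - 1) / nR
  list(delta_f = df, stderr = sqrt(max(var_df, 0)), estimator = "BAR",
       converged = TRUE)
}

#' Multistate Bennett acceptance ratio (MBAR) free energy estimation
#'
#' Solves the MBAR self-consistent equations for the dimensionless free
#' energies f_k of K lambda states given samples from (a subset of) those
#' states with reduced potentials cross-evaluated at all of them:
#' \deqn{f_k = -\ln \sum_n \frac{e^{-u_n(k)}}{\sum_l N_l e^{f_l - u_n(l)}}}
#' normalized so that f_1 = 0.  States with no samples of their own are
#' retained: their free energies are estimated by reweighting the pooled
#' samples.  Uncertainties come from the MBAR asymptotic covariance.
#'
#' The solver runs self-consistent iteration (seeded by chained forward
#' exponential averaging) and switches to Newton steps once the residual is
#' small; after the requested tolerance is met the solution is polished with
#' further Newton steps toward machine precision so downstream diagnostics
#' (overlap row sums) hold tightly.  Hitting `max_iter` is reported through
#' `converged = FALSE`, never as an error, so replicate aggregation can apply
#' an exclusion policy.
#'
#' @param rps a [reduced_potential_set()].
#' @param tolerance convergence threshold on max |Delta f_k| per iteration (kT).
#' @param max_iter maximum number of iterations.
#' @param initial_f optional length-K starting vector for f_k (kT).
#' @return An object of class `fep_estimate`: `f_k` (kT, `f_k[1] == 0`),
#'   `delta_f` = f_K - f_1 (kT), `delta_G_kcal`, `stderr` (K x K matrix of
#'   pairwise uncertainties, kT), `stderr_delta_f` (kT),
#'   `stderr_delta_G_kcal`, `estimator`, `converged`, `n_iterations`,
#'   `N_k`, `lambda_values`, `temperature`.
#' @references Shirts & Chodera, J. Chem. Phys. 129, 124105 (2008).
#' @examples
#' d <- make_harmonic_dataset(spring_constants = c(1, 4), n_per_state = 200,
#'                            seed = 1)
#' est <- mbar_solve(d$rps)
#' est$delta_f # close to log(2)
#' @export
mbar_solve <- function(rps, tolerance = 1e-8, max_iter = 10000L,
                       initial_f = NULL) {
  if (!inherits(rps, "fep_rps")) {
    fep_abort("`rps` must be a reduced_potential_set", "fepddg_input_error")
  }
  u <- rps$u
  K <- rps$K
  N_k <- rps$N_k
  sampled <- which(N_k > 0L)
  if (length(sampled) < 2L) {
    fep_abort("fewer than two states carry samples; free energies are under-determined",
              "fepddg_underdetermined_error")
  }
  us <- u[, sampled, drop = FALSE]
  Ns <- N_k[sampled]
  logNs <- log(Ns)
  Ks <- length(sampled)

  f <- if (!is.null(initial_f)) {
    if (length(initial_f) != K) {
      fep_abort("`initial_f` must have length K", "fepddg_input_error")
    }
    initial_f[sampled] - initial_f[sampled][1L]
  } else {
    .mbar_initial_f(us, rps$origin, sampled)
  }

  sc_update <- function(f) {
    ld <- .row_logsumexp(sweep(-us, 2L, logNs + f, "+"))
    fn <- -.col_logsumexp(-us - ld)
    fn - fn[1L]
  }
  newton_step <- function(f) {
    ld <- .row_logsumexp(sweep(-us, 2L, logNs + f, "+"))
    w <- exp(sweep(-us - ld, 2L, f, "+")) # w[n,k] = exp(f_k - u_nk - ld_n)
    g <- Ns * (colSums(w) - 1)
    H <- diag(Ns * colSums(w), Ks) - (Ns %o% Ns) * crossprod(w)
    step <- tryCatch(solve(H[-1L, -1L, drop = FALSE], -g[-1L]),
                     error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    fn <- f
    fn[-1L] <- f[-1L] + step
    fn
  }

  iter <- 0L
  converged <- FALSE
  resid <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    f_sc <- sc_update(f)
    resid <- max(abs(f_sc - f))
    if (resid < tolerance) {
      f <- f_sc
      converged <- TRUE
      break
    }
    f_next <- f_sc
    if (resid < 1e-2) {
      f_nt <- newton_step(f)
      if (!is.null(f_nt)) {
        chk <- sc_update(f_nt)
        if (max(abs(chk - f_nt)) < resid) f_next <- f_nt
      }
    }
    f <- f_next
  }
  if (converged) {
    # polish toward machine precision; keeps overlap row sums exact
    for (i in 1:5) {
      f_nt <- newton_step(f)
      if (is.null(f_nt)) break
      r_nt <- max(abs(sc_update(f_nt) - f_nt))
      if (!is.finite(r_nt) || r_nt >= resid) break
      f <- f_nt
      resid <- r_nt
      if (resid < 1e-14) break
    }
    f <- sc_update(f)
  }

  # evaluate all K states (including unsampled) against the final mixture
  ld <- .row_logsumexp(sweep(-us, 2L, logNs + f, "+"))
  f_full <- -.col_logsumexp(-u - ld)
  # per-sample state weights; colSums ~ 1 at self-consistency
  W <- exp(sweep(-u, 2L, f_full, "+") - ld)
  shift <- f_full[1L]
  f_full <- f_full - shift

  theta <- .mbar_theta(W, N_k)
  d2 <- outer(diag(theta), rep(1, K)) + outer(rep(1, K), diag(theta)) - 2 * theta
  se <- sqrt(pmax(d2, 0))

  delta_f <- f_full[K] - f_full[1L]
  kT <- kT_kcal_per_mol(rps$temperature)
  structure(
    list(f_k = f_full,
         delta_f = delta_f,
         delta_G_kcal = delta_f * kT,
         stderr = se,
         stderr_delta_f = se[1L, K],
         stderr_delta_G_kcal = se[1L, K] * kT,
         estimator = "MBAR",
         converged = converged,
         n_iterations = iter,
         N_k = N_k,
         lambda_values = rps$lambda_values,
         temperature = rps$temperature),
    class = "fep_estimate")
}

#' @export
print.fep_estimate <- function(x, ...) {
  cat(sprintf("%s estimate over %d states (%s after %d iterations)\n",
              x$estimator, length(x$f_k),
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  cat(sprintf("  end-to-end Delta f = %.4f +/- %.4f kT  (%.4f +/- %.4f kcal/mol)\n",
              x$delta_f, x$stderr_delta_f, x$delta_G_kcal, x$stderr_delta_G_kcal))
  invisible(x)
}

# chained forward exponential averages over the sampled states, as a starting
# point for the self-consistent iteration
.mbar_initial_f <- function(us, origin, sampled) {
  Ks <- length(sampled)
  f <- numeric(Ks)
  for (k in seq_len(Ks - 1L)) {
    rows <- origin == sampled[k]
    w <- us[rows, k + 1L] - us[rows, k]
    f[k + 1L] <- f[k] + exp_estimator(w)
  }
  f - f[1L]
}

# MBAR asymptotic covariance of the f_k from the weight matrix W (n x K),
# computed through the SVD of W so only K x K systems are ever inverted:
# Theta = V S (I - S V' diag(N) V S)^+ S V'
.mbar_theta <- function(W, N_k) {
  sv <- svd(W)
  D <- sv$d
  V <- sv$v
  K <- ncol(W)
  A <- t(V) %*% (N_k * V)
  M <- diag(K) - outer(D, D) * A
  Minv <- .pinv(M)
  V %*% (outer(D, D) * Minv) %*% t(V)
}

#' Statistical inefficiency of a time series
#'
#' Estimates g = 1 + 2 * sum_t (1 - t/n) * rho_t from the sample
#' autocorrelation function, truncating the sum at the first non-positive
#' autocorrelation.  g is the factor by which correlated samples are less
#' informative than independent ones; a constant series returns 1 by
#' convention.
#'
#' @param series numeric vector, length >= 2.
#' @param max_lag largest lag examined (defaults to min(n - 1, 1000)).
#' @return Scalar g >= 1.
#' @seealso [subsample()]
#' @export
statistical_inefficiency <- function(series, max_lag = NULL) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 2L) fep_abort("series must have length >= 2", "fepddg_input_error")
  if (any(!is.finite(series))) {
    fep_abort("series must be finite", "fepddg_input_error")
  }
  v <- stats::var(series)
  if (!is.finite(v) || v == 0) return(1)
  if (is.null(max_lag)) max_lag <- min(n - 1L, 1000L)
  rho <- stats::acf(series, lag.max = max_lag, plot = FALSE,
                    demean = TRUE)$acf[-1L]
  g <- 1
  for (t in seq_along(rho)) {
    if (rho[t] <= 0) break
    g <- g + 2 * (1 - t / n) * rho[t]
  }
  max(1, g)
}

#' Subsample a reduced potential set at a given statistical inefficiency
#'
#' Keeps every ceiling(g)-th sample within each origin state (starting from
#' the first), so retained samples are approximately independent.  `g = 1`
#' is the identity.
#'
#' @param rps a [reduced_potential_set()].
#' @param g statistical inefficiency (>= 1), e.g. from
#'   [statistical_inefficiency()].
#' @return A thinned `fep_rps`.
#' @export
subsample <- function(rps, g) {
  if (!inherits(rps, "fep_rps")) {
    fep_abort("`rps` must be a reduced_potential_set", "fepddg_input_error")
  }
  if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || g < 1) {
    fep_abort("`g` must be a single number >= 1", "fepddg_input_error")
  }
  stride <- as.integer(ceiling(g))
  if (stride == 1L) return(rps)
  keep <- logical(nrow(rps$u))
  for (k in seq_len(rps$K)) {
    idx <- which(rps$origin == k)
    if (length(idx)) keep[idx[seq(1L, length(idx), by = stride)]] <- TRUE
  }
  .rps_subset(rps, keep)
}
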