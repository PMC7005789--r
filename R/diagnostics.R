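#' MBAR overlap matrix and neighbor-overlap criterion
#'
#' Quantifies phase-space overlap between lambda states from the MBAR mixture
#' weights: `O[i, j] = N_j * sum_n W[n, i] * W[n, j]`, where `W[n, k]` is the
#' normalized weight of sample n in state k.  Each row of O sums to 1; entry
#' `O[i, j]` is the share of state i's distribution that is representable by
#' samples attributed to state j.  The scalar schedule diagnostic is the
#' minimum over adjacent pairs of the two off-diagonal entries; schedules
#' should keep it at or above 0.03, below which the statistical error of the
#' estimate grows sharply.
#'
#' @param rps the [reduced_potential_set()] the estimate was computed from.
#' @param estimate a converged [mbar_solve()] result on `rps`; a
#'   non-converged estimate is refused.
#' @param criterion minimum acceptable neighbor overlap (default 0.03).
#' @return An object of class `fep_overlap`: `O` (K x K), `min_neighbor_overlap`,
#'   `passes_criterion`, `criterion`.
#' @export
overlap_matrix <- function(rps, estimate, criterion = 0.03) {
  if (!inherits(rps, "fep_rps")) {
    fep_abort("`rps` must be a reduced_potential_set", "fepddg_input_error")
  }
  if (!inherits(estimate, "fep_estimate")) {
    fep_abort("`estimate` must come from mbar_solve()", "fepddg_input_error")
  }
  if (!isTRUE(estimate$converged)) {
    fep_abort("overlap diagnostic refused: the free energy estimate did not converge",
              "fepddg_convergence_error")
  }
  K <- rps$K
  N_k <- rps$N_k
  f <- estimate$f_k
  sampled <- which(N_k > 0L)
  ld <- .row_logsumexp(
    sweep(-rps$u[, sampled, drop = FALSE], 2L, log(N_k[sampled]) + f[sampled], "+"))
  W <- exp(sweep(-rps$u, 2L, f, "+") - ld)
  O <- sweep(crossprod(W), 2L, N_k, "*")
  neighbor <- vapply(seq_len(K - 1L), function(i) {
    min(O[i, i + 1L], O[i + 1L, i])
  }, numeric(1))
  m <- min(neighbor)
  structure(
    list(O = O, min_neighbor_overlap = m,
         passes_criterion = m >= criterion, criterion = criterion),
    class = "fep_overlap")
}

#' @export
print.fep_overlap <- function(x, ...) {
  cat(sprintf("Overlap matrix (%d states): min neighbor overlap = %.4f (%s criterion %.2f)\n",
              nrow(x$O), x$min_neighbor_overlap,
              if (x$passes_criterion) "passes" else "FAILS", x$criterion))
  invisible(x)
}

#' Discard the equilibration window of a time series
#'
#' Removes all samples recorded before `t_discard_ns` (samples at exactly the
#' cut time are kept), per state and per replicate.  Applies to reduced
#' potential sets and to center-of-mass distance trajectories (singly or in
#' lists).  Typical discard windows are 2 ns for alchemical-mutation runs and
#' 1 ns for double-annihilation runs.
#'
#' @param x a `fep_rps`, a `fep_com`, or a list of `fep_com` objects, with
#'   times in ps.
#' @param t_discard_ns equilibration window to drop, in ns (>= 0).
#' @return Object of the same class with early samples removed.  Erroring if
#'   the truncation empties any productive state or trajectory.
#' @export
discard_equilibration <- function(x, t_discard_ns) {
  if (!is.numeric(t_discard_ns) || length(t_discard_ns) != 1L ||
      !is.finite(t_discard_ns) || t_discard_ns < 0) {
    fep_abort("`t_discard_ns` must be a single number >= 0", "fepddg_input_error")
  }
  UseMethod("discard_equilibration")
}

#' @export
discard_equilibration.fep_rps <- function(x, t_discard_ns) {
  if (t_discard_ns == 0) return(x)
  if (is.null(x$times)) {
    fep_abort("reduced potential set carries no sample times", "fepddg_input_error")
  }
  keep <- x$times >= t_discard_ns * 1000
  kept_N <- tabulate(x$origin[keep], x$K)
  emptied <- which(x$N_k > 0L & kept_N == 0L)
  if (length(emptied)) {
    fep_abort(sprintf(
      "discarding the first %g ns empties sampled state(s): %s",
      t_discard_ns, paste(emptied, collapse = ", ")),
      "fepddg_input_error")
  }
  .rps_subset(x, keep)
}

#' @export
discard_equilibration.fep_com <- function(x, t_discard_ns) {
  if (t_discard_ns == 0) return(x)
  keep <- x$times >= t_discard_ns * 1000
  if (!any(keep)) {
    fep_abort(sprintf(
      "discarding the first %g ns empties COM trajectory (lambda %d, replicate %d)",
      t_discard_ns, x$lambda_index, x$replicate_id),
      "fepddg_input_error")
  }
  com_trajectory(x$lambda_index, x$replicate_id, x$times[keep], x$distances[keep])
}

#' @export
discard_equilibration.list <- function(x, t_discard_ns) {
  lapply(x, discard_equilibration, t_discard_ns = t_discard_ns)
}

#' Free energy estimate as a function of accumulated simulation time
#'
#' Re-estimates the end-to-end free energy difference on growing time windows
#' to visualize convergence: for each window end t, MBAR is solved on the
#' post-discard samples with time <= t.  Windows in which any sampled state
#' retains fewer than two samples are flagged and skipped.  The final window
#' uses all post-discard data and therefore equals the full [mbar_solve()]
#' result.
#'
#' @param rps a [reduced_potential_set()] with per-sample times (ps).
#' @param window_ends_ns optional increasing vector of window end times (ns);
#'   defaults to `n_windows` evenly spaced end points between the discard
#'   time and the last sample.
#' @param n_windows number of default windows.
#' @param discard_ns equilibration window dropped before any estimation (ns).
#' @param tolerance,max_iter passed to [mbar_solve()].
#' @return An object of class `fep_convergence`: data frame `series` with
#'   columns `window_end_ns`, `delta_G_kcal`, `stderr_kcal`, `converged`,
#'   plus `skipped` (window end times with insufficient samples).
#' @export
convergence_series <- function(rps, window_ends_ns = NULL, n_windows = 10L,
                               discard_ns = 0, tolerance = 1e-8,
                               max_iter = 10000L) {
  if (!inherits(rps, "fep_rps")) {
    fep_abort("`rps` must be a reduced_potential_set", "fepddg_input_error")
  }
  if (is.null(rps$times)) {
    fep_abort("reduced potential set carries no sample times", "fepddg_input_error")
  }
  x <- discard_equilibration(rps, discard_ns)
  t_max_ns <- max(x$times) / 1000
  if (is.null(window_ends_ns)) {
    window_ends_ns <- seq(discard_ns, t_max_ns,
                          length.out = n_windows + 1L)[-1L]
  }
  window_ends_ns <- as.numeric(window_ends_ns)
  if (is.unsorted(window_ends_ns, strictly = TRUE)) {
    fep_abort("`window_ends_ns` must be strictly increasing", "fepddg_input_error")
  }
  if (max(window_ends_ns) > t_max_ns + 1e-9) {
    fep_abort("window grid extends beyond the available time span",
              "fepddg_input_error")
  }
  rows <- list()
  skipped <- numeric(0)
  for (t_end in window_ends_ns) {
    keep <- x$times <= t_end * 1000 + 1e-9
    kept_N <- tabulate(x$origin[keep], x$K)
    if (any(x$N_k > 0L & kept_N < 2L)) {
      skipped <- c(skipped, t_end)
      next
    }
    est <- mbar_solve(.rps_subset(x, keep), tolerance = tolerance,
                      max_iter = max_iter)
    rows[[length(rows) + 1L]] <- data.frame(
      window_end_ns = t_end,
      delta_G_kcal = est$delta_G_kcal,
      stderr_kcal = est$stderr_delta_G_kcal,
      converged = est$converged)
  }
  if (!length(rows)) {
    fep_abort("no window retained enough samples for estimation",
              "fepddg_input_error")
  }
  structure(list(series = do.call(rbind, rows), skipped = skipped,
                 discard_ns = discard_ns),
            class = "fep_convergence")
}

#' @export
print.fep_convergence <- function(x, ...) {
  cat(sprintf("Convergence series: %d windows (discard %g ns, %d skipped)\n",
              nrow(x$series), x$discard_ns, length(x$skipped)))
  print(x$series, row.names = FALSE)
  invisible(x)
}
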