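#' Reduced potential set: samples cross-evaluated at all lambda states
#'
#' The container every estimator consumes.  Each of the n samples was drawn
#' from one of K lambda states (its *origin*), and its reduced potential
#' u = U/(k_B T) has been evaluated at every one of the K states, giving an
#' n x K matrix.  Because MBAR weights are invariant under adding a per-sample
#' constant to a row of `u`, energies may be supplied either as absolute
#' reduced potentials or as differences relative to the origin state (the
#' GROMACS dhdl convention, where the self column is zero).
#'
#' @param u numeric matrix, n samples x K states, all finite (units of kT).
#' @param origin integer vector of length n; `origin[i]` is the 1-based index
#'   of the state sample i was drawn from.
#' @param lambda_values per-state lambda descriptor: a numeric vector of
#'   length K (single coupling parameter), or a K x 2 matrix of
#'   (lambda_coulomb, lambda_vdw) pairs for annihilation paths.  Defaults to
#'   an even grid on \[0, 1\].
#' @param times optional per-sample simulation time in ps.
#' @param replicate optional per-sample replicate id (or a single id).
#' @param temperature absolute temperature in kelvin used to reduce the
#'   energies (recorded for later conversion to kcal/mol).
#' @return An object of class `fep_rps` with fields `u`, `origin`, `K`,
#'   `N_k` (samples per state), `lambda_values`, `times`, `replicate`,
#'   `temperature`.
#' @seealso [mbar_solve()], [make_harmonic_dataset()], [read_ukln_table()]
#' @export
reduced_potential_set <- function(u, origin, lambda_values = NULL,
                                  times = NULL, replicate = NULL,
                                  temperature = 300) {
  u <- as.matrix(u)
  storage.mode(u) <- "double"
  if (anyNA(u) || any(!is.finite(u))) {
    fep_abort("reduced potentials `u` must be finite (no NA/NaN/Inf)",
              "fepddg_input_error")
  }
  K <- ncol(u)
  n <- nrow(u)
  if (K < 2L) fep_abort("need at least K = 2 lambda states", "fepddg_input_error")
  if (n < 1L) fep_abort("`u` has no sample rows", "fepddg_input_error")
  origin <- as.integer(origin)
  if (length(origin) != n || anyNA(origin) || any(origin < 1L | origin > K)) {
    fep_abort(sprintf(
      "`origin` must map each of the %d samples to a state index in 1..%d", n, K),
      "fepddg_input_error")
  }
  if (is.null(lambda_values)) {
    lambda_values <- seq(0, 1, length.out = K)
  } else if (is.matrix(lambda_values)) {
    if (nrow(lambda_values) != K) {
      fep_abort("`lambda_values` matrix must have one row per state",
                "fepddg_input_error")
    }
  } else if (length(lambda_values) != K) {
    fep_abort("`lambda_values` must have one entry per state", "fepddg_input_error")
  }
  if (!is.null(times)) {
    times <- as.numeric(times)
    if (length(times) != n) {
      fep_abort("`times` must have one entry per sample", "fepddg_input_error")
    }
  }
  if (!is.null(replicate)) {
    if (length(replicate) == 1L) replicate <- rep(as.integer(replicate), n)
    replicate <- as.integer(replicate)
    if (length(replicate) != n) {
      fep_abort("`replicate` must be scalar or one entry per sample",
                "fepddg_input_error")
    }
  }
  .check_temperature(temperature)
  structure(
    list(u = u, origin = origin, K = K, N_k = tabulate(origin, K),
         lambda_values = lambda_values, times = times, replicate = replicate,
         temperature = temperature),
    class = "fep_rps")
}

#' @export
print.fep_rps <- function(x, ...) {
  cat(sprintf("Reduced potential set: %d samples across %d lambda states\n",
              nrow(x$u), x$K))
  cat("  samples per state:", paste(x$N_k, collapse = " "), "\n")
  cat(sprintf("  temperature: %g K (kT = %.5f kcal/mol)\n",
              x$temperature, kT_kcal_per_mol(x$temperature)))
  if (!is.null(x$times)) {
    cat(sprintf("  time span: %g..%g ps\n", min(x$times), max(x$times)))
  }
  invisible(x)
}

# rebuild an fep_rps keeping a logical/integer row subset
.rps_subset <- function(rps, keep) {
  reduced_potential_set(
    u = rps$u[keep, , drop = FALSE],
    origin = rps$origin[keep],
    lambda_values = rps$lambda_values,
    times = if (!is.null(rps$times)) rps$times[keep],
    replicate = if (!is.null(rps$replicate)) rps$replicate[keep],
    temperature = rps$temperature)
}
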