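#' Center-of-mass distance trajectory
#'
#' One lambda window's time series of the protein-drug center-of-mass (COM)
#' distance, used to diagnose whether the drug stayed in the binding pocket
#' during an alchemical simulation.
#'
#' @param lambda_index 0-based lambda window index (0 = unperturbed).
#' @param replicate_id integer replicate id.
#' @param times simulation times in ps.
#' @param distances COM distances in nm (>= 0), same length as `times`.
#' @return An object of class `fep_com`.
#' @export
com_trajectory <- function(lambda_index, replicate_id, times, distances) {
  times <- as.numeric(times)
  distances <- as.numeric(distances)
  if (length(times) != length(distances) || !length(times)) {
    fep_abort("`times` and `distances` must be equal-length and non-empty",
              "fepddg_input_error")
  }
  if (any(!is.finite(distances)) || any(distances < 0)) {
    fep_abort("COM distances must be finite and >= 0", "fepddg_input_error")
  }
  structure(
    list(lambda_index = as.integer(lambda_index),
         replicate_id = as.integer(replicate_id),
         times = times, distances = distances),
    class = "fep_com")
}

#' @export
print.fep_com <- function(x, ...) {
  cat(sprintf("COM trajectory lambda %d replicate %d: %d frames, mean %.3f nm\n",
              x$lambda_index, x$replicate_id, length(x$times),
              mean(x$distances)))
  invisible(x)
}

.as_com_list <- function(x) {
  if (inherits(x, "fep_com")) return(list(x))
  if (is.list(x) && length(x) &&
      all(vapply(x, inherits, logical(1), "fep_com"))) {
    return(x)
  }
  fep_abort("expected a fep_com object or a list of them", "fepddg_input_error")
}

#' Bound-state COM distance threshold from unperturbed simulations
#'
#' Learns the classification threshold T = ave + 6 * std, where ave and std
#' are the mean and sample standard deviation of the COM distances pooled
#' across the unperturbed (lambda = 0) reference simulations.  Six standard
#' deviations make a false "unbound" call on a genuinely bound trajectory
#' essentially impossible.
#'
#' @param reference one `fep_com` or a list of them (the lambda = 0 runs).
#' @param discard_ns equilibration window dropped before pooling (ns).
#' @param per_replicate if TRUE, compute ave/std over per-trajectory mean
#'   distances instead of the pooled samples.
#' @return List with `threshold` (nm), `ave`, `std`, `n_reference`.
#' @export
com_threshold <- function(reference, discard_ns = 0, per_replicate = FALSE) {
  trajs <- .as_com_list(reference)
  trajs <- discard_equilibration(trajs, discard_ns)
  if (per_replicate) {
    pool <- vapply(trajs, function(tr) mean(tr$distances), numeric(1))
  } else {
    pool <- unlist(lapply(trajs, `[[`, "distances"))
  }
  if (!length(pool)) fep_abort("empty reference pool", "fepddg_input_error")
  ave <- mean(pool)
  std <- if (length(pool) > 1L) stats::sd(pool) else 0
  list(threshold = ave + 6 * std, ave = ave, std = std,
       n_reference = length(trajs))
}

#' Fraction of lambda trajectories that maintained the bound state
#'
#' Classifies each trajectory by its mean post-discard COM distance: bound
#' if and only if the mean is strictly below the threshold T.  P_bound is
#' 100 times the number of bound trajectories divided by the total number of
#' trajectories.  Values well below 100% at late lambda windows indicate the
#' end-point problem of annihilation schemes: the decoupled drug drifts out
#' of the pocket.
#'
#' @param trajectories one `fep_com` or a list of them.
#' @param threshold numeric threshold T in nm (> 0), or the list returned by
#'   [com_threshold()].
#' @param discard_ns equilibration window dropped before averaging (ns).
#' @return An object of class `fep_bound_report`: `threshold_T`,
#'   `reference_ave`, `reference_std` (NA when a bare numeric threshold was
#'   given), `per_trajectory` (data frame with lambda_index, replicate,
#'   mean_distance_nm, bound), `p_bound` (percent).
#' @export
p_bound <- function(trajectories, threshold, discard_ns = 0) {
  trajs <- .as_com_list(trajectories)
  ref_ave <- NA_real_
  ref_std <- NA_real_
  if (is.list(threshold)) {
    ref_ave <- threshold$ave
    ref_std <- threshold$std
    threshold <- threshold$threshold
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold <= 0) {
    fep_abort("`threshold` must be a single positive number (nm)",
              "fepddg_input_error")
  }
  trajs <- discard_equilibration(trajs, discard_ns)
  means <- vapply(trajs, function(tr) mean(tr$distances), numeric(1))
  bound <- means < threshold # strictly below: a mean exactly at T is unbound
  per <- data.frame(
    lambda_index = vapply(trajs, `[[`, integer(1), "lambda_index"),
    replicate = vapply(trajs, `[[`, integer(1), "replicate_id"),
    mean_distance_nm = means,
    bound = bound)
  structure(
    list(threshold_T = threshold, reference_ave = ref_ave,
         reference_std = ref_std, per_trajectory = per,
         p_bound = 100 * sum(bound) / length(bound)),
    class = "fep_bound_report")
}

#' @export
print.fep_bound_report <- function(x, ...) {
  cat(sprintf("P_bound = %.1f%% (%d of %d trajectories below T = %.3f nm)\n",
              x$p_bound, sum(x$per_trajectory$bound),
              nrow(x$per_trajectory), x$threshold_T))
  invisible(x)
}
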