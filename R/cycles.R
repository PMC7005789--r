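.leg_labels <- c("mutation_free", "mutation_bound", "bind_wt", "bind_mut")

#' Aggregate replicate free energy estimates into a cycle leg
#'
#' Pools independent production runs of one cycle leg into a mean and a
#' sample (n-1) standard deviation.  Replicates whose estimator did not
#' converge are excluded with the reason recorded, mirroring the practice of
#' dropping a non-converged run from an otherwise complete replicate set
#' rather than failing the whole leg.
#'
#' @param estimates list of [mbar_solve()] results, or a numeric vector of
#'   per-replicate leg free energies in kcal/mol (assumed converged).
#' @param label leg role: one of `"mutation_free"`, `"mutation_bound"`
#'   (alchemical-mutation cycle) or `"bind_wt"`, `"bind_mut"`
#'   (double-annihilation cycle).
#' @param policy `"exclude_nonconverged"` (default) drops flagged replicates;
#'   `"strict"` errors on any non-converged replicate.
#' @return An object of class `fep_leg`: `leg_label`, `replicate_dG`
#'   (kcal/mol, retained replicates), `mean_dG`, `sigma`,
#'   `n_replicates_used`, `excluded_replicates` (data frame of index +
#'   reason).
#' @export
aggregate_leg <- function(estimates, label,
                          policy = c("exclude_nonconverged", "strict")) {
  policy <- match.arg(policy)
  label <- match.arg(label, .leg_labels)
  if (is.numeric(estimates)) {
    values <- as.numeric(estimates)
    conv <- rep(TRUE, length(values))
  } else if (is.list(estimates) && length(estimates) &&
             all(vapply(estimates, inherits, logical(1), "fep_estimate"))) {
    values <- vapply(estimates, function(e) e$delta_G_kcal, numeric(1))
    conv <- vapply(estimates, function(e) isTRUE(e$converged), logical(1))
  } else {
    fep_abort("`estimates` must be fep_estimate objects or a numeric vector",
              "fepddg_input_error")
  }
  if (!length(values)) fep_abort("no replicate estimates supplied", "fepddg_input_error")
  if (policy == "strict" && any(!conv)) {
    fep_abort("non-converged replicate under strict policy",
              "fepddg_convergence_error")
  }
  excluded <- data.frame(index = which(!conv),
                         reason = rep("estimator did not converge", sum(!conv)),
                         stringsAsFactors = FALSE)
  kept <- values[conv]
  if (!length(kept)) {
    fep_abort("all replicates excluded as non-converged", "fepddg_convergence_error")
  }
  sigma <- if (length(kept) > 1L) stats::sd(kept) else {
    fep_warn("single replicate retained; sigma reported as 0")
    0
  }
  structure(
    list(leg_label = label, replicate_dG = kept, mean_dG = mean(kept),
         sigma = sigma, n_replicates_used = length(kept),
         excluded_replicates = excluded),
    class = "fep_leg")
}

#' @export
print.fep_leg <- function(x, ...) {
  cat(sprintf("Leg %s: mean dG = %.4f kcal/mol, sigma = %.4f (n = %d used, %d excluded)\n",
              x$leg_label, x$mean_dG, x$sigma, x$n_replicates_used,
              nrow(x$excluded_replicates)))
  invisible(x)
}

#' Assemble a relative binding free energy from an alchemical-mutation cycle
#'
#' DDG = dG_mutation(bound) - dG_mutation(free): the mutation is performed
#' once in the drug-free protein and once in the drug-bound complex, and the
#' difference isolates the mutation-induced change in binding free energy.
#' The uncertainty propagates both legs in quadrature:
#' sigma = sqrt(sigma_free^2 + sigma_bound^2).
#'
#' @param leg_free [aggregate_leg()] result labelled `"mutation_free"`.
#' @param leg_bound [aggregate_leg()] result labelled `"mutation_bound"`.
#' @param system,mutation free-text labels recorded in the result.
#' @return An object of class `fep_ddg`: `method = "MutationFEP"`, `system`,
#'   `mutation`, `ddG` (kcal/mol), `sigma`, `legs`.
#' @export
ddg_mutation <- function(leg_free, leg_bound, system = "", mutation = "") {
  .check_leg(leg_free, "mutation_free")
  .check_leg(leg_bound, "mutation_bound")
  structure(
    list(method = "MutationFEP", system = system, mutation = mutation,
         ddG = leg_bound$mean_dG - leg_free$mean_dG,
         sigma = sqrt(leg_free$sigma^2 + leg_bound$sigma^2),
         legs = list(leg1 = leg_free, leg2 = leg_bound)),
    class = "fep_ddg")
}

#' Assemble a relative binding free energy from a double-annihilation cycle
#'
#' DDG = dG_bind(mutant) - dG_bind(wild-type), each leg obtained by
#' annihilating the drug's interactions with its environment.  Following the
#' error convention of the double-annihilation protocol this package
#' mirrors, the reported sigma is the replicate standard deviation of the
#' *mutant* leg only; set `full_error_propagation = TRUE` for the symmetric
#' quadrature alternative.
#'
#' @param leg_wt [aggregate_leg()] result labelled `"bind_wt"`.
#' @param leg_mut [aggregate_leg()] result labelled `"bind_mut"`.
#' @param system,mutation free-text labels recorded in the result.
#' @param full_error_propagation if TRUE, sigma = sqrt(sigma_wt^2 + sigma_mut^2).
#' @return An object of class `fep_ddg` with `method = "MP-CAFEE"`.
#' @export
ddg_annihilation <- function(leg_wt, leg_mut, system = "", mutation = "",
                             full_error_propagation = FALSE) {
  .check_leg(leg_wt, "bind_wt")
  .check_leg(leg_mut, "bind_mut")
  sigma <- if (full_error_propagation) {
    sqrt(leg_wt$sigma^2 + leg_mut$sigma^2)
  } else {
    leg_mut$sigma
  }
  structure(
    list(method = "MP-CAFEE", system = system, mutation = mutation,
         ddG = leg_mut$mean_dG - leg_wt$mean_dG, sigma = sigma,
         legs = list(leg1 = leg_wt, leg2 = leg_mut)),
    class = "fep_ddg")
}

#' @export
print.fep_ddg <- function(x, ...) {
  lab <- paste(c(x$system, x$mutation)[nzchar(c(x$system, x$mutation))],
               collapse = " ")
  cat(sprintf("%s DDG%s = %.4f +/- %.4f kcal/mol\n", x$method,
              if (nzchar(lab)) paste0(" (", lab, ")") else "", x$ddG, x$sigma))
  invisible(x)
}

.check_leg <- function(leg, expected) {
  if (!inherits(leg, "fep_leg")) {
    fep_abort("legs must be built with aggregate_leg()", "fepddg_input_error")
  }
  if (!identical(leg$leg_label, expected)) {
    fep_abort(sprintf("expected a '%s' leg, got '%s'", expected, leg$leg_label),
              "fepddg_input_error")
  }
  invisible(leg)
}

#' Compose per-replicate binding free energies from annihilation sub-legs
#'
#' A double-annihilation binding free energy is the difference between
#' annihilating the drug in the complex and annihilating it in solvent.
#' This helper subtracts the two sub-legs per replicate (default) or
#' subtracts a shared mean solvent leg, returning a numeric vector suitable
#' for [aggregate_leg()].
#'
#' @param complex_estimates,solvent_estimates lists of [mbar_solve()] results
#'   or numeric vectors (kcal/mol).
#' @param shared_solvent if TRUE, subtract the mean over solvent replicates
#'   from every complex replicate instead of pairing them one-to-one.
#' @return Numeric vector of per-replicate dG_bind values (kcal/mol).
#' @export
combine_sublegs <- function(complex_estimates, solvent_estimates,
                            shared_solvent = FALSE) {
  as_vals <- function(x) {
    if (is.numeric(x)) return(as.numeric(x))
    vapply(x, function(e) {
      if (!inherits(e, "fep_estimate")) {
        fep_abort("sub-leg entries must be fep_estimate or numeric",
                  "fepddg_input_error")
      }
      e$delta_G_kcal
    }, numeric(1))
  }
  cv <- as_vals(complex_estimates)
  sv <- as_vals(solvent_estimates)
  if (shared_solvent) return(cv - mean(sv))
  if (length(cv) != length(sv)) {
    fep_abort("per-replicate pairing requires equally many complex and solvent sub-legs",
              "fepddg_input_error")
  }
  cv - sv
}
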