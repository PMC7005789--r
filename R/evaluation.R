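#' Experimental drug-sensitivity change as a binding free energy difference
#'
#' Converts wild-type/mutant pairs of experimental measurements into an
#' experimental DDG in kcal/mol.  Inhibition constants (Ki) and half-maximal
#' inhibitory concentrations (IC50) are converted through the standard
#' thermodynamic relation DDG = R T ln(mut / wt); for IC50 this assumes the
#' Cheng-Prusoff correction factor is shared across mutants, so the ratio of
#' IC50s equals the ratio of Ki's.  Direct binding free energies
#' (`measure_type = "dG"`) are simply differenced.  Positive DDG means the
#' mutation weakens binding (resistance).
#'
#' @param measure_type one of `"Ki"`, `"IC50"`, `"dG"` (vectorized).
#' @param wt_value,mut_value wild-type and mutant measurements; same units
#'   within a pair (concentration for Ki/IC50, kcal/mol for dG).  Must be
#'   positive for Ki/IC50.
#' @param temperature assay temperature in kelvin (vectorized, default 300).
#' @param units `"kcal"` (default, R T ln ratio) or `"log10"` (plain
#'   log10 of the ratio, dimensionless).
#' @return Numeric vector of experimental DDG values.
#' @examples
#' experimental_ddg("Ki", 1, 10) # 10-fold resistance ~ 1.37 kcal/mol
#' @export
experimental_ddg <- function(measure_type, wt_value, mut_value,
                             temperature = 300, units = c("kcal", "log10")) {
  units <- match.arg(units)
  n <- max(length(measure_type), length(wt_value), length(mut_value))
  measure_type <- rep_len(as.character(measure_type), n)
  wt_value <- rep_len(as.numeric(wt_value), n)
  mut_value <- rep_len(as.numeric(mut_value), n)
  temperature <- rep_len(as.numeric(temperature), n)
  if (!all(measure_type %in% c("Ki", "IC50", "dG"))) {
    fep_abort("`measure_type` must be 'Ki', 'IC50' or 'dG'", "fepddg_input_error")
  }
  ratio_like <- measure_type %in% c("Ki", "IC50")
  if (any(ratio_like & (wt_value <= 0 | mut_value <= 0))) {
    fep_abort("Ki/IC50 values must be positive", "fepddg_input_error")
  }
  if (any(temperature <= 0)) {
    fep_abort("assay temperature must be positive", "fepddg_input_error")
  }
  out <- numeric(n)
  if (units == "kcal") {
    out[ratio_like] <- .kB_kcal * temperature[ratio_like] *
      log(mut_value[ratio_like] / wt_value[ratio_like])
  } else {
    out[ratio_like] <- log10(mut_value[ratio_like] / wt_value[ratio_like])
  }
  out[!ratio_like] <- mut_value[!ratio_like] - wt_value[!ratio_like]
  out
}

#' Linear regression of calculated against experimental DDG
#'
#' Ordinary least squares of calculated DDG (response) on experimental DDG
#' (predictor), reporting the coefficient of determination R^2 (the squared
#' Pearson correlation, so it does not depend on which axis is regressed on
#' which for simple OLS), the fitted line and the residuals.
#'
#' @param ddg_exp experimental DDG values (kcal/mol), or a data frame with
#'   columns `ddg_exp` and `ddg_calc`.
#' @param ddg_calc calculated DDG values (kcal/mol); ignored when `ddg_exp`
#'   is a data frame.
#' @return An object of class `fep_regression`: `slope`, `intercept`,
#'   `r_squared`, `n_points`, `residuals`.
#' @export
fit_regression <- function(ddg_exp, ddg_calc = NULL) {
  if (is.data.frame(ddg_exp)) {
    if (!all(c("ddg_exp", "ddg_calc") %in% names(ddg_exp))) {
      fep_abort("data frame input needs columns 'ddg_exp' and 'ddg_calc'",
                "fepddg_schema_error")
    }
    ddg_calc <- ddg_exp$ddg_calc
    ddg_exp <- ddg_exp$ddg_exp
  }
  x <- as.numeric(ddg_exp)
  y <- as.numeric(ddg_calc)
  if (length(x) != length(y) || length(x) < 2L) {
    fep_abort("need >= 2 paired (experimental, calculated) points",
              "fepddg_input_error")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    fep_abort("regression inputs must be finite", "fepddg_input_error")
  }
  if (stats::var(x) == 0) {
    fep_abort("experimental values are all equal; regression is degenerate",
              "fepddg_input_error")
  }
  if (stats::var(y) == 0) {
    # flat response: the best fit line is horizontal and explains nothing
    return(structure(
      list(slope = 0, intercept = y[1L], r_squared = 0,
           n_points = length(x), residuals = rep(0, length(x))),
      class = "fep_regression"))
  }
  fit <- stats::lm(y ~ x)
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         # squared Pearson correlation == OLS R^2 for a simple regression,
         # and stays quiet on exactly collinear input
         r_squared = stats::cor(x, y)^2,
         n_points = length(x),
         residuals = unname(stats::residuals(fit))),
    class = "fep_regression")
}

#' @export
print.fep_regression <- function(x, ...) {
  cat(sprintf("calc = %.3f * exp + %.3f;  R^2 = %.3f  (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}
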