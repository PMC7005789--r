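# Plain tabular formats.  All are tab-separated text with a header row;
# state indices are 0-based on disk (engine convention) and 1-based in
# memory (R convention).

.read_tsv <- function(path, expected, what, expected_label = NULL) {
  if (!file.exists(path)) {
    fep_abort(sprintf("file not found: %s", path), "fepddg_io_error")
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(expected %in% names(df))) {
    if (is.null(expected_label)) {
      expected_label <- paste(expected, collapse = ", ")
    }
    fep_abort(sprintf("%s %s has unexpected columns; expected headers: %s",
                      what, path, expected_label),
              "fepddg_schema_error")
  }
  df
}

#' Read and write the u_kln sample table
#'
#' Bespoke tab-separated carrier for cross-evaluated reduced potentials: one
#' row per sample with headers `state` (0-based origin), `time` (ps),
#' `replicate`, then `u_at_0`, `u_at_1`, ... (dimensionless, kT).
#'
#' @param path file path.
#' @param lambda_values optional per-state lambda descriptors attached to the
#'   result (defaults to an even grid).
#' @param temperature kelvin, recorded on the result.
#' @return `read_ukln_table()` returns a [reduced_potential_set()];
#'   `write_ukln_table()` returns `path` invisibly.
#' @export
read_ukln_table <- function(path, lambda_values = NULL, temperature = 300) {
  df <- .read_tsv(path, c("state", "time", "replicate"), "u_kln table",
                  "state, time, replicate, u_at_0, u_at_1, ...")
  ucols <- grep("^u_at_\\d+$", names(df), value = TRUE)
  if (length(ucols) < 2L) {
    fep_abort(sprintf(
      "u_kln table %s needs >= 2 'u_at_<k>' columns; expected headers: state, time, replicate, u_at_0, u_at_1, ...",
      path), "fepddg_schema_error")
  }
  ord <- order(as.integer(sub("^u_at_", "", ucols)))
  ucols <- ucols[ord]
  K <- length(ucols)
  origin <- as.integer(df$state)
  if (any(origin < 0L | origin >= K)) {
    fep_abort(sprintf("origin state indices in %s must lie in [0, %d)", path, K),
              "fepddg_input_error")
  }
  reduced_potential_set(as.matrix(df[ucols]), origin + 1L,
                        lambda_values = lambda_values,
                        times = df$time, replicate = df$replicate,
                        temperature = temperature)
}

#' @rdname read_ukln_table
#' @param rps a [reduced_potential_set()] to serialize.
#' @export
write_ukln_table <- function(rps, path) {
  if (!inherits(rps, "fep_rps")) {
    fep_abort("`rps` must be a reduced_potential_set", "fepddg_input_error")
  }
  n <- nrow(rps$u)
  u <- rps$u
  colnames(u) <- paste0("u_at_", seq_len(rps$K) - 1L)
  df <- data.frame(
    state = rps$origin - 1L,
    time = if (is.null(rps$times)) rep(NA_real_, n) else rps$times,
    replicate = if (is.null(rps$replicate)) rep(1L, n) else rps$replicate)
  df <- cbind(df, as.data.frame(u))
  utils::write.table(format(df, digits = 12, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write center-of-mass distance tables
#'
#' Tab-separated with headers `lambda_index` (0-based), `replicate`,
#' `time_ps`, `com_distance_nm`; one [com_trajectory()] per
#' (lambda_index, replicate) pair.
#'
#' @param path file path.
#' @return `read_com_table()` returns a list of `fep_com` objects ordered by
#'   lambda then replicate; `write_com_table()` returns `path` invisibly.
#' @export
read_com_table <- function(path) {
  df <- .read_tsv(path, c("lambda_index", "replicate", "time_ps",
                          "com_distance_nm"), "COM table")
  key <- interaction(df$lambda_index, df$replicate, drop = TRUE)
  parts <- split(df, key)
  out <- lapply(parts, function(p) {
    p <- p[order(p$time_ps), ]
    com_trajectory(p$lambda_index[1L], p$replicate[1L], p$time_ps,
                   p$com_distance_nm)
  })
  ord <- order(vapply(out, `[[`, integer(1), "lambda_index"),
               vapply(out, `[[`, integer(1), "replicate_id"))
  unname(out[ord])
}

#' @rdname read_com_table
#' @param trajectories one `fep_com` or a list of them.
#' @export
write_com_table <- function(trajectories, path) {
  trajs <- .as_com_list(trajectories)
  df <- do.call(rbind, lapply(trajs, function(tr) {
    data.frame(lambda_index = tr$lambda_index, replicate = tr$replicate_id,
               time_ps = tr$times, com_distance_nm = tr$distances)
  }))
  utils::write.table(format(df, digits = 12, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an experimental sensitivity table
#'
#' Tab-separated with headers `system`, `mutation`, `measure_type` (one of
#' Ki, IC50, dG), `wt_value`, `mut_value`, `temperature_K`.  Values are
#' validated (positive for Ki/IC50) and the experimental DDG in kcal/mol is
#' appended as column `ddg_exp` via [experimental_ddg()].
#'
#' @param path file path.
#' @return A data frame with the input columns plus `ddg_exp`.
#' @export
read_experimental_table <- function(path) {
  df <- .read_tsv(path, c("system", "mutation", "measure_type", "wt_value",
                          "mut_value", "temperature_K"), "experimental table")
  df$ddg_exp <- experimental_ddg(df$measure_type, df$wt_value, df$mut_value,
                                 df$temperature_K)
  df
}

#' Write and read structured analysis reports
#'
#' Reports are JSON documents holding every estimate, uncertainty,
#' diagnostic flag and provenance field of an analysis; reading one back
#' restores the numeric content exactly (doubles are serialized at full
#' precision).
#'
#' @param results a named list (nested lists, vectors and data frames are
#'   supported).
#' @param path file path.
#' @return `write_report()` returns `path` invisibly; `read_report()`
#'   returns the deserialized list.
#' @export
write_report <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", null = "null",
                       force = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) {
    fep_abort(sprintf("file not found: %s", path), "fepddg_io_error")
  }
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
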