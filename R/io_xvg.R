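#' Read a GROMACS dhdl .xvg file
#'
#' Parses the xmgrace-flavoured text format the MD engine writes for
#' alchemical output: lines starting with `#` are comments, lines starting
#' with `@` are grace directives (of which `@ sN legend "..."` define the
#' data column labels), and the remaining lines are whitespace-separated
#' floats whose first column is time in ps.  Energies are left in the file's
#' units (kJ/mol); the temperature is recorded so [xvg_to_ukln()] can reduce
#' them to kT later.
#'
#' @param path file path.
#' @param temperature simulation temperature in kelvin.
#' @return An object of class `fep_xvg`: `times` (ps, strictly increasing),
#'   `column_labels` (one per data column after time), `values`
#'   (n_times x n_columns matrix), `temperature`.
#' @export
read_dhdl_xvg <- function(path, temperature = 300) {
  if (!file.exists(path)) {
    fep_abort(sprintf("file not found: %s", path), "fepddg_io_error")
  }
  .check_temperature(temperature)
  lines <- readLines(path, warn = FALSE)
  is_comment <- startsWith(lines, "#")
  is_directive <- startsWith(lines, "@")
  leg_pat <- "^@\\s*s(\\d+)\\s+legend\\s+\"(.*)\"\\s*$"
  leg_lines <- grep(leg_pat, lines, value = TRUE)
  labels <- character(0)
  if (length(leg_lines)) {
    idx <- as.integer(sub(leg_pat, "\\1", leg_lines))
    lab <- sub(leg_pat, "\\2", leg_lines)
    labels <- character(max(idx) + 1L)
    labels[idx + 1L] <- lab
  }
  data_lines <- which(!is_comment & !is_directive & nzchar(trimws(lines)))
  if (!length(data_lines)) {
    fep_abort(sprintf("%s contains no data rows", path), "fepddg_parse_error")
  }
  rows <- lapply(data_lines, function(i) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) {
      fep_abort(sprintf("malformed data row at line %d of %s", i, path),
                "fepddg_parse_error")
    }
    vals
  })
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L) {
    fep_abort(sprintf("inconsistent column count in %s", path),
              "fepddg_parse_error")
  }
  m <- do.call(rbind, rows)
  if (ncol(m) < 2L) {
    fep_abort(sprintf("%s has no data columns beyond time", path),
              "fepddg_parse_error")
  }
  times <- m[, 1L]
  if (is.unsorted(times, strictly = TRUE)) {
    fep_abort(sprintf("times in %s are not strictly increasing", path),
              "fepddg_parse_error")
  }
  values <- m[, -1L, drop = FALSE]
  if (length(labels) < ncol(values) || any(!nzchar(labels[seq_len(ncol(values))]))) {
    fep_warn(sprintf("missing legend lines in %s; using positional column names",
                     path))
    need <- which(seq_len(ncol(values)) > length(labels) |
                    !nzchar(labels[seq_len(ncol(values))]))
    labels <- c(labels, character(max(0, ncol(values) - length(labels))))
    labels[need] <- paste0("s", need - 1L)
  }
  structure(
    list(times = times, column_labels = labels[seq_len(ncol(values))],
         values = values, temperature = temperature),
    class = "fep_xvg")
}

#' Write an xvg series back to disk
#'
#' Emits legend directives and whitespace-separated data rows; numeric
#' values are written with enough digits that read-write-read round trips
#' are faithful well beyond six significant figures.
#'
#' @param series a `fep_xvg` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_xvg <- function(series, path) {
  if (!inherits(series, "fep_xvg")) {
    fep_abort("`series` must be a fep_xvg object", "fepddg_input_error")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# written by fepddg", con)
  for (j in seq_along(series$column_labels)) {
    writeLines(sprintf("@ s%d legend \"%s\"", j - 1L, series$column_labels[j]),
               con)
  }
  m <- cbind(series$times, series$values)
  writeLines(apply(m, 1L, function(r) paste(sprintf("%.10g", r), collapse = " ")),
             con)
  invisible(path)
}

# pull the cross-evaluation target lambda out of a dhdl legend string, e.g.
# '\xD\f{}H \xl\f{} to 0.5000' or 'DH lambda to (0.5000, 0.0000)'.
# Returns a numeric vector (length 1 or 2) or NULL for non-cross columns.
.xvg_cross_target <- function(label) {
  m <- regmatches(label, regexec("to\\s+\\(([^)]*)\\)\\s*$", label))[[1]]
  if (length(m) == 2L) {
    vals <- suppressWarnings(as.numeric(strsplit(m[2L], ",")[[1]]))
    if (!anyNA(vals)) return(vals)
  }
  m <- regmatches(label, regexec("to\\s+([-+0-9.eE]+)\\s*$", label))[[1]]
  if (length(m) == 2L) {
    v <- suppressWarnings(as.numeric(m[2L]))
    if (!is.na(v)) return(v)
  }
  NULL
}

#' Assemble a reduced potential set from per-state dhdl series
#'
#' Takes one [read_dhdl_xvg()] series per lambda state (in lambda order) and
#' builds the u matrix MBAR consumes.  Columns are identified by their
#' legend strings: cross-evaluation columns carry a "... to <lambda>"
#' target, and every state must provide the same K targets (its own target
#' may be absent, in which case the self column is zero -- the dhdl
#' convention of reporting energies relative to the sampling state, which
#' leaves MBAR weights unchanged).  Files exposing only dH/dlambda
#' derivative columns are rejected: MBAR requires cross-evaluated energies.
#'
#' @param series_per_state list of `fep_xvg` objects, one per state, ordered
#'   by lambda.
#' @param temperature kelvin; energies (kJ/mol) are divided by k_B T.
#' @param replicate replicate id recorded on the result.
#' @return A [reduced_potential_set()].
#' @export
xvg_to_ukln <- function(series_per_state, temperature = 300, replicate = 1L) {
  if (!is.list(series_per_state) || length(series_per_state) < 2L ||
      !all(vapply(series_per_state, inherits, logical(1), "fep_xvg"))) {
    fep_abort("`series_per_state` must be a list of >= 2 fep_xvg objects",
              "fepddg_input_error")
  }
  .check_temperature(temperature)
  K <- length(series_per_state)
  kT <- kT_kJ_per_mol(temperature)

  per_state <- lapply(seq_len(K), function(k) {
    s <- series_per_state[[k]]
    targets <- lapply(s$column_labels, .xvg_cross_target)
    cross <- which(!vapply(targets, is.null, logical(1)))
    if (!length(cross)) {
      if (any(grepl("dH/d", s$column_labels, fixed = TRUE))) {
        fep_abort(paste(
          "state", k, "provides only dH/dlambda derivative columns;",
          "MBAR needs energies cross-evaluated at the foreign lambda states",
          "(enable foreign-lambda output in the engine)"),
          "fepddg_input_error")
      }
      fep_abort(sprintf("state %d has no cross-evaluation columns", k),
                "fepddg_input_error")
    }
    keys <- vapply(targets[cross], function(v) paste(format(v, digits = 10),
                                                     collapse = ","),
                   character(1))
    list(series = s, cols = cross, keys = keys,
         targets = targets[cross])
  })

  all_keys <- sort(unique(unlist(lapply(per_state, `[[`, "keys"))))
  if (length(all_keys) != K) {
    fep_abort(sprintf(
      "states disagree on the lambda grid: %d distinct cross-evaluation targets for %d states",
      length(all_keys), K), "fepddg_input_error")
  }
  # lambda descriptors ordered as the states were supplied: key k belongs to
  # state k (series are required to be in lambda order)
  key_order <- all_keys
  lambda_list <- lapply(key_order, function(kk) {
    i <- which(vapply(per_state, function(ps) kk %in% ps$keys, logical(1)))[1L]
    per_state[[i]]$targets[[match(kk, per_state[[i]]$keys)]]
  })
  lambda_values <- if (all(lengths(lambda_list) == 1L)) {
    unlist(lambda_list)
  } else {
    do.call(rbind, lambda_list)
  }

  u_blocks <- vector("list", K)
  origin <- integer(0)
  times <- numeric(0)
  for (k in seq_len(K)) {
    ps <- per_state[[k]]
    missing_keys <- setdiff(key_order, ps$keys)
    if (length(missing_keys) > 1L ||
        (length(missing_keys) == 1L && missing_keys != key_order[k])) {
      fep_abort(sprintf(
        "state %d lacks cross-evaluations at foreign lambda(s): %s",
        k, paste(missing_keys, collapse = "; ")), "fepddg_input_error")
    }
    n <- length(ps$series$times)
    u <- matrix(0, n, K)
    for (j in seq_along(ps$keys)) {
      col <- match(ps$keys[j], key_order)
      u[, col] <- ps$series$values[, ps$cols[j]] / kT
    }
    u_blocks[[k]] <- u
    origin <- c(origin, rep(k, n))
    times <- c(times, ps$series$times)
  }
  reduced_potential_set(do.call(rbind, u_blocks), origin,
                        lambda_values = lambda_values, times = times,
                        replicate = replicate, temperature = temperature)
}
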