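# Internal helpers: classed error conditions and stable log-space reductions.

fep_abort <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "fepddg_error", "error")))
}

fep_warn <- function(msg, class = "fepddg_warning") {
  warning(warningCondition(msg, class = c(class, "fepddg_warning", "warning")))
}

# log(sum(exp(x))) without overflow
.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row/column-wise logsumexp for a matrix
.row_logsumexp <- function(M) {
  m <- apply(M, 1L, max)
  m + log(rowSums(exp(M - m)))
}

.col_logsumexp <- function(M) {
  m <- apply(M, 2L, max)
  m + log(colSums(exp(sweep(M, 2L, m))))
}

# log(1 + exp(x)) without overflow
.log1pexp <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

# Moore-Penrose pseudoinverse via SVD (small symmetric matrices only)
.pinv <- function(A, tol = NULL) {
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * max(s$d, 0)
  pos <- s$d > tol
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, pos, drop = FALSE] %*% ((1 / s$d[pos]) * t(s$u[, pos, drop = FALSE]))
}

# tiny FNV-1a hash of a character scalar, for report provenance
.fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(h %% 2147483648, b) + (h %/% 2147483648) * 2147483648
    # 32-bit modular multiply by the FNV prime, split to stay in exact doubles
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
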