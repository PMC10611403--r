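# Internal helpers shared across modules.

# consistent error constructor so callers can test condition classes
mmj_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "mmjive_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sign convention: flip each column of `v` so that its
# maximum-absolute entry is positive. Used for every loading/weight matrix
# so reports are reproducible across BLAS/LAPACK implementations.
fix_signs <- function(v, companion = NULL) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 1L)
  s <- apply(v, 2L, function(col) {
    i <- which.max(abs(col))
    if (col[i] < 0) -1 else 1
  })
  v <- sweep(v, 2L, s, `*`)
  if (is.null(companion)) return(v)
  list(v = v, companion = sweep(companion, 2L, s, `*`), signs = s)
}

# best rank-k approximation by truncated SVD; returns the approximation plus
# the factors. k = 0 gives a zero matrix.
rank_approx <- function(m, k) {
  if (k <= 0) {
    return(list(approx = matrix(0, nrow(m), ncol(m)), u = NULL, d = NULL,
                v = NULL))
  }
  s <- svd(m, nu = k, nv = k)
  d <- s$d[seq_len(k)]
  list(approx = s$u %*% (d * t(s$v)), u = s$u, d = d, v = s$v)
}

# orthonormalize columns (QR); keeps the leading ncol(m) columns
orthonormalize <- function(m) {
  q <- qr.Q(qr(m))
  q[, seq_len(ncol(m)), drop = FALSE]
}

# project columns of x off the column space of basis
project_off <- function(x, basis) {
  if (is.null(basis) || ncol(basis) == 0L) return(x)
  q <- qr.Q(qr(basis))
  x - q %*% (t(q) %*% x)
}

format_num <- function(x) {
  # fixed 12-significant-digit representation for deterministic writers
  ifelse(is.na(x), "", sprintf("%.12g", x))
}

# deterministic CSV writer: fixed column order, 12 significant digits
write_table_csv <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1L))
  for (j in which(num)) df[[j]] <- format_num(df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

matrix_to_df <- function(m, rowname_col = "feature") {
  df <- data.frame(rownames(m) %||% as.character(seq_len(nrow(m))),
                   as.data.frame(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- rowname_col
  df
}
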