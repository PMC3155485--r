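# Internal helpers shared across modules.

# Ordered off-diagonal dyads in sender-major order:
# (1,2),(1,3),...,(1,n),(2,1),(2,3),...,(n,n-1).
# Returns sender/receiver node indices and the column-major linear index of
# each dyad in an n x n matrix.
offdiag_dyads <- function(n) {
  s <- rep(seq_len(n), each = n)
  r <- rep(seq_len(n), times = n)
  keep <- s != r
  s <- s[keep]
  r <- r[keep]
  list(sender = s, receiver = r, lin = s + (r - 1L) * n)
}

offdiag_values <- function(m) {
  m[row(m) != col(m)]
}

# Population (divide-by-N) standard deviation; the convention under which a
# binary network's off-diagonal variance equals p(1 - p) exactly.
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

pop_var <- function(x) {
  mean((x - mean(x))^2)
}

zscore_pop <- function(x) {
  s <- pop_sd(x)
  if (s == 0) {
    stop("cannot standardize a constant vector")
  }
  (x - mean(x)) / s
}

check_square_named <- function(m, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(sprintf("%s must be a square matrix", what))
  }
  ids_r <- rownames(m)
  ids_c <- colnames(m)
  if (is.null(ids_r) || is.null(ids_c) || !identical(ids_r, ids_c)) {
    stop(sprintf("%s must carry identical row and column node ids", what))
  }
  invisible(m)
}

check_zero_diag <- function(m, what = "matrix") {
  if (any(diag(m) != 0)) {
    stop(sprintf("%s must have an all-zero diagonal", what))
  }
  invisible(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
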