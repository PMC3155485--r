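#' Vectorize a dyadic regression design
#'
#' Flattens the off-diagonal cells of the response matrix and each
#' covariate matrix into vectors over ordered dyads, in sender-major order
#' (1,2),(1,3),...,(2,1),(2,3),.... A dyad is included iff it is masked in
#' no covariate and non-missing in the response (listwise deletion over
#' the union of masks).
#'
#' @param y_matrix Square response matrix (valued or binary network).
#' @param covariates A [covariate_panel()] or list of
#'   [dyadic_covariate()]s sharing the response's node ids and order.
#' @return Object of class `"dyadic_design"`: node ids, sender/receiver
#'   indices, response vector `y`, predictor matrix `X` (one named column
#'   per covariate) and logical `included`.
#' @export
vectorize_dyads <- function(y_matrix, covariates) {
  check_square_named(y_matrix, "response matrix")
  ids <- rownames(y_matrix)
  n <- length(ids)
  for (cv in covariates) {
    if (!identical(rownames(cv$values), ids)) {
      stop(sprintf("covariate '%s' node ids do not match the response", cv$name))
    }
  }
  od <- offdiag_dyads(n)
  y <- as.numeric(y_matrix)[od$lin]
  X <- vapply(covariates, function(cv) as.numeric(cv$values)[od$lin],
              numeric(length(od$lin)))
  if (length(covariates) == 1) X <- matrix(X, ncol = 1)
  colnames(X) <- vapply(covariates, `[[`, character(1), "name")
  if (anyDuplicated(colnames(X))) stop("covariate names must be unique")
  masked <- Reduce(`|`, lapply(covariates, function(cv) as.vector(cv$mask)[od$lin]),
                   rep(FALSE, length(od$lin)))
  included <- !masked & !is.na(y)
  labels <- vapply(covariates, function(cv) cv$label %||% cv$name, character(1))
  structure(list(node_ids = ids, sender = od$sender, receiver = od$receiver,
                 lin = od$lin, y = y, X = X, included = included,
                 labels = labels),
            class = "dyadic_design")
}

#' Rebuild a matrix from a dyad vector
#'
#' Inverse of the flattening in [vectorize_dyads()]; the diagonal is zero
#' and excluded dyads become `NA` unless their value is supplied.
#'
#' @param v Vector over ordered dyads (length n(n-1)).
#' @param design The [vectorize_dyads()] design defining the order.
#' @return Square matrix with the design's node ids.
#' @export
devectorize_dyads <- function(v, design) {
  n <- length(design$node_ids)
  m <- matrix(0, n, n, dimnames = list(design$node_ids, design$node_ids))
  m[design$lin] <- v
  m
}

#' Ordinary least squares on a dyadic design
#'
#' Fits the response on the predictor columns with an intercept, over
#' included dyads only. With `standardized = TRUE` the response and each
#' predictor are z-scored (population standard deviation) first, so the
#' intercept is identically zero and coefficients are comparable in
#' magnitude across predictors. The adjusted R-squared uses
#' 1 - (1 - R^2)(N - 1)/(N - k - 1) with N included dyads and k
#' predictors.
#'
#' @param design A [vectorize_dyads()] design.
#' @param standardized Z-score response and predictors before fitting.
#' @return List with named `coefficients`, `intercept`, `r_squared`,
#'   `adj_r_squared`, `n_included`.
#' @export
ols_fit <- function(design, standardized = FALSE) {
  inc <- design$included
  y <- design$y[inc]
  X <- design$X[inc, , drop = FALSE]
  k <- ncol(X)
  N <- length(y)
  if (N < k + 2) {
    stop("need at least k + 2 included dyads to fit")
  }
  sds <- apply(X, 2, pop_sd)
  if (any(sds == 0)) {
    stop(sprintf("constant predictor column over included dyads: %s",
                 paste(colnames(X)[sds == 0], collapse = ", ")))
  }
  if (standardized) {
    y <- zscore_pop(y)
    X <- apply(X, 2, zscore_pop)
  }
  Xd <- cbind(`(Intercept)` = 1, X)
  qx <- qr(Xd)
  if (qx$rank < ncol(Xd)) {
    dropped <- colnames(Xd)[qx$pivot[(qx$rank + 1):ncol(Xd)]]
    stop(sprintf("collinear predictor column(s): %s",
                 paste(dropped, collapse = ", ")))
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(Xd %*% beta)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  adj <- 1 - (1 - r2) * (N - 1) / (N - k - 1)
  list(coefficients = beta[-1], intercept = unname(beta[1]),
       r_squared = r2, adj_r_squared = adj, n_included = N)
}

#' Permute node labels of a square matrix
#'
#' The QAP primitive: rows and columns are permuted jointly,
#' `m'[i, j] = m[perm[i], perm[j]]`, which relabels nodes while preserving
#' the network's structure (all label-invariant statistics are unchanged).
#'
#' @param m Square matrix.
#' @param perm Integer permutation of `1:nrow(m)`.
#' @return Permuted matrix carrying the original dimnames.
#' @export
permute_nodes <- function(m, perm) {
  n <- nrow(m)
  if (length(perm) != n || !setequal(perm, seq_len(n))) {
    stop("perm must be a bijection on 1..n")
  }
  out <- m[perm, perm, drop = FALSE]
  dimnames(out) <- dimnames(m)
  out
}

#' MR-QAP: dyadic regression with permutation inference
#'
#' Regresses the dyadic response on the covariate panel and assesses each
#' coefficient against its null distribution under random node-label
#' permutations. Two schemes:
#' \describe{
#'   \item{dsp (default)}{Dekker double semi-partialing: for each
#'     predictor, its matrix is residualized on the remaining predictors
#'     (plus intercept), the residual matrix is node-permuted, the model is
#'     refit with the permuted residual in that predictor's place, and that
#'     coefficient is collected. Robust to collinearity among dyadic
#'     covariates.}
#'   \item{y_permute}{the response matrix alone is node-permuted and the
#'     full model refit, collecting all coefficients per replicate.}
#' }
#' Raw coefficients are compared between observed and permuted fits (by
#' Frisch-Waugh the observed raw coefficient of a predictor equals the
#' coefficient of its residual on the other predictors, so the comparison
#' is on a common scale); standardized coefficients are what the result
#' table reports as "Estimate". P-values use the add-one convention
#' (#{exceedances} + 1)/(n_perm + 1), so they are never zero. Masked dyads
#' stay excluded in every permuted fit.
#'
#' @param y_matrix Square response matrix (valued or dichotomized network).
#' @param covariates A [covariate_panel()].
#' @param n_perm Number of permutation replicates (>= 99; default 2000).
#' @param method `"dsp"` or `"y_permute"`.
#' @param seed Required integer seed governing the permutation stream.
#' @param chunk_size Permutations processed per block (memory/speed
#'   trade-off; results are identical for any value).
#' @return Object of class `"mrqap_result"`: per-predictor raw and
#'   standardized coefficients with `p_two_sided`, `p_ge`, `p_le`; model
#'   R-squared, adjusted R-squared, intercepts, dyad counts, method, seed,
#'   and the raw permutation distribution (`perm_dist`, n_perm x k).
#' @export
qap_test <- function(y_matrix, covariates, n_perm = 2000,
                     method = c("dsp", "y_permute"), seed,
                     chunk_size = 250) {
  method <- match.arg(method)
  if (missing(seed) || is.null(seed)) stop("seed is required")
  if (n_perm < 99) stop("n_perm must be >= 99")
  design <- vectorize_dyads(y_matrix, covariates)
  obs_raw <- ols_fit(design, standardized = FALSE)
  obs_std <- ols_fit(design, standardized = TRUE)

  n <- length(design$node_ids)
  inc <- design$included
  Ninc <- sum(inc)
  Xi <- design$X[inc, , drop = FALSE]
  yi <- design$y[inc]
  k <- ncol(Xi)
  si <- design$sender[inc]
  ri <- design$receiver[inc]

  set.seed(as.integer(seed))
  perms <- lapply(seq_len(n_perm), function(i) sample.int(n))
  perm_dist <- matrix(NA_real_, n_perm, k,
                      dimnames = list(NULL, colnames(Xi)))
  chunks <- split(seq_len(n_perm),
                  ceiling(seq_len(n_perm) / chunk_size))

  # linear index of the permuted matrix cell feeding each included dyad
  perm_index <- function(p) p[si] + (p[ri] - 1L) * n

  if (method == "y_permute") {
    qx <- qr(cbind(1, Xi))
    yfull <- as.numeric(y_matrix)
    for (ch in chunks) {
      idx <- vapply(perms[ch], perm_index, integer(Ninc))
      Yp <- matrix(yfull[idx], nrow = Ninc)
      if (anyNA(Yp)) stop("response matrix contains NA cells")
      B <- qr.coef(qx, Yp)
      perm_dist[ch, ] <- t(B[-1, , drop = FALSE])
    }
  } else {
    # per-predictor precomputation: orthonormal basis of the other
    # predictors' column space, the predictor's residual matrix, and the
    # response residual
    pre <- lapply(seq_len(k), function(kk) {
      Z <- cbind(1, Xi[, -kk, drop = FALSE])
      qz <- qr(Z)
      Qz <- qr.qy(qz, diag(1, Ninc, ncol(Z)))
      xk <- Xi[, kk]
      rk <- xk - drop(Qz %*% crossprod(Qz, xk))
      ry <- yi - drop(Qz %*% crossprod(Qz, yi))
      rk_full <- matrix(NA_real_, n, n)
      rk_full[cbind(si, ri)] <- rk
      diag(rk_full) <- 0
      list(Z = Z, Qz = Qz, rfull = as.numeric(rk_full), ry = ry)
    })
    for (ch in chunks) {
      idx <- vapply(perms[ch], perm_index, integer(Ninc))
      for (kk in seq_len(k)) {
        p_k <- pre[[kk]]
        P <- matrix(p_k$rfull[idx], nrow = Ninc)
        if (anyNA(P)) {
          # masked cells permuted onto included dyads: complete-case refits
          for (jj in seq_along(ch)) {
            p_col <- P[, jj]
            ok <- !is.na(p_col)
            fit <- stats::lm.fit(cbind(p_k$Z[ok, , drop = FALSE], p_col[ok]),
                                 yi[ok])
            perm_dist[ch[jj], kk] <- fit$coefficients[ncol(p_k$Z) + 1]
          }
        } else {
          MP <- P - p_k$Qz %*% crossprod(p_k$Qz, P)
          num <- colSums(P * p_k$ry)
          den <- colSums(P * MP)
          b <- num / den
          b[den <= .Machine$double.eps * Ninc] <- 0
          perm_dist[ch, kk] <- b
        }
      }
    }
  }

  b_obs <- obs_raw$coefficients
  exceed_ge <- colSums(sweep(perm_dist, 2, b_obs, `>=`), na.rm = TRUE)
  exceed_le <- colSums(sweep(perm_dist, 2, b_obs, `<=`), na.rm = TRUE)
  exceed_abs <- colSums(sweep(abs(perm_dist), 2, abs(b_obs), `>=`),
                        na.rm = TRUE)
  coefficients <- data.frame(
    term = colnames(Xi),
    label = unname(design$labels),
    raw_coef = unname(b_obs),
    std_coef = unname(obs_std$coefficients),
    p_two_sided = unname((exceed_abs + 1) / (n_perm + 1)),
    p_ge = unname((exceed_ge + 1) / (n_perm + 1)),
    p_le = unname((exceed_le + 1) / (n_perm + 1)),
    stringsAsFactors = FALSE
  )
  structure(list(
    coefficients = coefficients,
    intercept_raw = obs_raw$intercept,
    intercept_std = obs_std$intercept,
    r_squared = obs_raw$r_squared,
    adj_r_squared = obs_raw$adj_r_squared,
    n_nodes = n,
    n_included_dyads = Ninc,
    n_excluded_dyads = n * (n - 1) - Ninc,
    n_permutations = n_perm,
    method = method,
    seed = as.integer(seed),
    perm_dist = perm_dist
  ), class = "mrqap_result")
}

significance_stars <- function(p) {
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ""))
}

#' Format an MR-QAP result as a publication-shaped table
#'
#' Rows in panel order with the standardized coefficient ("Estimate", 4
#' decimals), significance stars (`**` p < 0.05, `***` p < 0.01) and the
#' two-sided permutation p-value (3 decimals).
#'
#' @param result A [qap_test()] result.
#' @return Data frame with columns `term`, `estimate`, `sig`,
#'   `significance`.
#' @export
result_table <- function(result) {
  cf <- result$coefficients
  # round-then-add-zero avoids printing "-0.0000" for a zero intercept
  data.frame(
    term = c("Intercept", cf$label),
    estimate = sprintf("%.4f", round(c(result$intercept_std, cf$std_coef),
                                     10) + 0),
    sig = c("", significance_stars(cf$p_two_sided)),
    significance = c("", sprintf("%.3f", cf$p_two_sided)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.mrqap_result <- function(x, ...) {
  cat(sprintf("MR-QAP (%s, %d permutations, seed %d)\n",
              x$method, x$n_permutations, x$seed))
  print(result_table(x), row.names = FALSE)
  cat(sprintf("Observations (No of dyads)  %s\n",
              format(x$n_included_dyads, big.mark = ",")))
  cat(sprintf("Multiple R2 (Adj.)  %.3f (%.3f)\n",
              x$r_squared, x$adj_r_squared))
  invisible(x)
}

#' Write an MR-QAP result to machine-readable TSV / JSON
#'
#' The TSV carries full-precision raw and standardized coefficients and all
#' three permutation p-values, followed by footer rows for the model
#' statistics; the JSON carries the same content structurally. The two
#' formats round-trip each other exactly.
#'
#' @param result A [qap_test()] result.
#' @param path Output path.
#' @export
write_mrqap_tsv <- function(result, path) {
  cf <- result$coefficients
  num <- function(x) formatC(x, format = "g", digits = 17)
  rows <- data.frame(
    term = cf$term, label = cf$label,
    raw_coef = num(cf$raw_coef), std_coef = num(cf$std_coef),
    p_two_sided = num(cf$p_two_sided), p_ge = num(cf$p_ge),
    p_le = num(cf$p_le), stringsAsFactors = FALSE
  )
  footer <- data.frame(
    term = c("(intercept_raw)", "(intercept_std)", "(r_squared)",
             "(adj_r_squared)", "(n_included_dyads)", "(n_permutations)",
             "(method)", "(seed)"),
    label = "",
    raw_coef = c(num(result$intercept_raw), num(result$intercept_std),
                 num(result$r_squared), num(result$adj_r_squared),
                 as.character(result$n_included_dyads),
                 as.character(result$n_permutations),
                 result$method, as.character(result$seed)),
    std_coef = "", p_two_sided = "", p_ge = "", p_le = "",
    stringsAsFactors = FALSE
  )
  utils::write.table(rbind(rows, footer), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_mrqap_tsv
#' @export
write_mrqap_json <- function(result, path) {
  out <- unclass(result)
  out$perm_dist <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_mrqap_tsv
#' @return `read_mrqap_tsv()` / `read_mrqap_json()`: a list with the same
#'   coefficient table and model statistics (no permutation distribution).
#' @export
read_mrqap_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  is_footer <- grepl("^\\(", df$term)
  cf <- df[!is_footer, , drop = FALSE]
  ft <- df[is_footer, , drop = FALSE]
  getf <- function(key) ft$raw_coef[ft$term == sprintf("(%s)", key)]
  list(
    coefficients = data.frame(
      term = cf$term, label = cf$label,
      raw_coef = as.numeric(cf$raw_coef), std_coef = as.numeric(cf$std_coef),
      p_two_sided = as.numeric(cf$p_two_sided), p_ge = as.numeric(cf$p_ge),
      p_le = as.numeric(cf$p_le), stringsAsFactors = FALSE
    ),
    intercept_raw = as.numeric(getf("intercept_raw")),
    intercept_std = as.numeric(getf("intercept_std")),
    r_squared = as.numeric(getf("r_squared")),
    adj_r_squared = as.numeric(getf("adj_r_squared")),
    n_included_dyads = as.integer(getf("n_included_dyads")),
    n_permutations = as.integer(getf("n_permutations")),
    method = getf("method"),
    seed = as.integer(getf("seed"))
  )
}

#' @rdname write_mrqap_tsv
#' @export
read_mrqap_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$coefficients <- as.data.frame(x$coefficients, stringsAsFactors = FALSE)
  x
}

#' Dump the permutation distribution for diagnostics
#'
#' One column per predictor, one row per permutation replicate (raw
#' coefficient scale).
#'
#' @param result A [qap_test()] result.
#' @param path Output TSV path.
#' @export
write_perm_dist <- function(result, path) {
  utils::write.table(result$perm_dist, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
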