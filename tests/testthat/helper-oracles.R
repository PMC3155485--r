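# Independent brute-force oracles and small fixture builders.

# Pairwise absolute-difference matrix by explicit double loop.
oracle_abs_diff <- function(x) {
  n <- length(x)
  m <- matrix(0, n, n, dimnames = list(names(x), names(x)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) m[i, j] <- abs(x[i] - x[j])
    }
  }
  m
}

oracle_match <- function(x) {
  n <- length(x)
  m <- matrix(0, n, n, dimnames = list(names(x), names(x)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && !is.na(x[i]) && !is.na(x[j]) && x[i] == x[j]) m[i, j] <- 1
    }
  }
  m
}

oracle_coauthorship <- function(pubs) {
  ids <- names(pubs)
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && length(intersect(pubs[[i]], pubs[[j]])) > 0) m[i, j] <- 1
    }
  }
  m
}

# Network summary by explicit loops over ordered dyads.
oracle_summary <- function(m) {
  n <- nrow(m)
  vals <- c()
  n_arcs <- 0
  n_recip <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      vals <- c(vals, m[i, j])
      if (m[i, j] > 0) {
        n_arcs <- n_arcs + 1
        if (m[j, i] > 0) n_recip <- n_recip + 1
      }
    }
  }
  sym <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (m[i, j] == m[j, i]) sym <- sym + 1
    }
  }
  list(
    n_dyads = n * (n - 1),
    density_pct = 100 * mean(vals),
    sum = sum(vals),
    variance = mean((vals - mean(vals))^2),
    std_dev = sqrt(mean((vals - mean(vals))^2)),
    minimum = min(vals), maximum = max(vals),
    reciprocated_ties_pct = if (n_arcs == 0) 0 else 100 * n_recip / n_arcs,
    symmetric_pairs_pct = 100 * sym / (n * (n - 1) / 2)
  )
}

oracle_census <- function(m) {
  n <- nrow(m)
  mut <- asym <- nul <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      k <- (m[i, j] > 0) + (m[j, i] > 0)
      if (k == 2) mut <- mut + 1
      else if (k == 1) asym <- asym + 1
      else nul <- nul + 1
    }
  }
  list(mutual = mut, asymmetric = asym, null = nul)
}

# OLS by explicit normal equations.
oracle_ols <- function(X, y) {
  Xd <- cbind(1, X)
  solve(t(Xd) %*% Xd, t(Xd) %*% y)[, 1]
}

# Random valued matrix with zero diagonal.
random_valued <- function(n, p = 0.3, ids = sprintf("v%02d", seq_len(n))) {
  m <- matrix(sample(0:5, n * n, replace = TRUE,
                     prob = c(1 - p, rep(p / 5, 5))),
              n, n, dimnames = list(ids, ids))
  diag(m) <- 0L
  storage.mode(m) <- "integer"
  m
}

# Small complete roster without using the synthetic generator.
tiny_roster <- function(n = 6, seed = 99) {
  set.seed(seed)
  schema <- default_schema()
  roster(data.frame(
    id = sprintf("a%02d", seq_len(n)),
    age = sample(30:67, n, replace = TRUE),
    gender = sample(schema$gender, n, replace = TRUE),
    ebm_attitude = sample(schema$ebm_attitude, n, replace = TRUE),
    years_since_graduation = sample(7:55, n, replace = TRUE),
    specialization = sample(schema$specialization, n, replace = TRUE),
    tenure_nhs = sample(1:41, n, replace = TRUE),
    tenure_lha = sample(1:37, n, replace = TRUE),
    managerial_role = sample(schema$managerial_role, n, replace = TRUE),
    hospital = sample(schema$hospital, n, replace = TRUE),
    directorate = sample(schema$directorate, n, replace = TRUE),
    n_publications = sample(0:10, n, replace = TRUE),
    stringsAsFactors = FALSE
  ))
}

# Random dyadic covariates sharing ids with a response matrix.
random_panel <- function(ids, k = 3, seed = 1) {
  set.seed(seed)
  n <- length(ids)
  lapply(seq_len(k), function(j) {
    x <- stats::setNames(rnorm(n), ids)
    abs_diff_matrix(x, sprintf("x%d", j))
  })
}
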