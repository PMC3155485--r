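make_design <- function(n = 10, k = 3, seed = 3, p = 0.3) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  y <- random_valued(n, p = p, ids = ids)
  panel <- lapply(seq_len(k), function(j) {
    abs_diff_matrix(stats::setNames(rnorm(n), ids), sprintf("x%d", j))
  })
  names(panel) <- sprintf("x%d", seq_len(k))
  list(y = y, panel = panel, ids = ids)
}

test_that("dyads vectorize in sender-major order and devectorize invertibly", {
  d <- make_design(3, 1)
  des <- vectorize_dyads(d$y, d$panel)
  expect_equal(des$sender, c(1, 1, 2, 2, 3, 3))
  expect_equal(des$receiver, c(2, 3, 1, 3, 1, 2))
  expect_equal(des$y, c(d$y[1, 2], d$y[1, 3], d$y[2, 1], d$y[2, 3],
                        d$y[3, 1], d$y[3, 2]))
  back <- devectorize_dyads(des$y, des)
  expect_equal(back, matrix(as.numeric(d$y), 3, dimnames = dimnames(d$y)))
})

test_that("one masked dyad excludes exactly that ordered dyad pairwise", {
  d <- make_design(3, 2)
  cv <- d$panel[[1]]
  cv$mask["n01", "n02"] <- cv$mask["n02", "n01"] <- TRUE
  cv$values[cv$mask] <- NA
  des <- vectorize_dyads(d$y, list(cv, d$panel[[2]]))
  expect_equal(sum(des$included), 4)
})

test_that("OLS matches the normal-equations oracle to 1e-10", {
  set.seed(9)
  for (rep in 1:10) {
    d <- make_design(8, 2, seed = rep)
    des <- vectorize_dyads(d$y, d$panel)
    fit <- ols_fit(des)
    oracle <- oracle_ols(des$X[des$included, ], des$y[des$included])
    expect_equal(unname(c(fit$intercept, fit$coefficients)),
                 unname(oracle), tolerance = 1e-10)
  }
})

test_that("perfect fit: y equal to a predictor gives R2 = 1 and unit std coefficient", {
  set.seed(4)
  ids <- sprintf("n%02d", 1:8)
  x <- stats::setNames(runif(8), ids)
  cv <- abs_diff_matrix(x, "x1")
  cv2 <- abs_diff_matrix(stats::setNames(rnorm(8), ids), "x2")
  y <- cv$values
  des <- vectorize_dyads(y, list(cv, cv2))
  fit <- ols_fit(des, standardized = TRUE)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients["x1"]), 1, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["x2"]), 0, tolerance = 1e-10)
})

test_that("standardized fits have a zero intercept and scale-related coefficients", {
  for (seed in 1:5) {
    d <- make_design(12, 3, seed = seed)
    des <- vectorize_dyads(d$y, d$panel)
    raw <- ols_fit(des, standardized = FALSE)
    std <- ols_fit(des, standardized = TRUE)
    expect_lt(abs(std$intercept), 1e-10)
    inc <- des$included
    sdy <- sqrt(mean((des$y[inc] - mean(des$y[inc]))^2))
    sdx <- apply(des$X[inc, ], 2, function(v) sqrt(mean((v - mean(v))^2)))
    expect_equal(std$coefficients, raw$coefficients * sdx / sdy,
                 tolerance = 1e-10)
    expect_equal(std$r_squared, raw$r_squared, tolerance = 1e-12)
  }
})

test_that("adjusted R2 follows 1-(1-R2)(N-1)/(N-k-1)", {
  d <- make_design(9, 2)
  des <- vectorize_dyads(d$y, d$panel)
  fit <- ols_fit(des)
  N <- fit$n_included; k <- 2
  expect_equal(fit$adj_r_squared,
               1 - (1 - fit$r_squared) * (N - 1) / (N - k - 1))
})

test_that("degenerate designs are rejected with the offending column named", {
  d <- make_design(6, 2)
  const <- dyadic_covariate("flat", "match",
                            matrix(1, 6, 6, dimnames = list(d$ids, d$ids)) -
                              diag(6))
  des <- vectorize_dyads(d$y, list(d$panel[[1]], const))
  expect_error(ols_fit(des), "flat")
  dup <- d$panel[[1]]
  dup$name <- "x1_copy"
  des2 <- vectorize_dyads(d$y, list(d$panel[[1]], dup))
  expect_error(ols_fit(des2), "collinear")
})

test_that("single-predictor standardized coefficient equals the dyadic Pearson correlation", {
  for (seed in 1:5) {
    d <- make_design(10, 1, seed = seed + 30)
    des <- vectorize_dyads(d$y, d$panel)
    fit <- ols_fit(des, standardized = TRUE)
    r <- stats::cor(des$y[des$included], des$X[des$included, 1])
    expect_equal(unname(fit$coefficients), r, tolerance = 1e-10)
  }
})

test_that("node permutation is an identity/involution and preserves all summaries", {
  m <- random_valued(8, p = 0.4)
  expect_identical(permute_nodes(m, 1:8), m)
  p <- c(2, 1, 3:8)
  expect_identical(permute_nodes(permute_nodes(m, p), p), m)
  expect_error(permute_nodes(m, c(1, 1, 3:8)), "bijection")
  set.seed(12)
  for (rep in 1:10) {
    perm <- sample(8)
    s1 <- network_summary(m)
    s2 <- network_summary(permute_nodes(m, perm))
    expect_equal(unclass(s1), unclass(s2))
  }
})

test_that("QAP exchangeability: joint relabeling leaves the observed fit unchanged", {
  d <- make_design(12, 3, seed = 5, p = 0.4)
  res1 <- qap_test(d$y, d$panel, n_perm = 99, seed = 1)
  perm <- sample(12)
  yp <- permute_nodes(d$y, perm)
  panelp <- lapply(d$panel, function(cv) {
    cv$values <- permute_nodes(cv$values, perm)
    cv$mask <- permute_nodes(cv$mask, perm)
    cv
  })
  res2 <- qap_test(yp, panelp, n_perm = 99, seed = 1)
  expect_equal(res1$coefficients$raw_coef, res2$coefficients$raw_coef,
               tolerance = 1e-10)
  expect_equal(res1$r_squared, res2$r_squared, tolerance = 1e-12)
})

test_that("same seed and inputs give bit-identical results for both methods", {
  d <- make_design(10, 2, seed = 8, p = 0.4)
  for (method in c("dsp", "y_permute")) {
    r1 <- qap_test(d$y, d$panel, n_perm = 120, method = method, seed = 99)
    r2 <- qap_test(d$y, d$panel, n_perm = 120, method = method, seed = 99)
    expect_identical(r1, r2)
    r3 <- qap_test(d$y, d$panel, n_perm = 120, method = method, seed = 100)
    expect_false(identical(r1$perm_dist, r3$perm_dist))
  }
})

test_that("a response identical to the single predictor attains the minimum p-value", {
  set.seed(6)
  ids <- sprintf("n%02d", 1:10)
  x <- stats::setNames(runif(10), ids)
  cv <- abs_diff_matrix(x, "x1")
  y <- cv$values
  for (method in c("dsp", "y_permute")) {
    res <- qap_test(y, list(cv), n_perm = 199, method = method, seed = 21)
    expect_equal(res$coefficients$p_two_sided, 1 / 200)
    expect_equal(res$coefficients$p_ge, 1 / 200)
  }
})

test_that("p-values are calibrated under an exchangeable null (y_permute)", {
  set.seed(55)
  n_rep <- 60
  rej <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    ids <- sprintf("n%02d", 1:20)
    y <- random_valued(20, p = 0.15, ids = ids)
    cv <- abs_diff_matrix(stats::setNames(rnorm(20), ids), "x1")
    res <- qap_test(y, list(cv), n_perm = 199, method = "y_permute",
                    seed = 1000 + r)
    rej[r] <- res$coefficients$p_two_sided < 0.2
  }
  # 99% binomial band around 0.2 over 60 replicates
  lo <- qbinom(0.005, n_rep, 0.2)
  hi <- qbinom(0.995, n_rep, 0.2)
  expect_gte(sum(rej), lo)
  expect_lte(sum(rej), hi)
})

test_that("masked dyads stay excluded in every permuted fit", {
  d <- make_design(9, 2, seed = 14, p = 0.4)
  cv <- d$panel[[1]]
  cv$mask["n01", "n02"] <- cv$mask["n02", "n01"] <- TRUE
  cv$values[cv$mask] <- NA
  res <- qap_test(d$y, list(cv, d$panel[[2]]), n_perm = 99, seed = 5)
  expect_equal(res$n_included_dyads, 9 * 8 - 2)
  expect_equal(res$n_excluded_dyads, 2)
  expect_false(anyNA(res$coefficients$p_two_sided))
})

test_that("result table rounds estimates to 4 and p-values to 3 decimals", {
  d <- make_design(10, 2, seed = 3, p = 0.4)
  res <- qap_test(d$y, d$panel, n_perm = 255, seed = 2)
  tab <- result_table(res)
  expect_identical(tab$term[1], "Intercept")
  expect_identical(tab$estimate[1], "0.0000")
  expect_match(tab$estimate, "^-?[0-9]+\\.[0-9]{4}$")
  expect_match(tab$significance[-1], "^[0-9]\\.[0-9]{3}$")
  p <- res$coefficients$p_two_sided[1]
  expect_identical(tab$significance[2], sprintf("%.3f", p))
})

test_that("result TSV and JSON writers round-trip all values", {
  d <- make_design(10, 2, seed = 3, p = 0.4)
  res <- qap_test(d$y, d$panel, n_perm = 120, seed = 2)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_mrqap_tsv(res, tsv)
  write_mrqap_json(res, js)
  back_tsv <- read_mrqap_tsv(tsv)
  back_js <- read_mrqap_json(js)
  for (back in list(back_tsv, back_js)) {
    expect_equal(back$coefficients$raw_coef, res$coefficients$raw_coef)
    expect_equal(back$coefficients$p_two_sided, res$coefficients$p_two_sided)
    expect_equal(back$r_squared, res$r_squared)
    expect_equal(back$n_included_dyads, res$n_included_dyads)
  }
  expect_equal(back_tsv$coefficients$std_coef, back_js$coefficients$std_coef)
})
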