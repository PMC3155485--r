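test_that("absolute-difference covariate matches hand examples and the pairwise oracle", {
  x <- c(a = 47, b = 47)
  cv <- abs_diff_matrix(x, "age_diff")
  expect_equal(cv$values["a", "b"], 0)
  x2 <- c(a = 30, b = 67)
  expect_equal(abs_diff_matrix(x2, "age_diff")$values["a", "b"], 37)

  x3 <- c(u = 1, v = 2, w = 4)
  cv3 <- abs_diff_matrix(x3, "d")
  expected <- matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3, byrow = TRUE,
                     dimnames = list(names(x3), names(x3)))
  expect_equal(cv3$values, expected)

  set.seed(20)
  for (rep in 1:5) {
    x <- stats::setNames(rnorm(15), sprintf("n%02d", 1:15))
    expect_equal(abs_diff_matrix(x, "r")$values, oracle_abs_diff(x))
  }
  expect_error(abs_diff_matrix(letters[1:3], "bad"), "numeric")
})

test_that("same-category covariate matches rule and the pairwise oracle", {
  x <- c(a = "Neuroscience", b = "Neuroscience", c = "Oncology")
  cv <- same_category_matrix(x, "dir", levels = default_schema()$directorate)
  expect_equal(cv$values["a", "b"], 1)
  expect_equal(cv$values["a", "c"], 0)

  att <- c(p = "often/very often", q = "often/very often", r = "never")
  cv2 <- same_category_matrix(att, "ebm",
                              levels = default_schema()$ebm_attitude)
  expect_equal(sum(cv2$values), 2) # one matching pair, both directions

  set.seed(21)
  for (rep in 1:5) {
    x <- stats::setNames(sample(letters[1:4], 15, replace = TRUE),
                         sprintf("n%02d", 1:15))
    expect_equal(same_category_matrix(x, "r", levels = letters[1:4])$values,
                 oracle_match(x))
  }
  expect_error(same_category_matrix(c(a = "zzz"), "bad", levels = "yes"),
               "undeclared level")
})

test_that("match covariate equals zero-difference indicator on integer-coded categories", {
  set.seed(22)
  codes <- stats::setNames(sample(1:4, 12, replace = TRUE),
                           sprintf("n%02d", 1:12))
  m1 <- same_category_matrix(stats::setNames(as.character(codes),
                                             names(codes)), "m")$values
  d <- abs_diff_matrix(codes, "d")$values
  ind <- (d == 0) * 1
  diag(ind) <- 0
  off <- row(d) != col(d)
  expect_equal(m1[off], ind[off])
})

test_that("geographic-distance covariate is symmetric with zero same-site dyads", {
  tbl <- site_distance_table(data.frame(site_a = "A", site_b = "B", km = 12))
  sites <- c(x = "A", y = "B", z = "A")
  cv <- geo_distance_matrix(sites, tbl)
  expect_equal(cv$values["x", "y"], 12)
  expect_equal(cv$values["y", "x"], 12)
  expect_equal(cv$values["x", "z"], 0)

  tbl2 <- site_distance_table(data.frame(site_a = "A", site_b = "B", km = 5))
  sites3 <- c(p = "A", q = "A", r = "B")
  v <- geo_distance_matrix(sites3, tbl2)$values
  off <- row(v) != col(v)
  expect_equal(sum(v[off] == 5), 4)
  expect_equal(sum(v[off] == 0), 2)

  expect_error(geo_distance_matrix(c(a = "C"), tbl), "absent from")
})

test_that("co-authorship covariate marks shared-publication pairs only", {
  pubs <- list(a = c("P1", "P2"), b = "P2", c = character(0))
  cv <- coauthorship_matrix(pubs)
  expect_equal(cv$values, oracle_coauthorship(pubs))
  expect_equal(cv$values["a", "b"], 1)
  expect_equal(cv$values["b", "a"], 1)
  expect_equal(sum(cv$values), 2)
  none <- coauthorship_matrix(list(a = "P1", b = "P9"))
  expect_true(all(none$values == 0))
})

test_that("default covariate panel yields 13 predictors in table order with empty masks", {
  r <- tiny_roster(8)
  pubs <- stats::setNames(rep(list(character(0)), 8), roster_ids(r))
  pubs[[1]] <- "P1"; pubs[[2]] <- "P1"
  panel <- covariate_panel(r, pubs, default_site_distances())
  expect_length(panel, 13)
  expect_identical(names(panel), default_predictors()$name)
  expect_true(all(vapply(panel, function(cv) sum(cv$mask) == 0, logical(1))))

  empty <- covariate_panel(r, predictors = character(0))
  expect_length(empty, 0)
})

test_that("a missing attribute masks exactly 2(n-1) ordered dyads", {
  r <- tiny_roster(9)
  r$age[4] <- NA
  panel <- covariate_panel(r, predictors = "age_diff")
  cv <- panel$age_diff
  off <- row(cv$mask) != col(cv$mask)
  expect_equal(sum(cv$mask[off]), 2 * (9 - 1))
  expect_true(all(cv$mask[4, -4]))
  expect_true(all(cv$mask[-4, 4]))
})

test_that("all panel covariates are symmetric", {
  r <- tiny_roster(10, seed = 42)
  pubs <- stats::setNames(rep(list("P1"), 10), roster_ids(r))
  panel <- covariate_panel(r, pubs, default_site_distances())
  for (cv in panel) {
    expect_identical(cv$values, t(cv$values), label = cv$name)
  }
})

test_that("covariate panel serializes to TSVs + manifest and reads back identically", {
  r <- tiny_roster(7)
  r$tenure_lha[2] <- NA
  panel <- covariate_panel(r, predictors = c("age_diff", "tenure_lha_diff",
                                             "gender_same"))
  dir <- withr::local_tempdir()
  write_panel(panel, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_panel(dir)
  expect_identical(names(back), names(panel))
  for (nm in names(panel)) {
    expect_equal(back[[nm]]$values[!panel[[nm]]$mask],
                 panel[[nm]]$values[!panel[[nm]]$mask])
    expect_identical(back[[nm]]$mask, panel[[nm]]$mask)
    expect_identical(back[[nm]]$kind, panel[[nm]]$kind)
  }
})

test_that("site-distance table applies symmetric closure and zero self-distance", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site_a,site_b,km", "A,B,7", "B,C,3"), path)
  tbl <- read_site_distances(path)
  expect_equal(tbl["B", "A"], 7)
  expect_equal(unname(diag(unclass(tbl))), c(0, 0, 0))
  expect_true(is.na(tbl["A", "C"]))
})
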