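test_that("roster reads back file contents and enforces id/level invariants", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,age,gender", "a,30,M", "b,47,F", "c,67,M"), path)
  r <- read_roster(path)
  expect_identical(roster_ids(r), c("a", "b", "c"))
  expect_equal(r$age, c(30, 47, 67))

  writeLines(c("id,age", "a,30", "a,47"), path)
  expect_error(read_roster(path), "duplicate roster id: a")

  writeLines(c("id,specialization", "a,Oncology"), path)
  expect_error(read_roster(path), "unknown level 'Oncology'")
})

test_that("missing roster cells are recorded as missing, not zero", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,age,gender", "a,,M", "b,47,"), path)
  r <- read_roster(path)
  expect_true(is.na(r$age[1]))
  expect_true(is.na(r$gender[2]))
})

test_that("nominations are roster-restricted with an off-roster report", {
  r <- roster(data.frame(id = c("a", "b", "c")))
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ego,alter,strength", "a,b,4", "a,x,2"), path)
  out <- read_nominations(path, r)
  expect_equal(nrow(out$nominations), 1)
  expect_equal(out$nominations$alter, "b")
  expect_equal(out$off_roster, c(x = 1L))
  expect_equal(out$n_off_roster, 1L)

  writeLines(c("ego,alter,strength", "a,b,7"), path)
  expect_error(read_nominations(path, r), "out of range")
  writeLines(c("ego,alter,strength", "z,b,3"), path)
  expect_error(read_nominations(path, r), "ego not on roster")
  writeLines("ego,alter,strength", path)
  empty <- read_nominations(path, r)
  expect_equal(nrow(empty$nominations), 0)
  expect_equal(empty$n_off_roster, 0L)
})

test_that("valued network construction places strengths, resolves duplicates by max, drops self-ties", {
  r <- roster(data.frame(id = c("a", "b", "c")))
  net <- build_valued_network(r, data.frame(ego = "a", alter = "b",
                                            strength = 4L))
  expect_equal(net["a", "b"], 4L)
  expect_equal(sum(net), 4L)

  net2 <- build_valued_network(r, data.frame(ego = c("a", "a"),
                                             alter = c("b", "b"),
                                             strength = c(2L, 5L)))
  expect_equal(net2["a", "b"], 5L)

  expect_message(
    net3 <- build_valued_network(r, data.frame(ego = "a", alter = "a",
                                               strength = 3L)),
    "self-nomination")
  expect_true(all(net3 == 0))
  expect_equal(attr(net3, "n_self_dropped"), 1L)
})

test_that("network construction is permutation-equivariant in roster order", {
  set.seed(5)
  ids <- c("a", "b", "c", "d", "e")
  noms <- data.frame(ego = sample(ids, 12, replace = TRUE),
                     alter = sample(ids, 12, replace = TRUE),
                     strength = sample(1:5, 12, replace = TRUE))
  noms <- noms[noms$ego != noms$alter, ]
  r1 <- roster(data.frame(id = ids))
  perm <- c(3, 1, 5, 2, 4)
  r2 <- roster(data.frame(id = ids[perm]))
  n1 <- suppressMessages(build_valued_network(r1, noms))
  n2 <- suppressMessages(build_valued_network(r2, noms))
  expect_identical(unclass(n1[ids[perm], ids[perm]]),
                   unclass(n2[ids[perm], ids[perm]]))
  expect_identical(as.integer(n1["a", "b"]), as.integer(n2["a", "b"]))
})

test_that("dichotomize thresholds correctly and preserves the nonzero pattern at 1", {
  m <- random_valued(8)
  b1 <- dichotomize(m, 1)
  expect_equal(sum(b1), sum(m > 0))
  expect_true(all(b1 %in% 0:1))
  b3 <- dichotomize(m, 3)
  expect_equal(unname(b3[2, 1]), as.integer(m[2, 1] >= 3))
  expect_equal(sum(b3), sum(m >= 3))
  empty <- matrix(0L, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_true(all(dichotomize(valued_network(empty)) == 0))
  expect_error(dichotomize(m, 0), "1..5")
  expect_error(dichotomize(m, 6), "1..5")
})

test_that("matrix TSV round-trip is the identity for valued, binary and real matrices", {
  m <- random_valued(5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, path)
  expect_identical(read_matrix(path, "valued"), valued_network(m))

  b <- dichotomize(m)
  write_matrix(b, path)
  expect_identical(read_matrix(path, "binary"), b)

  set.seed(1)
  d <- matrix(rnorm(25), 5, 5, dimnames = dimnames(m))
  diag(d) <- 0
  write_matrix(d, path)
  expect_identical(read_matrix(path), d)
})

test_that("matrix reader rejects malformed files", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ta\tb\tc", "a\t0\t1\t2", "b\t1\t0\t1", "c\t2\t1\t0",
               "d\t0\t0\t0"), path)
  expect_error(read_matrix(path), "not square")
  writeLines(c("id\ta\tb", "a\t1\t2", "b\t3\t0"), path)
  expect_error(read_matrix(path, "valued"), "diagonal")
})

test_that("response rate matches hand-computed percentages", {
  expect_equal(response_rate(329, 297), 90.3)
  expect_equal(response_rate(10, 10), 100.0)
  expect_equal(response_rate(75, 48), 64.0)
  expect_error(response_rate(10, 11))
  expect_error(response_rate(0, 0))
})

test_that("graphml export writes a parseable graph with node attributes", {
  r <- tiny_roster(5)
  cfg <- synth_config(n_nodes = 10, seed = 3)
  sim <- simulate_study(synth_config(n_nodes = 12, seed = 3))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(dichotomize(sim$network), sim$roster, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 12)
  expect_true("hospital" %in% igraph::vertex_attr_names(g))
})

test_that("symmetrize_max is symmetric and never applied by the pipeline default", {
  m <- random_valued(6)
  s <- symmetrize_max(m)
  expect_identical(s, t(s))
  expect_true(all(s >= m))
})
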