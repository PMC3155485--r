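#' Validate a valued collaboration network
#'
#' The dependent relational variable: an n x n directed matrix of ordinal
#' tie strengths, `values[i, j]` being the strength (1-5) with which sender
#' i nominated receiver j, 0 meaning no nomination. Diagonal is zero by
#' construction.
#'
#' @param values Square numeric matrix with identical row/column node ids.
#' @return The validated integer matrix.
#' @export
valued_network <- function(values) {
  check_square_named(values, "valued network")
  check_zero_diag(values, "valued network")
  v <- offdiag_values(values)
  if (any(is.na(v)) || any(v != as.integer(v)) || any(v < 0) || any(v > 5)) {
    stop("valued network entries must be integers in 0..5")
  }
  storage.mode(values) <- "integer"
  values
}

#' Validate a binary (dichotomized) network
#'
#' @param values Square 0/1 matrix with identical row/column node ids and
#'   zero diagonal.
#' @return The validated integer matrix.
#' @export
binary_network <- function(values) {
  check_square_named(values, "binary network")
  check_zero_diag(values, "binary network")
  v <- offdiag_values(values)
  if (any(is.na(v)) || !all(v %in% c(0, 1))) {
    stop("binary network entries must be 0 or 1")
  }
  storage.mode(values) <- "integer"
  values
}

#' Read sociometric nominations from CSV
#'
#' The egocentric instrument yields rows `ego,alter,strength` with strength
#' on a five-point scale. Alters who are not on the roster (non-respondents
#' or external colleagues) are split off into a report and excluded from
#' matrix construction; egos must be rostered.
#'
#' @param path CSV with columns `ego`, `alter`, `strength`.
#' @param roster The study [roster()].
#' @return List with `nominations` (data frame of roster-restricted rows),
#'   `off_roster` (named integer vector counting nominations per off-roster
#'   alter) and `n_off_roster` (total excluded nominations).
#' @export
read_nominations <- function(path, roster) {
  if (!file.exists(path)) {
    stop(sprintf("nominations file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), check.names = FALSE)
  if (nrow(df) == 0) {
    return(list(nominations = data.frame(ego = character(), alter = character(),
                                         strength = integer()),
                off_roster = integer(0), n_off_roster = 0L))
  }
  need <- c("ego", "alter", "strength")
  if (!all(need %in% names(df))) {
    stop("nominations file must have columns ego, alter, strength")
  }
  nominations(data.frame(ego = as.character(df$ego),
                         alter = as.character(df$alter),
                         strength = df$strength,
                         stringsAsFactors = FALSE),
              roster)
}

#' Validate a nomination table against a roster
#'
#' @param df Data frame with columns `ego`, `alter`, `strength`.
#' @inheritParams read_nominations
#' @return Same structure as [read_nominations()].
#' @export
nominations <- function(df, roster) {
  ids <- roster_ids(roster)
  s <- suppressWarnings(as.numeric(df$strength))
  if (any(is.na(s)) || any(s != as.integer(s))) {
    stop("nomination strengths must parse as integers")
  }
  if (any(s < 1 | s > 5)) {
    bad <- which(s < 1 | s > 5)[1]
    stop(sprintf("nomination strength out of range 1-5 in row %d: %s",
                 bad, s[bad]))
  }
  df$strength <- as.integer(s)
  off_ego <- setdiff(df$ego, ids)
  if (length(off_ego) > 0) {
    stop(sprintf("nomination ego not on roster: %s",
                 paste(off_ego, collapse = ", ")))
  }
  off <- !df$alter %in% ids
  off_tab <- table(df$alter[off])
  off_roster <- stats::setNames(as.integer(off_tab), names(off_tab))
  kept <- df[!off, , drop = FALSE]
  rownames(kept) <- NULL
  list(nominations = kept, off_roster = off_roster,
       n_off_roster = sum(off))
}

#' Build the valued network from roster-restricted nominations
#'
#' Places each nomination strength at cell (ego, alter). Duplicate
#' nominations of the same alter resolve to the maximum reported strength;
#' self-nominations are dropped (their count is attached and reported via
#' `message()`).
#'
#' @param roster The study [roster()].
#' @param noms Data frame of roster-restricted nominations (`ego`, `alter`,
#'   `strength`), e.g. the `nominations` element of [read_nominations()].
#' @return A [valued_network()] matrix with attribute `n_self_dropped`.
#' @export
build_valued_network <- function(roster, noms) {
  ids <- roster_ids(roster)
  n <- length(ids)
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (nrow(noms) > 0) {
    if (!all(noms$alter %in% ids)) {
      stop("all nominations must be roster-restricted; filter off-roster alters first")
    }
    self <- noms$ego == noms$alter
    n_self <- sum(self)
    if (n_self > 0) {
      message(sprintf("dropped %d self-nomination(s)", n_self))
      noms <- noms[!self, , drop = FALSE]
    }
    if (nrow(noms) > 0) {
      i <- match(noms$ego, ids)
      j <- match(noms$alter, ids)
      # duplicates resolve by maximum strength
      ord <- order(noms$strength)
      idx <- cbind(i, j)[ord, , drop = FALSE]
      m[idx] <- noms$strength[ord]
    }
    attr(m, "n_self_dropped") <- n_self
  } else {
    attr(m, "n_self_dropped") <- 0L
  }
  out <- valued_network(m)
  attr(out, "n_self_dropped") <- attr(m, "n_self_dropped")
  out
}

#' Dichotomize a valued network
#'
#' `value[i, j] >= threshold` becomes 1, else 0. The default threshold of 1
#' treats any nomination as a tie.
#'
#' @param net A [valued_network()].
#' @param threshold Integer strength cut-off in 1..5.
#' @return A [binary_network()].
#' @export
dichotomize <- function(net, threshold = 1L) {
  if (length(threshold) != 1 || is.na(threshold) ||
      threshold != as.integer(threshold) || threshold < 1 || threshold > 5) {
    stop("threshold must be a single integer in 1..5")
  }
  b <- (net >= threshold) * 1L
  dimnames(b) <- dimnames(net)
  binary_network(b)
}

#' Symmetrize a network by the maximum of the two arcs
#'
#' Utility only: the analysis keeps the network directed throughout, since
#' reported reciprocation is well below 100%.
#'
#' @param net A valued or binary network matrix.
#' @return Symmetric matrix of pairwise maxima.
#' @export
symmetrize_max <- function(net) {
  out <- pmax(net, t(net))
  dimnames(out) <- dimnames(net)
  out
}

#' Write / read a square matrix as TSV with id headers
#'
#' The serialization dialect used for all networks and dyadic covariates:
#' a full square matrix in tab-separated form, first column and header row
#' carrying the node ids (row = sender, column = receiver). Round-trips are
#' bit-exact; `NA` cells encode masked (missing) dyads.
#'
#' @param m Square matrix with identical row/column ids.
#' @param path Output TSV path.
#' @export
write_matrix <- function(m, path) {
  check_square_named(m, "matrix")
  vals <- m
  if (is.double(vals)) {
    chr <- array(formatC(vals, format = "g", digits = 17), dim = dim(vals))
    chr[is.na(vals)] <- "NA"
  } else {
    chr <- array(as.character(vals), dim = dim(vals))
    chr[is.na(vals)] <- "NA"
  }
  out <- cbind(id = rownames(m), chr)
  colnames(out) <- c("id", colnames(m))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_matrix
#' @param type Validation applied after reading: `"numeric"` (any square
#'   matrix), `"valued"` (strengths 0-5, zero diagonal) or `"binary"`.
#' @return `read_matrix()`: the matrix with node-id dimnames.
#' @export
read_matrix <- function(path, type = c("numeric", "valued", "binary")) {
  type <- match.arg(type)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  ids_col <- as.character(df[[1]])
  ids_hdr <- colnames(df)[-1]
  if (nrow(df) != length(ids_hdr)) {
    stop(sprintf("matrix file is not square: %d data rows vs %d id columns",
                 nrow(df), length(ids_hdr)))
  }
  if (!identical(ids_col, ids_hdr)) {
    stop("row ids and column ids disagree in matrix file")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  dimnames(m) <- list(ids_col, ids_hdr)
  switch(type,
         numeric = m,
         valued = valued_network(m),
         binary = binary_network(m))
}

#' Export a network with node attributes as GraphML
#'
#' For external visualization tools; layout is out of scope here.
#'
#' @param net A binary or valued network matrix.
#' @param roster The study [roster()]; its attribute columns are attached
#'   as node attributes.
#' @param path Output GraphML path.
#' @export
write_graphml <- function(net, roster, path) {
  ids <- rownames(net)
  stopifnot(identical(ids, roster_ids(roster)))
  g <- igraph::graph_from_adjacency_matrix(net, mode = "directed",
                                           weighted = TRUE, diag = FALSE)
  for (col in setdiff(names(roster), "id")) {
    v <- roster[[col]]
    if (is.factor(v)) v <- as.character(v)
    g <- igraph::set_vertex_attr(g, col, value = v)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Survey response (compliance) rate
#'
#' @param n_rostered Number of individuals surveyed.
#' @param n_respondents Number who responded.
#' @return Percentage responding, rounded to one decimal.
#' @export
response_rate <- function(n_rostered, n_respondents) {
  if (length(n_rostered) != 1 || length(n_respondents) != 1 ||
      is.na(n_rostered) || is.na(n_respondents) ||
      n_rostered <= 0 || n_respondents < 0 || n_respondents > n_rostered) {
    stop("need 0 <= n_respondents <= n_rostered with n_rostered > 0")
  }
  round(100 * n_respondents / n_rostered, 1)
}
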