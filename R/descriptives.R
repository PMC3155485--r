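#' Summary statistics of a directed network
#'
#' Computed over the n(n-1) off-diagonal cells: density (mean cell value,
#' as a percent), population standard deviation and variance, sum, minimum
#' and maximum, arc reciprocity (percent of nonzero arcs whose reciprocal
#' arc is also nonzero; 0 when there are no arcs), symmetric pairs (percent
#' of unordered pairs with exactly equal values in both directions,
#' null-null pairs included) and the ordered dyad count. For a binary
#' network the population variance equals p(1 - p) with p the arc density.
#'
#' @param net Square valued or binary network matrix, zero diagonal,
#'   n >= 2.
#' @return Object of class `"network_summary"`.
#' @export
network_summary <- function(net) {
  check_square_named(net, "network")
  check_zero_diag(net, "network")
  n <- nrow(net)
  if (n < 2) stop("network summary needs at least 2 nodes")
  off <- row(net) != col(net)
  x <- as.numeric(net[off])
  n_dyads <- n * (n - 1)
  arcs <- net > 0
  n_arcs <- sum(arcs[off])
  recip <- if (n_arcs == 0) 0 else {
    100 * sum(arcs & t(arcs) & off) / n_arcs
  }
  upper <- upper.tri(net)
  sym_pairs <- 100 * sum(net[upper] == t(net)[upper]) / (n_dyads / 2)
  structure(list(
    n_nodes = as.integer(n),
    n_dyads = as.integer(n_dyads),
    density_pct = mean(x) * 100,
    std_dev = pop_sd(x),
    sum = sum(x),
    variance = pop_var(x),
    minimum = min(x),
    maximum = max(x),
    reciprocated_ties_pct = recip,
    symmetric_pairs_pct = sym_pairs
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("network summary: %d nodes, %d ordered dyads\n",
              x$n_nodes, x$n_dyads))
  cat(sprintf("  density %.2f%%  sum %g  sd %.4f  var %.4f  range [%g, %g]\n",
              x$density_pct, x$sum, x$std_dev, x$variance,
              x$minimum, x$maximum))
  cat(sprintf("  reciprocated ties %.2f%%  symmetric pairs %.2f%%\n",
              x$reciprocated_ties_pct, x$symmetric_pairs_pct))
  invisible(x)
}

#' Dyad census of a binary network
#'
#' Counts unordered pairs by mutuality: mutual (both arcs present),
#' asymmetric (exactly one) and null (neither). Arc reciprocity relates to
#' the census as 2M / (2M + A).
#'
#' @param net A [binary_network()] matrix.
#' @return List with `mutual`, `asymmetric`, `null`, classed
#'   `"dyad_census"`.
#' @export
dyad_census <- function(net) {
  check_square_named(net, "network")
  check_zero_diag(net, "network")
  off <- row(net) != col(net)
  if (!all(net[off] %in% c(0, 1))) {
    stop("dyad census requires a binary network")
  }
  upper <- upper.tri(net)
  a <- net[upper]
  b <- t(net)[upper]
  structure(list(
    mutual = sum(a == 1 & b == 1),
    asymmetric = sum(a + b == 1),
    null = sum(a == 0 & b == 0)
  ), class = "dyad_census")
}

#' @export
print.dyad_census <- function(x, ...) {
  cat(sprintf("dyad census: %d mutual, %d asymmetric, %d null\n",
              x$mutual, x$asymmetric, x$null))
  invisible(x)
}

#' Two-column network summary table
#'
#' The publication-shaped descriptive table: one column for the valued
#' network, one for its dichotomized version. Percentages and moments are
#' printed to two (four for sd/variance) decimals; full precision is kept
#' in the summary objects themselves.
#'
#' @param valued [network_summary()] of the valued network.
#' @param dichotomized [network_summary()] of the binary network.
#' @return Data frame with `statistic`, `valued`, `dichotomized` columns.
#' @export
summary_table <- function(valued, dichotomized) {
  fmt <- function(s) c(
    sprintf("%.2f", s$density_pct), sprintf("%.4f", s$std_dev),
    format(s$sum, big.mark = ",", scientific = FALSE),
    sprintf("%.4f", s$variance),
    format(s$minimum), format(s$maximum),
    sprintf("%.2f", s$reciprocated_ties_pct),
    sprintf("%.2f", s$symmetric_pairs_pct),
    format(s$n_dyads, big.mark = ",", scientific = FALSE)
  )
  data.frame(
    statistic = c("Density (Mean) (%)", "Std Dev", "Sum", "Variance",
                  "Minimum", "Maximum", "Reciprocated ties (%)",
                  "Symmetric Pairs (%)", "No of dyads"),
    valued = fmt(valued),
    dichotomized = fmt(dichotomized),
    stringsAsFactors = FALSE
  )
}

#' Write a network summary pair as TSV and JSON
#'
#' @inheritParams summary_table
#' @param path_tsv,path_json Output paths; either may be `NULL` to skip.
#' @export
write_summary <- function(valued, dichotomized, path_tsv = NULL,
                          path_json = NULL) {
  if (!is.null(path_tsv)) {
    utils::write.table(summary_table(valued, dichotomized), path_tsv,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(valued = unclass(valued), dichotomized = unclass(dichotomized)),
      path_json, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(NULL)
}
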