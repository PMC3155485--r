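#' Pipeline configuration
#'
#' Exactly one of the ingest paths (`roster`, `nominations`, plus optional
#' `publications` and `site_distances`) or a `simulate` config must be
#' supplied.
#'
#' @param roster,nominations,publications,site_distances Input CSV paths.
#' @param simulate A [synth_config()] to generate the study instead of
#'   reading it.
#' @param dichotomize_threshold Strength cut-off for the binary network.
#' @param predictors Predictor spec (default: full 13-predictor panel).
#' @param n_perm,method,alpha MR-QAP settings.
#' @param seed Seed for simulation and permutation streams.
#' @param out_dir Output directory (created if needed).
#' @return Validated list, classed `"pipeline_config"`.
#' @export
pipeline_config <- function(roster = NULL, nominations = NULL,
                            publications = NULL, site_distances = NULL,
                            simulate = NULL, dichotomize_threshold = 1L,
                            predictors = default_predictors(),
                            n_perm = 2000, method = "dsp", alpha = 0.05,
                            seed, out_dir) {
  if (missing(seed) || missing(out_dir)) {
    stop("seed and out_dir are required")
  }
  has_paths <- !is.null(roster) || !is.null(nominations)
  if (is.null(simulate) && !(!is.null(roster) && !is.null(nominations))) {
    stop("supply either both roster and nominations paths, or a simulate config")
  }
  if (!is.null(simulate) && has_paths) {
    stop("supply input paths or a simulate config, not both")
  }
  structure(list(roster = roster, nominations = nominations,
                 publications = publications,
                 site_distances = site_distances, simulate = simulate,
                 dichotomize_threshold = dichotomize_threshold,
                 predictors = predictors, n_perm = n_perm, method = method,
                 alpha = alpha, seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Publication-shaped attribute summary
#'
#' Continuous attributes as "mean +/- SD (min-max)" (sample SD), binary
#' attributes as count pairs, categorical attributes as per-level
#' "count (percent)" breakdowns that sum to the roster size.
#'
#' @param roster A [roster()].
#' @return Data frame with `characteristic` and `value` columns.
#' @export
summarize_attributes <- function(roster) {
  if (nrow(roster) == 0) stop("roster is empty")
  msd <- function(x) {
    x <- x[!is.na(x)]
    s <- if (length(x) > 1) stats::sd(x) else 0
    sprintf("%.2f ± %.2f (%g-%g)", mean(x), s, min(x), max(x))
  }
  cnt2 <- function(x, lev) {
    tab <- table(factor(x, levels = lev))
    sprintf("%d/%d", tab[[1]], tab[[2]])
  }
  cat_block <- function(title, x, lev) {
    tab <- table(factor(x, levels = lev))
    out <- list(c(title, ""))
    for (l in lev) {
      out <- c(out, list(c(paste0("  ", l),
                           sprintf("%d (%.2f)", tab[[l]],
                                   100 * tab[[l]] / sum(tab)))))
    }
    out
  }
  schema <- default_schema()
  has <- function(col) col %in% names(roster)
  rows <- list()
  if (has("ebm_attitude")) {
    rows <- c(rows, list(c("Attitude towards EBM, mean ± SD (range)",
                           msd(as.integer(roster$ebm_attitude)))))
  }
  if (has("age")) {
    rows <- c(rows, list(c("Age, year, mean ± SD (range)", msd(roster$age))))
  }
  if (has("gender")) {
    rows <- c(rows, list(c("Gender, No. M/F",
                           cnt2(roster$gender, schema$gender))))
  }
  if (has("years_since_graduation")) {
    rows <- c(rows, list(c("Years since Graduation, year, mean ± SD (range)",
                           msd(roster$years_since_graduation))))
  }
  if (has("specialization")) {
    rows <- c(rows, cat_block("Field of Specialization, No. Physicians (%)",
                              roster$specialization, schema$specialization))
  }
  if (has("tenure_nhs")) {
    rows <- c(rows, list(c("Tenure NHS, year, mean ± SD (range)",
                           msd(roster$tenure_nhs))))
  }
  if (has("tenure_lha")) {
    rows <- c(rows, list(c("Tenure LHA, year, mean ± SD (range)",
                           msd(roster$tenure_lha))))
  }
  if (has("managerial_role")) {
    rows <- c(rows, list(c("Managerial role, No. managers/professionals",
                           cnt2(roster$managerial_role,
                                schema$managerial_role))))
  }
  if (has("hospital")) {
    rows <- c(rows, cat_block("Hospital affiliation, No. Physicians (%)",
                              roster$hospital, schema$hospital))
  }
  if (has("directorate")) {
    rows <- c(rows, cat_block("Directorate affiliation, No. Physicians (%)",
                              roster$directorate, schema$directorate))
  }
  if (has("n_publications")) {
    rows <- c(rows, list(c("Number of Publications, mean ± SD (range)",
                           msd(roster$n_publications))))
  }
  data.frame(characteristic = vapply(rows, `[[`, character(1), 1),
             value = vapply(rows, `[[`, character(1), 2),
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Ingest (or simulate) -> build valued network -> dichotomize ->
#' descriptives -> covariate panel -> MR-QAP on both the valued and the
#' dichotomized response -> write a report bundle. All exclusion counts
#' (off-roster nominations, self-nominations, masked dyads) are logged via
#' `message()` and recorded in the run metadata. Given the same config and
#' seed, every output file is byte-identical across reruns.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `"report_bundle"` with the in-memory results
#'   and the paths written.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out, "data"), showWarnings = FALSE)
  log_lines <- character(0)
  log <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }

  stage <- "ingest"
  res <- tryCatch({
    if (!is.null(config$simulate)) {
      log("stage ingest: simulating study (n = %d, seed = %d)",
          config$simulate$n_nodes, config$seed)
      sim <- simulate_study(config$simulate, seed = config$seed)
      rost <- sim$roster
      pubs <- sim$publications
      sites <- sim$site_distances
      net <- sim$network
      write_roster(rost, file.path(out, "data", "roster.csv"))
      write_publications(pubs, file.path(out, "data", "publications.csv"))
      write_site_distances(sites, file.path(out, "data", "site_distances.csv"))
      n_off <- 0L
      n_self <- 0L
    } else {
      rost <- read_roster(config$roster)
      noms <- read_nominations(config$nominations, rost)
      n_off <- noms$n_off_roster
      log("stage ingest: %d nominations kept, %d off-roster excluded",
          nrow(noms$nominations), n_off)
      net <- suppressMessages(build_valued_network(rost, noms$nominations))
      n_self <- attr(net, "n_self_dropped") %||% 0L
      if (n_self > 0) log("stage ingest: dropped %d self-nomination(s)", n_self)
      pubs <- if (!is.null(config$publications)) {
        read_publications(config$publications, roster_ids(rost))
      } else NULL
      sites <- if (!is.null(config$site_distances)) {
        read_site_distances(config$site_distances)
      } else NULL
    }

    stage <- "networks"
    bin <- dichotomize(net, config$dichotomize_threshold)
    write_matrix(net, file.path(out, "network_valued.tsv"))
    write_matrix(bin, file.path(out, "network_dichotomized.tsv"))
    write_graphml(bin, rost, file.path(out, "network.graphml"))

    stage <- "descriptives"
    sv <- network_summary(net)
    sb <- network_summary(bin)
    write_summary(sv, sb, file.path(out, "network_summary.tsv"),
                  file.path(out, "network_summary.json"))
    attr_summary <- summarize_attributes(rost)
    utils::write.table(attr_summary, file.path(out, "attribute_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "covariates"
    panel <- covariate_panel(rost, publications = pubs,
                             site_distances = sites,
                             predictors = config$predictors)
    write_panel(panel, file.path(out, "covariates"))
    n_masked <- sum(Reduce(`|`, lapply(panel, `[[`, "mask")))
    log("stage covariates: %d predictors, %d masked dyads (listwise)",
        length(panel), n_masked)

    stage <- "mrqap"
    log("stage mrqap: %s, %d permutations, seed %d",
        config$method, config$n_perm, config$seed)
    res_v <- qap_test(net, panel, n_perm = config$n_perm,
                      method = config$method, seed = config$seed)
    res_b <- qap_test(bin, panel, n_perm = config$n_perm,
                      method = config$method, seed = config$seed)
    for (pair in list(list(res_v, "valued"), list(res_b, "dichotomized"))) {
      r <- pair[[1]]; tag <- pair[[2]]
      write_mrqap_tsv(r, file.path(out, sprintf("mrqap_%s.tsv", tag)))
      write_mrqap_json(r, file.path(out, sprintf("mrqap_%s.json", tag)))
      write_perm_dist(r, file.path(out, sprintf("perm_dist_%s.tsv", tag)))
      utils::write.table(result_table(r),
                         file.path(out, sprintf("table_mrqap_%s.tsv", tag)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    stage <- "report"
    meta <- list(
      package_version = as.character(utils::packageVersion("collabnet")),
      seed = config$seed, method = config$method, n_perm = config$n_perm,
      dichotomize_threshold = config$dichotomize_threshold,
      n_nodes = nrow(rost), n_dyads = nrow(rost) * (nrow(rost) - 1),
      n_off_roster_nominations = n_off, n_self_nominations = n_self,
      n_masked_dyads = res_v$n_excluded_dyads,
      n_included_dyads = res_v$n_included_dyads,
      simulated = !is.null(config$simulate)
    )
    jsonlite::write_json(meta, file.path(out, "run_metadata.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(out, "run_log.txt"))

    structure(list(roster = rost, network_valued = net,
                   network_dichotomized = bin,
                   summary_valued = sv, summary_dichotomized = sb,
                   attribute_summary = attr_summary, panel = panel,
                   mrqap_valued = res_v, mrqap_dichotomized = res_b,
                   metadata = meta, out_dir = out),
              class = "report_bundle")
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  res
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("report bundle in %s: %d nodes, %d included dyads\n",
              x$out_dir, x$metadata$n_nodes, x$metadata$n_included_dyads))
  invisible(x)
}
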