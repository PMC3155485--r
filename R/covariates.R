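#' Construct a dyadic covariate
#'
#' A dyadic covariate re-expresses node-level information at the dyad
#' level: an n x n matrix with zero diagonal plus a logical mask marking
#' dyads where the value is undefined (an attribute missing on either
#' side). Kinds:
#' \describe{
#'   \item{difference}{absolute attribute difference; 0 = identical, so
#'     smaller values mean greater homophily}
#'   \item{match}{1 iff both members share the same category}
#'   \item{distance}{non-negative pairwise distance (km)}
#'   \item{tie}{binary relational indicator such as co-authorship}
#' }
#' All kinds are symmetric even though the response network is directed.
#'
#' @param name Short machine name (used to address planted effects).
#' @param kind One of `"difference"`, `"match"`, `"distance"`, `"tie"`.
#' @param values Square matrix; `NA` at masked cells.
#' @param mask Logical matrix, `TRUE` where the dyad is undefined. Derived
#'   from `is.na(values)` when omitted.
#' @param label Human-readable row label for output tables.
#' @return Object of class `"dyadic_covariate"`.
#' @export
dyadic_covariate <- function(name, kind, values,
                             mask = NULL, label = name) {
  kind <- match.arg(kind, c("difference", "match", "distance", "tie"))
  check_square_named(values, sprintf("covariate '%s'", name))
  if (is.null(mask)) mask <- is.na(values)
  stopifnot(identical(dim(mask), dim(values)))
  diag(values) <- 0
  diag(mask) <- FALSE
  ok <- !mask & row(values) != col(values)
  v <- values[ok]
  if (any(is.na(v))) {
    stop(sprintf("covariate '%s' has NA values outside its mask", name))
  }
  if (kind %in% c("difference", "distance") && any(v < 0)) {
    stop(sprintf("covariate '%s' (%s) must be non-negative", name, kind))
  }
  if (kind %in% c("match", "tie") && !all(v %in% c(0, 1))) {
    stop(sprintf("covariate '%s' (%s) must be binary", name, kind))
  }
  if (!isTRUE(all(mask == t(mask))) ||
      !isTRUE(all(values[!mask & !t(mask)] == t(values)[!mask & !t(mask)],
                  na.rm = TRUE))) {
    stop(sprintf("covariate '%s' must be symmetric", name))
  }
  structure(list(name = name, kind = kind, values = values, mask = mask,
                 label = label),
            class = "dyadic_covariate")
}

#' @export
print.dyadic_covariate <- function(x, ...) {
  cat(sprintf("dyadic covariate '%s' (%s), %d nodes, %d masked dyads\n",
              x$name, x$kind, nrow(x$values),
              sum(x$mask[row(x$mask) != col(x$mask)])))
  invisible(x)
}

#' Absolute-difference dyadic covariate
#'
#' Continuous attributes enter the model as absolute sender-receiver
#' differences; 0 indicates the two physicians are identical on the
#' attribute, so larger values measure heterophily.
#'
#' @param x Numeric vector named by node ids.
#' @param name Covariate name.
#' @param label Display label.
#' @return A `difference`-kind [dyadic_covariate()]; dyads with a missing
#'   attribute on either side are masked.
#' @export
abs_diff_matrix <- function(x, name, label = name) {
  if (!is.numeric(x)) stop(sprintf("attribute '%s' must be numeric", name))
  ids <- names(x)
  if (is.null(ids)) stop("attribute vector must be named by node ids")
  vals <- abs(outer(x, x, "-"))
  dimnames(vals) <- list(ids, ids)
  miss <- is.na(x)
  mask <- outer(miss, miss, "|")
  vals[mask] <- NA
  dyadic_covariate(name, "difference", vals, mask, label)
}

#' Same-category dyadic covariate
#'
#' Categorical and binary attributes enter as match indicators: 1 iff both
#' members of the dyad belong to the same category.
#'
#' @param x Factor or character vector named by node ids.
#' @param levels Declared level set; values outside it are an error.
#' @inheritParams abs_diff_matrix
#' @return A `match`-kind [dyadic_covariate()].
#' @export
same_category_matrix <- function(x, name, levels = NULL, label = name) {
  ids <- names(x)
  if (is.null(ids)) stop("attribute vector must be named by node ids")
  if (is.factor(x)) {
    levels <- levels %||% base::levels(x)
    x <- as.character(x)
  }
  if (!is.null(levels)) {
    bad <- !is.na(x) & !x %in% levels
    if (any(bad)) {
      stop(sprintf("undeclared level '%s' for covariate '%s'",
                   x[which(bad)[1]], name))
    }
  }
  vals <- (outer(x, x, "==")) * 1
  dimnames(vals) <- list(ids, ids)
  miss <- is.na(x)
  mask <- outer(miss, miss, "|")
  vals[mask] <- NA
  dyadic_covariate(name, "match", vals, mask, label)
}

#' Site-distance table
#'
#' Symmetric lookup of pairwise distances (km) between sites, with zero
#' self-distance. Built from a long data frame `site_a, site_b, km`;
#' symmetric closure is applied, and self-distances are forced to zero.
#'
#' @param df Data frame with columns `site_a`, `site_b`, `km`.
#' @return A symmetric named distance matrix of class
#'   `"site_distance_table"`.
#' @export
site_distance_table <- function(df) {
  stopifnot(all(c("site_a", "site_b", "km") %in% names(df)))
  km <- as.numeric(df$km)
  if (any(is.na(km)) || any(km < 0)) stop("distances must be non-negative km")
  sites <- sort(unique(c(as.character(df$site_a), as.character(df$site_b))))
  m <- matrix(NA_real_, length(sites), length(sites),
              dimnames = list(sites, sites))
  diag(m) <- 0
  for (r in seq_len(nrow(df))) {
    a <- as.character(df$site_a[r]); b <- as.character(df$site_b[r])
    cur <- m[a, b]
    if (!is.na(cur) && cur != km[r]) {
      stop(sprintf("conflicting distances for sites (%s, %s)", a, b))
    }
    m[a, b] <- km[r]
    m[b, a] <- km[r]
  }
  structure(m, class = c("site_distance_table", "matrix"))
}

#' Read a site-distance table from CSV
#'
#' @param path CSV with columns `site_a`, `site_b`, `km`.
#' @return A [site_distance_table()].
#' @export
read_site_distances <- function(path) {
  site_distance_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @export
write_site_distances <- function(tbl, path) {
  sites <- rownames(tbl)
  idx <- which(upper.tri(tbl), arr.ind = TRUE)
  df <- data.frame(site_a = sites[idx[, 1]], site_b = sites[idx[, 2]],
                   km = tbl[idx])
  df <- df[!is.na(df$km), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Geographic-distance dyadic covariate
#'
#' Dyadic distance in km between the sites each node is affiliated with;
#' same-site dyads are 0.
#'
#' @param site_of Character vector of site names, named by node ids.
#' @param table A [site_distance_table()].
#' @inheritParams abs_diff_matrix
#' @return A `distance`-kind [dyadic_covariate()].
#' @export
geo_distance_matrix <- function(site_of, table, name = "geo_distance",
                                label = name) {
  ids <- names(site_of)
  if (is.null(ids)) stop("site vector must be named by node ids")
  site_of <- as.character(site_of)
  known <- rownames(table)
  miss <- is.na(site_of)
  bad <- !miss & !site_of %in% known
  if (any(bad)) {
    stop(sprintf("site '%s' absent from distance table", site_of[which(bad)[1]]))
  }
  si <- match(site_of, known)
  vals <- matrix(NA_real_, length(ids), length(ids),
                 dimnames = list(ids, ids))
  ok <- !miss
  vals[ok, ok] <- unclass(table)[si[ok], si[ok]]
  if (any(is.na(vals[ok, ok]))) {
    pair <- which(is.na(vals) & outer(ok, ok, "&"), arr.ind = TRUE)[1, ]
    stop(sprintf("distance for site pair (%s, %s) absent from table",
                 site_of[pair[1]], site_of[pair[2]]))
  }
  diag(vals) <- 0
  mask <- outer(miss, miss, "|")
  vals[mask] <- NA
  dyadic_covariate(name, "distance", vals, mask, label)
}

#' Co-authorship dyadic covariate
#'
#' 1 iff the two nodes share at least one publication id; the relational
#' control for prior scientific collaboration.
#'
#' @param pubs Named list mapping each node id to a character vector of
#'   publication ids (possibly empty).
#' @param ids Node id order for the matrix.
#' @inheritParams abs_diff_matrix
#' @return A `tie`-kind [dyadic_covariate()].
#' @export
coauthorship_matrix <- function(pubs, ids = names(pubs),
                                name = "co_authorship", label = name) {
  vals <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  long <- data.frame(
    id = rep(ids, times = vapply(pubs[ids], length, integer(1))),
    pub = unlist(pubs[ids], use.names = FALSE),
    stringsAsFactors = FALSE
  )
  if (nrow(long) > 0) {
    for (members in split(long$id, long$pub)) {
      members <- unique(members)
      if (length(members) > 1) {
        vals[members, members] <- 1
      }
    }
  }
  diag(vals) <- 0
  dyadic_covariate(name, "tie", vals, label = label)
}

#' Read a long-format publication membership file
#'
#' @param path CSV with columns `node_id`, `publication_id`.
#' @param ids Roster node ids (nodes without publications get empty sets).
#' @return Named list of publication-id vectors per node.
#' @export
read_publications <- function(path, ids) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("node_id", "publication_id") %in% names(df)))
  pubs <- stats::setNames(
    lapply(ids, function(i) unique(as.character(df$publication_id[df$node_id == i]))),
    ids
  )
  pubs
}

#' @export
write_publications <- function(pubs, path) {
  df <- data.frame(
    node_id = rep(names(pubs), times = vapply(pubs, length, integer(1))),
    publication_id = unlist(pubs, use.names = FALSE)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Default predictor specification
#'
#' The thirteen dyadic predictors of the collaboration model, in output
#' order: EBM-attitude match, age difference, gender match, years-since-
#' graduation difference, specialization match, NHS-tenure difference,
#' LHA-tenure difference, managerial-role match, hospital match,
#' directorate match, publication-count difference, co-authorship, and
#' geographic distance.
#'
#' @return Data frame with columns `name`, `attr`, `kind`, `label`.
#' @export
default_predictors <- function() {
  data.frame(
    name = c("ebm_attitude_same", "age_diff", "gender_same",
             "years_since_graduation_diff", "specialization_same",
             "tenure_nhs_diff", "tenure_lha_diff", "managerial_role_same",
             "hospital_same", "directorate_same", "n_publications_diff",
             "co_authorship", "geo_distance"),
    attr = c("ebm_attitude", "age", "gender", "years_since_graduation",
             "specialization", "tenure_nhs", "tenure_lha", "managerial_role",
             "hospital", "directorate", "n_publications", NA, NA),
    kind = c("match", "difference", "match", "difference", "match",
             "difference", "difference", "match", "match", "match",
             "difference", "tie", "distance"),
    label = c("Attitude towards EBM (same category)", "Age (difference in)",
              "Gender (same category)", "Years since Graduation (difference in)",
              "Field of Specialization (same category)",
              "Tenure NHS (difference in)", "Tenure LHA (difference in)",
              "Managerial role (same category)", "Hospital (same affiliation)",
              "Directorate (same affiliation)",
              "Number of Publications (difference in)",
              "Co-authorship (same category)", "Geographical distance"),
    stringsAsFactors = FALSE
  )
}

#' Build the ordered dyadic covariate panel
#'
#' Maps each entry of the predictor spec onto the roster (and, for
#' co-authorship and geographic distance, the auxiliary inputs) and returns
#' the ordered list of [dyadic_covariate()] objects.
#'
#' @param roster The study [roster()].
#' @param publications Named list of publication ids per node (required if
#'   the spec includes `co_authorship`).
#' @param site_distances A [site_distance_table()] (required if the spec
#'   includes `geo_distance`); node sites are taken from the roster's
#'   `hospital` column.
#' @param predictors Spec as from [default_predictors()]; a character
#'   vector of names selects a subset in the given order.
#' @return List of dyadic covariates, classed `"covariate_panel"`.
#' @export
covariate_panel <- function(roster, publications = NULL,
                            site_distances = NULL,
                            predictors = default_predictors()) {
  all_spec <- default_predictors()
  if (is.character(predictors)) {
    bad <- setdiff(predictors, all_spec$name)
    if (length(bad) > 0) {
      stop(sprintf("unknown predictor(s): %s", paste(bad, collapse = ", ")))
    }
    predictors <- all_spec[match(predictors, all_spec$name), , drop = FALSE]
  }
  ids <- roster_ids(roster)
  schema <- attr(roster, "schema") %||% default_schema()
  panel <- vector("list", nrow(predictors))
  for (r in seq_len(nrow(predictors))) {
    nm <- predictors$name[r]
    kind <- predictors$kind[r]
    lab <- predictors$label[r]
    panel[[r]] <- switch(
      kind,
      difference = {
        a <- predictors$attr[r]
        if (!a %in% names(roster)) stop(sprintf("roster lacks attribute '%s'", a))
        abs_diff_matrix(stats::setNames(roster[[a]], ids), nm, label = lab)
      },
      match = {
        a <- predictors$attr[r]
        if (!a %in% names(roster)) stop(sprintf("roster lacks attribute '%s'", a))
        same_category_matrix(stats::setNames(as.character(roster[[a]]), ids),
                             nm, levels = schema[[a]], label = lab)
      },
      tie = {
        if (is.null(publications)) {
          stop("publications required for the co-authorship covariate")
        }
        coauthorship_matrix(publications, ids, name = nm, label = lab)
      },
      distance = {
        if (is.null(site_distances)) {
          stop("site_distances required for the geographic-distance covariate")
        }
        geo_distance_matrix(stats::setNames(as.character(roster$hospital), ids),
                            site_distances, name = nm, label = lab)
      },
      stop(sprintf("unresolvable predictor kind '%s'", kind))
    )
  }
  names(panel) <- predictors$name
  structure(panel, class = "covariate_panel")
}

#' Serialize / load a covariate panel
#'
#' One TSV matrix per covariate (masked dyads as `NA`) plus a JSON manifest
#' recording name, kind, label, file and masked-dyad count.
#'
#' @param panel A [covariate_panel()].
#' @param dir Directory to write into (created if needed).
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- lapply(panel, function(cv) {
    file <- sprintf("%s.tsv", cv$name)
    vals <- cv$values
    vals[cv$mask] <- NA
    write_matrix(vals, file.path(dir, file))
    list(name = cv$name, kind = cv$kind, label = cv$label, file = file,
         n_masked_dyads = sum(cv$mask[row(cv$mask) != col(cv$mask)]))
  })
  jsonlite::write_json(unname(manifest), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_panel
#' @return `read_panel()`: the reconstructed [covariate_panel()].
#' @export
read_panel <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  panel <- lapply(manifest, function(entry) {
    vals <- read_matrix(file.path(dir, entry$file))
    dyadic_covariate(entry$name, entry$kind, vals, label = entry$label)
  })
  names(panel) <- vapply(manifest, `[[`, character(1), "name")
  structure(panel, class = "covariate_panel")
}
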