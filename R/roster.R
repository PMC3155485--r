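#' Default roster attribute schema
#'
#' Declares the level sets for the categorical attributes of a physician
#' roster: gender, 4-level attitude towards evidence-based medicine (EBM),
#' field of specialization, managerial role, hospital affiliation (six
#' sites) and clinical directorate affiliation (three directorates).
#' Continuous attributes (age, years since graduation, NHS and LHA tenure,
#' publication count) are unconstrained non-negative numerics.
#'
#' @return Named list mapping each categorical attribute to its character
#'   vector of allowed levels.
#' @export
default_schema <- function() {
  list(
    gender = c("M", "F"),
    ebm_attitude = c("never", "rarely", "sometimes", "often/very often"),
    specialization = c("medical", "surgical", "obstetrics-gynaecology",
                       "paediatrics"),
    managerial_role = c("manager", "professional"),
    hospital = c("Bellaria", "Budrio", "Maggiore", "Porretta",
                 "Bentivoglio", "Mazzacorati/Roncati"),
    directorate = c("Neuroscience", "Oncology", "Maternal-Health")
  )
}

roster_continuous_attrs <- function() {
  c("age", "years_since_graduation", "tenure_nhs", "tenure_lha",
    "n_publications")
}

#' Construct and validate a roster
#'
#' A roster is a data frame with one row per individual: a unique string
#' `id` plus the attribute columns named in [default_schema()] and the
#' continuous attributes. Missing attribute values are permitted (`NA`),
#' missing ids are not.
#'
#' @param df Data frame with an `id` column and attribute columns.
#' @param schema Level sets for categorical attributes, as from
#'   [default_schema()].
#' @return The validated roster, classed `"roster"`, with categorical
#'   columns converted to factors over the declared levels and row order
#'   preserved.
#' @export
roster <- function(df, schema = default_schema()) {
  stopifnot(is.data.frame(df))
  if (!"id" %in% names(df)) {
    stop("roster must have an 'id' column")
  }
  ids <- as.character(df$id)
  if (any(is.na(ids) | ids == "")) {
    stop("roster ids must be non-empty")
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate roster id: %s", paste(unique(dup), collapse = ", ")))
  }
  df$id <- ids
  for (attr in names(schema)) {
    if (!attr %in% names(df)) next
    vals <- as.character(df[[attr]])
    bad <- which(!is.na(vals) & !vals %in% schema[[attr]])
    if (length(bad) > 0) {
      stop(sprintf("unknown level '%s' for attribute '%s' in roster row %d",
                   vals[bad[1]], attr, bad[1]))
    }
    df[[attr]] <- factor(vals, levels = schema[[attr]])
  }
  for (attr in intersect(roster_continuous_attrs(), names(df))) {
    v <- df[[attr]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(as.character(v)))
      if (any(!is.na(v) & is.na(vn))) {
        stop(sprintf("attribute '%s' must be numeric", attr))
      }
      df[[attr]] <- vn
    }
  }
  rownames(df) <- NULL
  structure(df, schema = schema, class = c("roster", "data.frame"))
}

#' Read a roster from CSV
#'
#' One row per individual, header matching the roster column names. Empty
#' cells are read as missing, never as zero.
#'
#' @inheritParams roster
#' @param path Path to the CSV file.
#' @return A validated [roster()].
#' @export
read_roster <- function(path, schema = default_schema()) {
  if (!file.exists(path)) {
    stop(sprintf("roster file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), check.names = FALSE)
  roster(df, schema = schema)
}

#' Write a roster to CSV
#'
#' @param x A [roster()].
#' @param path Output CSV path.
#' @export
write_roster <- function(x, path) {
  df <- as.data.frame(x)
  for (col in names(df)) {
    if (is.factor(df[[col]])) df[[col]] <- as.character(df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Node ids of a roster, in roster order
#'
#' @param x A [roster()].
#' @return Character vector of ids.
#' @export
roster_ids <- function(x) as.character(x$id)
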