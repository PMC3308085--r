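# Delimited-text readers and writers for the four claims/registry streams
# plus result tables. CSV, header required, ISO-8601 dates, UTF-8.

ra_schemas <- function() {
  list(
    fills = list(
      columns = c("patient_id", "drug", "fill_date", "days_supply",
                  "strength_mg", "quantity", "route"),
      date_cols = "fill_date",
      num_cols = c("days_supply", "strength_mg", "quantity")
    ),
    infusions = list(
      columns = c("patient_id", "drug", "date", "dose_mg"),
      date_cols = "date",
      num_cols = "dose_mg"
    ),
    procedures = list(
      columns = c("patient_id", "date", "kind"),
      date_cols = "date",
      num_cols = character()
    ),
    visits = list(
      columns = c("patient_id", "date", "tjc28", "sjc28", "esr_mm_hr",
                  "patient_global", "physician_global"),
      date_cols = "date",
      num_cols = c("tjc28", "sjc28", "esr_mm_hr", "patient_global",
                   "physician_global")
    ),
    comorbidities = list(
      columns = c("patient_id", "condition", "flag"),
      date_cols = character(),
      num_cols = character()
    ),
    episodes = list(
      columns = c("patient_id", "index_drug", "index_date", "episode_class",
                  "baseline_date", "outcome_date"),
      date_cols = c("index_date", "baseline_date", "outcome_date"),
      num_cols = character()
    )
  )
}

parse_iso_date <- function(x) {
  out <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  ok <- !is.na(x) & nzchar(x)
  parsed <- as.Date(x[ok], format = "%Y-%m-%d")
  # as.Date() is lenient about impossible days; require exact round-trip
  parsed[!is.na(parsed) & format(parsed, "%Y-%m-%d") != x[ok]] <- NA
  out[ok] <- parsed
  out
}

# per-stream record validation; returns character vector of row problems
validate_stream <- function(df, schema) {
  probs <- character()
  bad <- function(rows, msg) {
    if (any(rows)) {
      sprintf("row %d: %s", which(rows), msg)
    } else {
      character()
    }
  }
  if (schema == "fills") {
    probs <- c(probs,
      bad(!(df$drug %in% ra_drugs()), "unknown drug"),
      bad(is.na(df$fill_date), "unparseable fill_date"),
      bad(is.na(df$days_supply) | df$days_supply < 0, "days_supply must be >= 0"),
      bad(is.na(df$strength_mg) | df$strength_mg < 0, "strength_mg must be >= 0"),
      bad(is.na(df$quantity) | df$quantity < 0, "quantity must be >= 0"),
      bad(!(df$route %in% c("oral", "subcutaneous")), "route must be oral or subcutaneous"))
  } else if (schema == "infusions") {
    probs <- c(probs,
      bad(!(df$drug %in% ra_infused()), "drug is not an infused biologic"),
      bad(is.na(df$date), "unparseable date"),
      bad(is.na(df$dose_mg) | df$dose_mg <= 0, "dose_mg must be > 0"))
  } else if (schema == "procedures") {
    probs <- c(probs,
      bad(is.na(df$date), "unparseable date"),
      bad(!(df$kind %in% "glucocorticoid_injection"), "unknown procedure kind"))
  } else if (schema == "visits") {
    probs <- c(probs,
      bad(is.na(df$date), "unparseable date"),
      bad(is.na(df$tjc28) | df$tjc28 < 0 | df$tjc28 > 28, "tjc28 outside [0, 28]"),
      bad(is.na(df$sjc28) | df$sjc28 < 0 | df$sjc28 > 28, "sjc28 outside [0, 28]"),
      bad(is.na(df$esr_mm_hr) | df$esr_mm_hr < 0, "esr_mm_hr must be >= 0"),
      bad(is.na(df$patient_global) | df$patient_global < 0 | df$patient_global > 100,
          "patient_global outside [0, 100]"),
      bad(is.na(df$physician_global) | df$physician_global < 0 | df$physician_global > 100,
          "physician_global outside [0, 100]"))
  } else if (schema == "episodes") {
    probs <- c(probs,
      bad(is.na(df$index_date), "unparseable index_date"),
      bad(is.na(df$outcome_date), "unparseable outcome_date"),
      bad(!(df$episode_class %in% c("biologic", "dmard")), "unknown episode_class"))
  } else if (schema == "comorbidities") {
    probs <- c(probs,
      bad(!(tolower(df$flag) %in% c("true", "false")), "flag must be TRUE/FALSE"))
  }
  probs
}

#' Read a claims, registry, or episode stream from CSV
#'
#' Reads one of the delimited-text input streams, checks the header against
#' the documented schema, parses ISO-8601 dates, and validates every row
#' against the stream's invariants. Malformed rows abort with a message
#' listing row numbers and offending fields.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema One of `"fills"`, `"infusions"`, `"procedures"`, `"visits"`,
#'   `"comorbidities"`, `"episodes"`.
#' @return A `data.frame` of typed, validated records (dates as `Date`,
#'   counts and doses numeric). An empty file with a valid header yields a
#'   zero-row frame.
#' @seealso [write_stream()] for the inverse; the column layouts are listed
#'   in the package README.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("patient_id,drug,fill_date,days_supply,strength_mg,quantity,route",
#'              "P1,etanercept,2005-03-01,28,50,4,subcutaneous"), f)
#' read_stream(f, "fills")
#' @export
read_stream <- function(path, schema = c("fills", "infusions", "procedures",
                                         "visits", "comorbidities",
                                         "episodes")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  sch <- ra_schemas()[[schema]]
  df <- read.csv(path, colClasses = "character", check.names = FALSE,
                 fileEncoding = "UTF-8")
  missing <- setdiff(sch$columns, names(df))
  if (length(missing)) {
    stop("schema error in ", path, " [", schema, "]: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  df <- df[sch$columns]
  for (col in sch$date_cols) df[[col]] <- parse_iso_date(df[[col]])
  for (col in sch$num_cols) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & nzchar(raw) & is.na(val))
    if (length(bad)) {
      stop("row error in ", path, " [", schema, "]: unparseable number in '",
           col, "' at row(s) ", paste(bad, collapse = ", "))
    }
    df[[col]] <- val
  }
  if (schema == "comorbidities") {
    df$flag <- tolower(df$flag) == "true"
  }
  if (nrow(df)) {
    probs <- validate_stream(df, schema)
    if (length(probs)) {
      stop("row error in ", path, " [", schema, "]:\n  ",
           paste(head(probs, 20), collapse = "\n  "))
    }
  }
  rownames(df) <- NULL
  df
}

#' Write a stream or result table to CSV
#'
#' Serialises a record frame with ISO-8601 dates so that
#' `read_stream(write_stream(x))` round-trips exactly. Flag-set columns (as
#' produced by [classify_episodes()]) are written as a `|`-joined list.
#'
#' @param x A data.frame (a claims stream, episode table, or result table).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(x, path) {
  out <- as.data.frame(x)
  for (col in names(out)) {
    if (inherits(out[[col]], "Date")) out[[col]] <- format(out[[col]], "%Y-%m-%d")
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write and read algorithm / gold-standard classification results
#'
#' Result tables carry one row per episode with the binary classification and
#' the reason flags serialised as a `|`-joined list (empty string when the
#' episode was classified effective).
#'
#' @param results A result frame from [classify_episodes()] or
#'   [evaluate_gold_standard()].
#' @param path CSV file path.
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   returns the result frame with `effective` logical, dates as `Date`, and
#'   a `flags` character column.
#' @export
write_results <- function(results, path) {
  out <- as.data.frame(results)
  if (!is.null(out$flags) && is.list(out$flags)) {
    out$flags <- vapply(out$flags, paste, character(1), collapse = "|")
  }
  write_stream(out, path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, colClasses = "character", check.names = FALSE,
                 fileEncoding = "UTF-8")
  for (col in intersect(c("index_date", "baseline_date", "outcome_date", "date"),
                        names(df))) {
    df[[col]] <- parse_iso_date(df[[col]])
  }
  for (col in intersect(c("effective", "reached_lda", "improved_gt_1_2",
                          "adherent", ra_flags()), names(df))) {
    df[[col]] <- tolower(df[[col]]) == "true"
  }
  for (col in intersect(c("mpr", "das28_baseline", "das28_outcome",
                          "cdai_outcome", "expected_infusions",
                          "observed_infusions"), names(df))) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df
}
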