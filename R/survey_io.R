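# Reading, validating and mapping survey tables.

#' The seven analysis cause groups
#'
#' Fixed enumeration, in the canonical order used throughout the package
#' (also the deterministic tie-break order for imputation): NCD, CD, INJURY,
#' PAIN, SURGERY, OTHER, UNIDENTIFIED. CD includes maternal and child health
#' reasons, following burden-of-disease grouping conventions.
#'
#' @return character vector of length 7.
#' @export
cause_groups <- function() {
  c("NCD", "CD", "INJURY", "PAIN", "SURGERY", "OTHER", "UNIDENTIFIED")
}

# Disease-specific categories used for CHE attribution.
disease_categories <- function() c("NCD", "CD", "INJURY")

#' Default reason-to-cause-group codebook
#'
#' The surveys offer 18 raw reasons for seeking care; this best-effort
#' mapping collapses them to the seven analysis groups. The real instrument
#' mapping is not public, so the codebook ships as an editable CSV
#' (`inst/extdata/reason_codebook.csv`) and every pipeline stage takes the
#' codebook as an input, making the mapping explicit and swappable.
#'
#' @return data frame with columns `code` (integer), `reason`, `group`.
#' @export
default_codebook <- function() {
  path <- system.file("extdata", "reason_codebook.csv", package = "chedecomp")
  if (path == "") path <- file.path("inst", "extdata", "reason_codebook.csv")
  read_codebook(path)
}

#' Read and validate a reason codebook
#'
#' @param path CSV with columns `code` and `group` (a `reason` label column
#'   is optional).
#' @return validated codebook data frame.
#' @export
read_codebook <- function(path) {
  cb <- read.csv(path, stringsAsFactors = FALSE)
  require_columns(cb, c("code", "group"), "codebook")
  if (anyDuplicated(cb$code)) stop("codebook: duplicate reason codes", call. = FALSE)
  bad <- setdiff(unique(cb$group), cause_groups())
  if (length(bad))
    stop(sprintf("codebook: unknown cause group(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  if (!all(disease_categories() %in% cb$group))
    stop("codebook: must map at least one code to each of NCD, CD, INJURY",
         call. = FALSE)
  cb$code <- as.integer(cb$code)
  cb
}

#' Map raw reason codes to cause groups
#'
#' Total and deterministic: every code in the codebook maps to exactly one
#' group; `NA` codes (censored visits) map to `NA`.
#'
#' @param raw_code integer vector of raw reason codes.
#' @param codebook codebook from [read_codebook()] / [default_codebook()].
#' @return character vector of cause groups.
#' @export
map_reason_to_group <- function(raw_code, codebook = default_codebook()) {
  idx <- match(raw_code, codebook$code)
  unknown <- !is.na(raw_code) & is.na(idx)
  if (any(unknown)) {
    stop(sprintf("unknown reason code(s) %s; valid codes: %s",
                 paste(unique(raw_code[unknown]), collapse = ", "),
                 paste(codebook$code, collapse = ", ")), call. = FALSE)
  }
  codebook$group[idx]
}

# Column schema for the three flat tables (name, type, units, NA allowed).
sage_schema <- function() {
  list(
    households = data.frame(
      column = c("household_id", "country", "stratum", "psu", "weight",
                 "hh_type", "size", "expenditure", "food_expenditure",
                 "asset_index", "wealth_quintile", "urban"),
      type = c("character", "character", "character", "character", "numeric",
               "character", "integer", "numeric", "numeric", "numeric",
               "integer", "integer"),
      units = c("", "", "", "", "relative", "", "persons", "currency/year",
                "currency/year", "z-score", "quintile 1-5", "0/1"),
      allow_na = FALSE, stringsAsFactors = FALSE),
    respondents = data.frame(
      column = c("respondent_id", "household_id", "country", "age", "sex",
                 "urban", "education", "wealth_quintile", "weight"),
      type = c("character", "character", "character", "numeric", "character",
               "integer", "integer", "integer", "numeric"),
      units = c("", "", "", "years", "", "0/1", "level 0-3", "quintile 1-5",
                "relative"),
      allow_na = FALSE, stringsAsFactors = FALSE),
    visits = data.frame(
      column = c("visit_id", "respondent_id", "household_id", "country",
                 "care_level", "rank", "reason_code", "cause", "facility",
                 "oop_cost"),
      type = c("character", "character", "character", "character",
               "character", "integer", "integer", "character", "character",
               "numeric"),
      units = c("", "", "", "", "", "1=most recent", "code 1-18", "", "",
                "currency"),
      allow_na = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                   TRUE, TRUE, TRUE, TRUE),
      stringsAsFactors = FALSE))
}

#' Write a synthetic survey to disk
#'
#' Writes the three observed flat tables as CSV (and optionally Parquet via
#' the arrow package), the ground-truth visit sidecar, and a machine-readable
#' JSON schema (column, type, units, missingness). Missing cells are written
#' as empty fields, never sentinel numbers.
#'
#' @param sim a `sage_sim` object from [simulate_sage()].
#' @param dir output directory (created if needed).
#' @param format "csv" (default) or "parquet" (requires arrow; CSV is always
#'   written too).
#' @return `dir`, invisibly.
#' @export
write_sage <- function(sim, dir, format = c("csv", "parquet")) {
  stopifnot(inherits(sim, "sage_sim"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(households = sim$households, respondents = sim$respondents,
               visits = sim$visits)
  for (nm in names(tabs)) {
    write.csv(tabs[[nm]], file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE, na = "")
    if (format == "parquet" && requireNamespace("arrow", quietly = TRUE))
      arrow::write_parquet(tabs[[nm]], file.path(dir, paste0(nm, ".parquet")))
  }
  write.csv(sim$truth$visits, file.path(dir, "truth_visits.csv"),
            row.names = FALSE, na = "")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(sage_schema(), file.path(dir, "schema.json"),
                         dataframe = "rows", pretty = TRUE)
  }
  invisible(dir)
}

check_table <- function(df, spec, what) {
  require_columns(df, spec$column, what)
  for (i in seq_len(nrow(spec))) {
    col <- spec$column[i]
    v <- df[[col]]
    if (!spec$allow_na[i] && anyNA(v)) {
      stop(sprintf("%s: column '%s' has missing values at row(s) %s", what, col,
                   paste(head(which(is.na(v)), 5), collapse = ", ")),
           call. = FALSE)
    }
    if (spec$type[i] %in% c("numeric", "integer") && !is.numeric(v))
      stop(sprintf("%s: column '%s' must be numeric", what, col), call. = FALSE)
  }
  invisible(df)
}

#' Read and validate survey tables
#'
#' Reads the households, respondents and visits tables, validates them
#' against the published schema, enforces referential integrity (every visit
#' belongs to a respondent, every respondent to a household), rejects
#' negative costs and nonpositive weights, and extracts the survey design.
#'
#' @param paths either a directory containing `households.csv`,
#'   `respondents.csv`, `visits.csv`, or a named list of the three file
#'   paths.
#' @param codebook reason codebook; when supplied, observed `reason_code`s
#'   are validated against it.
#' @param quiet suppress the validation summary message.
#' @return list with `households`, `respondents`, `visits`, `design`.
#' @export
read_survey <- function(paths, codebook = default_codebook(), quiet = FALSE) {
  if (is.character(paths) && length(paths) == 1L) {
    paths <- list(households = file.path(paths, "households.csv"),
                  respondents = file.path(paths, "respondents.csv"),
                  visits = file.path(paths, "visits.csv"))
  }
  for (nm in c("households", "respondents", "visits")) {
    if (!file.exists(paths[[nm]]))
      stop(sprintf("file not found: %s", paths[[nm]]), call. = FALSE)
  }
  schema <- sage_schema()
  households <- read.csv(paths$households, stringsAsFactors = FALSE,
                         colClasses = setNames(schema$households$type,
                                               schema$households$column))
  respondents <- read.csv(paths$respondents, stringsAsFactors = FALSE,
                          colClasses = setNames(schema$respondents$type,
                                                schema$respondents$column))
  visits <- read.csv(paths$visits, stringsAsFactors = FALSE, na.strings = "",
                     colClasses = setNames(schema$visits$type,
                                           schema$visits$column))
  validate_survey(households, respondents, visits, codebook, quiet = quiet)
}

#' Validate in-memory survey tables
#'
#' Same checks as [read_survey()] for tables already in R.
#' @inheritParams read_survey
#' @param households,respondents,visits the three tables.
#' @return list with validated `households`, `respondents`, `visits`,
#'   `design`.
#' @export
validate_survey <- function(households, respondents, visits,
                            codebook = default_codebook(), quiet = FALSE) {
  schema <- sage_schema()
  check_table(households, schema$households, "households")
  check_table(respondents, schema$respondents, "respondents")
  check_table(visits, schema$visits, "visits")

  if (any(households$weight <= 0))
    stop("households: weights must be positive", call. = FALSE)
  if (anyDuplicated(households$household_id))
    stop("households: duplicate household_id", call. = FALSE)
  if (anyDuplicated(respondents$respondent_id))
    stop("respondents: duplicate respondent_id", call. = FALSE)
  orphan_r <- !(respondents$household_id %in% households$household_id)
  if (any(orphan_r))
    stop(sprintf("integrity error: %d respondent(s) reference unknown households (e.g. %s)",
                 sum(orphan_r), respondents$respondent_id[which(orphan_r)[1]]),
         call. = FALSE)
  orphan_v <- !(visits$respondent_id %in% respondents$respondent_id)
  if (any(orphan_v))
    stop(sprintf("integrity error: %d visit(s) reference unknown respondents (e.g. %s)",
                 sum(orphan_v), visits$visit_id[which(orphan_v)[1]]),
         call. = FALSE)
  if (any(visits$oop_cost < 0, na.rm = TRUE))
    stop("visits: negative oop_cost is invalid", call. = FALSE)
  if (nrow(visits) && any(visits$rank < 1, na.rm = TRUE))
    stop("visits: recency rank must be >= 1", call. = FALSE)
  if (!is.null(codebook)) {
    obs_codes <- visits$reason_code[!is.na(visits$reason_code)]
    invisible(map_reason_to_group(obs_codes, codebook))
  }
  if (!quiet) {
    message(sprintf("survey validated: %d households, %d respondents, %d visits (%d with observed cause, %d with observed cost)",
                    nrow(households), nrow(respondents), nrow(visits),
                    sum(!is.na(visits$cause)), sum(!is.na(visits$oop_cost))))
  }
  list(households = households, respondents = respondents, visits = visits,
       design = households[, c("household_id", "stratum", "psu", "weight")])
}
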