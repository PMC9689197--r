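# CSV dialects:
#   multiplier table: sex,age_years,age_months,multiplier
#   growth database:  sex,percentile,age_years,age_months,sitting_height_cm
#   multiplier set:   sex,percentile,age_years,age_months,multiplier
# All UTF-8, ages as integers. Line numbers in errors count the header as 1.

read_dialect <- function(path, header) {
  if (!file.exists(path)) {
    sm_stop(sprintf("file not found: %s", path), "spinemult_parse_error")
  }
  raw <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) sm_stop(sprintf("cannot read %s: %s", path,
                                        conditionMessage(e)),
                                "spinemult_parse_error"))
  if (!identical(names(raw), header)) {
    sm_stop(sprintf("%s: header must be exactly %s", path,
                    paste(header, collapse = ",")), "spinemult_parse_error")
  }
  raw
}

num_col <- function(raw, col, path, integer = FALSE) {
  x <- suppressWarnings(as.numeric(raw[[col]]))
  bad <- which(is.na(x) | (integer & x != trunc(x)))
  if (length(bad)) {
    sm_stop(sprintf("%s: line %d: invalid %s value %s", path, bad[1] + 1L,
                    col, dQuote(raw[[col]][bad[1]])), "spinemult_parse_error")
  }
  if (integer) as.integer(x) else x
}

#' Read and write multiplier tables in the table CSV dialect
#'
#' The dialect is `sex,age_years,age_months,multiplier`, one row per table
#' cell. Reading validates the full set of table invariants (see
#' [validate_table()]); writing serializes multipliers rounded half-even to 3
#' decimals, so `write` then `read` is the identity at 3-decimal precision.
#'
#' @param path File path.
#' @param provenance Provenance string for the loaded table (default: the
#'   path).
#' @return `read_multiplier_table()` returns a [multiplier_table()];
#'   `write_multiplier_table()` returns `path` invisibly.
#' @export
read_multiplier_table <- function(path, provenance = path) {
  raw <- read_dialect(path, c("sex", "age_years", "age_months", "multiplier"))
  cells <- data.frame(sex = raw$sex,
                      age_years = num_col(raw, "age_years", path, integer = TRUE),
                      age_months = num_col(raw, "age_months", path, integer = TRUE),
                      multiplier = num_col(raw, "multiplier", path),
                      stringsAsFactors = FALSE)
  multiplier_table(cells, provenance = provenance, validate = TRUE)
}

#' @rdname read_multiplier_table
#' @param table A [multiplier_table()].
#' @export
write_multiplier_table <- function(table, path) {
  if (!inherits(table, "multiplier_table")) {
    sm_stop("`table` must be a multiplier_table", "spinemult_domain_error")
  }
  df <- as.data.frame(table)
  df$multiplier <- sprintf("%.3f", round(df$multiplier, 3))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write growth databases in the growth CSV dialect
#'
#' The dialect is `sex,percentile,age_years,age_months,sitting_height_cm`, one
#' record per row. Reading rejects malformed rows, non-positive heights and
#' duplicate (sex, percentile, age) keys with the offending line number, and
#' requires a maturity-age record for every percentile curve present.
#'
#' @param path File path.
#' @param maturity_age Named vector of maturity ages per sex, in total months
#'   (default male 216, female 192).
#' @param provenance Provenance string (default: the path).
#' @return `read_growth_database()` returns a [growth_database()];
#'   `write_growth_database()` returns `path` invisibly.
#' @export
read_growth_database <- function(path,
                                 maturity_age = c(male = 216L, female = 192L),
                                 provenance = path) {
  raw <- read_dialect(path, c("sex", "percentile", "age_years", "age_months",
                              "sitting_height_cm"))
  rec <- data.frame(sex = raw$sex, percentile = raw$percentile,
                    age_years = num_col(raw, "age_years", path, integer = TRUE),
                    age_months = num_col(raw, "age_months", path, integer = TRUE),
                    sitting_height_cm = num_col(raw, "sitting_height_cm", path),
                    stringsAsFactors = FALSE)
  bad_sex <- which(!rec$sex %in% c("male", "female"))
  if (length(bad_sex)) {
    sm_stop(sprintf("%s: line %d: sex must be male or female, got %s", path,
                    bad_sex[1] + 1L, dQuote(rec$sex[bad_sex[1]])),
            "spinemult_parse_error")
  }
  bad_h <- which(rec$sitting_height_cm <= 0)
  if (length(bad_h)) {
    sm_stop(sprintf("%s: line %d: non-positive sitting height", path,
                    bad_h[1] + 1L), "spinemult_parse_error")
  }
  dup <- which(duplicated(rec[c("sex", "percentile", "age_years", "age_months")]))
  if (length(dup)) {
    sm_stop(sprintf("%s: line %d: duplicate record for (%s, %s, %d+%d)", path,
                    dup[1] + 1L, rec$sex[dup[1]], rec$percentile[dup[1]],
                    rec$age_years[dup[1]], rec$age_months[dup[1]]),
            "spinemult_parse_error")
  }
  growth_database(rec, maturity_age = maturity_age, provenance = provenance)
}

#' @rdname read_growth_database
#' @param db A [growth_database()].
#' @export
write_growth_database <- function(db, path) {
  if (!inherits(db, "growth_database")) {
    sm_stop("`db` must be a growth_database", "spinemult_domain_error")
  }
  r <- db$records
  df <- data.frame(sex = r$sex, percentile = r$percentile,
                   age_years = r$month %/% 12L, age_months = r$month %% 12L,
                   sitting_height_cm = sprintf("%.6f", r$sitting_height),
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write multiplier sets
#'
#' The dialect is `sex,percentile,age_years,age_months,multiplier`.
#' Multipliers are written at 6 decimal places (derived sets carry more
#' precision than the 3-decimal printed tables).
#'
#' @param path File path.
#' @param maturity_age Optional named maturity ages per sex for validation.
#' @param provenance Provenance string (default: the path).
#' @return `read_multiplier_set()` returns a [multiplier_set()];
#'   `write_multiplier_set()` returns `path` invisibly.
#' @export
read_multiplier_set <- function(path, maturity_age = NULL, provenance = path) {
  raw <- read_dialect(path, c("sex", "percentile", "age_years", "age_months",
                              "multiplier"))
  multiplier_set(
    data.frame(sex = raw$sex, percentile = raw$percentile,
               month = 12L * num_col(raw, "age_years", path, integer = TRUE) +
                 num_col(raw, "age_months", path, integer = TRUE),
               multiplier = num_col(raw, "multiplier", path),
               stringsAsFactors = FALSE),
    maturity_age = maturity_age, provenance = provenance)
}

#' @rdname read_multiplier_set
#' @param mset A [multiplier_set()].
#' @export
write_multiplier_set <- function(mset, path) {
  if (!inherits(mset, "multiplier_set")) {
    sm_stop("`mset` must be a multiplier_set", "spinemult_domain_error")
  }
  v <- mset$values
  df <- data.frame(sex = v$sex, percentile = v$percentile,
                   age_years = v$month %/% 12L, age_months = v$month %% 12L,
                   multiplier = sprintf("%.6f", v$multiplier),
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
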