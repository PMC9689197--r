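#' Age- and sex-specific multiplier tables
#'
#' A multiplier table maps age (on a contiguous monthly grid) and sex to the
#' dimensionless multiplier M, the ratio of the dimension at skeletal maturity
#' to the dimension at that age. Within each sex, M is at least 1, decreases
#' monotonically with age, and equals exactly 1 at the maturity age (girls
#' 16y, boys 18y in the packaged sitting-height tables).
#'
#' `multiplier_table()` builds a table from a data frame in the table CSV
#' dialect (columns `sex`, `age_years`, `age_months`, `multiplier`); by default
#' it refuses a table that violates any invariant. Use `validate = FALSE`
#' together with [validate_table()] to inspect a suspect table instead.
#'
#' @param cells Data frame with columns `sex` ("male"/"female"), `age_years`,
#'   `age_months` (integers), `multiplier` (numeric).
#' @param provenance Free-text origin of the table, carried along for
#'   reporting.
#' @param validate If `TRUE` (default), stop with the first violated invariant.
#' @return An object of class `multiplier_table` with fields `entries`
#'   (data frame `sex`, `month`, `multiplier`), per-sex `first_age` and
#'   `maturity_age` (in total months), and `provenance`.
#' @seealso [sitting_height_multipliers()], [lookup_multiplier()],
#'   [validate_table()]
#' @export
multiplier_table <- function(cells, provenance = "user", validate = TRUE) {
  need <- c("sex", "age_years", "age_months", "multiplier")
  if (!is.data.frame(cells) || !all(need %in% names(cells))) {
    sm_stop(sprintf("`cells` must be a data frame with columns %s",
                    paste(need, collapse = ", ")), "spinemult_table_error")
  }
  if (nrow(cells) == 0L) sm_stop("multiplier table has no entries", "spinemult_table_error")
  if (!all(cells$sex %in% c("male", "female"))) {
    sm_stop('table `sex` values must be "male" or "female"', "spinemult_table_error")
  }
  if (anyNA(cells[need]) || !is.numeric(cells$multiplier) ||
      any(!is.finite(cells$multiplier))) {
    sm_stop("table contains missing or non-numeric cells", "spinemult_table_error")
  }
  month <- 12L * as.integer(cells$age_years) + as.integer(cells$age_months)
  if (any(month < 0)) sm_stop("table contains negative ages", "spinemult_table_error")
  entries <- data.frame(sex = as.character(cells$sex), month = month,
                        multiplier = as.numeric(cells$multiplier),
                        stringsAsFactors = FALSE)
  dup <- duplicated(entries[c("sex", "month")])
  if (any(dup)) {
    d <- entries[which(dup)[1], ]
    sm_stop(sprintf("duplicate table entry: %s at %d months", d$sex, d$month),
            "spinemult_table_error")
  }
  entries <- entries[order(entries$sex, entries$month), , drop = FALSE]
  rownames(entries) <- NULL
  obj <- structure(
    list(entries = entries,
         first_age = tapply(entries$month, entries$sex, min),
         maturity_age = tapply(entries$month, entries$sex, max),
         provenance = provenance),
    class = "multiplier_table")
  if (validate) {
    report <- validate_table(obj)
    if (nrow(report) > 0L) {
      v <- report[1L, ]
      sm_stop(sprintf("invalid multiplier table (%s): %s", v$invariant, v$message),
              "spinemult_table_error")
    }
  }
  obj
}

# Cache for the packaged table (parsed once per session).
.pkg_cache <- new.env(parent = emptyenv())

#' The packaged sitting-height multiplier tables
#'
#' Returns the published monthly sitting-height multipliers: boys from 0y3m to
#' maturity at 18y0m (M = 1.000), girls from 0y3m to maturity at 16y0m.
#' Ages 0y1m and 0y2m carry no published value and are treated as below the
#' table domain. Values are stored exactly as printed, to three decimals.
#'
#' The fixture is re-validated on first load; a corrupted installation raises
#' an integrity error naming the first violated invariant.
#'
#' @return A [multiplier_table()].
#' @examples
#' tab <- sitting_height_multipliers()
#' lookup_multiplier(tab, "male", age_ym(7, 6))$multiplier  # 1.364
#' @export
sitting_height_multipliers <- function() {
  if (is.null(.pkg_cache$packaged)) {
    path <- system.file("extdata", "sitting_height_multipliers.csv",
                        package = "spinemult", mustWork = TRUE)
    tab <- read_multiplier_table(path, provenance = "packaged sitting-height tables")
    ok <- identical(sort(names(tab$first_age)), c("female", "male")) &&
      tab$first_age[["male"]] == 3L && tab$maturity_age[["male"]] == 216L &&
      tab$first_age[["female"]] == 3L && tab$maturity_age[["female"]] == 192L
    if (!ok) {
      sm_stop("packaged fixture corrupt: age extents differ from the published tables",
              "spinemult_table_error")
    }
    .pkg_cache$packaged <- tab
  }
  .pkg_cache$packaged
}

#' Look up the multiplier for a sex and age
#'
#' Exact lookup on the monthly grid; no interpolation is ever performed
#' (decimal ages snap to the month via [parse_decimal_age()]). Ages below the
#' table's first age raise an under-age error. Ages past maturity raise an
#' over-age error unless `clamp_post_maturity = TRUE`, in which case the
#' multiplier is 1 (no growth remains) and the result is flagged.
#'
#' @param table A [multiplier_table()].
#' @param sex `"male"` or `"female"`.
#' @param age Age in any form accepted by [as_age_ym()].
#' @param clamp_post_maturity Return M = 1 with a flag for post-maturity ages
#'   instead of raising. Default `FALSE`: library callers must opt in.
#' @return A list with `multiplier` (numeric) and `post_maturity` (logical).
#' @examples
#' tab <- sitting_height_multipliers()
#' lookup_multiplier(tab, "female", "10+0")     # 1.178
#' lookup_multiplier(tab, "male", 25, clamp_post_maturity = TRUE)
#' @export
lookup_multiplier <- function(table, sex, age, clamp_post_maturity = FALSE) {
  if (!inherits(table, "multiplier_table")) {
    sm_stop("`table` must be a multiplier_table", "spinemult_domain_error")
  }
  sex <- match_sex(sex)
  age <- as_age_ym(age)
  m <- total_months(age)
  if (!sex %in% names(table$first_age)) {
    sm_stop(sprintf("table has no entries for sex %s", dQuote(sex)),
            "spinemult_domain_error")
  }
  if (m < table$first_age[[sex]]) {
    sm_stop(sprintf("age %s is below the first tabulated age for %s (%d months)",
                    format(age), sex, table$first_age[[sex]]),
            "spinemult_underage_error")
  }
  if (m > table$maturity_age[[sex]]) {
    if (clamp_post_maturity) {
      return(list(multiplier = 1.0, post_maturity = TRUE))
    }
    sm_stop(sprintf(
      "age %s is past skeletal maturity for %s (%d months); set clamp_post_maturity = TRUE for M = 1",
      format(age), sex, table$maturity_age[[sex]]), "spinemult_overage_error")
  }
  e <- table$entries
  val <- e$multiplier[e$sex == sex & e$month == m]
  list(multiplier = val, post_maturity = FALSE)
}

#' Check a multiplier table against its structural invariants
#'
#' Reports, never raises. Checks per sex: the monthly grid is contiguous from
#' the first age to maturity; every multiplier is at least 1; multipliers are
#' non-increasing with age; the maturity-age multiplier is exactly 1.
#'
#' @param table A [multiplier_table()] (typically built with
#'   `validate = FALSE`).
#' @return A data frame with columns `sex`, `month`, `invariant`, `message`;
#'   zero rows iff the table is valid.
#' @export
validate_table <- function(table) {
  if (!inherits(table, "multiplier_table")) {
    sm_stop("`table` must be a multiplier_table", "spinemult_domain_error")
  }
  bad <- list()
  note <- function(sex, month, invariant, message) {
    bad[[length(bad) + 1L]] <<- data.frame(
      sex = sex, month = as.integer(month), invariant = invariant,
      message = message, stringsAsFactors = FALSE)
  }
  for (sex in sort(names(table$first_age))) {
    e <- table$entries[table$entries$sex == sex, , drop = FALSE]
    e <- e[order(e$month), , drop = FALSE]
    full <- seq(min(e$month), max(e$month))
    missing <- setdiff(full, e$month)
    for (m in missing) {
      note(sex, m, "contiguous_monthly_grid",
           sprintf("no entry at %d months for %s", m, sex))
    }
    low <- which(e$multiplier < 1 - 1e-9)
    for (i in low) {
      note(sex, e$month[i], "multiplier_at_least_one",
           sprintf("M = %s at %d months for %s is below 1",
                   format(e$multiplier[i]), e$month[i], sex))
    }
    if (nrow(e) > 1L) {
      up <- which(diff(e$multiplier) > 1e-9)
      for (i in up) {
        note(sex, e$month[i + 1L], "non_increasing_with_age",
             sprintf("M rises from %s to %s between %d and %d months for %s",
                     format(e$multiplier[i]), format(e$multiplier[i + 1L]),
                     e$month[i], e$month[i + 1L], sex))
      }
    }
    last <- e$multiplier[nrow(e)]
    if (abs(last - 1) > 1e-9) {
      note(sex, max(e$month), "maturity_multiplier_is_one",
           sprintf("M = %s at maturity (%d months) for %s; must equal 1",
                   format(last), max(e$month), sex))
    }
  }
  if (length(bad) == 0L) {
    return(data.frame(sex = character(), month = integer(),
                      invariant = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, bad)
  rownames(out) <- NULL
  out
}

#' @export
print.multiplier_table <- function(x, ...) {
  cat("<multiplier_table>", x$provenance, "\n")
  for (sex in sort(names(x$first_age))) {
    n <- sum(x$entries$sex == sex)
    cat(sprintf("  %s: %d monthly entries, %d-%d months (M %s-%s)\n",
                sex, n, x$first_age[[sex]], x$maturity_age[[sex]],
                fmt_mult(max(x$entries$multiplier[x$entries$sex == sex])),
                fmt_mult(min(x$entries$multiplier[x$entries$sex == sex]))))
  }
  invisible(x)
}

#' @export
as.data.frame.multiplier_table <- function(x, ...) {
  data.frame(sex = x$entries$sex,
             age_years = x$entries$month %/% 12L,
             age_months = x$entries$month %% 12L,
             multiplier = x$entries$multiplier,
             stringsAsFactors = FALSE)
}
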