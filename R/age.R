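#' Chronological age in completed years and months
#'
#' The multiplier tables are indexed by age on a monthly grid written
#' "years + months" (e.g. `7+6` is seven years six months). `age_ym()`
#' constructs such an age; [total_months()] converts it to the integer month
#' index used for table lookups.
#'
#' @param years Non-negative integer years.
#' @param months Integer months, `0 <= months <= 11`.
#' @return An object of class `age_ym` with fields `years` and `months`.
#' @examples
#' age_ym(7, 6)
#' total_months(age_ym(7, 6))
#' @export
age_ym <- function(years, months = 0L) {
  if (!is.numeric(years) || length(years) != 1L || !is.finite(years) ||
      years < 0 || years != trunc(years)) {
    sm_stop("`years` must be a single non-negative integer", "spinemult_domain_error")
  }
  if (!is.numeric(months) || length(months) != 1L || !is.finite(months) ||
      months != trunc(months) || months < 0 || months > 11) {
    sm_stop("`months` must be a single integer in 0..11", "spinemult_domain_error")
  }
  structure(list(years = as.integer(years), months = as.integer(months)),
            class = "age_ym")
}

#' @rdname age_ym
#' @param age An age: an `age_ym`, a string `"Y+M"` (e.g. `"10+6"`), or a
#'   decimal number of years (routed through [parse_decimal_age()]).
#' @export
total_months <- function(age) {
  age <- as_age_ym(age)
  12L * age$years + age$months
}

#' Convert a decimal age in years to a whole-month age
#'
#' The table grid is monthly, so decimal ages are snapped to the nearest month.
#' Exact half-month ties round down (toward the younger age): sub-month
#' precision is spurious and the younger month is the conservative choice for
#' growth-remaining estimates.
#'
#' @param years A single non-negative decimal number of years.
#' @return An [age_ym()] object.
#' @examples
#' parse_decimal_age(10.5)  # 10+6
#' parse_decimal_age(0.25)  # 0+3
#' @export
parse_decimal_age <- function(years) {
  if (!is.numeric(years) || length(years) != 1L || !is.finite(years) || years < 0) {
    sm_stop("`years` must be a single non-negative number", "spinemult_domain_error")
  }
  tm <- years * 12
  frac <- tm - floor(tm)
  m <- if (abs(frac - 0.5) <= 1e-9) floor(tm) else round(tm)
  m <- as.integer(m)
  age_ym(m %/% 12L, m %% 12L)
}

#' Parse an age written as "Y+M" or as decimal years
#'
#' `"10+6"` parses to ten years six months (the notation the printed tables
#' use); anything numeric-looking is treated as decimal years.
#'
#' @param text A single string, e.g. `"10+6"` or `"10.5"`.
#' @return An [age_ym()] object.
#' @export
parse_age <- function(text) {
  if (inherits(text, "age_ym")) return(text)
  if (is.numeric(text)) return(parse_decimal_age(text))
  if (!is.character(text) || length(text) != 1L) {
    sm_stop("age must be an age_ym, a \"Y+M\" string, or decimal years",
            "spinemult_domain_error")
  }
  text <- trimws(text)
  if (grepl("^\\d+\\s*\\+\\s*\\d+$", text)) {
    parts <- as.integer(strsplit(text, "\\+")[[1]])
    return(age_ym(parts[1], parts[2]))
  }
  if (grepl("^\\d*\\.?\\d+$", text)) {
    return(parse_decimal_age(as.numeric(text)))
  }
  sm_stop(sprintf("cannot parse age %s", dQuote(text)), "spinemult_domain_error")
}

#' @rdname parse_age
#' @param x An age in any accepted form.
#' @export
as_age_ym <- function(x) parse_age(x)

#' @export
format.age_ym <- function(x, ...) sprintf("%d+%d", x$years, x$months)

#' @export
print.age_ym <- function(x, ...) {
  cat("<age>", format(x), sprintf("(%d months)\n", total_months(x)))
  invisible(x)
}
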