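#' Percentile-structured growth-reference database
#'
#' A growth reference records sitting height by sex, percentile (or SD line)
#' and age. Multipliers are derived from it by dividing the sitting height at
#' skeletal maturity by the sitting height at each age within the same sex and
#' percentile curve. Percentile labels are opaque strings; no ordering or
#' spacing between them is assumed.
#'
#' @param records Data frame with columns `sex` ("male"/"female"),
#'   `percentile` (label), `age_years`, `age_months` (integers),
#'   `sitting_height_cm` (positive).
#' @param maturity_age Named integer vector (total months) giving the maturity
#'   age per sex; defaults to the packaged 216 (male) / 192 (female).
#' @param provenance Free-text origin.
#' @param validate If `TRUE` (default), enforce the invariants: positive
#'   heights, unique (sex, percentile, age) keys, and a maturity-age record
#'   for every (sex, percentile) curve present.
#' @return An object of class `growth_database` with fields `records`
#'   (data frame `sex`, `percentile`, `month`, `sitting_height`),
#'   `maturity_age`, `provenance`.
#' @seealso [derive_multipliers()], [read_growth_database()]
#' @export
growth_database <- function(records,
                            maturity_age = c(male = 216L, female = 192L),
                            provenance = "user", validate = TRUE) {
  need <- c("sex", "percentile", "age_years", "age_months", "sitting_height_cm")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    sm_stop(sprintf("`records` must be a data frame with columns %s",
                    paste(need, collapse = ", ")), "spinemult_data_error")
  }
  if (nrow(records) == 0L) sm_stop("growth database has no records", "spinemult_data_error")
  if (!all(records$sex %in% c("male", "female"))) {
    sm_stop('record `sex` values must be "male" or "female"', "spinemult_data_error")
  }
  rec <- data.frame(sex = as.character(records$sex),
                    percentile = as.character(records$percentile),
                    month = 12L * as.integer(records$age_years) +
                      as.integer(records$age_months),
                    sitting_height = as.numeric(records$sitting_height_cm),
                    stringsAsFactors = FALSE)
  if (validate) {
    bad <- which(!is.finite(rec$sitting_height) | rec$sitting_height <= 0)
    if (length(bad)) {
      sm_stop(sprintf("non-positive sitting height in record %d (%s, %s, %d months)",
                      bad[1], rec$sex[bad[1]], rec$percentile[bad[1]],
                      rec$month[bad[1]]), "spinemult_data_error")
    }
    dup <- which(duplicated(rec[c("sex", "percentile", "month")]))
    if (length(dup)) {
      d <- rec[dup[1], ]
      sm_stop(sprintf("duplicate record for (%s, %s, %d months)",
                      d$sex, d$percentile, d$month), "spinemult_data_error")
    }
    for (sex in unique(rec$sex)) {
      if (!sex %in% names(maturity_age)) {
        sm_stop(sprintf("no maturity age given for sex %s", dQuote(sex)),
                "spinemult_data_error")
      }
      sub <- rec[rec$sex == sex, ]
      for (p in unique(sub$percentile)) {
        if (!any(sub$percentile == p & sub$month == maturity_age[[sex]])) {
          sm_stop(sprintf(
            "percentile %s (%s) has no record at the maturity age (%d months)",
            dQuote(p), sex, maturity_age[[sex]]), "spinemult_derivation_error")
        }
      }
    }
  }
  rec <- rec[order(rec$sex, rec$percentile, rec$month), , drop = FALSE]
  rownames(rec) <- NULL
  structure(list(records = rec,
                 maturity_age = maturity_age,
                 provenance = provenance),
            class = "growth_database")
}

#' A set of multipliers indexed by sex, percentile and age
#'
#' The per-percentile analogue of a [multiplier_table()]: one multiplier per
#' (sex, percentile, age), typically produced by [derive_multipliers()] or
#' [ground_truth()].
#'
#' @param values Data frame with columns `sex`, `percentile`, `month` (total
#'   months), `multiplier` (> 0).
#' @param maturity_age Optional named vector of maturity ages per sex; when
#'   supplied, every percentile must carry M = 1 there.
#' @param provenance Free-text origin.
#' @param validate Enforce the invariants (default `TRUE`).
#' @return An object of class `multiplier_set`.
#' @export
multiplier_set <- function(values, maturity_age = NULL, provenance = "user",
                           validate = TRUE) {
  need <- c("sex", "percentile", "month", "multiplier")
  if (!is.data.frame(values) || !all(need %in% names(values))) {
    sm_stop(sprintf("`values` must be a data frame with columns %s",
                    paste(need, collapse = ", ")), "spinemult_data_error")
  }
  values <- values[need]
  if (validate) {
    if (nrow(values) == 0L || any(!is.finite(values$multiplier)) ||
        any(values$multiplier <= 0)) {
      sm_stop("multiplier set must be non-empty with positive multipliers",
              "spinemult_data_error")
    }
    if (!is.null(maturity_age)) {
      for (sex in intersect(unique(values$sex), names(maturity_age))) {
        at <- values[values$sex == sex & values$month == maturity_age[[sex]], ]
        if (any(abs(at$multiplier - 1) > 1e-9)) {
          sm_stop(sprintf("multiplier at maturity differs from 1 for sex %s",
                          dQuote(sex)), "spinemult_data_error")
        }
      }
    }
  }
  values <- values[order(values$sex, values$percentile, values$month), ,
                   drop = FALSE]
  rownames(values) <- NULL
  structure(list(values = values, maturity_age = maturity_age,
                 provenance = provenance),
            class = "multiplier_set")
}

#' Derive multipliers from a growth database
#'
#' For every record, the multiplier is the sitting height at skeletal maturity
#' of the same (sex, percentile) curve divided by the sitting height at that
#' age: M = Lm / L. By construction M = 1 at the maturity age, and scaling a
#' whole percentile curve by any constant leaves its multipliers unchanged.
#'
#' @param db A [growth_database()].
#' @return A [multiplier_set()] with one multiplier per input record.
#' @examples
#' db <- growth_database(data.frame(
#'   sex = "female", percentile = "P50",
#'   age_years = c(5, 16), age_months = 0,
#'   sitting_height_cm = c(60, 90)))
#' derive_multipliers(db)$values$multiplier  # 1.5 at 5y, 1 at maturity
#' @export
derive_multipliers <- function(db) {
  if (!inherits(db, "growth_database")) {
    sm_stop("`db` must be a growth_database", "spinemult_data_error")
  }
  rec <- db$records
  mat_month <- db$maturity_age[rec$sex]
  is_mat <- rec$month == mat_month
  lm_tab <- rec[is_mat, c("sex", "percentile", "sitting_height")]
  names(lm_tab)[3] <- "mature_height"
  miss <- unique(rec[!paste(rec$sex, rec$percentile) %in%
                       paste(lm_tab$sex, lm_tab$percentile),
                     c("sex", "percentile")])
  if (nrow(miss)) {
    sm_stop(sprintf("no maturity record for percentile %s (%s)",
                    dQuote(miss$percentile[1]), miss$sex[1]),
            "spinemult_derivation_error")
  }
  merged <- merge(rec, lm_tab, by = c("sex", "percentile"), sort = FALSE)
  out <- data.frame(sex = merged$sex, percentile = merged$percentile,
                    month = merged$month,
                    multiplier = merged$mature_height / merged$sitting_height,
                    stringsAsFactors = FALSE)
  multiplier_set(out, maturity_age = db$maturity_age,
                 provenance = paste0("derived from: ", db$provenance))
}

#' Cross-percentile variability of a multiplier set
#'
#' The multiplier method rests on percentile invariance: at a given age and
#' sex, multipliers are nearly identical across percentile curves. This
#' statistic quantifies the departure: at each (sex, age) the maximum absolute
#' deviation of the percentile multipliers from their cross-percentile mean,
#' summarized per sex (and pooled) by the unweighted mean over ages and the
#' maximum over ages.
#'
#' @param mset A [multiplier_set()].
#' @return An object of class `variability_report`: `per_age` (data frame
#'   `sex`, `month`, `n_percentiles`, `deviation`), `per_sex` (data frame
#'   `sex`, `mean_variability`, `max_variability`), and pooled
#'   `mean_variability` / `max_variability` across both sexes.
#' @export
variability_stats <- function(mset) {
  if (!inherits(mset, "multiplier_set")) {
    sm_stop("`mset` must be a multiplier_set", "spinemult_data_error")
  }
  v <- mset$values
  key <- paste(v$sex, v$month)
  dev <- tapply(v$multiplier, key, function(m) max(abs(m - mean(m))))
  npct <- tapply(v$multiplier, key, length)
  parts <- do.call(rbind, strsplit(names(dev), " ", fixed = TRUE))
  per_age <- data.frame(sex = parts[, 1], month = as.integer(parts[, 2]),
                        n_percentiles = as.integer(npct),
                        deviation = as.numeric(dev),
                        stringsAsFactors = FALSE)
  per_age <- per_age[order(per_age$sex, per_age$month), , drop = FALSE]
  rownames(per_age) <- NULL
  per_sex <- aggregate(deviation ~ sex, per_age, mean)
  names(per_sex)[2] <- "mean_variability"
  per_sex$max_variability <- aggregate(deviation ~ sex, per_age, max)$deviation
  structure(list(per_age = per_age,
                 per_sex = per_sex,
                 mean_variability = mean(per_age$deviation),
                 max_variability = max(per_age$deviation)),
            class = "variability_report")
}

#' Mean multiplier curve across percentiles
#'
#' Unweighted mean of the multipliers over percentile labels at each age, for
#' one sex. This is the curve used when comparing multiplier sets across
#' reference databases.
#'
#' @param mset A [multiplier_set()].
#' @param sex `"male"` or `"female"`.
#' @return Data frame with columns `month` and `multiplier`, sorted by age.
#' @export
mean_multiplier_curve <- function(mset, sex) {
  if (!inherits(mset, "multiplier_set")) {
    sm_stop("`mset` must be a multiplier_set", "spinemult_data_error")
  }
  sex <- match_sex(sex)
  v <- mset$values[mset$values$sex == sex, , drop = FALSE]
  if (nrow(v) == 0L) {
    sm_stop(sprintf("multiplier set has no entries for sex %s", dQuote(sex)),
            "spinemult_domain_error")
  }
  out <- aggregate(multiplier ~ month, v, mean)
  out <- out[order(out$month), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare two multiplier sets by polynomial regression
#'
#' Reference databases are compared through their mean multiplier curves: on
#' the ages the two sets share (matched exactly by total months, no
#' interpolation), a least-squares polynomial of the given degree is fitted
#' with set `b`'s mean curve as response and set `a`'s as predictor. Near-1 R2
#' and small residual RMSE indicate the two references encode the same
#' multiplier relationship. The raw maximum absolute difference between the
#' mean curves is reported alongside (pre-fit, so a constant offset shows up
#' here even when the regression absorbs it).
#'
#' @param a,b [multiplier_set()] objects (predictor and response).
#' @param sex `"male"` or `"female"`.
#' @param degree Polynomial degree (the default 3 suits the smooth, convex
#'   multiplier-vs-multiplier relationship; the CLI requires it explicitly).
#' @return An object of class `comparison_result`: `degree`, `r_squared`,
#'   `rmse`, `max_abs_diff`, `n_shared_ages`.
#' @export
compare_multiplier_sets <- function(a, b, sex, degree = 3L) {
  if (!is.numeric(degree) || length(degree) != 1L || degree < 1 ||
      degree != trunc(degree)) {
    sm_stop("`degree` must be a positive integer", "spinemult_domain_error")
  }
  ca <- mean_multiplier_curve(a, sex)
  cb <- mean_multiplier_curve(b, sex)
  shared <- merge(ca, cb, by = "month", suffixes = c("_a", "_b"))
  n <- nrow(shared)
  if (n < degree + 1) {
    sm_stop(sprintf("only %d shared ages; need at least degree + 1 = %d",
                    n, degree + 1), "spinemult_domain_error")
  }
  x <- shared$multiplier_a
  y <- shared$multiplier_b
  fit <- tryCatch(
    lm(y ~ poly(x, degree = degree, raw = TRUE)),
    error = function(e) sm_stop(
      sprintf("polynomial fit of degree %d failed: %s", degree,
              conditionMessage(e)), "spinemult_domain_error"))
  res <- residuals(fit)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot <= .Machine$double.eps^2) 1 else 1 - ss_res / ss_tot
  structure(list(degree = as.integer(degree),
                 r_squared = min(max(r2, 0), 1),
                 rmse = sqrt(mean(res^2)),
                 max_abs_diff = max(abs(x - y)),
                 n_shared_ages = n),
            class = "comparison_result")
}

#' @export
print.growth_database <- function(x, ...) {
  r <- x$records
  cat("<growth_database>", x$provenance, "\n")
  for (sex in sort(unique(r$sex))) {
    sub <- r[r$sex == sex, ]
    cat(sprintf("  %s: %d records, %d percentile curves, ages %d-%d months (maturity %d)\n",
                sex, nrow(sub), length(unique(sub$percentile)),
                min(sub$month), max(sub$month), x$maturity_age[[sex]]))
  }
  invisible(x)
}

#' @export
print.multiplier_set <- function(x, ...) {
  v <- x$values
  cat("<multiplier_set>", x$provenance, "\n")
  cat(sprintf("  %d values, %d percentile curves, M %s-%s\n", nrow(v),
              length(unique(paste(v$sex, v$percentile))),
              fmt_mult(min(v$multiplier)), fmt_mult(max(v$multiplier))))
  invisible(x)
}

#' @export
print.variability_report <- function(x, ...) {
  cat(render_report(x, "text"))
  invisible(x)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(render_report(x, "text"))
  invisible(x)
}
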