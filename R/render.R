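#' Construct a prediction record
#'
#' Low-level constructor behind the clinical prediction functions, exported so
#' callers (including the CLI) can build renderable records for derived
#' quantities such as the limb-lengthening target, where the operation itself
#' returns a bare number.
#'
#' @param formula Formula identifier string.
#' @param predicted_value Non-negative result, cm.
#' @param multiplier_used Multiplier M applied, `>= 1`, or `NA` when the
#'   formula does not use the table.
#' @param inputs Named list of echoed inputs.
#' @param post_maturity Logical flag.
#' @return An object of class `prediction_result`.
#' @export
as_prediction_result <- function(formula, predicted_value,
                                 multiplier_used = NA_real_,
                                 inputs = list(), post_maturity = FALSE) {
  prediction_result(formula, predicted_value, multiplier_used, inputs,
                    post_maturity)
}

fmt_input <- function(name, value) {
  if (is.numeric(value) && value == trunc(value) &&
      name %in% c("n_fused")) {
    sprintf("%d", as.integer(value))
  } else if (is.numeric(value)) {
    paste0(fmt_cm(value), " cm")
  } else {
    as.character(value)
  }
}

# The 47/53 ratio prints as "88.6%", truncated (not rounded) to one decimal,
# matching its conventional citation.
vitruvian_ratio_label <- function() {
  sprintf("%.1f%% (47/53)", floor(100 * 47 / 53 * 10) / 10)
}

#' Render a result as text, JSON or CSV
#'
#' Deterministic, byte-identical rendering of prediction records, variability
#' reports and comparison results. Multipliers are displayed to 3 decimals and
#' centimetre quantities to 2; JSON carries full precision.
#'
#' @param x A `prediction_result`, `variability_report` or
#'   `comparison_result`.
#' @param format `"text"`, `"json"` (a single JSON object per line) or
#'   `"csv"`.
#' @return A single character string (with trailing newline).
#' @export
render_report <- function(x, format = c("text", "json", "csv")) {
  UseMethod("render_report")
}

#' @export
render_report.prediction_result <- function(x, format = c("text", "json", "csv")) {
  format <- match.arg(format)
  if (format == "text") {
    lines <- c(
      paste0("formula: ", x$formula),
      paste0("inputs: ", paste(vapply(names(x$inputs), function(n)
        sprintf("%s=%s", n, fmt_input(n, x$inputs[[n]])), character(1)),
        collapse = ", ")),
      if (x$formula %in% c("limb_lengthening_target", "mature_standing_height"))
        paste0("sitting:standing ratio: 53%, limb target ", vitruvian_ratio_label()),
      paste0("multiplier: ",
             if (is.na(x$multiplier_used)) "-" else fmt_mult(x$multiplier_used)),
      paste0("predicted: ", fmt_cm(x$predicted_value), " cm"),
      paste0("post_maturity: ", if (isTRUE(x$post_maturity)) "yes" else "no"))
    return(paste0(paste(lines, collapse = "\n"), "\n"))
  }
  if (format == "json") {
    return(paste0(jsonlite::toJSON(
      list(formula = x$formula, inputs = x$inputs,
           multiplier = x$multiplier_used,
           predicted_value = x$predicted_value,
           post_maturity = isTRUE(x$post_maturity)),
      auto_unbox = TRUE, digits = NA, na = "null"), "\n"))
  }
  df <- c(list(formula = x$formula), x$inputs,
          list(multiplier = x$multiplier_used,
               predicted_value = x$predicted_value,
               post_maturity = isTRUE(x$post_maturity)))
  paste0(paste(names(df), collapse = ","), "\n",
         paste(vapply(df, function(v) as.character(v), character(1)),
               collapse = ","), "\n")
}

#' @export
render_report.variability_report <- function(x, format = c("text", "json", "csv")) {
  format <- match.arg(format)
  if (format == "text") {
    lines <- "cross-percentile multiplier variability"
    for (i in seq_len(nrow(x$per_sex))) {
      s <- x$per_sex[i, ]
      lines <- c(lines, sprintf("  %s: mean %s, max %s (%d ages)", s$sex,
                                fmt_mult(s$mean_variability),
                                fmt_mult(s$max_variability),
                                sum(x$per_age$sex == s$sex)))
    }
    lines <- c(lines, sprintf("  pooled: mean %s, max %s",
                              fmt_mult(x$mean_variability),
                              fmt_mult(x$max_variability)))
    return(paste0(paste(lines, collapse = "\n"), "\n"))
  }
  if (format == "json") {
    return(paste0(jsonlite::toJSON(
      list(per_sex = x$per_sex, mean_variability = x$mean_variability,
           max_variability = x$max_variability, per_age = x$per_age),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"), "\n"))
  }
  con <- textConnection("out", "w", local = TRUE)
  write.csv(x$per_age, con, row.names = FALSE, quote = FALSE)
  close(con)
  paste0(paste(out, collapse = "\n"), "\n")
}

#' @export
render_report.comparison_result <- function(x, format = c("text", "json", "csv")) {
  format <- match.arg(format)
  if (format == "text") {
    lines <- c(
      sprintf("multiplier-set comparison (degree %d, %d shared ages, exact age match)",
              x$degree, x$n_shared_ages),
      sprintf("  R-squared: %.6f", x$r_squared),
      sprintf("  RMSE: %.6f", x$rmse),
      sprintf("  max |mean_a - mean_b| (pre-fit): %.6f", x$max_abs_diff))
    return(paste0(paste(lines, collapse = "\n"), "\n"))
  }
  rec <- list(degree = x$degree, r_squared = x$r_squared, rmse = x$rmse,
              max_abs_diff = x$max_abs_diff, n_shared_ages = x$n_shared_ages)
  if (format == "json") {
    return(paste0(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n"))
  }
  paste0(paste(names(rec), collapse = ","), "\n",
         paste(vapply(rec, as.character, character(1)), collapse = ","), "\n")
}
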