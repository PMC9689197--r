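#' @title Clinical predictions from sitting-height multipliers
#' @description Every clinical formula is a one-step arithmetic operation on
#'   the age- and sex-specific multiplier M: predicted mature sitting height
#'   is S x M; growth remaining in a spine segment of current length L is
#'   L x (M - 1); a single vertebra's mature height divides the segment
#'   prediction by the number of vertebrae in the segment (5 lumbar,
#'   12 thoracic); arthrodesis growth loss multiplies the per-vertebra growth
#'   remaining by the number of vertebrae fused.
#' @name clinical-predictions
NULL

prediction_result <- function(formula, predicted_value, multiplier_used,
                              inputs, post_maturity) {
  if (!is.na(multiplier_used) && multiplier_used < 1) {
    sm_stop("multiplier used in a prediction must be at least 1",
            "spinemult_domain_error")
  }
  if (predicted_value < 0) {
    sm_stop("predicted value must be non-negative", "spinemult_domain_error")
  }
  structure(list(formula = formula,
                 predicted_value = predicted_value,
                 multiplier_used = multiplier_used,
                 inputs = inputs,
                 post_maturity = post_maturity),
            class = "prediction_result")
}

#' Number of vertebrae in a spine segment
#'
#' The lumbar spine has 5 vertebrae, the thoracic spine 12; each vertebra is
#' assumed to contribute an equal share of its segment's growth.
#'
#' @param segment `"lumbar"` or `"thoracic"`.
#' @return Integer 5 or 12.
#' @export
vertebra_count <- function(segment) {
  if (!is.character(segment) || length(segment) != 1L ||
      !segment %in% c("lumbar", "thoracic")) {
    sm_stop('`segment` must be "lumbar" or "thoracic"', "spinemult_domain_error")
  }
  c(lumbar = 5L, thoracic = 12L)[[segment]]
}

#' Predict sitting height at skeletal maturity
#'
#' Mature sitting height is the current sitting height S times the multiplier
#' M for the child's sex and age.
#'
#' @param sitting_height Current sitting height S in cm.
#' @param sex `"male"` or `"female"`.
#' @param age Age in any form accepted by [as_age_ym()].
#' @param table Multiplier table; defaults to the packaged sitting-height
#'   tables.
#' @param clamp_post_maturity Treat post-maturity ages as M = 1 (flagged)
#'   instead of raising.
#' @return A `prediction_result`: `predicted_value` (cm), `multiplier_used`,
#'   echoed `inputs`, `post_maturity` flag, `formula` identifier.
#' @examples
#' p <- predict_mature_sitting_height(70, "female", "10+0")
#' p$predicted_value  # 70 * 1.178 = 82.46
#' @export
predict_mature_sitting_height <- function(sitting_height, sex, age,
                                          table = sitting_height_multipliers(),
                                          clamp_post_maturity = FALSE) {
  assert_scalar_positive(sitting_height, "sitting_height")
  sex <- match_sex(sex)
  age <- as_age_ym(age)
  lk <- lookup_multiplier(table, sex, age, clamp_post_maturity)
  prediction_result("mature_sitting_height",
                    sitting_height * lk$multiplier, lk$multiplier,
                    list(sitting_height = sitting_height, sex = sex,
                         age = format(age)),
                    lk$post_maturity)
}

#' Predict the mature height of a single vertebra
#'
#' The current segment length times M predicts the mature segment length;
#' dividing by the segment's vertebra count (5 lumbar, 12 thoracic) gives the
#' mature height of one vertebra, under the equal-contribution assumption.
#'
#' @param segment_length Current length of the named spine segment, cm.
#' @param segment `"lumbar"` or `"thoracic"`.
#' @inheritParams predict_mature_sitting_height
#' @return A `prediction_result` with the mature single-vertebra height in cm.
#' @examples
#' predict_single_vertebra_height(14, "lumbar", "male", "10+0")$predicted_value
#' # 14 * 1.263 / 5 = 3.5364
#' @export
predict_single_vertebra_height <- function(segment_length, segment, sex, age,
                                           table = sitting_height_multipliers(),
                                           clamp_post_maturity = FALSE) {
  assert_scalar_positive(segment_length, "segment_length")
  nv <- vertebra_count(segment)
  sex <- match_sex(sex)
  age <- as_age_ym(age)
  lk <- lookup_multiplier(table, sex, age, clamp_post_maturity)
  prediction_result("single_vertebra_height",
                    segment_length * lk$multiplier / nv, lk$multiplier,
                    list(segment_length = segment_length, segment = segment,
                         sex = sex, age = format(age)),
                    lk$post_maturity)
}

#' Growth remaining in a spine segment
#'
#' Growth remaining G is the segment's length at maturity minus its current
#' length: G = L x (M - 1). At maturity M = 1 and no growth remains.
#'
#' @param segment_length Current length L of the spine section, cm.
#' @inheritParams predict_mature_sitting_height
#' @return A `prediction_result` with the remaining growth in cm.
#' @examples
#' growth_remaining(80, "male", "10+0")$predicted_value  # 80 * 0.263 = 21.04
#' @export
growth_remaining <- function(segment_length, sex, age,
                             table = sitting_height_multipliers(),
                             clamp_post_maturity = FALSE) {
  assert_scalar_positive(segment_length, "segment_length")
  sex <- match_sex(sex)
  age <- as_age_ym(age)
  lk <- lookup_multiplier(table, sex, age, clamp_post_maturity)
  prediction_result("growth_remaining",
                    segment_length * (lk$multiplier - 1), lk$multiplier,
                    list(segment_length = segment_length, sex = sex,
                         age = format(age)),
                    lk$post_maturity)
}

#' Plan a spinal arthrodesis (fusion)
#'
#' Bundles the inputs of the growth-loss calculation: which segment, its
#' current length, how many vertebrae will be fused, and the child's sex and
#' age (the age at which growth in the fused levels stops).
#'
#' @param segment `"lumbar"` or `"thoracic"`.
#' @param segment_length Current length of the segment, cm.
#' @param n_fused Number of vertebrae to fuse, between 1 and the segment's
#'   vertebra count.
#' @param sex `"male"` or `"female"`.
#' @param age Age in any form accepted by [as_age_ym()].
#' @return An object of class `arthrodesis_plan`.
#' @export
arthrodesis_plan <- function(segment, segment_length, n_fused, sex, age) {
  nv <- vertebra_count(segment)
  assert_scalar_positive(segment_length, "segment_length")
  if (!is.numeric(n_fused) || length(n_fused) != 1L || !is.finite(n_fused) ||
      n_fused != trunc(n_fused) || n_fused < 1 || n_fused > nv) {
    sm_stop(sprintf("`n_fused` must be an integer in 1..%d for the %s segment",
                    nv, segment), "spinemult_domain_error")
  }
  structure(list(segment = segment, segment_length = segment_length,
                 n_fused = as.integer(n_fused), sex = match_sex(sex),
                 age = as_age_ym(age)),
            class = "arthrodesis_plan")
}

#' Growth lost to arthrodesis
#'
#' Fusing vertebrae arrests their growth; the loss is the growth remaining of
#' one vertebra in the segment, L x (M - 1) / vertebra count, times the number
#' of vertebrae fused Vf.
#'
#' @param plan An [arthrodesis_plan()].
#' @inheritParams predict_mature_sitting_height
#' @return A `prediction_result` with the predicted height loss in cm.
#' @examples
#' plan <- arthrodesis_plan("thoracic", 20, 3, "male", "8+0")
#' arthrodesis_growth_loss(plan)$predicted_value  # 20 * 0.338 / 12 * 3 = 1.69
#' @export
arthrodesis_growth_loss <- function(plan,
                                    table = sitting_height_multipliers(),
                                    clamp_post_maturity = FALSE) {
  if (!inherits(plan, "arthrodesis_plan")) {
    sm_stop("`plan` must be an arthrodesis_plan", "spinemult_domain_error")
  }
  nv <- vertebra_count(plan$segment)
  lk <- lookup_multiplier(table, plan$sex, plan$age, clamp_post_maturity)
  prediction_result("arthrodesis_growth_loss",
                    plan$segment_length * (lk$multiplier - 1) / nv * plan$n_fused,
                    lk$multiplier,
                    list(segment = plan$segment,
                         segment_length = plan$segment_length,
                         n_fused = plan$n_fused, sex = plan$sex,
                         age = format(plan$age)),
                    lk$post_maturity)
}

#' Vitruvian limb-lengthening target
#'
#' In adults of normal proportions, sitting height is 53% of standing height
#' and the lower extremity 47%. Limb lengthening in achondroplasia is planned
#' against the predicted mature sitting height: the target lower-extremity
#' length is 47/53 of it (about 88.6%). The ratio is applied as the exact
#' rational 47/53; 88.6% is a display rounding only.
#'
#' @param predicted_mature_sitting_height Predicted mature sitting height, cm.
#' @return Target lower-extremity length in cm (bare numeric).
#' @examples
#' limb_lengthening_target(53)  # 47
#' @export
limb_lengthening_target <- function(predicted_mature_sitting_height) {
  assert_scalar_positive(predicted_mature_sitting_height,
                         "predicted_mature_sitting_height")
  predicted_mature_sitting_height * (47 / 53)
}

#' Estimate mature standing height from mature sitting height
#'
#' Sitting height is 53% of standing height at maturity, so standing height is
#' sitting height divided by 0.53 (equivalently times 100/53).
#'
#' @inheritParams limb_lengthening_target
#' @return Estimated mature standing height in cm (bare numeric).
#' @examples
#' estimate_mature_standing_height(53)  # 100
#' @export
estimate_mature_standing_height <- function(predicted_mature_sitting_height) {
  assert_scalar_positive(predicted_mature_sitting_height,
                         "predicted_mature_sitting_height")
  predicted_mature_sitting_height * (100 / 53)
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(render_report(x, "text"))
  invisible(x)
}

#' @export
print.arthrodesis_plan <- function(x, ...) {
  cat(sprintf("<arthrodesis_plan> %s, %.2f cm, fuse %d of %d vertebrae, %s, age %s\n",
              x$segment, x$segment_length, x$n_fused, vertebra_count(x$segment),
              x$sex, format(x$age)))
  invisible(x)
}
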