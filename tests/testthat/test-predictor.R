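test_that("mature sitting height is current height times the multiplier", {
  p <- predict_mature_sitting_height(70, "female", "10+0")
  expect_equal(p$predicted_value, 70 * 1.178)  # 82.46
  expect_equal(p$multiplier_used, 1.178)
  expect_equal(p$formula, "mature_sitting_height")
  expect_false(p$post_maturity)
  expect_equal(predict_mature_sitting_height(50, "male", "7+6")$predicted_value,
               50 * 1.364)  # 68.20
  # identity at maturity
  expect_equal(predict_mature_sitting_height(88, "male", "18+0")$predicted_value, 88)
  expect_error(predict_mature_sitting_height(0, "male", "10+0"),
               class = "spinemult_domain_error")
  expect_error(predict_mature_sitting_height(70, "male", "0+1"),
               class = "spinemult_underage_error")
})

test_that("single-vertebra prediction divides the segment prediction evenly", {
  expect_equal(
    predict_single_vertebra_height(14, "lumbar", "male", "10+0")$predicted_value,
    14 * 1.263 / 5)  # 3.5364
  expect_equal(
    predict_single_vertebra_height(24, "thoracic", "male", "18+0")$predicted_value,
    2)  # M = 1 at maturity, 24/12
  expect_equal(
    predict_single_vertebra_height(20, "thoracic", "female", "10+0")$predicted_value,
    20 * 1.178 / 12)
  expect_error(predict_single_vertebra_height(14, "cervical", "male", "10+0"),
               class = "spinemult_domain_error")
})

test_that("growth remaining is L(M - 1) and vanishes at maturity", {
  expect_equal(growth_remaining(80, "male", "10+0")$predicted_value,
               80 * (1.263 - 1))  # 21.04
  expect_equal(growth_remaining(60, "female", "7+6")$predicted_value,
               60 * 0.296)  # 17.76
  expect_equal(growth_remaining(35, "female", "16+0")$predicted_value, 0)
  expect_equal(growth_remaining(35, "male", 30,
                                clamp_post_maturity = TRUE)$predicted_value, 0)
})

test_that("arthrodesis loss scales the per-vertebra growth remaining by Vf", {
  plan <- arthrodesis_plan("thoracic", 20, 3, "male", "8+0")
  expect_equal(arthrodesis_growth_loss(plan)$predicted_value,
               20 * (1.338 - 1) / 12 * 3)  # 1.69
  plan2 <- arthrodesis_plan("lumbar", 15, 2, "female", "10+0")
  expect_equal(arthrodesis_growth_loss(plan2)$predicted_value,
               15 * 0.178 / 5 * 2)  # 1.068
  # full-segment fusion at maturity loses nothing
  plan3 <- arthrodesis_plan("lumbar", 16, 5, "female", "16+0")
  expect_equal(arthrodesis_growth_loss(plan3)$predicted_value, 0)
  expect_error(arthrodesis_plan("lumbar", 15, 6, "female", "10+0"),
               class = "spinemult_domain_error")
  expect_error(arthrodesis_plan("thoracic", 15, 0, "female", "10+0"),
               class = "spinemult_domain_error")
})

test_that("Vitruvian limb target and standing height use exact rationals", {
  expect_equal(limb_lengthening_target(88), 88 * 47 / 53)  # 78.038
  expect_equal(limb_lengthening_target(53), 47)
  expect_equal(round(limb_lengthening_target(100), 2), 88.68)
  expect_equal(estimate_mature_standing_height(53), 100)
  expect_equal(estimate_mature_standing_height(90), 90 / 0.53)  # 169.81
  expect_error(limb_lengthening_target(-1), class = "spinemult_domain_error")
  expect_error(estimate_mature_standing_height(0), class = "spinemult_domain_error")
})

test_that("prediction identities hold across random inputs", {
  tab <- sitting_height_multipliers()
  set.seed(11)
  for (i in 1:50) {
    sex <- sample(c("male", "female"), 1)
    month <- sample(seq(3L, tab$maturity_age[[sex]]), 1)
    age <- age_ym(month %/% 12L, month %% 12L)
    L <- runif(1, 10, 95)
    # growth remaining = predicted mature length - current length
    expect_equal(growth_remaining(L, sex, age)$predicted_value,
                 predict_mature_sitting_height(L, sex, age)$predicted_value - L)
    # fusing the whole segment forfeits the whole segment's remaining growth
    seg <- sample(c("lumbar", "thoracic"), 1)
    plan <- arthrodesis_plan(seg, L, vertebra_count(seg), sex, age)
    expect_equal(arthrodesis_growth_loss(plan)$predicted_value,
                 growth_remaining(L, sex, age)$predicted_value)
    # Vitruvian closure: sitting + limb target = sitting * 100/53
    h <- runif(1, 40, 100)
    expect_equal(h + limb_lengthening_target(h),
                 estimate_mature_standing_height(h), tolerance = 1e-12)
    expect_equal(h / estimate_mature_standing_height(h), 0.53,
                 tolerance = 1e-12)
  }
})
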