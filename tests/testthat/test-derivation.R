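test_that("multipliers are mature height over current height per curve", {
  ms <- derive_multipliers(toy_db())
  v <- ms$values
  expect_equal(v$multiplier[v$month == 60], 90 / 60)  # 1.5 at 5y
  expect_equal(v$multiplier[v$month == 120], 90 / 75)
  expect_equal(v$multiplier[v$month == 192], 1)       # maturity
})

test_that("missing maturity records are named in the error", {
  rec <- data.frame(sex = "male", percentile = "P10",
                    age_years = 5L, age_months = 0L,
                    sitting_height_cm = 60)
  expect_error(growth_database(rec),
               regexp = "P10", class = "spinemult_derivation_error")
  db <- growth_database(rec, validate = FALSE)
  expect_error(derive_multipliers(db),
               regexp = "P10", class = "spinemult_derivation_error")
})

test_that("scalar-multiple percentile curves share identical multipliers", {
  months <- c(seq(12L, 180L, by = 24L), 192L)
  base <- 90 / (1 + (192 - months) / 150)
  rec <- do.call(rbind, lapply(c(0.9, 1, 1.12), function(k) {
    data.frame(sex = "female", percentile = sprintf("x%.2f", k),
               age_years = months %/% 12L, age_months = months %% 12L,
               sitting_height_cm = k * base)
  }))
  ms <- derive_multipliers(growth_database(rec))
  vs <- variability_stats(ms)
  expect_equal(vs$max_variability, 0, tolerance = 1e-12)
  expect_equal(vs$mean_variability, 0, tolerance = 1e-12)
  # and scaling the whole database leaves the derived set unchanged
  rec2 <- rec
  rec2$sitting_height_cm <- rec2$sitting_height_cm * 3.7
  ms2 <- derive_multipliers(growth_database(rec2))
  expect_equal(ms2$values$multiplier, ms$values$multiplier, tolerance = 1e-12)
})

test_that("variability is the max deviation from the cross-percentile mean", {
  vals <- data.frame(
    sex = "male", percentile = rep(c("A", "B"), each = 2),
    month = rep(c(60L, 216L), 2), multiplier = c(1.4, 1, 1.6, 1))
  vs <- variability_stats(multiplier_set(vals, maturity_age = c(male = 216L)))
  expect_equal(vs$per_age$deviation[vs$per_age$month == 60], 0.1)
  expect_equal(vs$per_age$deviation[vs$per_age$month == 216], 0)
  expect_equal(vs$mean_variability, 0.05)
  expect_equal(vs$max_variability, 0.1)
  # single percentile: all zeros
  vs1 <- variability_stats(derive_multipliers(toy_db()))
  expect_equal(vs1$max_variability, 0)
})

test_that("derivation and variability match the brute-force oracle", {
  set.seed(101)
  for (i in 1:25) {
    db <- random_small_db()
    got <- derive_multipliers(db)$values
    want <- oracle_derive(db)
    expect_equal(got$multiplier, want$multiplier, tolerance = 1e-12)
    expect_equal(got[c("sex", "percentile", "month")],
                 want[c("sex", "percentile", "month")],
                 ignore_attr = TRUE)
    vs <- variability_stats(derive_multipliers(db))
    ov <- oracle_variability(got)
    expect_equal(vs$per_age$deviation, ov$per_age$deviation, tolerance = 1e-12)
    expect_equal(vs$max_variability, ov$max, tolerance = 1e-12)
    # note: pooled mean averages per-(sex, age) cells, same as the oracle
    expect_equal(vs$mean_variability, ov$mean, tolerance = 1e-12)
  }
})

test_that("mean multiplier curve averages percentiles without weights", {
  vals <- data.frame(
    sex = "female", percentile = rep(c("A", "B"), each = 2),
    month = rep(c(60L, 192L), 2), multiplier = c(1.4, 1, 1.6, 1))
  mc <- mean_multiplier_curve(multiplier_set(vals), "female")
  expect_equal(mc$multiplier[mc$month == 60], 1.5)
  expect_error(mean_multiplier_curve(multiplier_set(vals), "male"),
               class = "spinemult_domain_error")
})

test_that("comparing a multiplier set with itself is a perfect fit", {
  ms <- derive_multipliers(generate_database(synthetic_config(noise_sd = 0)))
  cmp <- compare_multiplier_sets(ms, ms, "male", degree = 3)
  expect_equal(cmp$r_squared, 1, tolerance = 1e-9)
  expect_equal(cmp$rmse, 0, tolerance = 1e-9)
  expect_equal(cmp$max_abs_diff, 0)
  expect_equal(cmp$n_shared_ages, 17L)
})

test_that("an affine offset is absorbed by the fit but shows in the raw diff", {
  ms <- derive_multipliers(generate_database(synthetic_config(noise_sd = 0)))
  shifted <- multiplier_set(transform(ms$values, multiplier = multiplier + 0.01),
                            provenance = "shifted")
  cmp <- compare_multiplier_sets(ms, shifted, "female", degree = 1)
  expect_equal(cmp$r_squared, 1, tolerance = 1e-9)
  expect_equal(cmp$rmse, 0, tolerance = 1e-9)
  expect_equal(cmp$max_abs_diff, 0.01, tolerance = 1e-12)
})

test_that("small independent noise yields a small regression RMSE", {
  ms <- derive_multipliers(generate_database(synthetic_config(noise_sd = 0)))
  set.seed(404)
  noisy <- multiplier_set(transform(
    ms$values, multiplier = multiplier + rnorm(nrow(ms$values), 0, 0.005)),
    provenance = "noisy")
  cmp <- compare_multiplier_sets(ms, noisy, "male", degree = 3)
  expect_lte(cmp$rmse, 0.01)
  expect_gt(cmp$r_squared, 0.99)
})

test_that("too few shared ages is a domain error", {
  vals <- data.frame(sex = "male", percentile = "P50",
                     month = c(60L, 120L, 216L), multiplier = c(1.5, 1.2, 1))
  ms <- multiplier_set(vals)
  expect_error(compare_multiplier_sets(ms, ms, "male", degree = 3),
               class = "spinemult_domain_error")
})
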