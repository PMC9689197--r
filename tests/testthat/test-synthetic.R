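test_that("noise-free proportional databases invert back to the seed table", {
  cfg <- synthetic_config(percentiles = c("P3", "P50", "P97"), noise_sd = 0)
  db <- generate_database(cfg)
  ms <- derive_multipliers(db)
  tab <- sitting_height_multipliers()$entries
  v <- ms$values
  for (i in seq_len(nrow(v))) {
    seed_val <- tab$multiplier[tab$sex == v$sex[i] & tab$month == v$month[i]]
    expect_equal(v$multiplier[i], seed_val, tolerance = 1e-12)
  }
  # proportional curves: zero cross-percentile variability even with
  # different mature heights
  expect_equal(variability_stats(ms)$max_variability, 0, tolerance = 1e-12)
})

test_that("generation is bit-stable in the seed and differs across seeds", {
  cfg1 <- synthetic_config(noise_sd = 0.02, rng_seed = 7L)
  cfg2 <- synthetic_config(noise_sd = 0.02, rng_seed = 7L)
  cfg3 <- synthetic_config(noise_sd = 0.02, rng_seed = 8L)
  expect_identical(generate_database(cfg1)$records,
                   generate_database(cfg2)$records)
  expect_false(identical(generate_database(cfg1)$records,
                         generate_database(cfg3)$records))
  # generation must not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_database(cfg1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("maturity records are always emitted and noise-free", {
  cfg <- synthetic_config(noise_sd = 0.05, rng_seed = 3L,
                          age_grid = seq(24L, 180L, by = 24L))
  db <- generate_database(cfg)
  r <- db$records
  for (sex in c("male", "female")) {
    mat <- db$maturity_age[[sex]]
    at <- r[r$sex == sex & r$month == mat, ]
    expect_equal(nrow(at), 5L)  # one per percentile
    expect_equal(at$sitting_height,
                 unname(cfg$mature_heights[[sex]][at$percentile]),
                 tolerance = 1e-12)
  }
})

test_that("ground truth matches the generator analytically", {
  # proportional: per-percentile copy of the seed table
  cfg <- synthetic_config(percentiles = c("A", "B"), noise_sd = 0)
  tt <- ground_truth(cfg)
  ms <- derive_multipliers(generate_database(cfg))
  expect_equal(tt$values$multiplier, ms$values$multiplier, tolerance = 1e-12)
  # sd_offset with zero spreads collapses to the proportional ground truth
  cfg0 <- synthetic_config(mode = "sd_offset", spread_at_birth = 0,
                           spread_at_maturity = 0, noise_sd = 0)
  tt0 <- ground_truth(cfg0)
  tab <- sitting_height_multipliers()$entries
  for (i in seq_len(nrow(tt0$values))) {
    seed_val <- tab$multiplier[tab$sex == tt0$values$sex[i] &
                                 tab$month == tt0$values$month[i]]
    expect_equal(tt0$values$multiplier[i], seed_val, tolerance = 1e-12)
  }
  # sd_offset: derivation of the noise-free database recovers the truth
  cfg2 <- synthetic_config(mode = "sd_offset", noise_sd = 0)
  expect_equal(derive_multipliers(generate_database(cfg2))$values$multiplier,
               ground_truth(cfg2)$values$multiplier, tolerance = 1e-12)
})

test_that("sd_offset variability peaks at the youngest age and shrinks", {
  cfg <- synthetic_config(mode = "sd_offset", noise_sd = 0,
                          spread_at_birth = 4, spread_at_maturity = 1)
  vs <- variability_stats(ground_truth(cfg))
  for (sex in c("male", "female")) {
    dev <- vs$per_age$deviation[vs$per_age$sex == sex]
    months <- vs$per_age$month[vs$per_age$sex == sex]
    dev <- dev[order(months)]
    expect_equal(which.max(dev), 1L)           # maximal at the youngest age
    expect_true(all(diff(dev) <= 1e-12))       # strictly shrinking band
  }
})

test_that("derived multipliers stay near truth under 1% relative noise", {
  cfg <- synthetic_config(percentiles = c("-1SD", "0SD", "+1SD"),
                          noise_sd = 0.01, rng_seed = 2024L,
                          age_grid = seq(12L, 192L, by = 9L))
  db <- generate_database(cfg)
  ms <- derive_multipliers(db)
  tt <- ground_truth(cfg)
  expect_equal(ms$values[c("sex", "percentile", "month")],
               tt$values[c("sex", "percentile", "month")], ignore_attr = TRUE)
  err <- abs(ms$values$multiplier - tt$values$multiplier)
  expect_lt(max(err), 0.05)
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(noise_sd = 0.25),
               class = "spinemult_domain_error")
  expect_error(synthetic_config(spread_at_birth = 1, spread_at_maturity = 2,
                                mode = "sd_offset"),
               class = "spinemult_domain_error")
  expect_error(synthetic_config(percentiles = c("A", "A")),
               class = "spinemult_domain_error")
  expect_error(generate_database(synthetic_config(age_grid = c(1L, 60L))),
               class = "spinemult_domain_error")  # below the first table age
  expect_error(generate_database(synthetic_config(age_grid = c(60L, 200L))),
               class = "spinemult_domain_error")  # past female maturity
})
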