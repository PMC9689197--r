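# Independent brute-force oracles for the derivation machinery. These share
# no code with the package internals: plain nested loops over records.

# db: growth_database. Returns data.frame(sex, percentile, month, multiplier).
oracle_derive <- function(db) {
  rec <- db$records
  out <- NULL
  for (i in seq_len(nrow(rec))) {
    sex <- rec$sex[i]; p <- rec$percentile[i]
    lm_height <- NA_real_
    for (j in seq_len(nrow(rec))) {
      if (rec$sex[j] == sex && rec$percentile[j] == p &&
          rec$month[j] == db$maturity_age[[sex]]) {
        lm_height <- rec$sitting_height[j]
      }
    }
    out <- rbind(out, data.frame(
      sex = sex, percentile = p, month = rec$month[i],
      multiplier = lm_height / rec$sitting_height[i],
      stringsAsFactors = FALSE))
  }
  out[order(out$sex, out$percentile, out$month), , drop = FALSE]
}

# values: data.frame(sex, percentile, month, multiplier). Returns
# list(per_age = data.frame(sex, month, deviation), mean, max) by loops.
oracle_variability <- function(values) {
  per_age <- NULL
  for (sex in sort(unique(values$sex))) {
    months <- sort(unique(values$month[values$sex == sex]))
    for (m in months) {
      ms <- values$multiplier[values$sex == sex & values$month == m]
      dev <- 0
      for (x in ms) dev <- max(dev, abs(x - mean(ms)))
      per_age <- rbind(per_age, data.frame(sex = sex, month = m,
                                           deviation = dev,
                                           stringsAsFactors = FALSE))
    }
  }
  list(per_age = per_age,
       mean = mean(per_age$deviation),
       max = max(per_age$deviation))
}

# Random small growth database: <= 4 percentiles, <= 10 ages per sex.
random_small_db <- function() {
  sexes <- sample(c("male", "female"), sample(1:2, 1))
  maturity <- c(male = 216L, female = 192L)
  rec <- NULL
  for (sex in sexes) {
    npct <- sample(1:4, 1)
    nages <- sample(2:10, 1)
    months <- sort(sample(setdiff(seq(3L, maturity[[sex]] - 1L), 0), nages - 1L))
    months <- c(months, maturity[[sex]])
    for (p in paste0("P", seq_len(npct))) {
      mature <- runif(1, 75, 100)
      # monotone-ish curve: mature height divided by a decreasing factor
      heights <- mature / (1 + runif(length(months), 0, 1.5) *
                             (1 - months / maturity[[sex]]))
      heights[length(heights)] <- mature
      rec <- rbind(rec, data.frame(
        sex = sex, percentile = p,
        age_years = months %/% 12L, age_months = months %% 12L,
        sitting_height_cm = heights, stringsAsFactors = FALSE))
    }
  }
  growth_database(rec, maturity_age = maturity, provenance = "random small")
}

# Minimal single-percentile toy database in dialect form.
toy_db <- function() {
  growth_database(data.frame(
    sex = "female", percentile = "P50",
    age_years = c(5L, 10L, 16L), age_months = 0L,
    sitting_height_cm = c(60, 75, 90), stringsAsFactors = FALSE))
}
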