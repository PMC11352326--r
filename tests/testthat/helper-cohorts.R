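# Shared fixtures built in code.

# Minimal hand-built cohort: every child exactly at the family midparent on
# the +13 cm common scale (identity cohort for trivial regression checks).
identity_cohort <- function(n_families = 5) {
  rows <- lapply(seq_len(n_families), function(i) {
    fh <- 165 + 3 * i          # spread the families out
    mh <- fh - 13
    mp <- (fh + (mh + 13)) / 2 # +13 common scale midparent (= fh here)
    data.frame(
      family_id = sprintf("F%02d", i),
      person_id = sprintf("F%02d-%s", i, c("father", "mother", "child1", "child2")),
      role = c("father", "mother", "child", "child"),
      sex = c("male", "female", "male", "female"),
      age = 25,
      height = c(fh, mh, mp, mp - 13)
    )
  })
  as_cohort(do.call(rbind, rows))
}

# Closed-form least-squares oracle from raw sums, independent of stats::lm.
ols_sums_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  b <- sxy / sxx
  list(slope = b, intercept = mean(y) - b * mean(x), r_squared = sxy^2 / (sxx * syy))
}

statage_fixture <- function() {
  system.file("extdata", "cdc_statage_240mo_synthetic.csv", package = "targetheight")
}
simple_fixture <- function() {
  system.file("extdata", "percentiles_simple_synthetic.csv", package = "targetheight")
}
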