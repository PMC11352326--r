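test_that("cohort validation enforces the nuclear-family structure", {
  coh <- identity_cohort()
  expect_s3_class(coh, "mph_cohort")
  df <- as.data.frame(coh)
  expect_error(as_cohort(df[df$role != "mother", ]), "exactly one father, one mother")
  df2 <- df; df2$height[1] <- 95
  expect_error(as_cohort(df2), "plausibility")
  df3 <- df; df3$age[1] <- 10
  expect_error(as_cohort(df3), "15")
  df4 <- df; df4$sex[df4$role == "father"] <- "female"
  expect_error(as_cohort(df4), "fathers must be male")
  # CSV aliases accepted
  df5 <- df; names(df5)[names(df5) == "age"] <- "age_years"
  names(df5)[names(df5) == "height"] <- "height_cm"
  expect_s3_class(as_cohort(df5), "mph_cohort")
})

test_that("cohort CSV round-trips through write_cohort/read_cohort", {
  coh <- simulate_cohort(simulation_params(n_families = 4), seed = 2)
  path <- tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$height, coh$height, tolerance = 1e-9)
  expect_equal(back$sex, coh$sex)
  expect_equal(back$role, coh$role)
})

test_that("midparent regression matches a closed-form sums oracle to 1e-9", {
  set.seed(21)
  for (rep in 1:4) {
    coh <- simulate_cohort(simulation_params(n_families = 15))
    for (scheme in c("tanner13", "mult1.08", "zscore-cdc")) {
      fit <- midparent_regression(coh, scheme)
      d <- fit$data
      oracle <- ols_sums_oracle(d$midparent_common, d$child_common)
      expect_equal(fit$slope, oracle$slope, tolerance = 1e-9)
      expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-9)
      expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-9)
      expect_equal(fit$heritability, fit$slope)  # heritability is the slope
      expect_equal(fit$systematic_error,
                   mean(d$child_common - d$midparent_common), tolerance = 1e-12)
    }
  }
})

test_that("children equal to their midparent give slope 1, R^2 1, zero error", {
  fit <- midparent_regression(identity_cohort(), scheme_preset("tanner13"),
                              shrinkage_model = NULL)
  expect_equal(fit$slope, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$systematic_error, 0, tolerance = 1e-9)
  expect_error(midparent_regression(identity_cohort(1)), "2 families")
})

test_that("noise-free cohorts recover the generative slope to machine precision", {
  for (b in c(0.6, 0.79, 1.0)) {
    params <- simulation_params(n_families = 30, midparent_slope = b,
                                assortative_corr = 0)
    coh <- ideal_cohort(params, seed = 100 + round(100 * b))
    fit <- midparent_regression(coh, scheme_preset("zscore-cdc"))
    expect_equal(fit$slope, b, tolerance = 1e-9)
    expect_equal(fit$intercept, 0, tolerance = 1e-9)
    expect_equal(fit$systematic_error, mean(fit$data$child_common -
                                              fit$data$midparent_common),
                 tolerance = 1e-12)
  }
})

test_that("stochastic cohorts recover generative slopes within 3 standard errors", {
  for (b in c(0.6, 0.79, 1.0)) {
    coh <- simulate_cohort(simulation_params(n_families = 300, midparent_slope = b),
                           seed = round(1000 * b))
    sm <- summary(midparent_regression(coh, scheme_preset("zscore-cdc")))
    expect_lt(abs(sm$fit$slope - b), 3 * sm$slope_se)
  }
})

test_that("age correction removes the parental-shrinkage bias it targets", {
  coh <- simulate_cohort(simulation_params(n_families = 400), seed = 77)
  fit_on <- midparent_regression(coh, scheme_preset("mult1.08"))
  fit_off <- midparent_regression(coh, scheme_preset("mult1.08"),
                                  shrinkage_model = NULL)
  # cohort-level expected bias: mean parental shrinkage (common scale) minus
  # the small child-side shrinkage
  parents <- coh$role != "child"
  shr <- shrinkage(coh$age, coh$sex, age_shrinkage_model())
  expected <- mean(tapply(shr[parents], coh$family_id[parents], mean)[
    as.character(coh$family_id[coh$role == "child"])]) -
    mean(shr[coh$role == "child"])
  expect_lt(abs(fit_on$systematic_error), 0.25)
  expect_gt(fit_off$systematic_error, 2)
  expect_lt(abs(fit_off$systematic_error - expected), 0.5)
})

test_that("the scheme comparison table has the standard seven-row layout", {
  coh <- simulate_cohort(simulation_params(n_families = 40), seed = 9)
  tab <- scheme_comparison_table(coh)
  expect_equal(nrow(tab), 7)
  expect_equal(tab$age_corrected, c(FALSE, rep(TRUE, 6)))
  expect_equal(tab$scheme[1:2], c("+13 cm", "+13 cm"))
  expect_equal(tab$units, c(rep("cm", 3), "SDS", "cm", "cm", "SDS"))
  expect_true(all(tab$r_squared >= 0 & tab$r_squared <= 1))
  expect_equal(tab$heritability, tab$slope)
  # uncorrected row carries the age bias, corrected +13 row does not
  expect_gt(tab$systematic_error[1], tab$systematic_error[2])

  # a single custom scheme gives a single row
  one <- scheme_comparison_table(identity_cohort(), schemes = list("tanner13"),
                                 age_corrected = FALSE)
  expect_equal(nrow(one), 1)
  expect_equal(one$slope, 1, tolerance = 1e-9)
})

test_that("within-family residual spread recovers the generative SDs", {
  # degenerate: noise-free cohort with slope 1 has zero residuals everywhere
  ideal <- ideal_cohort(simulation_params(n_families = 10, midparent_slope = 1),
                        seed = 4)
  wfr0 <- within_family_residuals(ideal, scheme_preset("zscore-cdc"),
                                  rtm = rtm_params(1, 0))
  expect_equal(wfr0$pooled$sd, c(0, 0), tolerance = 1e-9)
  expect_true(all(wfr0$per_family$sd[!is.na(wfr0$per_family$sd)] < 1e-9))

  # stochastic: pooled per-sex SDs inside chi-square 99% sampling bounds
  coh <- simulate_cohort(simulation_params(n_families = 300), seed = 13)
  wfr <- within_family_residuals(coh, scheme_preset("zscore-cdc"))
  for (i in 1:2) {
    sx <- wfr$pooled$sex[i]
    sigma <- if (sx == "male") 4.5 else 4.2
    n <- wfr$pooled$n[i]
    bounds <- sigma * sqrt(qchisq(c(0.005, 0.995), n - 1) / (n - 1))
    expect_gt(wfr$pooled$sd[i], bounds[1])
    expect_lt(wfr$pooled$sd[i], bounds[2])
  }
  # families need two same-sex children to contribute a within-family SD
  expect_true(all(wfr$per_family$n[!is.na(wfr$per_family$sd)] >= 2))
  expect_true(all(is.na(wfr$per_family$sd[wfr$per_family$n < 2])))
})

test_that("family-level differences show regression to the mean", {
  # children exactly at their midparent: all family differences zero,
  # correlation undefined (identity_cohort is exact in +13 arithmetic)
  r0 <- family_level_rtm(identity_cohort(6), scheme_preset("tanner13"),
                         shrinkage_model = NULL)
  expect_true(is.na(r0$r))
  expect_match(r0$note, "undefined")

  # generative slope < 1: negative family-level correlation in most seeds
  negs <- vapply(1:10, function(s) {
    coh <- simulate_cohort(simulation_params(), seed = 500 + s)
    family_level_rtm(coh, scheme_preset("mult1.08"))$r
  }, numeric(1))
  expect_gt(mean(negs < 0), 0.5)
  # and strongly negative on a large cohort
  big <- simulate_cohort(simulation_params(n_families = 200), seed = 3)
  res <- family_level_rtm(big, scheme_preset("mult1.08"))
  expect_lt(res$r, -0.2)
  expect_lt(res$p_value, 0.01)
  expect_error(family_level_rtm(identity_cohort(2)), "3 families")
})

test_that("residual spread is unrelated to midparent height when homoscedastic", {
  # constant spread: exactly zero correlation by convention
  ideal <- ideal_cohort(simulation_params(n_families = 10, midparent_slope = 1),
                        seed = 14)
  r0 <- residual_spread_vs_midparent(ideal, scheme_preset("zscore-cdc"),
                                     rtm = rtm_params(1, 0))
  expect_equal(r0$r, 0)
  expect_equal(r0$p_value, 1)

  # homoscedastic generator: non-significant at the 5% level in at least 90%
  # of seeds (100 seeds keep the rate estimate stable)
  sig <- vapply(1:100, function(s) {
    coh <- simulate_cohort(simulation_params(), seed = 700 + s)
    residual_spread_vs_midparent(coh)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(!sig), 0.9)

  # spread proportional to midparent: clearly positive correlation
  params <- simulation_params(n_families = 60)
  coh <- simulate_cohort(params, seed = 15)
  d <- as.data.frame(coh)
  kids <- d$role == "child"
  mp <- tapply(d$height[!kids], d$family_id[!kids], mean)
  scale_by <- (as.numeric(mp[as.character(d$family_id)]) - 140) / 25
  # re-spread children's heights around their family mean by a midparent-
  # dependent factor
  fam_mean <- tapply(d$height[kids], d$family_id[kids], mean)
  centered <- d$height[kids] - as.numeric(fam_mean[as.character(d$family_id[kids])])
  d$height[kids] <- as.numeric(fam_mean[as.character(d$family_id[kids])]) +
    centered * scale_by[kids]
  het <- residual_spread_vs_midparent(as_cohort(d))
  expect_gt(het$r, 0.2)
})

test_that("sample reference estimates per-sex peak moments from the cohort", {
  ref <- cdc_reference()
  coh <- simulate_cohort(simulation_params(n_families = 500), seed = 31)
  est <- sample_reference(coh)
  expect_lt(abs(est$mean_male - ref$mean_male), 1)
  expect_lt(abs(est$mean_female - ref$mean_female), 1)
  expect_gt(est$mean_male, est$mean_female)
})
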