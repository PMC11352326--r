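#' Offspring-on-midparent height regression
#'
#' Fits the cohort evaluation model: every member's height is optionally
#' corrected for age-related shrinkage, placed on the scheme's common scale,
#' and each child's common-scale height is regressed by ordinary least
#' squares on their family's mid-parental value (each child is one
#' observation). The slope is the midparent-sense heritability; the
#' systematic error is the mean difference between children's heights and
#' their mid-parental height, in common-scale units (cm for
#' additive/multiplicative schemes, SDS for the zscore scheme).
#'
#' @param cohort an `mph_cohort` (see [as_cohort()], [read_cohort()],
#'   [simulate_cohort()]).
#' @param scheme a [sex_correction_scheme()] or preset name for
#'   [scheme_preset()].
#' @param shrinkage_model an [age_shrinkage_model()], or `NULL` for no age
#'   correction.
#' @param ref reference population used when converting predictions back to
#'   cm for cm-scale schemes.
#' @return an object of class `"mph_fit"`: the fitted regression plus the
#'   per-child data and method metadata. Supports `print`, `summary`,
#'   `coef`, `predict`, `residuals`, `plot` and `simulate`.
#' @examples
#' coh <- simulate_cohort(simulation_params(), seed = 1)
#' fit <- midparent_regression(coh, scheme = "zscore-cdc")
#' coef(fit)
#' @export
midparent_regression <- function(cohort, scheme = scheme_preset("zscore-cdc"),
                                 shrinkage_model = age_shrinkage_model(),
                                 ref = cdc_reference()) {
  if (is.character(scheme)) {
    scheme <- if (identical(scheme, "zscore-sample")) {
      scheme_preset(scheme, ref = sample_reference(cohort, shrinkage_model))
    } else scheme_preset(scheme)
  }
  if (length(unique(cohort$family_id)) < 2) stop("need at least 2 families")
  d <- .cohort_common(cohort, scheme, shrinkage_model)
  if (stats::sd(d$midparent_common) == 0) {
    stop("midparent values have zero variance; regression undefined")
  }
  fit <- stats::lm(child_common ~ midparent_common, data = d)
  sst <- sum((d$child_common - mean(d$child_common))^2)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sst
  structure(
    list(lm = fit,
         data = d,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2,
         heritability = unname(stats::coef(fit)[2]),
         systematic_error = mean(d$child_common - d$midparent_common),
         units = if (scheme$variant == "zscore") "SDS" else "cm",
         scheme = scheme,
         shrinkage_model = shrinkage_model,
         age_corrected = !is.null(shrinkage_model),
         ref = ref,
         n_children = nrow(d),
         n_families = length(unique(d$family_id))),
    class = "mph_fit"
  )
}

#' @export
print.mph_fit <- function(x, digits = 3, ...) {
  cat("Offspring-on-midparent height regression\n")
  cat(sprintf("  sex correction: %s; age correction: %s\n",
              x$scheme$label, if (x$age_corrected) "yes" else "no"))
  cat(sprintf("  %d children in %d families\n", x$n_children, x$n_families))
  cat(sprintf("  fit: Y = %.*gX %+.*g  (R^2 = %.0f%%, heritability = %.0f%%)\n",
              digits, x$slope, digits, x$intercept,
              100 * x$r_squared, 100 * x$heritability))
  cat(sprintf("  systematic error: %.3g %s\n", x$systematic_error, x$units))
  invisible(x)
}

#' @export
coef.mph_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.mph_fit <- function(object, ...) stats::residuals(object$lm)

#' @export
summary.mph_fit <- function(object, ...) {
  sm <- summary(object$lm)
  structure(list(fit = object, lm_summary = sm,
                 slope_se = sm$coefficients["midparent_common", "Std. Error"]),
            class = "summary.mph_fit")
}

#' @export
print.summary.mph_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  slope SE: %.4g;  residual SD (common scale): %.3g\n",
              x$slope_se, x$lm_summary$sigma))
  invisible(x)
}

#' Predict corrected target heights from a fitted midparent regression
#'
#' Applies the fitted slope/intercept on the common scale to new parental
#' records: parents are age-corrected with the fit's shrinkage model,
#' placed on its common scale, averaged, mapped through the fitted line,
#' and transformed back to the child's sex.
#'
#' @param object an `mph_fit`.
#' @param newdata data frame with columns `father_height`, `father_age`,
#'   `mother_height`, `mother_age`, `child_sex`.
#' @param ... unused.
#' @return numeric vector of target heights in cm.
#' @export
predict.mph_fit <- function(object, newdata, ...) {
  need <- c("father_height", "father_age", "mother_height", "mother_age", "child_sex")
  missing <- setdiff(need, names(newdata))
  if (length(missing)) stop("newdata is missing column(s): ", paste(missing, collapse = ", "))
  sm <- object$shrinkage_model
  fh <- if (is.null(sm)) newdata$father_height else
    peak_height(newdata$father_height, newdata$father_age, "male", sm)
  mh <- if (is.null(sm)) newdata$mother_height else
    peak_height(newdata$mother_height, newdata$mother_age, "female", sm)
  mp <- mid_parental(to_common_scale(fh, "male", object$scheme),
                     to_common_scale(mh, "female", object$scheme))
  from_common_scale(object$intercept + object$slope * mp,
                    newdata$child_sex, object$scheme)
}

#' Scatter plot of child height against mid-parental height
#'
#' @param x an `mph_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mph_fit <- function(x, ...) {
  u <- x$units
  graphics::plot(x$data$midparent_common, x$data$child_common,
                 xlab = sprintf("mid-parental height (%s)", u),
                 ylab = sprintf("child height (%s)", u),
                 main = sprintf("%s (R² = %.0f%%)", x$scheme$label,
                                100 * x$r_squared), ...)
  graphics::abline(x$lm, col = "red", lwd = 2)
  invisible(x)
}

#' Simulate cohorts from a fitted midparent regression
#'
#' Generates synthetic cohorts whose offspring-on-midparent slope equals the
#' fitted slope and whose per-sex residual SDs match those estimated from
#' the fit's cm-scale residuals.
#'
#' @param object an `mph_fit`.
#' @param nsim number of cohorts.
#' @param seed integer seed.
#' @param params a [simulation_params()] used as the base settings; its
#'   slope and residual SDs are overridden by the fitted values.
#' @param ... unused.
#' @return a list of `nsim` cohorts.
#' @export
simulate.mph_fit <- function(object, nsim = 1, seed = NULL,
                             params = simulation_params(), ...) {
  d <- object$data
  pred_common <- stats::fitted(object$lm)
  pred_cm <- from_common_scale(pred_common, d$sex, object$scheme)
  res_cm <- d$height_peak - pred_cm
  sd_son <- stats::sd(res_cm[d$sex == "male"])
  sd_daughter <- stats::sd(res_cm[d$sex == "female"])
  params$midparent_slope <- object$slope
  if (is.finite(sd_son) && sd_son > 0) params$residual_sd_son <- sd_son
  if (is.finite(sd_daughter) && sd_daughter > 0) params$residual_sd_daughter <- sd_daughter
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) simulate_cohort(params))
}
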