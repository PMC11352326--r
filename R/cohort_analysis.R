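# Degeneracy guard for the correlation analyses: values that are constant up
# to floating-point noise (relative 1e-9) carry no trend information.
.near_constant <- function(v) {
  stats::sd(v) <= 1e-9 * (abs(mean(v)) + 1)
}

#' Compare correction schemes on a cohort
#'
#' Runs [midparent_regression()] for each (age correction, sex-correction
#' scheme) combination and tabulates slope, intercept, R^2, heritability and
#' systematic error — one row per scheme, in the standard comparison order:
#' uncorrected-age +13 cm first, then the age-corrected schemes (+13 cm,
#' x1.08, CDC Z-score, +10.82 cm sample, x1.066 sample, sample Z-score).
#'
#' @param cohort an `mph_cohort`.
#' @param schemes optional list of [sex_correction_scheme()] objects (or
#'   preset names); if `NULL`, the seven standard rows are produced.
#' @param shrinkage_model the [age_shrinkage_model()] used for the
#'   age-corrected rows.
#' @param age_corrected logical vector matched to `schemes` (recycled);
#'   ignored when `schemes` is `NULL`.
#' @return a data frame with one row per combination, including a
#'   `linear_fit` display column and a `units` column (`"cm"` or `"SDS"`;
#'   systematic error of zscore rows is in SDS).
#' @export
scheme_comparison_table <- function(cohort, schemes = NULL,
                                    shrinkage_model = age_shrinkage_model(),
                                    age_corrected = TRUE) {
  if (is.null(schemes)) {
    schemes <- list(scheme_preset("tanner13"),
                    scheme_preset("tanner13"),
                    scheme_preset("mult1.08"),
                    scheme_preset("zscore-cdc"),
                    scheme_preset("add10.82-sample"),
                    scheme_preset("mult1.066-sample"),
                    scheme_preset("zscore-sample",
                                  ref = sample_reference(cohort, shrinkage_model)))
    age_corrected <- c(FALSE, rep(TRUE, 6))
  } else {
    schemes <- lapply(schemes, function(s) {
      if (is.character(s)) {
        if (identical(s, "zscore-sample")) {
          scheme_preset(s, ref = sample_reference(cohort, shrinkage_model))
        } else scheme_preset(s)
      } else s
    })
    age_corrected <- rep_len(age_corrected, length(schemes))
  }
  rows <- Map(function(sch, age_on) {
    f <- midparent_regression(cohort, sch,
                              shrinkage_model = if (age_on) shrinkage_model else NULL)
    data.frame(
      age_corrected = age_on,
      scheme = sch$label,
      linear_fit = sprintf("Y = %.3gX %+.3g", f$slope, f$intercept),
      slope = f$slope, intercept = f$intercept,
      r_squared = f$r_squared, heritability = f$heritability,
      systematic_error = f$systematic_error, units = f$units,
      stringsAsFactors = FALSE
    )
  }, schemes, as.list(age_corrected))
  do.call(rbind, rows)
}

#' Within-family residual spread around the target height
#'
#' For every family, computes each child's residual — peak height minus the
#' family target height on the child's own sex scale, where the target is
#' the age-, sex- and regression-to-the-mean-corrected mid-parental height —
#' and summarizes the per-family residual SDs by sex (families contribute a
#' within-family SD for a sex only when they have at least two children of
#' that sex) together with the pooled all-children SD per sex.
#'
#' @param cohort an `mph_cohort`.
#' @param scheme sex-correction scheme (object or preset name).
#' @param shrinkage_model an [age_shrinkage_model()] or `NULL`.
#' @param rtm an [rtm_params()]; set `raw_midparent = TRUE` to measure
#'   residuals around the uncorrected mid-parental height instead.
#' @param ref reference population (standardization of cm-scale schemes and
#'   back-conversion of zscore targets).
#' @param raw_midparent if `TRUE`, skip the regression-to-the-mean step.
#' @return a list with `per_family` (family_id, sex, n, sd), `summary`
#'   (per sex: number of contributing families, mean and SD of the
#'   within-family SDs), `pooled` (per sex: n, sd), and `residuals` (the
#'   per-child table).
#' @export
within_family_residuals <- function(cohort, scheme = scheme_preset("mult1.08"),
                                    shrinkage_model = age_shrinkage_model(),
                                    rtm = rtm_params(), ref = cdc_reference(),
                                    raw_midparent = FALSE) {
  if (is.character(scheme)) {
    scheme <- if (identical(scheme, "zscore-sample")) {
      scheme_preset(scheme, ref = sample_reference(cohort, shrinkage_model))
    } else scheme_preset(scheme)
  }
  d <- .cohort_common(cohort, scheme, shrinkage_model)
  target_common <- if (raw_midparent) d$midparent_common else {
    .target_common(d$midparent_common, scheme, rtm, ref)
  }
  target_cm <- from_common_scale(target_common, d$sex, scheme)
  d$residual <- d$height_peak - target_cm

  per_family <- do.call(rbind, lapply(split(d, list(d$family_id, d$sex), drop = TRUE),
    function(g) {
      data.frame(family_id = g$family_id[1], sex = g$sex[1], n = nrow(g),
                 sd = if (nrow(g) >= 2) stats::sd(g$residual) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  rownames(per_family) <- NULL

  summarize_sex <- function(sx) {
    sds <- per_family$sd[per_family$sex == sx & !is.na(per_family$sd)]
    data.frame(sex = sx, n_families = length(sds),
               mean_within_sd = if (length(sds)) mean(sds) else NA_real_,
               sd_within_sd = if (length(sds) >= 2) stats::sd(sds) else NA_real_)
  }
  pooled_sex <- function(sx) {
    r <- d$residual[d$sex == sx]
    data.frame(sex = sx, n = length(r),
               sd = if (length(r) >= 2) stats::sd(r) else NA_real_)
  }
  list(per_family = per_family,
       summary = rbind(summarize_sex("male"), summarize_sex("female")),
       pooled = rbind(pooled_sex("male"), pooled_sex("female")),
       residuals = d)
}

#' Family-level regression to the mean
#'
#' For each family, the difference between the mean common-scale height of
#' its children and the family's mid-parental value, plotted against the
#' mid-parental value. Regression to the mean shows up as a negative
#' Pearson correlation: tall-parent families have children shorter than
#' their midparent, short-parent families taller.
#'
#' @inheritParams within_family_residuals
#' @return a list with `pairs` (per family: midparent_common,
#'   mean_child_minus_midparent, n_children), `r`, `p_value`, and `n`.
#'   When the differences are constant the correlation is undefined and
#'   `r`/`p_value` are `NA`.
#' @export
family_level_rtm <- function(cohort, scheme = scheme_preset("mult1.08"),
                             shrinkage_model = age_shrinkage_model()) {
  if (is.character(scheme)) scheme <- scheme_preset(scheme)
  d <- .cohort_common(cohort, scheme, shrinkage_model)
  fams <- split(d, d$family_id)
  if (length(fams) < 3) stop("need at least 3 families")
  pairs <- do.call(rbind, lapply(fams, function(g) {
    data.frame(family_id = g$family_id[1],
               midparent_common = g$midparent_common[1],
               mean_child_minus_midparent = mean(g$child_common) - g$midparent_common[1],
               n_children = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- NULL
  x <- pairs$midparent_common
  y <- pairs$mean_child_minus_midparent
  if (.near_constant(y) || .near_constant(x)) {
    return(list(pairs = pairs, r = NA_real_, p_value = NA_real_, n = nrow(pairs),
                note = "correlation undefined (constant values)"))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(pairs = pairs, r = unname(ct$estimate), p_value = ct$p.value, n = nrow(pairs))
}

#' Residual spread versus mid-parental height
#'
#' Tests whether families with taller parents show a wider spread of
#' children's heights around the family target: Pearson correlation between
#' the family mid-parental value and the family's residual SD (residuals as
#' in [within_family_residuals()], pooled over the family's children).
#'
#' @inheritParams within_family_residuals
#' @return list with `pairs` (midparent_common, residual_sd, n_children),
#'   `r`, `p_value`, `n`. Constant residual SDs give `r = 0` (no trend) with
#'   `p_value = 1`.
#' @export
residual_spread_vs_midparent <- function(cohort, scheme = scheme_preset("mult1.08"),
                                         shrinkage_model = age_shrinkage_model(),
                                         rtm = rtm_params(), ref = cdc_reference()) {
  wfr <- within_family_residuals(cohort, scheme, shrinkage_model, rtm, ref)
  d <- wfr$residuals
  fams <- split(d, d$family_id)
  if (length(fams) < 3) stop("need at least 3 families")
  pairs <- do.call(rbind, lapply(fams, function(g) {
    data.frame(family_id = g$family_id[1],
               midparent_common = g$midparent_common[1],
               residual_sd = if (nrow(g) >= 2) stats::sd(g$residual) else NA_real_,
               n_children = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- NULL
  keep <- !is.na(pairs$residual_sd)
  x <- pairs$midparent_common[keep]
  y <- pairs$residual_sd[keep]
  if (length(x) < 3) stop("need at least 3 families with >= 2 children")
  if (.near_constant(y)) {
    return(list(pairs = pairs, r = 0, p_value = 1, n = length(x),
                note = "residual SDs constant; no trend"))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(pairs = pairs, r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
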