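#' Regression-to-the-mean parameters
#'
#' Linear map on the standardized scale from mid-parental height to expected
#' child height: `z_child = slope * z_midparent + intercept`. The default
#' (0.79, -0.077) is the fitted offspring-on-midparent relation under age
#' correction and CDC Z-score sex correction; slope < 1 encodes regression
#' to the mean.
#'
#' @param slope standardized regression slope (midparent-sense heritability).
#' @param intercept standardized intercept.
#' @return an object of class `"rtm_params"`.
#' @export
rtm_params <- function(slope = 0.79, intercept = -0.077) {
  if (!is.finite(slope) || !is.finite(intercept)) stop("rtm parameters must be finite")
  if (slope <= 0) stop("slope must be positive")
  structure(list(slope = slope, intercept = intercept), class = "rtm_params")
}

#' Residual model for children's heights around their target
#'
#' Per-sex SD of adult children's heights around the corrected family target.
#' `basis = "within_family"` ships the mean within-family SDs (4.5 cm sons,
#' 4.2 cm daughters); `basis = "pooled"` the all-children SDs (4.7 / 4.4 cm),
#' the default for clinical assessment since a new child is compared against
#' between-family variability as well.
#'
#' @param basis `"pooled"` or `"within_family"`, or supply SDs directly.
#' @param sd_son,sd_daughter residual SDs in cm (override the basis preset).
#' @return an object of class `"residual_model"`.
#' @export
residual_model <- function(basis = c("pooled", "within_family"),
                           sd_son = NULL, sd_daughter = NULL) {
  basis <- match.arg(basis)
  defaults <- switch(basis,
                     pooled = c(4.7, 4.4),
                     within_family = c(4.5, 4.2))
  sd_son <- sd_son %||% defaults[1]
  sd_daughter <- sd_daughter %||% defaults[2]
  if (sd_son <= 0 || sd_daughter <= 0) stop("residual SDs must be positive")
  structure(list(sd_son = sd_son, sd_daughter = sd_daughter, basis = basis),
            class = "residual_model")
}

.residual_sd <- function(residual, sex) {
  ifelse(match_sex(sex) == "male", residual$sd_son, residual$sd_daughter)
}

#' Classical normal-range cutoff policy
#'
#' The fixed cutoffs the probability-based assessment is compared against:
#' Tanner's +/-10 cm for boys and +/-9 cm for girls around the target, and
#' the +/-1.64 SDS interval.
#'
#' @param tanner_range_son,tanner_range_daughter cm half-widths.
#' @param sds_range SDS half-width.
#' @return an object of class `"cutoff_policy"`.
#' @export
cutoff_policy <- function(tanner_range_son = 10, tanner_range_daughter = 9,
                          sds_range = 1.64) {
  if (tanner_range_son <= 0 || tanner_range_daughter <= 0 || sds_range <= 0) {
    stop("cutoff ranges must be positive")
  }
  structure(list(tanner_range_son = tanner_range_son,
                 tanner_range_daughter = tanner_range_daughter,
                 sds_range = sds_range),
            class = "cutoff_policy")
}

#' A person record
#'
#' Convenience constructor for one individual (typically a parent in a
#' clinical query).
#'
#' @param sex sex code.
#' @param height measured height, cm.
#' @param age age at measurement, years; `NA` allowed only with downstream
#'   `assume_peak = TRUE`.
#' @return a list of class `"member"`.
#' @export
member <- function(sex, height, age = NA_real_) {
  sex <- match_sex(sex)
  if (!is.finite(height) || height <= 0) stop("height must be a positive number")
  structure(list(sex = sex, height = as.numeric(height), age = as.numeric(age)),
            class = "member")
}

#' Mid-parental value on a common scale
#'
#' @param father_common,mother_common the two parents' heights after
#'   transformation to the same common scale.
#' @return their arithmetic mean.
#' @export
mid_parental <- function(father_common, mother_common) {
  (father_common + mother_common) / 2
}

#' Classical Tanner target height
#'
#' Average of the parents' measured heights plus 6.5 cm for a son or minus
#' 6.5 cm for a daughter; no age or regression-to-the-mean correction.
#' Algebraically identical to adding 13 cm to the mother's height,
#' averaging, and transforming back to the child's sex.
#'
#' @param father,mother parental heights, cm.
#' @param child_sex sex code of the child.
#' @return target height, cm.
#' @export
tanner_target <- function(father, mother, child_sex) {
  if (any(c(father, mother) <= 0)) stop("heights must be positive")
  child_sex <- match_sex(child_sex)
  (father + mother) / 2 + ifelse(child_sex == "male", 6.5, -6.5)
}

#' Corrected target height
#'
#' The full prediction pipeline: parental heights are corrected for
#' age-related shrinkage to peak heights, placed on a common scale by the
#' sex-correction scheme, averaged, pulled toward the population mean by the
#' standardized regression-to-the-mean map, and transformed back to the
#' child's sex. For cm-scale schemes (additive/multiplicative) the
#' regression step standardizes the male-equivalent midparent against the
#' male reference before applying the map, keeping all schemes structurally
#' parallel.
#'
#' @param father,mother [member()] objects (or lists with `sex`, `height`,
#'   `age`).
#' @param child_sex sex code of the child.
#' @param shrinkage_model an [age_shrinkage_model()], or `NULL` to skip age
#'   correction.
#' @param scheme a [sex_correction_scheme()].
#' @param rtm an [rtm_params()].
#' @param ref reference population used for percentile reporting and for
#'   standardizing cm-scale schemes.
#' @param assume_peak if `TRUE`, a missing parental age is treated as "no
#'   shrinkage"; otherwise missing age is an error (a silent fallback would
#'   reintroduce the age bias the correction exists to remove).
#' @return an object of class `"target_prediction"` with `target_height`
#'   (cm), `target_percentile` (fraction), `common_scale_midparent`, and the
#'   method metadata.
#' @export
corrected_target <- function(father, mother, child_sex,
                             shrinkage_model = age_shrinkage_model(),
                             scheme = scheme_preset("zscore-cdc"),
                             rtm = rtm_params(),
                             ref = cdc_reference(),
                             assume_peak = FALSE) {
  child_sex <- match_sex(child_sex)
  stopifnot(inherits(rtm, "rtm_params"), inherits(scheme, "sex_correction_scheme"))
  peak_of <- function(m, who) {
    if (is.na(m$age)) {
      if (!assume_peak) {
        stop("missing ", who, " age; pass assume_peak = TRUE to treat the ",
             "measured height as peak height")
      }
      return(m$height)
    }
    if (is.null(shrinkage_model)) m$height
    else peak_height(m$height, m$age, m$sex, shrinkage_model)
  }
  f_peak <- peak_of(father, "father")
  m_peak <- peak_of(mother, "mother")
  mp <- mid_parental(to_common_scale(f_peak, father$sex, scheme),
                     to_common_scale(m_peak, mother$sex, scheme))

  if (scheme$variant == "zscore") {
    z_target <- rtm$slope * mp + rtm$intercept
    target <- from_common_scale(z_target, child_sex, scheme)
  } else {
    # male-equivalent cm: standardize against the male reference, apply the
    # standardized map, de-standardize, then back to the child's sex
    z_mp <- (mp - ref$mean_male) / ref$sd_male
    z_target <- rtm$slope * z_mp + rtm$intercept
    target <- from_common_scale(ref$mean_male + z_target * ref$sd_male,
                                child_sex, scheme)
  }
  structure(
    list(target_height = target,
         target_percentile = height_to_percentile(target, child_sex, ref),
         common_scale_midparent = mp,
         child_sex = child_sex,
         parents = list(father = father, mother = mother,
                        father_peak = f_peak, mother_peak = m_peak),
         scheme = scheme, shrinkage_model = shrinkage_model, rtm = rtm,
         ref = ref),
    class = "target_prediction"
  )
}

#' @export
print.target_prediction <- function(x, ...) {
  cat(sprintf("Corrected target height (%s): %.1f cm (%.0fth percentile)\n",
              x$child_sex, round(x$target_height, 1),
              100 * x$target_percentile))
  cat(sprintf("  scheme: %s;  rtm: slope %.3g, intercept %.3g\n",
              x$scheme$label, x$rtm$slope, x$rtm$intercept))
  cat(sprintf("  parental peak heights: father %.1f cm, mother %.1f cm\n",
              x$parents$father_peak, x$parents$mother_peak))
  invisible(x)
}

#' Probability of a deviation from target height
#'
#' One-sided normal tail probability that a child's adult height deviates
#' from the target by at least the observed amount, under the empirical
#' residual distribution `D ~ Normal(0, sd_sex)`: `P(D <= d)` for negative
#' deviations, `P(D >= d)` for positive ones (0.5 at zero).
#'
#' @param deviation signed deviation(s), cm (child minus target).
#' @param child_sex sex code(s).
#' @param residual a [residual_model()].
#' @return tail probability in (0, 0.5].
#' @export
deviation_probability <- function(deviation, child_sex,
                                  residual = residual_model("pooled")) {
  stopifnot(inherits(residual, "residual_model"))
  sd <- .residual_sd(residual, child_sex)
  stats::pnorm(-abs(deviation) / sd)
}

#' Assess a child's projected height against the target
#'
#' Compares a projected adult height (a growth-chart or bone-age
#' extrapolation supplied by the clinician) with a corrected target
#' prediction: reports the deviation, its one- and two-sided tail
#' probabilities under the residual model, and for reference the classical
#' fixed-cutoff verdicts (Tanner +/-9/10 cm; +/-1.64 SDS).
#'
#' @param projected_height projected adult height, cm.
#' @param prediction a [corrected_target()] result for the same child.
#' @param residual a [residual_model()].
#' @param cutoffs a [cutoff_policy()].
#' @param ref reference population for the SDS cutoff conversion; defaults
#'   to the prediction's reference.
#' @return an object of class `"height_assessment"`.
#' @export
assess_child <- function(projected_height, prediction,
                         residual = residual_model("pooled"),
                         cutoffs = cutoff_policy(), ref = NULL) {
  stopifnot(inherits(prediction, "target_prediction"))
  if (!is.finite(projected_height) || projected_height <= 0) {
    stop("projected_height must be a positive number")
  }
  ref <- ref %||% prediction$ref
  sex <- prediction$child_sex
  dev <- projected_height - prediction$target_height
  p1 <- deviation_probability(dev, sex, residual)
  tanner_cut <- if (sex == "male") cutoffs$tanner_range_son else cutoffs$tanner_range_daughter
  sds_cut_cm <- sds_interval_to_cm(cutoffs$sds_range, sex, ref)
  structure(
    list(projected_height = projected_height,
         target_height = prediction$target_height,
         deviation = dev,
         probability_one_sided = p1,
         probability_two_sided = min(1, 2 * p1),
         tanner_cutoff_cm = tanner_cut,
         tanner_verdict = ifelse(abs(dev) <= tanner_cut, "inside", "outside"),
         sds_cutoff_cm = sds_cut_cm,
         sds_verdict = ifelse(abs(dev) <= sds_cut_cm, "inside", "outside"),
         residual = residual, cutoffs = cutoffs, child_sex = sex,
         prediction = prediction),
    class = "height_assessment"
  )
}

#' @export
print.height_assessment <- function(x, ...) {
  cat(sprintf("Projected %.1f cm vs target %.1f cm: deviation %+.1f cm\n",
              x$projected_height, x$target_height, x$deviation))
  cat(sprintf("  P(deviation at least this extreme, one-sided): %.0f%% (two-sided %.0f%%)\n",
              100 * x$probability_one_sided, 100 * x$probability_two_sided))
  cat(sprintf("  classical cutoffs: Tanner +/-%g cm -> %s; +/-%g SDS (%.1f cm) -> %s\n",
              x$tanner_cutoff_cm, x$tanner_verdict,
              x$cutoffs$sds_range, x$sds_cutoff_cm, x$sds_verdict))
  invisible(x)
}
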