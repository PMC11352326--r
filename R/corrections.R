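# Age correction: cumulative stature shrinkage, quadratic in years past onset
# (the shrinkage *rate* increases at a constant rate). Default acceleration is
# calibrated so that shrinkage at age 62, the cohort mean parental age, equals
# the 2.7 cm uncorrected intergenerational bias: 0.00264 * 32^2 = 2.70 cm.

#' Age-related height shrinkage model
#'
#' Cumulative loss of standing height starting at `onset_age` and
#' accelerating at a constant rate, i.e. quadratic in `(age - onset_age)`.
#' Per-sex accelerations are supported; the shipped default uses a single
#' calibrated acceleration for both sexes.
#'
#' @param onset_age age in years at which shrinkage begins (default 30).
#' @param accel_male,accel_female acceleration, cm/year^2 (>= 0).
#' @return an object of class `"age_shrinkage_model"`.
#' @export
age_shrinkage_model <- function(onset_age = 30, accel_male = 0.00264,
                                accel_female = 0.00264) {
  if (onset_age <= 0) stop("onset_age must be positive")
  if (accel_male < 0 || accel_female < 0) stop("accelerations must be >= 0")
  structure(list(onset_age = onset_age, accel_male = accel_male,
                 accel_female = accel_female),
            class = "age_shrinkage_model")
}

#' @export
print.age_shrinkage_model <- function(x, ...) {
  cat(sprintf("Shrinkage model: onset %g y, accel male %g cm/y^2, female %g cm/y^2\n",
              x$onset_age, x$accel_male, x$accel_female))
  invisible(x)
}

#' Cumulative shrinkage at a given age
#'
#' @param age age(s) in years, >= 0.
#' @param sex sex code(s), see [match_sex()].
#' @param model an [age_shrinkage_model()].
#' @return cm lost since peak: 0 at or below onset,
#'   `accel_sex * (age - onset)^2` beyond it.
#' @export
shrinkage <- function(age, sex, model = age_shrinkage_model()) {
  if (any(!is.finite(age)) || any(age < 0)) stop("age must be finite and >= 0")
  sex <- match_sex(sex)
  accel <- ifelse(sex == "male", model$accel_male, model$accel_female)
  accel * pmax(age - model$onset_age, 0)^2
}

#' Peak (age-corrected) height
#'
#' Adds back the estimated age-related shrinkage to a measured adult height;
#' a no-op at or below the shrinkage onset age.
#'
#' @param measured measured height(s), cm.
#' @inheritParams shrinkage
#' @return peak height(s), cm.
#' @export
peak_height <- function(measured, age, sex, model = age_shrinkage_model()) {
  if (any(measured <= 0)) stop("measured height must be positive")
  measured + shrinkage(age, sex, model)
}

#' Sex-correction scheme
#'
#' One of the three models for placing male and female heights on a common
#' scale: `additive` adds a constant to female heights (classical Tanner
#' uses 13 cm), `multiplicative` multiplies female heights by a factor
#' (1.08 from the CDC charts; Galton's original choice), and `zscore`
#' standardizes each sex by its reference mean and SD. For the first two the
#' common scale is male-equivalent cm; for `zscore` it is dimensionless SDS.
#'
#' @param variant `"additive"`, `"multiplicative"`, or `"zscore"`.
#' @param constant additive constant, cm (additive variant only).
#' @param factor multiplicative factor (multiplicative variant only).
#' @param ref a [reference_population()] (zscore variant only).
#' @param label display label.
#' @return an object of class `"sex_correction_scheme"`.
#' @seealso [scheme_preset()] for the named presets.
#' @export
sex_correction_scheme <- function(variant = c("additive", "multiplicative", "zscore"),
                                  constant = NULL, factor = NULL, ref = NULL,
                                  label = NULL) {
  variant <- match.arg(variant)
  switch(variant,
    additive = {
      if (is.null(constant)) stop("additive scheme requires `constant`")
      if (!is.null(factor)) stop("additive scheme takes no `factor`")
      label <- label %||% sprintf("+%g cm", constant)
    },
    multiplicative = {
      if (is.null(factor)) stop("multiplicative scheme requires `factor`")
      if (!is.null(constant)) stop("multiplicative scheme takes no `constant`")
      if (factor <= 0) stop("factor must be positive")
      label <- label %||% sprintf("* %g", factor)
    },
    zscore = {
      if (is.null(ref)) stop("zscore scheme requires a reference population")
      stopifnot(inherits(ref, "reference_population"))
      label <- label %||% sprintf("Z score (%s)", ref$label)
    }
  )
  structure(list(variant = variant, constant = constant, factor = factor,
                 ref = ref, label = label),
            class = "sex_correction_scheme")
}

#' @export
print.sex_correction_scheme <- function(x, ...) {
  cat(sprintf("Sex-correction scheme: %s [%s]\n", x$label, x$variant))
  invisible(x)
}

#' Named sex-correction scheme presets
#'
#' The six schemes of the evaluation table: `"tanner13"` (+13 cm),
#' `"mult1.08"` (x1.08, CDC-chart derived), `"zscore-cdc"`,
#' `"add10.82-sample"` and `"mult1.066-sample"` (constants fitted on the
#' study cohort, shipped as constants), and `"zscore-sample"` (per-sex
#' standardization against a cohort-estimated reference, which must be
#' supplied via `ref`, e.g. from [sample_reference()]).
#'
#' @param name preset name.
#' @param ref reference population for the zscore presets; defaults to
#'   [cdc_reference()] for `"zscore-cdc"` and is required for
#'   `"zscore-sample"`.
#' @return a [sex_correction_scheme()].
#' @export
scheme_preset <- function(name = c("tanner13", "mult1.08", "zscore-cdc",
                                   "add10.82-sample", "mult1.066-sample",
                                   "zscore-sample"),
                          ref = NULL) {
  name <- match.arg(name)
  switch(name,
    "tanner13" = sex_correction_scheme("additive", constant = 13, label = "+13 cm"),
    "mult1.08" = sex_correction_scheme("multiplicative", factor = 1.08, label = "* 1.08"),
    "zscore-cdc" = sex_correction_scheme("zscore", ref = ref %||% cdc_reference(),
                                         label = "Z score (CDC)"),
    "add10.82-sample" = sex_correction_scheme("additive", constant = 10.82,
                                              label = "+10.82 (Sample)"),
    "mult1.066-sample" = sex_correction_scheme("multiplicative", factor = 1.066,
                                               label = "* 1.066 (Sample)"),
    "zscore-sample" = {
      if (is.null(ref)) {
        stop("the 'zscore-sample' preset needs a cohort-estimated reference; ",
             "supply ref = sample_reference(cohort)")
      }
      sex_correction_scheme("zscore", ref = ref, label = "Z score (Sample)")
    }
  )
}

#' Transform a height to the scheme's common scale
#'
#' Additive/multiplicative schemes leave male heights unchanged and shift or
#' scale female heights to male-equivalent cm; the zscore scheme
#' standardizes both sexes to SDS.
#'
#' @param height height(s), cm, > 0.
#' @param sex sex code(s).
#' @param scheme a [sex_correction_scheme()].
#' @return common-scale value(s).
#' @export
to_common_scale <- function(height, sex, scheme) {
  stopifnot(inherits(scheme, "sex_correction_scheme"))
  if (any(height <= 0)) stop("height must be positive")
  sex <- rep_len(match_sex(sex), length(height))
  switch(scheme$variant,
    additive = ifelse(sex == "female", height + scheme$constant, height),
    multiplicative = ifelse(sex == "female", height * scheme$factor, height),
    zscore = height_to_zscore(height, sex, scheme$ref)
  )
}

#' Transform a common-scale value back to a height for a target sex
#'
#' Exact inverse of [to_common_scale()] for the same scheme and sex.
#'
#' @param value common-scale value(s).
#' @param sex target sex code(s).
#' @inheritParams to_common_scale
#' @return height(s), cm.
#' @export
from_common_scale <- function(value, sex, scheme) {
  stopifnot(inherits(scheme, "sex_correction_scheme"))
  sex <- rep_len(match_sex(sex), length(value))
  switch(scheme$variant,
    additive = ifelse(sex == "female", value - scheme$constant, value),
    multiplicative = ifelse(sex == "female", value / scheme$factor, value),
    zscore = zscore_to_height(value, sex, scheme$ref)
  )
}
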