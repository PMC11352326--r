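# Cohort container: a validated data.frame of nuclear-family members with
# columns family_id, person_id, role (father|mother|child), sex, age, height.

#' Validate a data frame as a family cohort
#'
#' Checks the nuclear-family structure (exactly one father and one mother
#' per family, at least one child), sex codes, the adult-height plausibility
#' window (100, 230) cm, and the adult-age inclusion rule (age >= 15).
#'
#' @param df a data frame with columns `family_id`, `person_id`, `role`,
#'   `sex`, `age`, `height` (the CSV aliases `age_years`/`height_cm` are
#'   accepted).
#' @return the cohort, classed `c("mph_cohort", "data.frame")`.
#' @export
as_cohort <- function(df) {
  stopifnot(is.data.frame(df))
  nm <- names(df)
  if ("age_years" %in% nm && !"age" %in% nm) names(df)[nm == "age_years"] <- "age"
  if ("height_cm" %in% nm && !"height" %in% nm) names(df)[names(df) == "height_cm"] <- "height"
  need <- c("family_id", "person_id", "role", "sex", "age", "height")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("cohort is missing column(s): ", paste(missing, collapse = ", "))
  df$role <- tolower(as.character(df$role))
  if (!all(df$role %in% c("father", "mother", "child"))) {
    stop("role must be one of father, mother, child")
  }
  df$sex <- match_sex(df$sex)
  if (any(df$role == "father" & df$sex != "male") ||
      any(df$role == "mother" & df$sex != "female")) {
    stop("fathers must be male and mothers female")
  }
  if (any(!is.finite(df$height) | df$height <= 100 | df$height >= 230)) {
    stop("heights must lie in the (100, 230) cm plausibility window")
  }
  if (any(!is.finite(df$age) | df$age < 15)) {
    stop("ages must be >= 15 years (adult heights only)")
  }
  byfam <- split(df$role, df$family_id)
  ok <- vapply(byfam, function(r) {
    sum(r == "father") == 1 && sum(r == "mother") == 1 && sum(r == "child") >= 1
  }, logical(1))
  if (!all(ok)) {
    stop("each family needs exactly one father, one mother and at least one child; ",
         "offending family_id(s): ", paste(names(byfam)[!ok], collapse = ", "))
  }
  df <- df[, need]
  class(df) <- c("mph_cohort", "data.frame")
  df
}

#' Read a family cohort from CSV
#'
#' Expects columns `family_id, person_id, role, sex, age_years, height_cm`
#' (roles `father|mother|child`, sex `M|F` or `male|female`).
#'
#' @param path path to a CSV file.
#' @return an `mph_cohort` data frame (see [as_cohort()]).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  as_cohort(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a family cohort to CSV
#'
#' @param cohort an `mph_cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "mph_cohort"))
  out <- data.frame(family_id = cohort$family_id, person_id = cohort$person_id,
                    role = cohort$role,
                    sex = ifelse(cohort$sex == "male", "M", "F"),
                    age_years = cohort$age, height_cm = cohort$height)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.mph_cohort <- function(x, ...) {
  fam <- unique(x$family_id)
  nchild <- table(x$family_id[x$role == "child"])
  cat(sprintf("Family cohort: %d families, %d children (%d-%d per family, mean %.1f)\n",
              length(fam), sum(x$role == "child"),
              min(nchild), max(nchild), mean(nchild)))
  NextMethod()
}

#' Estimate a reference population from a cohort
#'
#' Per-sex mean and SD of peak (age-corrected) heights across all adults in
#' the cohort, as used by the sample Z-score sex-correction scheme.
#'
#' @param cohort an `mph_cohort`.
#' @param shrinkage_model an [age_shrinkage_model()], or `NULL` to use
#'   measured heights.
#' @return a [reference_population()] labelled `"Sample"`.
#' @export
sample_reference <- function(cohort, shrinkage_model = age_shrinkage_model()) {
  stopifnot(inherits(cohort, "mph_cohort"))
  h <- if (is.null(shrinkage_model)) cohort$height else {
    peak_height(cohort$height, cohort$age, cohort$sex, shrinkage_model)
  }
  m <- cohort$sex == "male"
  reference_population(mean_male = mean(h[m]), sd_male = stats::sd(h[m]),
                       mean_female = mean(h[!m]), sd_female = stats::sd(h[!m]),
                       label = "Sample")
}

# Internal: per-child table of common-scale child value and family midparent
# value after optional age correction. Shared by the regression, residual and
# family-level analyses.
.cohort_common <- function(cohort, scheme, shrinkage_model = NULL) {
  stopifnot(inherits(cohort, "mph_cohort"), inherits(scheme, "sex_correction_scheme"))
  h <- if (is.null(shrinkage_model)) cohort$height else {
    peak_height(cohort$height, cohort$age, cohort$sex, shrinkage_model)
  }
  common <- to_common_scale(h, cohort$sex, scheme)
  parents <- cohort$role != "child"
  mp_by_fam <- tapply(common[parents], cohort$family_id[parents], mean)
  kids <- cohort[cohort$role == "child", ]
  data.frame(
    family_id = kids$family_id,
    person_id = kids$person_id,
    sex = kids$sex,
    height_peak = h[cohort$role == "child"],
    child_common = common[cohort$role == "child"],
    midparent_common = as.numeric(mp_by_fam[as.character(kids$family_id)]),
    stringsAsFactors = FALSE
  )
}

# Common-scale family target from a common-scale midparent value: for the
# zscore scheme the standardized map applies directly; for cm-scale schemes
# the male-equivalent value is standardized against the male reference first.
.target_common <- function(mp_common, scheme, rtm, ref) {
  if (scheme$variant == "zscore") {
    rtm$slope * mp_common + rtm$intercept
  } else {
    z <- (mp_common - ref$mean_male) / ref$sd_male
    ref$mean_male + (rtm$slope * z + rtm$intercept) * ref$sd_male
  }
}
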