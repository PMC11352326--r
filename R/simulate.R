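#' Parameters for the synthetic family-cohort simulator
#'
#' Defaults emulate the study cohort: 23 nuclear families with 7-16 adult
#' children each, parental ages 62 +/- 5 years, a standardized
#' offspring-on-midparent slope of 0.79, within-family residual SDs of
#' 4.5 cm (sons) and 4.2 cm (daughters), and quadratic post-age-30 parental
#' shrinkage. Spousal (assortative-mating) height correlation defaults to
#' 0.2; child ages are uniform on 20-45 years so child-side age correction
#' is a near no-op for most children.
#'
#' @param n_families number of families.
#' @param children_min,children_max family-size range (children per family,
#'   drawn uniformly).
#' @param midparent_slope standardized offspring-on-midparent slope.
#' @param residual_sd_son,residual_sd_daughter residual SDs, cm.
#' @param ref a [reference_population()] defining the peak-height scale.
#' @param assortative_corr spousal correlation of standardized heights,
#'   in `[0, 1)`.
#' @param parent_age_mean,parent_age_sd parental age distribution, years.
#' @param child_age_min,child_age_max child age range (uniform), years.
#' @param shrinkage an [age_shrinkage_model()] applied to produce measured
#'   (shrunken) heights from peak heights.
#' @param secular_trend constant added to children's peak heights, cm
#'   (default 0: no secular trend).
#' @return an object of class `"simulation_params"`.
#' @export
simulation_params <- function(n_families = 23, children_min = 7, children_max = 16,
                              midparent_slope = 0.79,
                              residual_sd_son = 4.5, residual_sd_daughter = 4.2,
                              ref = cdc_reference(), assortative_corr = 0.2,
                              parent_age_mean = 62, parent_age_sd = 5,
                              child_age_min = 20, child_age_max = 45,
                              shrinkage = age_shrinkage_model(),
                              secular_trend = 0) {
  stopifnot(n_families >= 1, children_min >= 1, children_max <= 20,
            children_min <= children_max,
            residual_sd_son > 0, residual_sd_daughter > 0,
            assortative_corr >= 0, assortative_corr < 1,
            parent_age_sd >= 0, child_age_min <= child_age_max,
            inherits(ref, "reference_population"),
            inherits(shrinkage, "age_shrinkage_model"))
  structure(as.list(environment()), class = "simulation_params")
}

#' Simulate a synthetic nuclear-family cohort
#'
#' Parents' peak standardized heights are drawn from a bivariate standard
#' normal with the assortative-mating correlation; each child's
#' standardized peak height is `slope * z_midparent + eps` with
#' `eps ~ Normal(0, residual_sd_sex / sd_sex)`; sexes are Bernoulli(0.5);
#' standardized values map to cm through the reference; measured heights
#' are peak heights minus the age-related shrinkage at each person's age.
#'
#' @param params a [simulation_params()].
#' @param seed optional integer seed; given the same seed the cohort is
#'   bit-identical across calls.
#' @return an `mph_cohort`.
#' @export
simulate_cohort <- function(params = simulation_params(), seed = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  if (!is.null(seed)) set.seed(seed)
  p <- params
  ref <- p$ref
  rho <- p$assortative_corr

  rows <- vector("list", p$n_families)
  for (i in seq_len(p$n_families)) {
    zf <- stats::rnorm(1)
    zm <- rho * zf + sqrt(1 - rho^2) * stats::rnorm(1)
    father_peak <- ref$mean_male + zf * ref$sd_male
    mother_peak <- ref$mean_female + zm * ref$sd_female
    father_age <- stats::rnorm(1, p$parent_age_mean, p$parent_age_sd)
    mother_age <- stats::rnorm(1, p$parent_age_mean, p$parent_age_sd)

    n_kids <- sample(p$children_min:p$children_max, 1)
    kid_sex <- ifelse(stats::runif(n_kids) < 0.5, "male", "female")
    sd_ref <- ifelse(kid_sex == "male", ref$sd_male, ref$sd_female)
    mean_ref <- ifelse(kid_sex == "male", ref$mean_male, ref$mean_female)
    sd_res <- ifelse(kid_sex == "male", p$residual_sd_son, p$residual_sd_daughter)
    z_mp <- (zf + zm) / 2
    z_kid <- p$midparent_slope * z_mp + stats::rnorm(n_kids, 0, sd_res / sd_ref)
    kid_peak <- mean_ref + z_kid * sd_ref + p$secular_trend
    kid_age <- stats::runif(n_kids, p$child_age_min, p$child_age_max)

    fid <- sprintf("F%03d", i)
    rows[[i]] <- data.frame(
      family_id = fid,
      person_id = c(paste0(fid, "-father"), paste0(fid, "-mother"),
                    sprintf("%s-child%02d", fid, seq_len(n_kids))),
      role = c("father", "mother", rep("child", n_kids)),
      sex = c("male", "female", kid_sex),
      age = c(father_age, mother_age, kid_age),
      height = c(father_peak - shrinkage(father_age, "male", p$shrinkage),
                 mother_peak - shrinkage(mother_age, "female", p$shrinkage),
                 kid_peak - shrinkage(kid_age, kid_sex, p$shrinkage)),
      stringsAsFactors = FALSE
    )
  }
  as_cohort(do.call(rbind, rows))
}

#' Noise-free cohort for exact-identity tests
#'
#' Same generative pipeline as [simulate_cohort()] but with the residual
#' term set to zero and every age fixed at 25 years (below the shrinkage
#' onset): each child's standardized height equals exactly
#' `slope * z_midparent`, so the offspring-on-midparent regression recovers
#' the generative slope to machine precision.
#'
#' @inheritParams simulate_cohort
#' @return an `mph_cohort`.
#' @export
ideal_cohort <- function(params = simulation_params(), seed = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  if (!is.null(seed)) set.seed(seed)
  ref <- params$ref
  rho <- params$assortative_corr
  rows <- vector("list", params$n_families)
  for (i in seq_len(params$n_families)) {
    zf <- stats::rnorm(1)
    zm <- rho * zf + sqrt(1 - rho^2) * stats::rnorm(1)
    n_kids <- sample(params$children_min:params$children_max, 1)
    kid_sex <- ifelse(stats::runif(n_kids) < 0.5, "male", "female")
    sd_ref <- ifelse(kid_sex == "male", ref$sd_male, ref$sd_female)
    mean_ref <- ifelse(kid_sex == "male", ref$mean_male, ref$mean_female)
    z_kid <- params$midparent_slope * (zf + zm) / 2
    fid <- sprintf("F%03d", i)
    rows[[i]] <- data.frame(
      family_id = fid,
      person_id = c(paste0(fid, "-father"), paste0(fid, "-mother"),
                    sprintf("%s-child%02d", fid, seq_len(n_kids))),
      role = c("father", "mother", rep("child", n_kids)),
      sex = c("male", "female", kid_sex),
      age = 25,
      height = c(ref$mean_male + zf * ref$sd_male,
                 ref$mean_female + zm * ref$sd_female,
                 mean_ref + z_kid * sd_ref),
      stringsAsFactors = FALSE
    )
  }
  as_cohort(do.call(rbind, rows))
}
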