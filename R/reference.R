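#' @keywords internal
"_PACKAGE"

# Sexes are stored as "male"/"female"; CSV and CLI inputs also accept M/F and 1/2.
.sexes <- c("male", "female")

#' Normalize a sex code
#'
#' Accepts `"male"`/`"female"`, `"M"`/`"F"` (any case), or the growth-chart
#' numeric convention `1` (male) / `2` (female), vectorized.
#'
#' @param sex character or numeric vector of sex codes.
#' @return character vector with elements `"male"` or `"female"`.
#' @export
match_sex <- function(sex) {
  if (is.numeric(sex)) {
    if (!all(sex %in% c(1, 2))) stop("numeric sex codes must be 1 (male) or 2 (female)")
    return(.sexes[sex])
  }
  s <- tolower(as.character(sex))
  s[s == "m"] <- "male"
  s[s == "f"] <- "female"
  if (!all(s %in% .sexes)) {
    stop("unrecognized sex code(s): ", paste(unique(sex[!s %in% .sexes]), collapse = ", "))
  }
  s
}

#' Reference population for height standardization
#'
#' Holds the per-sex adult mean and standard deviation of height used for
#' Z-score (SDS) standardization and percentile conversion.
#'
#' @param mean_male,sd_male adult male mean and SD height, cm.
#' @param mean_female,sd_female adult female mean and SD height, cm.
#' @param label short text label for provenance.
#' @return an object of class `"reference_population"`.
#' @seealso [cdc_reference()] for the shipped default.
#' @export
reference_population <- function(mean_male, sd_male, mean_female, sd_female,
                                 label = "custom") {
  stopifnot(is.numeric(mean_male), is.numeric(sd_male),
            is.numeric(mean_female), is.numeric(sd_female))
  if (sd_male <= 0 || sd_female <= 0) stop("reference SDs must be positive")
  structure(
    list(mean_male = as.numeric(mean_male), sd_male = as.numeric(sd_male),
         mean_female = as.numeric(mean_female), sd_female = as.numeric(sd_female),
         label = as.character(label)),
    class = "reference_population"
  )
}

#' @export
print.reference_population <- function(x, ...) {
  cat(sprintf("Reference population: %s\n", x$label))
  cat(sprintf("  male:   mean %.1f cm, SD %.2f cm\n", x$mean_male, x$sd_male))
  cat(sprintf("  female: mean %.1f cm, SD %.2f cm\n", x$mean_female, x$sd_female))
  invisible(x)
}

#' Adult CDC-anchored reference population
#'
#' Per-sex adult (age-20) normal reference derived from published anchor
#' points of the CDC growth charts: the 95% SDS interval of +/-1.64 SDS
#' corresponds to 10.6 cm for women and 11.7 cm for men (so
#' `sd_female = 10.6/1.64`, `sd_male = 11.7/1.64`), 163 cm is the female
#' median, and 163 cm sits at the male 3rd percentile
#' (`mean_male = 163 - qnorm(0.03) * sd_male`).
#'
#' @return a [reference_population()].
#' @export
cdc_reference <- function() {
  sd_f <- 10.6 / 1.64
  sd_m <- 11.7 / 1.64
  reference_population(
    mean_male = 163 - stats::qnorm(0.03) * sd_m, sd_male = sd_m,
    mean_female = 163, sd_female = sd_f,
    label = "CDC (derived adult anchors)"
  )
}

.ref_mean <- function(ref, sex) ifelse(sex == "male", ref$mean_male, ref$mean_female)
.ref_sd <- function(ref, sex) ifelse(sex == "male", ref$sd_male, ref$sd_female)

#' Convert height to a Z-score (SDS)
#'
#' @param height height in cm (vectorized).
#' @param sex sex code(s), see [match_sex()].
#' @param ref a [reference_population()].
#' @return Z-score(s): `(height - mean_sex) / sd_sex`.
#' @export
height_to_zscore <- function(height, sex, ref = cdc_reference()) {
  if (!all(is.finite(height))) stop("height must be finite")
  sex <- match_sex(sex)
  (height - .ref_mean(ref, sex)) / .ref_sd(ref, sex)
}

#' Convert a Z-score (SDS) to height
#'
#' Inverse of [height_to_zscore()].
#'
#' @param z Z-score(s).
#' @inheritParams height_to_zscore
#' @return height(s) in cm.
#' @export
zscore_to_height <- function(z, sex, ref = cdc_reference()) {
  if (!all(is.finite(z))) stop("z must be finite")
  sex <- match_sex(sex)
  .ref_mean(ref, sex) + z * .ref_sd(ref, sex)
}

#' Convert a percentile to height under the normal reference model
#'
#' @param p percentile as a fraction in (0, 1) (vectorized).
#' @inheritParams height_to_zscore
#' @return height(s) in cm: `mean_sex + sd_sex * qnorm(p)`.
#' @export
percentile_to_height <- function(p, sex, ref = cdc_reference()) {
  if (!all(is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("percentile must be a fraction strictly between 0 and 1")
  }
  zscore_to_height(stats::qnorm(p), sex, ref)
}

#' Convert height to a percentile under the normal reference model
#'
#' Exact inverse of [percentile_to_height()].
#'
#' @inheritParams height_to_zscore
#' @return percentile fraction(s) in (0, 1).
#' @export
height_to_percentile <- function(height, sex, ref = cdc_reference()) {
  stats::pnorm(height_to_zscore(height, sex, ref))
}

#' Width of an SDS interval in cm
#'
#' Converts a symmetric SDS half-width (e.g. the 1.64 SDS used for 95%
#' normal-range cutoffs) to cm for a given sex.
#'
#' @param sds positive SDS half-width.
#' @inheritParams height_to_zscore
#' @return cm: `sds * sd_sex`.
#' @export
sds_interval_to_cm <- function(sds, sex, ref = cdc_reference()) {
  if (any(sds < 0)) stop("sds must be non-negative")
  sex <- match_sex(sex)
  sds * .ref_sd(ref, sex)
}

#' Percentile table of adult heights by sex
#'
#' @param percentile percentile fractions in (0, 1), strictly increasing.
#' @param height_male,height_female heights in cm, strictly increasing.
#' @param provenance text describing where the table came from.
#' @return an object of class `"percentile_table"` (a data frame).
#' @export
percentile_table <- function(percentile, height_male, height_female,
                             provenance = "unspecified") {
  if (length(percentile) < 2) stop("a percentile table needs at least 2 rows")
  if (any(percentile <= 0) || any(percentile >= 1)) {
    stop("percentiles must be fractions in (0, 1)")
  }
  if (any(diff(percentile) <= 0)) stop("percentiles must be strictly increasing")
  if (any(diff(height_male) <= 0) || any(diff(height_female) <= 0)) {
    stop("heights must be strictly increasing with percentile for each sex")
  }
  structure(
    data.frame(percentile = percentile, height_male = height_male,
               height_female = height_female),
    provenance = provenance,
    class = c("percentile_table", "data.frame")
  )
}

#' Zero-intercept multiplicative sex-correction factor
#'
#' Regresses male height on female height at the same percentile with the
#' intercept forced to zero; the slope is the multiplicative factor that
#' converts female to male-equivalent height.
#'
#' @param female,male paired heights in cm at matching percentiles. `female`
#'   may also be a [percentile_table()], in which case `male` is ignored.
#' @return the least-squares slope `sum(male * female) / sum(female^2)`.
#' @export
fit_multiplicative_factor <- function(female, male = NULL) {
  if (inherits(female, "percentile_table")) {
    male <- female$height_male
    female <- female$height_female
  }
  if (length(female) < 2 || length(female) != length(male)) {
    stop("need at least 2 paired heights")
  }
  if (any(female < 0) || any(male < 0)) stop("heights must be positive")
  denom <- sum(female^2)
  if (denom == 0) stop("female heights are all zero; factor undefined")
  sum(male * female) / denom
}

#' Male-female height difference profile across percentiles
#'
#' Computes the male minus female height difference at each percentile of a
#' table and fits a line of difference on female height. A constant
#' (additive) sex correction corresponds to slope 0; a multiplicative
#' correction by factor k corresponds to slope k - 1 through the origin.
#'
#' @param table a [percentile_table()].
#' @return a list with `profile` (data frame: percentile, female_height,
#'   difference), `slope`, `intercept`, and `r_squared` of the linear fit.
#' @export
sex_difference_profile <- function(table) {
  stopifnot(inherits(table, "percentile_table"))
  d <- table$height_male - table$height_female
  f <- table$height_female
  fit <- stats::lm(d ~ f)
  sst <- sum((d - mean(d))^2)
  list(
    profile = data.frame(percentile = table$percentile, female_height = f,
                         difference = d),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    # R^2 computed from residual sums; NA for a constant difference profile
    r_squared = if (sst <= 1e-12 * (mean(d)^2 + 1)) NA_real_ else
      1 - sum(stats::residuals(fit)^2) / sst
  )
}

#' Read a growth-chart percentile table from CSV
#'
#' Understands two dialects: the CDC stature-for-age ("statage") layout with
#' columns `Sex` (1 = male, 2 = female), `Agemos`, and percentile columns
#' `P3 P5 P10 P25 P50 P75 P90 P95 P97`; and a simple 3-column layout
#' `percentile,height_male,height_female` (percentiles as fractions or on
#' the 0-100 scale). For the CDC dialect the final (oldest) age present is
#' used, i.e. adult height.
#'
#' @param path path to a CSV file.
#' @return a [percentile_table()].
#' @export
read_reference_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  pcols <- c("p3", "p5", "p10", "p25", "p50", "p75", "p90", "p95", "p97")
  if (all(c("sex", "agemos") %in% nm) && all(pcols %in% nm)) {
    names(df) <- nm
    .parse_statage(df, path)
  } else if (all(c("percentile", "height_male", "height_female") %in% nm)) {
    names(df) <- nm
    .parse_simple_table(df, path)
  } else {
    stop("unrecognized growth-chart CSV dialect in ", path,
         ": expected CDC statage columns (Sex, Agemos, P3..P97) or ",
         "(percentile, height_male, height_female)")
  }
}

# Coerce a column to numeric, reporting the first malformed row by CSV line
# number (header is line 1).
.num_col <- function(df, col, path) {
  v <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(!is.finite(v))
  if (length(bad)) {
    stop(sprintf("malformed row at line %d of %s: non-numeric '%s'",
                 bad[1] + 1L, path, col))
  }
  v
}

.parse_statage <- function(df, path) {
  pcols <- c("p3", "p5", "p10", "p25", "p50", "p75", "p90", "p95", "p97")
  for (col in c("agemos", pcols)) df[[col]] <- .num_col(df, col, path)
  bad <- which(!df$sex %in% c(1, 2))
  if (length(bad)) {
    stop(sprintf("malformed row at line %d of %s: Sex must be 1 or 2",
                 bad[1] + 1L, path))
  }
  age <- max(df$agemos)
  last <- df[df$agemos == age, , drop = FALSE]
  get_sex <- function(code) {
    row <- last[last$sex == code, pcols, drop = FALSE]
    if (nrow(row) != 1) {
      stop("expected exactly one row per sex at the oldest age (",
           age, " months) in ", path)
    }
    as.numeric(row[1, ])
  }
  percentile_table(
    percentile = c(3, 5, 10, 25, 50, 75, 90, 95, 97) / 100,
    height_male = get_sex(1), height_female = get_sex(2),
    provenance = sprintf("%s (statage dialect, age %g months)", basename(path), age)
  )
}

.parse_simple_table <- function(df, path) {
  for (col in c("percentile", "height_male", "height_female")) {
    df[[col]] <- .num_col(df, col, path)
  }
  p <- df$percentile
  if (any(p > 1)) p <- p / 100  # 0-100 scale
  o <- order(p)
  percentile_table(p[o], df$height_male[o], df$height_female[o],
                   provenance = basename(path))
}

#' Read a reference population from a YAML or JSON config file
#'
#' The file must provide `mean_male`, `sd_male`, `mean_female`, `sd_female`
#' (cm) and may provide `label`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [reference_population()].
#' @export
read_reference_population <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("mean_male", "sd_male", "mean_female", "sd_female")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    stop("reference config ", path, " missing field(s): ",
         paste(missing, collapse = ", "))
  }
  reference_population(cfg$mean_male, cfg$sd_male, cfg$mean_female,
                       cfg$sd_female, label = cfg$label %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
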