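#' Education correction of a raw MoCA score
#'
#' Adds one point for participants with fewer than 12 years of education, the
#' instrument's standard low-education correction, capped at the instrument
#' maximum of 30. Vectorised over both arguments.
#'
#' @param raw integer score(s) in 0-30.
#' @param education years of education (>= 0).
#' @return integer score(s) in 0-30; `adjusted - raw` is always 0 or 1.
#' @examples
#' education_adjust(25, 10)  # 26
#' education_adjust(25, 12)  # 25 (12 years is not < 12)
#' education_adjust(30, 8)   # 30 (capped)
#' @export
education_adjust <- function(raw, education) {
  if (any(raw < 0 | raw > SCORE_MAX, na.rm = TRUE)) {
    stop("raw score outside [0,", SCORE_MAX, "]", call. = FALSE)
  }
  if (any(education < 0, na.rm = TRUE)) stop("education must be >= 0")
  as.integer(pmin(SCORE_MAX, raw + as.integer(education < 12)))
}

#' Demographic normative model for z-scores
#'
#' A linear normative model `predicted = intercept + beta_age * age +
#' beta_edu * education + beta_sex * [sex == "M"]` with a residual standard
#' deviation, used to convert raw scores into demographically corrected
#' z-scores. Published normative coefficients are supplied by the user as
#' configuration; the package default [default_norm_model()] is a clearly
#' labelled synthetic placeholder.
#'
#' @param intercept predicted score for the reference subject (score points).
#' @param beta_age points per year of age.
#' @param beta_edu points per year of education.
#' @param beta_sex points added when sex is `"M"` (indicator coding).
#' @param residual_sd residual standard deviation (score points, > 0).
#' @return object of class `norm_model`.
#' @export
norm_model <- function(intercept, beta_age = 0, beta_edu = 0, beta_sex = 0,
                       residual_sd) {
  stopifnot(is.numeric(residual_sd), residual_sd > 0)
  structure(list(intercept = intercept, beta_age = beta_age,
                 beta_edu = beta_edu, beta_sex = beta_sex,
                 residual_sd = residual_sd),
            class = "norm_model")
}

#' @export
print.norm_model <- function(x, ...) {
  cat(sprintf(
    "norm_model: predicted = %.3f + %.4f*age + %.4f*edu + %.4f*[M]; sd = %.3f\n",
    x$intercept, x$beta_age, x$beta_edu, x$beta_sex, x$residual_sd))
  invisible(x)
}

#' Synthetic placeholder normative model
#'
#' NOT a published norm: a placeholder calibrated so that simulated normal
#' controls (MoCA mean 26.5, SD 2.4) get z-scores with mean ~0 and SD ~1.
#' Replace with real normative coefficients for any substantive use.
#'
#' @return a [norm_model()].
#' @export
default_norm_model <- function() {
  norm_model(intercept = 26.5, residual_sd = 2.4)
}

#' Demographically corrected z-score
#'
#' `z = (raw - predicted(age, sex, education)) / residual_sd`. Affine in the
#' raw score with positive slope `1/residual_sd`, so ordering of subjects with
#' identical demographics is preserved. Vectorised.
#'
#' @param raw raw score(s).
#' @param age years.
#' @param sex `"F"` or `"M"`.
#' @param education years.
#' @param model a [norm_model()].
#' @return numeric z-score(s).
#' @export
z_score <- function(raw, age, sex, education, model = default_norm_model()) {
  stopifnot(inherits(model, "norm_model"))
  predicted <- model$intercept + model$beta_age * age +
    model$beta_edu * education + model$beta_sex * (toupper(sex) == "M")
  (raw - predicted) / model$residual_sd
}
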