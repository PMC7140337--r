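#' Generative parameters for one diagnostic group
#'
#' Describes how one group's subjects are simulated: discrete test scores as
#' `round(Normal(mean, sd))` clipped to 0-30 (rounding half away from zero),
#' demographics from range-truncated normals rounded to integer years, sex as
#' Bernoulli draws, and z-scores either directly normal or (when a
#' [norm_model()] is supplied to the simulator) computed from the simulated
#' raw score and demographics.
#'
#' @param label group label (`"NC"`, `"NF"`, `"MILD"`, `"MAJOR"`).
#' @param n number of subjects (>= 0).
#' @param moca_mean,moca_sd MoCA generative mean/SD (score points).
#' @param mmse_mean,mmse_sd MMSE generative mean/SD (score points).
#' @param z_mean,z_sd z-score generative mean/SD (standard units).
#' @param age_mean,age_sd,age_range age distribution (years; range truncates).
#' @param edu_mean,edu_sd,edu_range education distribution (years).
#' @param female_fraction probability a subject is female, in `[0, 1]`.
#' @return object of class `group_spec`.
#' @export
group_spec <- function(label, n, moca_mean, moca_sd, mmse_mean, mmse_sd,
                       z_mean, z_sd, age_mean, age_sd, age_range,
                       edu_mean, edu_sd, edu_range, female_fraction) {
  label <- toupper(label)
  stopifnot(label %in% GROUP_LEVELS, n >= 0,
            moca_sd >= 0, mmse_sd >= 0, z_sd >= 0, age_sd >= 0, edu_sd >= 0,
            length(age_range) == 2, age_range[1] <= age_range[2],
            length(edu_range) == 2, edu_range[1] <= edu_range[2],
            female_fraction >= 0, female_fraction <= 1)
  structure(list(label = label, n = as.integer(n),
                 moca_mean = moca_mean, moca_sd = moca_sd,
                 mmse_mean = mmse_mean, mmse_sd = mmse_sd,
                 z_mean = z_mean, z_sd = z_sd,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 edu_mean = edu_mean, edu_sd = edu_sd, edu_range = edu_range,
                 female_fraction = female_fraction),
            class = "group_spec")
}

#' Solve mixture-component moments for an unreported subgroup
#'
#' Given the pooled mean/SD of a two-component mixture, the moments of one
#' component and the component sizes, returns the mean/SD the other component
#' must have for the mixture to reproduce the pooled moments exactly
#' (first- and second-moment identities).
#'
#' @param pooled_mean,pooled_sd pooled target moments.
#' @param known_mean,known_sd known component moments.
#' @param n_known,n_other component sizes.
#' @return list with `mean` and `sd` of the other component.
#' @examples
#' # MoCA: pooled patients (19.1, 4.5) from MILD (22.0, 3.6), 159:288
#' solve_mixture_component(19.1, 4.5, 22.0, 3.6, 159, 288)
#' @export
solve_mixture_component <- function(pooled_mean, pooled_sd, known_mean,
                                    known_sd, n_known, n_other) {
  w1 <- n_known / (n_known + n_other)
  w2 <- 1 - w1
  m2 <- (pooled_mean - w1 * known_mean) / w2
  ex2 <- pooled_sd^2 + pooled_mean^2          # pooled second moment
  ex2_other <- (ex2 - w1 * (known_sd^2 + known_mean^2)) / w2
  v2 <- ex2_other - m2^2
  if (v2 < 0) {
    stop("no real solution: implied component variance is negative",
         call. = FALSE)
  }
  list(mean = m2, sd = sqrt(v2))
}

#' Default memory-clinic cohort specification
#'
#' Four groups with the published memory-clinic study structure: 283 normal
#' controls (NC), 49 clinic patients with normal cognitive findings (NF), 159
#' Mild NCD and 288 Major NCD patients (447 patients in total). Score and
#' demographic parameters follow the published group table; the Major-NCD
#' parameters are not published separately and are solved by
#' [solve_mixture_component()] so the 159:288 Mild:Major mixture reproduces
#' the published pooled patient moments — MoCA (19.1, 4.5), MMSE (25.1, 3.5),
#' z (-2.1, 1.0).
#'
#' @param seed master seed; per-group substreams are derived from it so any
#'   single group can be regenerated independently.
#' @return object of class `cohort_spec`: list of four [group_spec()]s plus
#'   the seed.
#' @export
default_cohort_spec <- function(seed = 1L) {
  mo <- solve_mixture_component(19.1, 4.5, 22.0, 3.6, 159, 288)
  mm <- solve_mixture_component(25.1, 3.5, 27.2, 2.2, 159, 288)
  zz <- solve_mixture_component(-2.1, 1.0, -1.5, 1.0, 159, 288)
  ag <- solve_mixture_component(78.3, 5.9, 76.0, 6.0, 159, 288)
  ed <- solve_mixture_component(12.2, 3.0, 12.4, 3.1, 159, 288)
  # pooled female fraction 0.557, Mild 0.535 -> Major by first-moment identity
  fem <- (0.557 - (159 / 447) * 0.535) / (288 / 447)
  cohort_spec(list(
    group_spec("NC", 283, 26.5, 2.4, 29.2, 0.9, 0.0, 1.0,
               73.8, 5.2, c(65, 91), 13.6, 2.9, c(7, 20), 0.548),
    group_spec("NF", 49, 26.5, 2.2, 29.0, 1.0, 0.1, 1.0,
               73.1, 5.6, c(65, 88), 13.8, 2.7, c(8, 20), 0.408),
    group_spec("MILD", 159, 22.0, 3.6, 27.2, 2.2, -1.5, 1.0,
               76.0, 6.0, c(65, 91), 12.4, 3.1, c(7, 20), 0.535),
    group_spec("MAJOR", 288, mo$mean, mo$sd, mm$mean, mm$sd, zz$mean, zz$sd,
               ag$mean, ag$sd, c(65, 91), ed$mean, ed$sd, c(7, 20), fem)
  ), seed = seed)
}

#' Bundle group specifications into a cohort specification
#'
#' @param groups list of four [group_spec()]s with distinct labels.
#' @param seed integer master seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, seed = 1L) {
  labels <- vapply(groups, function(g) g$label, character(1))
  if (anyDuplicated(labels)) stop("group labels must be distinct")
  structure(list(groups = setNames(groups, labels), seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("cohort_spec (seed", x$seed, ")\n")
  for (g in x$groups) {
    cat(sprintf("  %-5s n=%4d  MoCA %.2f (%.2f)  MMSE %.2f (%.2f)  z %.2f (%.2f)\n",
                g$label, g$n, g$moca_mean, g$moca_sd, g$mmse_mean, g$mmse_sd,
                g$z_mean, g$z_sd))
  }
  invisible(x)
}

# truncated-normal sampler via inverse CDF; degenerate sd -> constant mean
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  pmin(upper, pmax(lower, qnorm(u, mean, sd)))
}

# discrete 0-30 score: round half away from zero, then clip
sim_score <- function(n, mean, sd) {
  as.integer(pmin(SCORE_MAX, pmax(0, round_half_away(rnorm(n, mean, sd)))))
}

# exact moments of clip(round(Normal(m, s)), 0, 30)
discretised_moments <- function(m, s) {
  k <- 0:SCORE_MAX
  hi <- pnorm(k + 0.5, m, s)
  lo <- pnorm(k - 0.5, m, s)
  p <- hi - lo
  p[1] <- hi[1]                      # all mass below 0.5 lands on 0
  p[length(p)] <- 1 - lo[length(p)]  # all mass above 29.5 lands on 30
  mu <- sum(k * p)
  list(mean = mu, sd = sqrt(max(0, sum(k^2 * p) - mu^2)))
}

#' Latent normal parameters reproducing target observed score moments
#'
#' Published group means/SDs describe the *observed* discrete, bounded scores.
#' Rounding adds variance and the 0/30 bounds truncate it (near the ceiling
#' the observed mean also shifts down), so drawing at the printed parameters
#' and discretising would systematically miss them. This solves, by
#' fixed-point iteration on the exact discretised moments, for the latent
#' `Normal(mean, sd)` whose rounded and clipped scores have the target mean
#' and SD.
#'
#' @param target_mean,target_sd observed-score moments to reproduce
#'   (`target_sd > 0`).
#' @return list with latent `mean` and `sd`.
#' @examples
#' lat <- calibrate_latent(29.2, 0.9)  # near-ceiling MMSE controls
#' @export
calibrate_latent <- function(target_mean, target_sd) {
  stopifnot(target_sd > 0, target_mean >= 0, target_mean <= SCORE_MAX)
  m <- target_mean
  s <- target_sd
  for (i in 1:200) {
    obs <- discretised_moments(m, s)
    dm <- target_mean - obs$mean
    rs <- target_sd / obs$sd
    m <- m + dm
    s <- s * rs
    if (abs(dm) < 1e-10 && abs(rs - 1) < 1e-10) break
  }
  list(mean = m, sd = s)
}

#' Simulate one diagnostic group
#'
#' Draws `g$n` subjects under the group's generative parameters. Scores are
#' drawn independently of each other (no within-subject MoCA-MMSE
#' correlation). When `model` is supplied, `moca_z` is computed from the
#' simulated raw MoCA score and demographics instead of being drawn from the
#' group's z distribution. Seeding is the caller's responsibility (see
#' [simulate_study()] for seeded use).
#'
#' @param g a [group_spec()].
#' @param id_prefix prefix for subject ids.
#' @param model optional [norm_model()] for derived z-scores.
#' @param calibrate treat the group specification's score means/SDs as target
#'   *observed* moments and draw from the [calibrate_latent()] solution
#'   (default), so the simulated discrete scores reproduce them; `FALSE`
#'   draws the latent normal at those values directly, accepting the
#'   rounding/clipping distortion.
#' @return data.frame of `g$n` subject rows (no cohort class; internal to
#'   [simulate_study()] but exported for testing single groups).
#' @export
simulate_group <- function(g, id_prefix = g$label, model = NULL,
                           calibrate = TRUE) {
  stopifnot(inherits(g, "group_spec"))
  n <- g$n
  age <- as.integer(round_half_away(
    rtruncnorm(n, g$age_mean, g$age_sd, g$age_range[1], g$age_range[2])))
  edu <- as.integer(round_half_away(
    rtruncnorm(n, g$edu_mean, g$edu_sd, g$edu_range[1], g$edu_range[2])))
  sex <- ifelse(rbinom(n, 1, g$female_fraction) == 1, "F", "M")
  latent <- function(mean, sd) {
    if (calibrate && sd > 0) calibrate_latent(mean, sd) else
      list(mean = mean, sd = sd)
  }
  lmo <- latent(g$moca_mean, g$moca_sd)
  lmm <- latent(g$mmse_mean, g$mmse_sd)
  moca <- sim_score(n, lmo$mean, lmo$sd)
  mmse <- sim_score(n, lmm$mean, lmm$sd)
  z <- if (is.null(model)) {
    rnorm(n, g$z_mean, g$z_sd)
  } else {
    z_score(moca, age, sex, edu, model)
  }
  data.frame(
    id = sprintf("%s-%04d", id_prefix, seq_len(n)),
    group = rep(g$label, n), age = age, education = edu, sex = sex,
    moca_raw = moca, mmse = mmse, moca_z = z,
    stringsAsFactors = FALSE
  )
}

#' Simulate a full study cohort
#'
#' Deterministic given the specification's seed: each group uses a substream
#' seed
#' derived from the master seed and the group's position, so regenerating any
#' subset of groups reproduces the same subjects.
#'
#' @param spec a [cohort_spec()]; defaults to the published study structure.
#' @param model optional [norm_model()] passed to [simulate_group()].
#' @param calibrate see [simulate_group()].
#' @return a [study_cohort()] whose provenance records the seed.
#' @examples
#' ds <- simulate_study(default_cohort_spec(seed = 42))
#' table(ds$group)
#' @export
simulate_study <- function(spec = default_cohort_spec(), model = NULL,
                           calibrate = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  parts <- vector("list", length(spec$groups))
  for (i in seq_along(spec$groups)) {
    set.seed(derive_seed(spec$seed, i))
    parts[[i]] <- simulate_group(spec$groups[[i]], model = model,
                                 calibrate = calibrate)
  }
  study_cohort(do.call(rbind, parts),
               provenance = sprintf("simulated (seed=%d, groups=%s)",
                                    spec$seed,
                                    paste(names(spec$groups), collapse = "/")))
}
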