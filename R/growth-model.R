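#' Parameters of the synthetic mandibular growth law
#'
#' The simulator models mandibular length (Condylion-Pogonion distance, mm)
#' as a linear background plus a logistic pubertal spurt:
#' \deqn{L(t) = b + r (t - 96) + g \,\sigma\!\left(\frac{t - p}{s}\right)}
#' where \eqn{t} is age in months, \eqn{b} the length at age 8 years
#' (96 months), \eqn{r} the background growth rate, \eqn{g} the total extra
#' length added by the spurt, \eqn{p} the age of peak velocity and \eqn{s}
#' the logistic time scale. The velocity \eqn{dL/dt} is then the logistic
#' density, with a single maximum exactly at \eqn{t = p} — the analytic
#' ground truth the staging module must recover.
#'
#' @param baseline_length_mm mandibular length at age 96 months (mm, > 0).
#' @param linear_rate_mm_per_month background growth rate (mm/month, >= 0).
#' @param spurt_gain_mm total length added by the pubertal spurt (mm, >= 0;
#'   zero gives purely linear growth).
#' @param peak_age_months age of peak growth velocity, in [96, 180].
#' @param spurt_scale_months logistic time scale of the spurt (months, > 0).
#' @param noise_sd_mm standard deviation of measurement noise added to each
#'   observed length (mm, >= 0).
#' @param sex `"F"` or `"M"` (carried through to the series manifest).
#' @return An object of class `growth_model_params`.
#' @seealso [simulate_growth_series()], [sample_growth_model_params()]
#' @export
growth_model_params <- function(baseline_length_mm = 100,
                                linear_rate_mm_per_month = 0.05,
                                spurt_gain_mm = 12,
                                peak_age_months = 144,
                                spurt_scale_months = 6,
                                noise_sd_mm = 0.3,
                                sex = c("F", "M")) {
  sex <- match.arg(sex)
  check_number(baseline_length_mm, "baseline_length_mm", min = 0, strict_min = TRUE)
  check_number(linear_rate_mm_per_month, "linear_rate_mm_per_month", min = 0)
  check_number(spurt_gain_mm, "spurt_gain_mm", min = 0)
  check_number(peak_age_months, "peak_age_months", min = 96, max = 180)
  check_number(spurt_scale_months, "spurt_scale_months", min = 0, strict_min = TRUE)
  check_number(noise_sd_mm, "noise_sd_mm", min = 0)
  structure(
    list(
      baseline_length_mm = baseline_length_mm,
      linear_rate_mm_per_month = linear_rate_mm_per_month,
      spurt_gain_mm = spurt_gain_mm,
      peak_age_months = peak_age_months,
      spurt_scale_months = spurt_scale_months,
      noise_sd_mm = noise_sd_mm,
      sex = sex
    ),
    class = "growth_model_params"
  )
}

#' Draw growth-law parameters from a population prior
#'
#' Samples subject-level parameters around typical values for longitudinal
#' cephalometric growth studies. Sex shifts only the prior mean of the peak
#' age (girls earlier than boys: 138 vs 156 months).
#'
#' @param sex `"F"` or `"M"`.
#' @param seed integer seed.
#' @param noise_sd_mm measurement noise passed through to the parameters.
#' @return A `growth_model_params` object.
#' @export
sample_growth_model_params <- function(sex = c("F", "M"), seed, noise_sd_mm = 0.3) {
  sex <- match.arg(sex)
  with_seed(seed, {
    peak_mean <- if (sex == "F") 138 else 156
    peak <- min(170, max(115, stats::rnorm(1, peak_mean, 8)))
    growth_model_params(
      baseline_length_mm = stats::rnorm(1, 100, 3),
      linear_rate_mm_per_month = stats::runif(1, 0.03, 0.08),
      spurt_gain_mm = max(6, stats::rnorm(1, 12, 2)),
      peak_age_months = peak,
      spurt_scale_months = stats::runif(1, 4, 8),
      noise_sd_mm = noise_sd_mm,
      sex = sex
    )
  })
}

#' True mandibular length under the synthetic growth law
#'
#' @param age_months numeric vector of ages (months).
#' @param params a [growth_model_params()] object.
#' @return Numeric vector of lengths (mm), noise-free.
#' @export
true_length <- function(age_months, params) {
  stopifnot(inherits(params, "growth_model_params"))
  z <- (age_months - params$peak_age_months) / params$spurt_scale_months
  params$baseline_length_mm +
    params$linear_rate_mm_per_month * (age_months - 96) +
    params$spurt_gain_mm * stats::plogis(z)
}

# geometry of the synthetic film: landmark anchor positions in mm
# (1 mm per pixel when rendered); origin top-left, y increases downward
.film_geom <- list(
  co = c(x = 20, y = 40),          # condylion: posterior-superior
  mand_angle_deg = 35,             # Co -> Pog direction below horizontal
  column_x = 60,                   # cervical column centerline
  basion_y = 48,                   # superior ROI limit
  c4_y = 112,                      # inferior ROI limit
  film_size = 160                  # full synthetic film is 160 x 160 px
)

#' Construct a growth series from its parts
#'
#' @param subject_id opaque subject identifier.
#' @param films data frame with columns `film_index`, `age_months`, `co_x`,
#'   `co_y`, `pog_x`, `pog_y`, `basion_x`, `basion_y`, `c4inf_x`, `c4inf_y`,
#'   `image_ref`, `quality_ok`.
#' @param sex `"F"` or `"M"`.
#' @param skeletal_class `"I"`, `"II"` or `"III"`.
#' @param syndromic logical flag (exclusion criterion).
#' @param true_peak_age_months known peak age for synthetic series, or `NA`.
#' @return Object of class `growth_series`.
#' @export
growth_series <- function(subject_id, films, sex = "F", skeletal_class = "I",
                          syndromic = FALSE, true_peak_age_months = NA_real_) {
  stopifnot(is.data.frame(films), nrow(films) >= 1)
  needed <- c("film_index", "age_months", "co_x", "co_y", "pog_x", "pog_y",
              "basion_x", "basion_y", "c4inf_x", "c4inf_y")
  missing_cols <- setdiff(needed, names(films))
  if (length(missing_cols) > 0) {
    stopf("films is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (!"image_ref" %in% names(films)) films$image_ref <- NA_character_
  if (!"quality_ok" %in% names(films)) films$quality_ok <- TRUE
  if (any(!is.finite(films$age_months)) || any(films$age_months <= 0)) {
    stop("film ages must be positive and finite", call. = FALSE)
  }
  if (is.unsorted(films$age_months, strictly = TRUE)) {
    stop("film ages must be strictly increasing", call. = FALSE)
  }
  if (!sex %in% c("F", "M")) stop("`sex` must be \"F\" or \"M\"", call. = FALSE)
  if (!skeletal_class %in% c("I", "II", "III")) {
    stop("`skeletal_class` must be one of \"I\", \"II\", \"III\"", call. = FALSE)
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      sex = sex,
      skeletal_class = skeletal_class,
      syndromic = isTRUE(syndromic),
      films = films,
      true_peak_age_months = true_peak_age_months
    ),
    class = "growth_series"
  )
}

#' @export
print.growth_series <- function(x, ...) {
  cat(sprintf(
    "<growth_series> subject %s (sex %s, class %s): %d films, ages %.0f-%.0f months\n",
    x$subject_id, x$sex, x$skeletal_class, nrow(x$films),
    min(x$films$age_months), max(x$films$age_months)
  ))
  invisible(x)
}

#' Simulate one longitudinal cephalometric series
#'
#' Draws film ages (first film uniform in 96-108 months, consecutive gaps
#' uniform in 9-18 months, matching the serial-radiograph archives the
#' pipeline targets), evaluates the growth law at those ages, adds Gaussian
#' measurement noise to each observed length, and places the Condylion and
#' Pogonion landmarks so that their Euclidean distance equals the observed
#' length. Basion and the inferior border of C4 are placed above and below
#' the synthetic cervical column with a small positional jitter.
#'
#' @param params a [growth_model_params()] object.
#' @param n_films number of films (>= 2).
#' @param seed integer seed; all randomness in the series flows from it.
#' @param subject_id identifier stored in the series.
#' @return A [growth_series()] with `true_peak_age_months` filled in.
#' @export
simulate_growth_series <- function(params, n_films = 8, seed,
                                   subject_id = sprintf("synthetic-%04d", seed %% 10000L)) {
  stopifnot(inherits(params, "growth_model_params"))
  if (!is.numeric(n_films) || length(n_films) != 1L || n_films < 2) {
    stop("`n_films` must be an integer >= 2", call. = FALSE)
  }
  n_films <- as.integer(n_films)
  g <- .film_geom
  with_seed(seed, {
    ages <- cumsum(c(stats::runif(1, 96, 108), stats::runif(n_films - 1L, 9, 18)))
    len_true <- true_length(ages, params)
    len_obs <- len_true + stats::rnorm(n_films, 0, params$noise_sd_mm)
    theta <- g$mand_angle_deg * pi / 180
    films <- data.frame(
      film_index = seq_len(n_films),
      age_months = ages,
      co_x = rep(g$co[["x"]], n_films),
      co_y = rep(g$co[["y"]], n_films),
      pog_x = g$co[["x"]] + len_obs * cos(theta),
      pog_y = g$co[["y"]] + len_obs * sin(theta),
      basion_x = g$column_x + stats::rnorm(n_films, 0, 0.5),
      basion_y = g$basion_y + stats::rnorm(n_films, 0, 1),
      c4inf_x = g$column_x + stats::rnorm(n_films, 0, 0.5),
      c4inf_y = g$c4_y + stats::rnorm(n_films, 0, 1),
      image_ref = NA_character_,
      quality_ok = TRUE
    )
    growth_series(
      subject_id = subject_id,
      films = films,
      sex = params$sex,
      skeletal_class = "I",
      true_peak_age_months = params$peak_age_months
    )
  })
}

#' Simulate a cohort of growth series
#'
#' Convenience wrapper drawing per-subject parameters from
#' [sample_growth_model_params()]. The sex ratio (54% female) and skeletal
#' class ratio (45% class I, 55% class II) follow the composition of the
#' longitudinal growth-center archives the pipeline is designed for.
#'
#' @param n_subjects number of subjects.
#' @param seed integer seed.
#' @param noise_sd_mm measurement noise (mm).
#' @param n_films_range inclusive integer range of films per subject.
#' @return List of [growth_series()] objects.
#' @export
simulate_growth_cohort <- function(n_subjects, seed, noise_sd_mm = 0.3,
                                   n_films_range = c(6L, 9L)) {
  stopifnot(n_subjects >= 1)
  meta <- with_seed(child_seed(seed, "cohort-meta"), {
    data.frame(
      sex = sample(c("F", "M"), n_subjects, replace = TRUE, prob = c(0.54, 0.46)),
      skeletal_class = sample(c("I", "II"), n_subjects, replace = TRUE,
                              prob = c(0.45, 0.55)),
      n_films = {
        choices <- seq(n_films_range[1], n_films_range[2])
        choices[sample.int(length(choices), n_subjects, replace = TRUE)]
      }
    )
  })
  lapply(seq_len(n_subjects), function(i) {
    p <- sample_growth_model_params(meta$sex[i], seed = child_seed(seed, paste0("params", i)),
                                    noise_sd_mm = noise_sd_mm)
    s <- simulate_growth_series(p, n_films = meta$n_films[i],
                                seed = child_seed(seed, paste0("series", i)),
                                subject_id = sprintf("synthetic-%04d", i))
    s$skeletal_class <- meta$skeletal_class[i]
    s
  })
}
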