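# Shared fixtures and independent oracle implementations used across the
# suite. Oracles are deliberately written from first principles (explicit
# loops, no reuse of package internals) so they can disagree with the
# implementation they check.

# build a growth series whose films have prescribed lengths and ages;
# landmarks are laid out on a horizontal line so Co-Pog distance equals
# the requested length exactly
series_from_lengths <- function(lengths, ages, subject_id = "fixture",
                                sex = "F", skeletal_class = "I",
                                quality_ok = TRUE) {
  n <- length(lengths)
  films <- data.frame(
    film_index = seq_len(n), age_months = ages,
    co_x = 0, co_y = 40, pog_x = lengths, pog_y = 40,
    basion_x = 60, basion_y = 48, c4inf_x = 60, c4inf_y = 112,
    image_ref = NA_character_,
    quality_ok = rep(quality_ok, length.out = n)
  )
  growth_series(subject_id, films, sex = sex, skeletal_class = skeletal_class)
}

# random growth-law parameters used by recovery sweeps; peak constrained to
# fall inside the sampled 8-film age window
random_growth_params <- function(noise_sd_mm) {
  growth_model_params(
    baseline_length_mm = runif(1, 95, 105),
    linear_rate_mm_per_month = runif(1, 0.03, 0.08),
    spurt_gain_mm = runif(1, 8, 16),
    peak_age_months = runif(1, 115, 155),
    spurt_scale_months = runif(1, 5, 8),
    noise_sd_mm = noise_sd_mm
  )
}

# interval on which the noise-free trajectory has maximal average velocity:
# the ground truth the velocity gold standard encodes
true_peak_interval <- function(series, params) {
  ages <- series$films$age_months
  which.max(diff(true_length(ages, params)) / diff(ages))
}

random_confusion <- function(max_count = 40) {
  as_confusion_matrix(matrix(sample(0:max_count, 9, replace = TRUE), 3, 3))
}

# scalar re-derivations of every diagnostic measure via explicit loops
oracle_ovr <- function(cm, i) {
  tp <- fp <- fn <- tn <- 0
  for (r in 1:3) for (cc in 1:3) {
    v <- cm[r, cc]
    if (r == i && cc == i) tp <- tp + v
    else if (r == i) fn <- fn + v
    else if (cc == i) fp <- fp + v
    else tn <- tn + v
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

oracle_kappa <- function(cm, weighting = "none") {
  n <- sum(cm)
  po <- pe <- 0
  for (i in 1:3) for (j in 1:3) {
    w <- switch(weighting,
                none = as.numeric(i == j),
                linear = 1 - abs(i - j) / 2,
                quadratic = 1 - (i - j)^2 / 4)
    po <- po + w * cm[i, j] / n
    pe <- pe + w * (sum(cm[i, ]) / n) * (sum(cm[, j]) / n)
  }
  (po - pe) / (1 - pe)
}

# first-principles stage labeling: recompute lengths, rates, argmax and
# window membership with explicit loops
oracle_labels <- function(series, relative_threshold = 1) {
  f <- series$films
  n <- nrow(f)
  len <- numeric(n)
  for (i in seq_len(n)) {
    len[i] <- sqrt((f$co_x[i] - f$pog_x[i])^2 + (f$co_y[i] - f$pog_y[i])^2)
  }
  rates <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    rates[i] <- (len[i + 1] - len[i]) / (f$age_months[i + 1] - f$age_months[i])
  }
  peak <- 1
  for (i in seq_along(rates)) if (rates[i] > rates[peak]) peak <- i
  thr <- relative_threshold * rates[peak]
  lo <- peak
  while (lo > 1 && rates[lo - 1] >= thr - 1e-12 * abs(rates[peak])) lo <- lo - 1
  hi <- peak
  while (hi < length(rates) && rates[hi + 1] >= thr - 1e-12 * abs(rates[peak])) hi <- hi + 1
  labs <- character(n)
  labs[1] <- "unlabeled"
  for (i in 2:n) {
    iv <- i - 1
    labs[i] <- if (iv < lo) "pre_pubertal" else if (iv > hi) "post_pubertal" else "pubertal"
  }
  labs
}

# a random series with monotone-ish lengths for oracle-equivalence sweeps
random_series <- function() {
  n <- sample(4:9, 1)
  ages <- cumsum(c(runif(1, 96, 108), runif(n - 1, 9, 18)))
  lengths <- 95 + cumsum(runif(n, 0, 3))
  series_from_lengths(lengths, ages)
}

# one small trained designed-CNN fixture, trained once per test run and
# shared by the classifier tests
.fixture_env <- new.env(parent = emptyenv())
trained_fixture <- function() {
  if (!is.null(.fixture_env$model)) return(.fixture_env)
  ds <- build_synthetic_dataset(30, render_params(), seed = 7)
  sp <- stratified_split(ds$manifest, seed = 1)
  data <- dataset_from_split(sp, ds$images)
  model <- build_model(model_config("designed_cnn"), seed = 1)
  model <- train_model(model, data, train_config(epochs = 18, batch_size = 32,
                                                 seed = 0))
  .fixture_env$model <- model
  .fixture_env$data <- data
  .fixture_env
}
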