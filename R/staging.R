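#' Mandibular length from Condylion and Pogonion
#'
#' Euclidean distance between the Condylion (Co) and Pogonion (Pog)
#' landmarks in millimetres — the mandibular length measure underlying the
#' growth-velocity gold standard.
#'
#' @param co,pog numeric length-2 vectors `(x, y)` in mm.
#' @return Distance in mm (scalar, >= 0).
#' @export
mandibular_length <- function(co, pog) {
  co <- as.numeric(co); pog <- as.numeric(pog)
  if (length(co) != 2L || length(pog) != 2L ||
      any(!is.finite(co)) || any(!is.finite(pog))) {
    stop("`co` and `pog` must be finite (x, y) coordinate pairs", call. = FALSE)
  }
  sqrt(sum((co - pog)^2))
}

# lengths of every film in a series, in film order
series_lengths <- function(series) {
  f <- series$films
  sqrt((f$co_x - f$pog_x)^2 + (f$co_y - f$pog_y)^2)
}

#' Per-interval mandibular growth velocity
#'
#' For each pair of consecutive films, the increase in mandibular length
#' (mm) divided by the elapsed time (months): the growth rate in mm/month
#' attributed to the interval ending at the later film.
#'
#' @param series a [growth_series()] with at least two films.
#' @return Data frame with one row per interval: `from_index`, `to_index`,
#'   `delta_length_mm`, `delta_months`, `rate_mm_per_month`.
#' @export
growth_intervals <- function(series) {
  stopifnot(inherits(series, "growth_series"))
  n <- nrow(series$films)
  if (n < 2L) stop("need at least 2 films to form growth intervals", call. = FALSE)
  ages <- series$films$age_months
  if (is.unsorted(ages, strictly = TRUE)) {
    stop("film ages must be strictly increasing", call. = FALSE)
  }
  len <- series_lengths(series)
  data.frame(
    from_index = seq_len(n - 1L),
    to_index = seq_len(n - 1L) + 1L,
    delta_length_mm = diff(len),
    delta_months = diff(ages),
    rate_mm_per_month = diff(len) / diff(ages)
  )
}

#' Locate the pubertal peak window among growth intervals
#'
#' Finds the interval of maximal growth velocity and extends it to the
#' maximal contiguous run of intervals whose velocity is at least
#' `relative_threshold` times the maximum. With the default threshold of 1
#' the window is the argmax interval alone; smaller thresholds widen the
#' "during the peak" window. Ties at the maximum are resolved toward the
#' earliest qualifying run containing the first argmax.
#'
#' @param intervals data frame from [growth_intervals()], or a numeric
#'   vector of rates.
#' @param relative_threshold number in (0, 1].
#' @return Integer vector of interval indices forming a contiguous window.
#' @export
find_peak_window <- function(intervals, relative_threshold = 1) {
  rates <- if (is.data.frame(intervals)) intervals$rate_mm_per_month else as.numeric(intervals)
  if (length(rates) == 0L) stop("need at least one growth interval", call. = FALSE)
  check_number(relative_threshold, "relative_threshold", min = 0, max = 1,
               strict_min = TRUE)
  peak <- which.max(rates)                      # first argmax on ties
  qualifies <- rates >= relative_threshold * max(rates) - 1e-12 * abs(max(rates))
  lo <- peak
  while (lo > 1L && qualifies[lo - 1L]) lo <- lo - 1L
  hi <- peak
  while (hi < length(rates) && qualifies[hi + 1L]) hi <- hi + 1L
  seq.int(lo, hi)
}

#' Assign pre/pubertal/post stage labels to each film
#'
#' Each film after the first is labeled by the position of its preceding
#' growth interval relative to the peak window: before the window is
#' pre-pubertal, inside it pubertal, after it post-pubertal. The first film
#' has no preceding interval — its growth status before capture is
#' unobservable — and is returned as `"unlabeled"`.
#'
#' @inheritParams growth_intervals
#' @param relative_threshold passed to [find_peak_window()].
#' @return Character vector of length `nrow(series$films)` with values in
#'   `c("unlabeled", stage_levels())`, non-decreasing in stage order.
#' @export
assign_stage_labels <- function(series, relative_threshold = 1) {
  iv <- growth_intervals(series)
  window <- find_peak_window(iv, relative_threshold)
  interval_stage <- ifelse(
    seq_len(nrow(iv)) < min(window), "pre_pubertal",
    ifelse(seq_len(nrow(iv)) > max(window), "post_pubertal", "pubertal")
  )
  c(UNLABELED, interval_stage)
}

#' Check a series against the study's inclusion/exclusion criteria
#'
#' Inclusion: at least six films between the ages of 8 and 15 years
#' (96-180 months); every gap between consecutive films within 9-18
#' months; all films of adequate quality (vertebrae visible). Exclusion:
#' skeletal class III; syndromic cases. All violations are returned as
#' reason codes rather than raised as errors.
#'
#' @inheritParams growth_intervals
#' @return List with elements `pass` (logical) and `reasons` (character
#'   vector of violated-criterion codes, empty when `pass` is `TRUE`).
#' @export
check_eligibility <- function(series) {
  stopifnot(inherits(series, "growth_series"))
  reasons <- character(0)
  ages <- series$films$age_months
  if (sum(ages >= 96 & ages <= 180) < 6L) reasons <- c(reasons, "too-few-films")
  gaps <- diff(ages)
  if (length(gaps) > 0 && any(gaps < 9 | gaps > 18)) {
    reasons <- c(reasons, "gap-out-of-range")
  }
  if (any(!series$films$quality_ok)) reasons <- c(reasons, "poor-quality-film")
  if (identical(series$skeletal_class, "III")) reasons <- c(reasons, "class-III-excluded")
  if (isTRUE(series$syndromic)) reasons <- c(reasons, "syndromic-excluded")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Per-film staging table for one series
#'
#' @inheritParams assign_stage_labels
#' @return Data frame with `subject_id`, `film_index`, `age_months`,
#'   `length_mm`, `preceding_rate_mm_per_month` (`NA` for the first film)
#'   and `stage_label`.
#' @export
stage_labels_table <- function(series, relative_threshold = 1) {
  labels <- assign_stage_labels(series, relative_threshold)
  iv <- growth_intervals(series)
  data.frame(
    subject_id = series$subject_id,
    film_index = series$films$film_index,
    age_months = series$films$age_months,
    length_mm = series_lengths(series),
    preceding_rate_mm_per_month = c(NA_real_, iv$rate_mm_per_month),
    stage_label = labels
  )
}
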