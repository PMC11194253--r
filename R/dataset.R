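round_half_up <- function(x) floor(x + 0.5)

#' Draw a balanced subset of labeled ROIs
#'
#' Seeded uniform draw without replacement of up to `n_per_class` items per
#' stage. Classes with fewer candidates contribute everything they have,
#' with a warning (the shortfall mirrors quality-based exclusions in real
#' collections).
#'
#' @param labeled_rois data frame with a `stage_label` column (e.g. the ROI
#'   manifest from [batch_extract()] or the render manifest with its
#'   `stage` column renamed).
#' @param n_per_class target per-class count.
#' @param seed integer seed.
#' @return Subset of `labeled_rois` rows, stages interleaved in level order.
#' @export
select_balanced <- function(labeled_rois, n_per_class, seed) {
  stopifnot(is.data.frame(labeled_rois), "stage_label" %in% names(labeled_rois))
  if (n_per_class < 0) stop("`n_per_class` must be >= 0", call. = FALSE)
  picks <- with_seed(seed, {
    lapply(stage_levels(), function(st) {
      idx <- which(labeled_rois$stage_label == st)
      if (length(idx) == 0L && n_per_class > 0) {
        stopf("no candidates for stage \"%s\"", st)
      }
      if (length(idx) < n_per_class) {
        warning(sprintf("stage \"%s\": only %d of %d requested candidates",
                        st, length(idx), n_per_class), call. = FALSE)
        idx
      } else {
        sort(sample(idx, n_per_class))
      }
    })
  })
  labeled_rois[unlist(picks), , drop = FALSE]
}

#' Stratified train/validation/test split
#'
#' Splits per stage: the test set takes `round(class_size * test_frac)`
#' items (half-up rounding, capped so at least one training item remains),
#' or exactly `fixed_test_per_class` when given — the fixed option
#' reproduces the balanced 32-per-class test layout used at the pipeline's
#' design scale. Validation then takes `val_frac` of the remaining pool per
#' stage. Membership is a seeded draw, deterministic given the seed.
#'
#' @param subset data frame with a `stage_label` column.
#' @param test_frac fraction of each class reserved for testing.
#' @param val_frac fraction of the post-test pool used for validation.
#' @param seed integer seed.
#' @param fixed_test_per_class optional integer overriding the fractional
#'   test count in every class.
#' @return Object of class `dataset_split`: list with data frames `train`,
#'   `validation`, `test`, the `seed`, `ratios`, and a `counts` matrix
#'   (partition x stage).
#' @export
stratified_split <- function(subset, test_frac = 0.15, val_frac = 0.20, seed = 0L,
                             fixed_test_per_class = NULL) {
  stopifnot(is.data.frame(subset), "stage_label" %in% names(subset))
  if (nrow(subset) == 0L) stop("`subset` is empty", call. = FALSE)
  check_number(test_frac, "test_frac", min = 0, max = 1)
  check_number(val_frac, "val_frac", min = 0, max = 1)
  stages <- intersect(stage_levels(), unique(subset$stage_label))
  parts <- with_seed(seed, {
    lapply(stages, function(st) {
      idx <- which(subset$stage_label == st)
      n <- length(idx)
      if (n < 3L) stopf("cannot stratify: stage \"%s\" has only %d item(s)", st, n)
      n_test <- if (is.null(fixed_test_per_class)) {
        round_half_up(n * test_frac)
      } else {
        as.integer(fixed_test_per_class)
      }
      n_test <- max(0L, min(n_test, n - 1L))       # keep at least 1 in train
      test_idx <- if (n_test > 0) sort(sample(idx, n_test)) else integer(0)
      pool <- setdiff(idx, test_idx)
      n_val <- min(round_half_up(length(pool) * val_frac), length(pool) - 1L)
      val_idx <- if (n_val > 0) sort(sample(pool, n_val)) else integer(0)
      train_idx <- setdiff(pool, val_idx)
      list(train = train_idx, validation = val_idx, test = test_idx)
    })
  })
  take <- function(part) {
    subset[sort(unlist(lapply(parts, `[[`, part))), , drop = FALSE]
  }
  out <- list(
    train = take("train"), validation = take("validation"), test = take("test"),
    seed = as.integer(seed),
    ratios = c(test_frac = test_frac, val_frac = val_frac),
    fixed_test_per_class = fixed_test_per_class
  )
  out$counts <- sapply(stage_levels(), function(st) {
    c(train = sum(out$train$stage_label == st),
      validation = sum(out$validation$stage_label == st),
      test = sum(out$test$stage_label == st))
  })
  class(out) <- "dataset_split"
  out
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("<dataset_split>\n")
  print(x$counts)
  invisible(x)
}

#' Flatten a split into one manifest with a partition column
#'
#' @param split a [stratified_split()] result.
#' @return Data frame of all rows with an added `partition` column.
#' @export
split_manifest <- function(split) {
  stopifnot(inherits(split, "dataset_split"))
  do.call(rbind, lapply(c("train", "validation", "test"), function(p) {
    d <- split[[p]]
    if (nrow(d) == 0L) return(NULL)
    d$partition <- p
    d
  }))
}
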