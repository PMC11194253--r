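#' Ordered stage levels
#'
#' The three mandibular growth stages in their natural order, as used
#' throughout the package. Films whose preceding growth interval is
#' undefined (the first film of a series) carry the pseudo-level
#' `"unlabeled"` and are excluded from classifier datasets.
#'
#' @return Character vector `c("pre_pubertal", "pubertal", "post_pubertal")`.
#' @export
stage_levels <- function() c("pre_pubertal", "pubertal", "post_pubertal")

#' @rdname stage_levels
#' @export
UNLABELED <- "unlabeled"

#' Coerce labels to an ordered stage factor
#'
#' @param x character vector of stage names (subset of [stage_levels()]).
#' @return Ordered factor with the three stage levels.
#' @export
as_stage <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x) & x != UNLABELED]), stage_levels())
  if (length(bad) > 0) {
    stop("unknown stage label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  x[x == UNLABELED] <- NA_character_
  factor(x, levels = stage_levels(), ordered = TRUE)
}

# internal: run `code` with a private RNG state seeded by `seed`,
# restoring whatever global state existed before (no global side effects)
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), code)
}

# internal: derive a stream-specific child seed so that distinct pipeline
# stages driven by one user seed draw from unrelated streams
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.integer(seed) * 1103L + h * 12289L) %% 2147483647L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  if (strict_min && x <= min) stopf("`%s` must be > %g", name, min)
  if (!strict_min && x < min) stopf("`%s` must be >= %g", name, min)
  if (x > max) stopf("`%s` must be <= %g", name, max)
  invisible(x)
}
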