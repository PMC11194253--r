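#' Region-of-interest image container
#'
#' @param pixels numeric matrix with intensities in `[0, 1]`.
#' @param stage_label stage name or `"unlabeled"`.
#' @param source list with `subject_id` and `film_index` (provenance).
#' @param crop_box integer vector `(top, bottom, left, right)` in source
#'   pixel coordinates (inclusive), or `NA` for rendered images.
#' @return Object of class `roi_image`.
#' @export
roi_image <- function(pixels, stage_label = UNLABELED,
                      source = list(subject_id = NA_character_,
                                    film_index = NA_integer_),
                      crop_box = c(top = NA_integer_, bottom = NA_integer_,
                                   left = NA_integer_, right = NA_integer_)) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (any(pixels < -1e-9 | pixels > 1 + 1e-9)) {
    stop("`pixels` must lie in [0, 1]", call. = FALSE)
  }
  if (!stage_label %in% c(stage_levels(), UNLABELED)) {
    stopf("unknown stage label \"%s\"", stage_label)
  }
  structure(list(pixels = pixels, stage_label = stage_label,
                 source = source, crop_box = crop_box),
            class = "roi_image")
}

#' @export
print.roi_image <- function(x, ...) {
  cat(sprintf("<roi_image> %d x %d, stage %s\n",
              nrow(x$pixels), ncol(x$pixels), x$stage_label))
  invisible(x)
}

#' Resample an intensity matrix to a target size
#'
#' Separable bilinear interpolation with the pixel-center convention
#' (no corner alignment); `"nearest"` subsampling is provided as a simple
#' reference method.
#'
#' @param img numeric matrix.
#' @param out_h,out_w target size in pixels.
#' @param method `"bilinear"` or `"nearest"`.
#' @return `out_h` x `out_w` numeric matrix.
#' @export
resize_image <- function(img, out_h, out_w, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(is.matrix(img), out_h >= 1, out_w >= 1)
  h <- nrow(img); w <- ncol(img)
  src_r <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  src_c <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  src_r <- pmin(pmax(src_r, 1), h)
  src_c <- pmin(pmax(src_c, 1), w)
  if (method == "nearest") {
    return(img[pmin(pmax(round(src_r), 1), h),
               pmin(pmax(round(src_c), 1), w), drop = FALSE])
  }
  r0 <- pmin(floor(src_r), h - ifelse(h > 1, 1, 0)); r1 <- pmin(r0 + 1, h)
  c0 <- pmin(floor(src_c), w - ifelse(w > 1, 1, 0)); c1 <- pmin(c0 + 1, w)
  fr <- src_r - r0; fc <- src_c - c0
  rows_interp <- img[r0, , drop = FALSE] * (1 - fr) + img[r1, , drop = FALSE] * fr
  out <- rows_interp[, c0, drop = FALSE] %*% diag(1 - fc, length(fc)) +
    rows_interp[, c1, drop = FALSE] %*% diag(fc, length(fc))
  out
}

# min-max rescale to [0, 1]; constant input maps to all zeros
minmax_rescale <- function(img) {
  rng <- range(img)
  if (rng[2] - rng[1] <= 0) return(matrix(0, nrow(img), ncol(img)))
  (img - rng[1]) / (rng[2] - rng[1])
}

# reproduce an ROI from a stored crop box (round-trip contract)
crop_from_box <- function(image, crop_box, out_size = 64L,
                          method = "bilinear") {
  crop <- image[crop_box[["top"]]:crop_box[["bottom"]],
                crop_box[["left"]]:crop_box[["right"]], drop = FALSE]
  minmax_rescale(resize_image(crop, out_size, out_size, method))
}

#' Extract the cervical-vertebrae region of interest
#'
#' Crops the cervical column from a full lateral film: the vertical extent
#' runs from the Basion row to the C4 inferior-border row inclusive; the
#' horizontal extent is centered on the mean column of the two landmarks
#' with half-width `lateral_margin_frac` times the vertical extent, clipped
#' to the image. The crop is resampled to `out_size` x `out_size` and
#' min-max rescaled to `[0, 1]` (a constant crop maps to all zeros). No
#' smoothing, sharpening or histogram filtering is applied.
#'
#' @param image numeric intensity matrix (origin top-left, rows downward).
#' @param basion,c4_inferior landmark positions `(x, y)` in pixel
#'   coordinates (`x` = column, `y` = row); Basion must lie strictly above
#'   the C4 landmark.
#' @param lateral_margin_frac half-width of the crop as a fraction of its
#'   vertical extent (default 0.5 gives a square field of view).
#' @param out_size output side length in pixels.
#' @param stage_label,source stored on the returned [roi_image()].
#' @param method resampling method, see [resize_image()].
#' @return A [roi_image()] with `crop_box = (top, bottom, left, right)`
#'   inclusive source coordinates.
#' @export
extract_roi <- function(image, basion, c4_inferior, lateral_margin_frac = 0.5,
                        out_size = 64L, stage_label = UNLABELED,
                        source = list(subject_id = NA_character_,
                                      film_index = NA_integer_),
                        method = "bilinear") {
  stopifnot(is.matrix(image))
  check_number(lateral_margin_frac, "lateral_margin_frac", min = 0, strict_min = TRUE)
  basion <- as.numeric(basion); c4_inferior <- as.numeric(c4_inferior)
  h <- nrow(image); w <- ncol(image)
  pts <- rbind(basion, c4_inferior)
  if (any(!is.finite(pts)) || any(pts[, 1] < 1 | pts[, 1] > w) ||
      any(pts[, 2] < 1 | pts[, 2] > h)) {
    stop("landmarks must lie inside the image", call. = FALSE)
  }
  top <- round(basion[2]); bottom <- round(c4_inferior[2])
  if (top >= bottom) {
    stop("Basion must lie strictly above the C4 inferior border", call. = FALSE)
  }
  vert <- bottom - top + 1L
  if (vert < 8L) stop("degenerate crop: vertical extent below 8 rows", call. = FALSE)
  center_col <- (basion[1] + c4_inferior[1]) / 2
  half <- lateral_margin_frac * vert
  left <- max(1L, as.integer(round(center_col - half)))
  right <- min(w, as.integer(round(center_col + half)))
  box <- c(top = as.integer(top), bottom = as.integer(bottom),
           left = left, right = right)
  pixels <- crop_from_box(image, box, out_size = out_size, method = method)
  roi_image(pixels, stage_label = stage_label, source = source, crop_box = box)
}

#' Label films and extract ROIs for a whole manifest
#'
#' Reconstructs each subject's series from a manifest table, assigns stage
#' labels from the growth-velocity gold standard, and crops one ROI per
#' labeled, quality-passing film. Films that are unlabeled (first of a
#' series), flagged `quality_ok = FALSE`, or whose image cannot be read or
#' cropped are skipped and reported; the run continues.
#'
#' @param manifest data frame in the series-manifest schema (see
#'   [write_series_manifest()]), with `image_path` pointing at readable
#'   grayscale images.
#' @param out_dir directory for the 64 x 64 ROI PNGs; created if missing.
#' @param lateral_margin_frac,relative_threshold see [extract_roi()] and
#'   [assign_stage_labels()].
#' @param out_size ROI side length.
#' @param image_base directory against which relative `image_path` entries
#'   are resolved (manifests are portable when they store relative paths).
#' @return List with `manifest` (data frame: `roi_path`, `subject_id`,
#'   `film_index`, `age_months`, `stage_label`, crop-box columns) and
#'   `failures` (data frame: `subject_id`, `film_index`, `reason`).
#' @export
batch_extract <- function(manifest, out_dir, lateral_margin_frac = 0.5,
                          relative_threshold = 1, out_size = 64L,
                          image_base = NULL) {
  series_list <- manifest_to_series(manifest)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list(); fails <- list()
  for (s in series_list) {
    labels <- tryCatch(assign_stage_labels(s, relative_threshold),
                       error = function(e) NULL)
    if (is.null(labels)) {
      fails[[length(fails) + 1L]] <- data.frame(
        subject_id = s$subject_id, film_index = NA_integer_,
        reason = "cannot-stage-series")
      next
    }
    for (i in seq_len(nrow(s$films))) {
      f <- s$films[i, ]
      if (labels[i] == UNLABELED) {
        fails[[length(fails) + 1L]] <- data.frame(
          subject_id = s$subject_id, film_index = f$film_index,
          reason = "unlabeled-first-film")
        next
      }
      if (!isTRUE(f$quality_ok)) {
        fails[[length(fails) + 1L]] <- data.frame(
          subject_id = s$subject_id, film_index = f$film_index,
          reason = "quality-excluded")
        next
      }
      res <- tryCatch({
        src <- f$image_ref
        if (!is.null(image_base) && !is.na(src) && !file.exists(src)) {
          src <- file.path(image_base, src)
        }
        img <- read_image(src)
        roi <- extract_roi(img, basion = c(f$basion_x, f$basion_y),
                           c4_inferior = c(f$c4inf_x, f$c4inf_y),
                           lateral_margin_frac = lateral_margin_frac,
                           out_size = out_size, stage_label = labels[i],
                           source = list(subject_id = s$subject_id,
                                         film_index = f$film_index))
        path <- file.path(out_dir, sprintf("%s_film%02d_roi.png",
                                           s$subject_id, f$film_index))
        write_image(roi$pixels, path)
        data.frame(roi_path = path, subject_id = s$subject_id,
                   film_index = f$film_index, age_months = f$age_months,
                   stage_label = labels[i],
                   crop_top = roi$crop_box[["top"]],
                   crop_bottom = roi$crop_box[["bottom"]],
                   crop_left = roi$crop_box[["left"]],
                   crop_right = roi$crop_box[["right"]])
      }, error = function(e) e)
      if (inherits(res, "error")) {
        fails[[length(fails) + 1L]] <- data.frame(
          subject_id = s$subject_id, film_index = f$film_index,
          reason = conditionMessage(res))
      } else {
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  empty_fail <- data.frame(subject_id = character(0), film_index = integer(0),
                           reason = character(0))
  out <- list(
    manifest = if (length(rows)) do.call(rbind, rows) else NULL,
    failures = if (length(fails)) do.call(rbind, fails) else empty_fail
  )
  if (!is.null(out$manifest)) {
    utils::write.csv(out$manifest, file.path(out_dir, "roi_manifest.csv"),
                     row.names = FALSE)
  }
  out
}
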