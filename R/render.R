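#' Parameters of the synthetic vertebra renderer
#'
#' The renderer draws three stacked vertebral-body silhouettes whose
#' geometry varies systematically with growth stage, emulating the two
#' morphological trends visible across maturation: vertebral bodies become
#' taller relative to their width, and the lower border develops a deeper
#' concavity. Both mappings must be strictly increasing from pre-pubertal
#' to post-pubertal so that the three classes are separable by
#' construction; the renderer is a geometric stand-in, not an anatomical
#' claim.
#'
#' @param image_size integer pair (height, width) in pixels, each >= 32.
#' @param stage one of [stage_levels()].
#' @param body_aspect_by_stage named numeric vector: vertebral-body
#'   height:width ratio per stage, strictly increasing.
#' @param concavity_depth_by_stage named numeric vector: lower-border
#'   concavity depth as a fraction of body height, strictly increasing.
#' @param noise_sd additive Gaussian intensity noise (image in `[0, 1]`).
#' @param jitter_rotation_deg maximal random rotation of the column (deg).
#' @return Object of class `render_params`.
#' @export
render_params <- function(image_size = c(64L, 64L),
                          stage = "pre_pubertal",
                          body_aspect_by_stage = c(pre_pubertal = 0.70,
                                                   pubertal = 0.85,
                                                   post_pubertal = 1.00),
                          concavity_depth_by_stage = c(pre_pubertal = 0.05,
                                                      pubertal = 0.15,
                                                      post_pubertal = 0.28),
                          noise_sd = 0.05,
                          jitter_rotation_deg = 3) {
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  image_size <- as.integer(image_size)
  if (any(image_size < 32L)) stop("`image_size` must be at least 32 x 32", call. = FALSE)
  if (!stage %in% stage_levels()) {
    stopf("unknown stage \"%s\" (expected one of %s)",
          stage, paste(stage_levels(), collapse = ", "))
  }
  for (nm in c("body_aspect_by_stage", "concavity_depth_by_stage")) {
    v <- get(nm)
    if (!all(stage_levels() %in% names(v))) {
      stopf("`%s` must be named by all three stages", nm)
    }
    if (is.unsorted(v[stage_levels()], strictly = TRUE)) {
      stopf("`%s` must strictly increase pre -> pubertal -> post", nm)
    }
  }
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(jitter_rotation_deg, "jitter_rotation_deg", min = 0)
  structure(
    list(image_size = image_size, stage = stage,
         body_aspect_by_stage = body_aspect_by_stage[stage_levels()],
         concavity_depth_by_stage = concavity_depth_by_stage[stage_levels()],
         noise_sd = noise_sd, jitter_rotation_deg = jitter_rotation_deg),
    class = "render_params"
  )
}

# draw a column of three vertebral bodies onto a blank canvas.
# cx, cy_top, cy_bottom: column centerline and vertical span, in pixel
# coordinates (origin top-left, y downward); angle_deg rotates the column
# about its own center. Returns an h x w intensity matrix in [0, 1]
# without noise.
draw_vertebral_column <- function(h, w, cx, cy_top, cy_bottom,
                                  aspect, concavity, angle_deg = 0,
                                  background = 0.15, body_intensity = 0.85) {
  span <- cy_bottom - cy_top
  body_h <- span / 3.6                       # 3 bodies + interbody gaps
  body_w <- body_h / aspect
  cy_mid <- (cy_top + cy_bottom) / 2
  spacing <- span / 3
  th <- angle_deg * pi / 180
  # pixel-center coordinates relative to the column center, rotated back
  xs <- matrix(rep(seq_len(w) - cx, each = h), h, w)
  ys <- matrix(rep(seq_len(h) - cy_mid, times = w), h, w)
  xr <- cos(th) * xs + sin(th) * ys
  yr <- -sin(th) * xs + cos(th) * ys
  img <- matrix(background, h, w)
  for (k in -1:1) {
    cyk <- k * spacing
    inside <- abs(xr) <= body_w / 2 & abs(yr - cyk) <= body_h / 2
    # lower-border concavity: semi-ellipse carved out of the bottom edge
    ry <- max(concavity * body_h, 1e-9)
    rx <- 0.35 * body_w
    carve <- (xr / rx)^2 + ((yr - (cyk + body_h / 2)) / ry)^2 <= 1 &
      yr <= cyk + body_h / 2
    img[inside & !carve] <- body_intensity
  }
  img
}

#' Render one stage-conditioned vertebra-like image
#'
#' Deterministic given `(params, seed)`: draws three stacked vertebral
#' bodies with the stage's aspect ratio and lower-border concavity, applies
#' a small random rotation (up to `jitter_rotation_deg`) and additive
#' Gaussian intensity noise, and clips to `[0, 1]`.
#'
#' @param params a [render_params()] object (carries the stage).
#' @param seed integer seed.
#' @return Object of class `roi_image`: `pixels` (matrix in `[0, 1]`),
#'   `stage_label`, `source`, `crop_box`.
#' @export
render_synthetic_roi <- function(params, seed) {
  stopifnot(inherits(params, "render_params"))
  h <- params$image_size[1]; w <- params$image_size[2]
  aspect <- params$body_aspect_by_stage[[params$stage]]
  concavity <- params$concavity_depth_by_stage[[params$stage]]
  with_seed(seed, {
    angle <- if (params$jitter_rotation_deg > 0) {
      stats::runif(1, -params$jitter_rotation_deg, params$jitter_rotation_deg)
    } else 0
    img <- draw_vertebral_column(h, w, cx = (w + 1) / 2,
                                 cy_top = 0.1 * h, cy_bottom = 0.9 * h,
                                 aspect = aspect, concavity = concavity,
                                 angle_deg = angle)
    if (params$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(h * w, 0, params$noise_sd), h, w)
    }
    img[img < 0] <- 0; img[img > 1] <- 1
    roi_image(img, stage_label = params$stage,
              source = list(subject_id = sprintf("render-seed-%d", as.integer(seed)),
                            film_index = NA_integer_))
  })
}

#' Render a balanced labeled image collection
#'
#' Generates `n_per_class` images for each of the three stages with
#' per-image seeds derived from `seed`. When `out_dir` is given the images
#' are written as 8-bit grayscale PNGs together with a manifest CSV
#' (`path`, `stage`, `seed`).
#'
#' @param n_per_class images per stage (>= 1; 240 reproduces the balanced
#'   720-image design the pipeline is sized for).
#' @param render a [render_params()] template (its `stage` is overridden).
#' @param seed integer seed.
#' @param out_dir optional output directory.
#' @return List with `images` (list of `roi_image`) and `manifest`
#'   (data frame `image_id`, `path`, `stage_label`, `seed`; `path` is `NA`
#'   when not written).
#' @export
build_synthetic_dataset <- function(n_per_class, render = render_params(),
                                    seed = 0L, out_dir = NULL) {
  if (!is.numeric(n_per_class) || length(n_per_class) != 1L || n_per_class < 0) {
    stop("`n_per_class` must be a nonnegative integer", call. = FALSE)
  }
  n_per_class <- as.integer(n_per_class)
  images <- list()
  rows <- list()
  idx <- 0L
  for (stage in stage_levels()) {
    p <- render
    p$stage <- stage
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      s <- child_seed(seed, paste0(stage, "-", i))
      im <- render_synthetic_roi(p, seed = s)
      path <- NA_character_
      if (!is.null(out_dir)) {
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        path <- file.path(out_dir, sprintf("%s_%04d.png", stage, i))
        write_image(im$pixels, path)
      }
      images[[idx]] <- im
      rows[[idx]] <- data.frame(image_id = idx, path = path,
                                stage_label = stage, seed = s)
    }
  }
  manifest <- if (idx > 0) do.call(rbind, rows) else {
    data.frame(image_id = integer(0), path = character(0),
               stage_label = character(0), seed = integer(0))
  }
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "render_manifest.csv"),
                     row.names = FALSE)
  }
  list(images = images, manifest = manifest)
}

#' Render full synthetic films for a cohort of growth series
#'
#' Draws a 160 x 160 synthetic lateral film per labeled film: a cervical
#' column spanning the Basion-to-C4 landmarks with morphology conditioned
#' on the film's gold-standard stage (first, unlabeled films use the
#' pre-pubertal morphology). Images are written as PNGs and `image_ref` is
#' filled in on the returned series.
#'
#' @param series_list list of [growth_series()].
#' @param out_dir directory for the PNG files.
#' @param render a [render_params()] template (noise and jitter reused).
#' @param seed integer seed.
#' @param relative_threshold passed to [assign_stage_labels()].
#' @return The input list with `image_ref` set on every film.
#' @export
render_cohort_films <- function(series_list, out_dir, render = render_params(),
                                seed = 0L, relative_threshold = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  size <- .film_geom$film_size
  lapply(series_list, function(s) {
    labels <- assign_stage_labels(s, relative_threshold)
    labels[labels == UNLABELED] <- "pre_pubertal"
    refs <- character(nrow(s$films))
    for (i in seq_len(nrow(s$films))) {
      f <- s$films[i, ]
      stage <- labels[i]
      im_seed <- child_seed(seed, paste0(s$subject_id, "-film-", i))
      img <- with_seed(im_seed, {
        angle <- if (render$jitter_rotation_deg > 0) {
          stats::runif(1, -render$jitter_rotation_deg, render$jitter_rotation_deg)
        } else 0
        img <- draw_vertebral_column(
          size, size,
          cx = (f$basion_x + f$c4inf_x) / 2,
          cy_top = f$basion_y, cy_bottom = f$c4inf_y,
          aspect = render$body_aspect_by_stage[[stage]],
          concavity = render$concavity_depth_by_stage[[stage]],
          angle_deg = angle
        )
        if (render$noise_sd > 0) {
          img <- img + matrix(stats::rnorm(size * size, 0, render$noise_sd), size, size)
        }
        img[img < 0] <- 0; img[img > 1] <- 1
        img
      })
      refs[i] <- file.path(out_dir, sprintf("%s_film%02d.png", s$subject_id, i))
      write_image(img, refs[i])
    }
    s$films$image_ref <- refs
    s
  })
}
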