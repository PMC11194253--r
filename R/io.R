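#' Read a grayscale image into an intensity matrix
#'
#' PNG images are read with \pkg{png}; color images are averaged to a
#' single channel. Intensities are returned in `[0, 1]`, origin top-left.
#'
#' @param path file path.
#' @return Numeric matrix (rows = image rows).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE], c(1, 2), mean)
  as.matrix(a)
}

#' Write an intensity matrix as an 8-bit grayscale PNG
#'
#' @param pixels numeric matrix in `[0, 1]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(pixels, path) {
  stopifnot(is.matrix(pixels))
  pixels[pixels < 0] <- 0; pixels[pixels > 1] <- 1
  # quantize to 8 bits explicitly so a write/read round trip is exact
  png::writePNG(round(pixels * 255) / 255, target = path)
  invisible(path)
}

#' Flatten growth series into the series-manifest table
#'
#' One row per film with the columns `subject_id`, `sex`, `skeletal_class`,
#' `film_index`, `age_months`, the four landmark coordinate pairs,
#' `image_path`, `quality_ok` and `true_peak_age_months` (`NA` for real
#' data).
#'
#' @param series_list list of [growth_series()].
#' @return Data frame in manifest schema.
#' @export
series_to_manifest <- function(series_list) {
  if (inherits(series_list, "growth_series")) series_list <- list(series_list)
  do.call(rbind, lapply(series_list, function(s) {
    f <- s$films
    data.frame(
      subject_id = s$subject_id, sex = s$sex, skeletal_class = s$skeletal_class,
      film_index = f$film_index, age_months = f$age_months,
      co_x = f$co_x, co_y = f$co_y, pog_x = f$pog_x, pog_y = f$pog_y,
      basion_x = f$basion_x, basion_y = f$basion_y,
      c4inf_x = f$c4inf_x, c4inf_y = f$c4inf_y,
      image_path = f$image_ref, quality_ok = f$quality_ok,
      true_peak_age_months = s$true_peak_age_months
    )
  }))
}

#' Rebuild growth series from a manifest table
#'
#' @param manifest data frame in the schema of [series_to_manifest()];
#'   `quality_ok` and `true_peak_age_months` are optional.
#' @return List of [growth_series()] in order of first appearance.
#' @export
manifest_to_series <- function(manifest) {
  stopifnot(is.data.frame(manifest))
  if (!"quality_ok" %in% names(manifest)) manifest$quality_ok <- TRUE
  if (!"true_peak_age_months" %in% names(manifest)) {
    manifest$true_peak_age_months <- NA_real_
  }
  if (!"image_path" %in% names(manifest)) manifest$image_path <- NA_character_
  ids <- unique(manifest$subject_id)
  lapply(ids, function(id) {
    m <- manifest[manifest$subject_id == id, , drop = FALSE]
    m <- m[order(m$age_months), , drop = FALSE]
    films <- data.frame(
      film_index = m$film_index, age_months = m$age_months,
      co_x = m$co_x, co_y = m$co_y, pog_x = m$pog_x, pog_y = m$pog_y,
      basion_x = m$basion_x, basion_y = m$basion_y,
      c4inf_x = m$c4inf_x, c4inf_y = m$c4inf_y,
      image_ref = m$image_path, quality_ok = m$quality_ok
    )
    growth_series(subject_id = id, films = films, sex = m$sex[1],
                  skeletal_class = m$skeletal_class[1],
                  true_peak_age_months = m$true_peak_age_months[1])
  })
}

#' Write / read the series manifest CSV
#'
#' @param series_list list of [growth_series()] (or a manifest data frame).
#' @param path CSV file path.
#' @return `write_series_manifest()` returns `path` invisibly;
#'   `read_series_manifest()` returns the manifest data frame.
#' @export
write_series_manifest <- function(series_list, path) {
  m <- if (is.data.frame(series_list)) series_list else series_to_manifest(series_list)
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_manifest
#' @export
read_series_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(subject_id = "character", sex = "character",
                                 skeletal_class = "character"))
}
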