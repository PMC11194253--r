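test_that("growth-law parameters are validated by field", {
  expect_error(growth_model_params(baseline_length_mm = -1), "baseline_length_mm")
  expect_error(growth_model_params(spurt_scale_months = 0), "spurt_scale_months")
  expect_error(growth_model_params(noise_sd_mm = -0.1), "noise_sd_mm")
  expect_error(growth_model_params(peak_age_months = 90), "peak_age_months")
  expect_error(simulate_growth_series(growth_model_params(), n_films = 1, seed = 1),
               "n_films")
})

test_that("degenerate flat growth yields identical lengths", {
  p <- growth_model_params(baseline_length_mm = 100,
                           linear_rate_mm_per_month = 0,
                           spurt_gain_mm = 0,
                           noise_sd_mm = 0)
  s <- simulate_growth_series(p, n_films = 6, seed = 3)
  lens <- sqrt((s$films$co_x - s$films$pog_x)^2 +
               (s$films$co_y - s$films$pog_y)^2)
  expect_equal(lens, rep(100, 6), tolerance = 1e-9)
})

test_that("analytic velocity of the growth law peaks at peak_age_months", {
  p <- growth_model_params(peak_age_months = 150, spurt_scale_months = 5,
                           noise_sd_mm = 0)
  t <- seq(96, 200, by = 0.01)
  v <- diff(true_length(t, p)) / diff(t)
  expect_equal(t[which.max(v)], 150, tolerance = 0.05)
})

test_that("simulated film ages obey the first-age and gap contracts", {
  for (seed in 1:30) {
    s <- simulate_growth_series(growth_model_params(), n_films = 7, seed = seed)
    ages <- s$films$age_months
    expect_false(is.unsorted(ages, strictly = TRUE))
    expect_gte(ages[1], 96); expect_lte(ages[1], 108)
    expect_true(all(diff(ages) >= 9 & diff(ages) <= 18))
    expect_equal(s$true_peak_age_months, 144)
    # basion above C4 inferior border throughout
    expect_true(all(s$films$basion_y < s$films$c4inf_y))
  }
})

test_that("interval velocities peak on the interval containing the spurt", {
  p <- growth_model_params(baseline_length_mm = 100,
                           linear_rate_mm_per_month = 0.05,
                           spurt_gain_mm = 12, peak_age_months = 144,
                           spurt_scale_months = 6, noise_sd_mm = 0)
  s <- simulate_growth_series(p, n_films = 8, seed = 1)
  iv <- growth_intervals(s)
  amax <- which.max(iv$rate_mm_per_month)
  ages <- s$films$age_months
  # dense numerical differentiation of L(t) as the independent oracle
  tt <- seq(ages[1], ages[length(ages)], by = 0.01)
  vv <- diff(true_length(tt, p)) / diff(tt)
  t_peak <- tt[which.max(vv)]
  expect_gte(t_peak, ages[amax])
  expect_lte(t_peak, ages[amax + 1])
})

test_that("velocity argmax stays within one interval of the peak age", {
  hits <- 0; n <- 60
  for (i in seq_len(n)) {
    set.seed(400 + i)
    p <- random_growth_params(0)
    s <- simulate_growth_series(p, n_films = 8, seed = 400 + i)
    amax <- which.max(growth_intervals(s)$rate_mm_per_month)
    contain <- findInterval(p$peak_age_months, s$films$age_months)
    if (abs(amax - contain) <= 1) hits <- hits + 1
  }
  expect_equal(hits, n)
})

test_that("same render parameters and seed give bit-identical images", {
  p <- render_params(stage = "pubertal")
  a <- render_synthetic_roi(p, seed = 11)
  b <- render_synthetic_roi(p, seed = 11)
  expect_identical(a$pixels, b$pixels)
  expect_equal(a$stage_label, "pubertal")
  d <- render_synthetic_roi(p, seed = 12)
  expect_false(identical(a$pixels, d$pixels))
})

test_that("stage is the only difference between matched noise-free renders", {
  base <- render_params(noise_sd = 0, jitter_rotation_deg = 0)
  pre <- base; pre$stage <- "pre_pubertal"
  post <- base; post$stage <- "post_pubertal"
  a <- render_synthetic_roi(pre, seed = 5)
  b <- render_synthetic_roi(post, seed = 5)
  expect_false(identical(a$pixels, b$pixels))
  # re-rendering either stage reproduces it exactly: the contrast is purely
  # the stage-conditioned shape parameters
  expect_identical(a$pixels, render_synthetic_roi(pre, seed = 5)$pixels)
  expect_identical(b$pixels, render_synthetic_roi(post, seed = 5)$pixels)
})

test_that("render parameter mappings must increase with stage", {
  expect_error(render_params(body_aspect_by_stage = c(pre_pubertal = 1,
                                                      pubertal = 0.8,
                                                      post_pubertal = 1.2)),
               "strictly increase")
  expect_error(render_params(stage = "adult"), "unknown stage")
  expect_error(render_params(image_size = 16), "32")
})

test_that("noise-free classes are linearly separable by nearest centroid", {
  ds <- build_synthetic_dataset(100, render_params(noise_sd = 0), seed = 7)
  X <- t(vapply(ds$images, function(im) as.vector(im$pixels), numeric(64^2)))
  y <- ds$manifest$stage_label
  centroids <- vapply(stage_levels(),
                      function(st) colMeans(X[y == st, , drop = FALSE]),
                      numeric(ncol(X)))
  # brute-force nearest-centroid assignment
  pred <- apply(X, 1, function(row) {
    stage_levels()[which.min(colSums((row - centroids)^2))]
  })
  expect_equal(mean(pred == y), 1.0)
})

test_that("balanced dataset builder produces n_per_class per stage", {
  ds <- build_synthetic_dataset(1, render_params(), seed = 0)
  expect_equal(nrow(ds$manifest), 3L)
  expect_equal(sort(ds$manifest$stage_label), sort(stage_levels()))

  out_dir <- withr::local_tempdir()
  ds10 <- build_synthetic_dataset(10, render_params(), seed = 1, out_dir = out_dir)
  expect_equal(nrow(ds10$manifest), 30L)
  expect_true(all(file.exists(ds10$manifest$path)))
  expect_true(file.exists(file.path(out_dir, "render_manifest.csv")))
  # round trip through the 8-bit PNG is exact by construction
  expect_equal(read_image(ds10$manifest$path[1]),
               round(ds10$images[[1]]$pixels * 255) / 255, tolerance = 1e-9)

  ds_b <- build_synthetic_dataset(10, render_params(), seed = 2)
  expect_identical(names(ds10$manifest), names(ds_b$manifest))
  same <- mapply(function(a, b) identical(a$pixels, b$pixels),
                 ds10$images, ds_b$images)
  expect_false(any(same))
})

test_that("mean class intensity profiles differ pairwise", {
  ds <- build_synthetic_dataset(50, render_params(noise_sd = 0), seed = 21)
  y <- ds$manifest$stage_label
  profile <- function(st) {
    rowMeans(vapply(ds$images[y == st], function(im) rowMeans(im$pixels),
                    numeric(64)))
  }
  pr <- profile("pre_pubertal"); pu <- profile("pubertal"); po <- profile("post_pubertal")
  expect_gt(mean(abs(pr - pu)), 0.005)
  expect_gt(mean(abs(pu - po)), 0.005)
  expect_gt(mean(abs(pr - po)), 0.005)
})

test_that("cohort simulation fills manifests that round-trip", {
  cohort <- simulate_growth_cohort(4, seed = 9)
  expect_length(cohort, 4)
  man <- series_to_manifest(cohort)
  back <- manifest_to_series(man)
  expect_length(back, 4)
  expect_equal(back[[2]]$films$age_months, cohort[[2]]$films$age_months)
  expect_equal(back[[2]]$sex, cohort[[2]]$sex)
  path <- withr::local_tempfile(fileext = ".csv")
  write_series_manifest(cohort, path)
  expect_equal(read_series_manifest(path)$subject_id, man$subject_id)
})
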