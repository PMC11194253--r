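# confusion matrices transcribed from the per-class counts recoverable from
# the reference designed-CNN and residual-net test results (32 true images
# per stage; the residual off-diagonals are one consistent completion — the
# per-class one-vs-rest counts are identical for every completion)
designed_cm <- function() {
  as_confusion_matrix(rbind(c(27, 5, 0),
                            c(9, 20, 3),
                            c(0, 1, 31)))
}
resnet_cm <- function() {
  as_confusion_matrix(rbind(c(25, 6, 1),
                            c(3, 28, 1),
                            c(1, 0, 31)))
}

test_that("confusion matrices tally true x predicted counts", {
  perfect <- confusion_matrix(rep(stage_levels(), each = 32),
                              rep(stage_levels(), each = 32))
  expect_equal(diag(perfect), c(pre_pubertal = 32L, pubertal = 32L,
                                post_pubertal = 32L))
  expect_equal(sum(perfect), 96L)

  all_pre <- confusion_matrix(rep(stage_levels(), each = 32),
                              rep("pre_pubertal", 96))
  expect_equal(unname(colSums(all_pre)), c(96L, 0L, 0L))

  expect_error(confusion_matrix(c("pubertal"), c("pubertal", "pubertal")),
               "equal length")
  expect_error(confusion_matrix("adolescent", "pubertal"), "unknown stage")
})

test_that("tallies agree with an explicit double-loop count", {
  set.seed(17)
  truth <- sample(stage_levels(), 500, replace = TRUE)
  pred <- sample(stage_levels(), 500, replace = TRUE)
  cm <- confusion_matrix(truth, pred)
  for (i in 1:3) for (j in 1:3) {
    n <- 0
    for (k in seq_along(truth)) {
      if (truth[k] == stage_levels()[i] && pred[k] == stage_levels()[j]) n <- n + 1
    }
    expect_equal(unname(cm[i, j]), n)
  }
})

test_that("classwise measures reproduce the reference designed-CNN results", {
  cw <- classwise_metrics(designed_cm())
  pre <- cw[cw$stage == "pre_pubertal", ]
  expect_equal(pre$tp, 27); expect_equal(pre$fp, 9)
  expect_equal(pre$fn, 5); expect_equal(pre$tn, 55)
  expect_equal(pre$sensitivity, 0.84375)
  expect_equal(pre$ppv, 0.75)
  expect_equal(pre$npv, 55 / 60, tolerance = 1e-9)
  expect_equal(pre$specificity, 55 / 64, tolerance = 1e-9)
  expect_equal(pre$accuracy, 82 / 96, tolerance = 1e-9)

  expect_equal(cw$sensitivity, c(0.84375, 0.625, 0.96875))
  # reference ranks: sensitivity 2/3/1, specificity 3/2/1, PPV 3/2/1,
  # NPV 2/3/1, accuracy 2/3/1
  expect_equal(cw$sensitivity_rank, c(2L, 3L, 1L))
  expect_equal(cw$specificity_rank, c(3L, 2L, 1L))
  expect_equal(cw$ppv_rank, c(3L, 2L, 1L))
  expect_equal(cw$npv_rank, c(2L, 3L, 1L))
  expect_equal(cw$accuracy_rank, c(2L, 3L, 1L))
})

test_that("classwise measures reproduce the reference residual-net results", {
  cw <- classwise_metrics(resnet_cm())
  expect_equal(cw$sensitivity, c(0.78125, 0.875, 0.96875))
  expect_equal(cw$specificity, c(0.9375, 0.90625, 0.96875))
  expect_equal(cw$ppv, c(25 / 29, 28 / 34, 31 / 33), tolerance = 1e-6)
  expect_equal(cw$npv, c(60 / 67, 58 / 62, 62 / 63), tolerance = 1e-6)
  expect_equal(cw$accuracy, c(85 / 96, 86 / 96, 93 / 96), tolerance = 1e-9)
  expect_equal(cw$sensitivity_rank, c(3L, 2L, 1L))
  expect_equal(cw$accuracy_rank, c(3L, 2L, 1L))
})

test_that("identity confusion matrix gives perfect tied measures", {
  cm <- as_confusion_matrix(diag(c(10, 10, 10)))
  cw <- classwise_metrics(cm)
  for (mname in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    expect_equal(cw[[mname]], rep(1, 3))
    expect_equal(cw[[paste0(mname, "_rank")]], rep(1L, 3))
  }
  expect_equal(overall_accuracy(cm), 1)
  for (w in c("none", "linear", "quadratic")) {
    expect_equal(cohens_kappa(cm, w), 1)
  }
})

test_that("zero denominators are reported as undefined, not zero", {
  cm <- as_confusion_matrix(rbind(c(0, 10, 0), c(0, 10, 0), c(0, 10, 0)))
  cw <- classwise_metrics(cm)
  expect_true(is.na(cw$ppv[cw$stage == "pre_pubertal"]))     # no predicted pre
  expect_true(is.na(cw$npv[cw$stage == "pubertal"]))         # all predicted pub
  expect_false(anyNA(cw$sensitivity))
})

test_that("overall accuracy is trace over total", {
  expect_equal(overall_accuracy(designed_cm()), 78 / 96)
  expect_equal(overall_accuracy(designed_cm()), 0.8125)
  expect_equal(overall_accuracy(resnet_cm()), 0.875)
  zero_diag <- as_confusion_matrix(rbind(c(0, 5, 5), c(5, 0, 5), c(5, 5, 0)))
  expect_equal(overall_accuracy(zero_diag), 0)
})

test_that("kappa reproduces the reference agreement values", {
  expect_equal(cohens_kappa(designed_cm(), "none"), (0.8125 - 1 / 3) / (2 / 3))
  expect_equal(cohens_kappa(designed_cm(), "none"), 0.71875)
  expect_equal(cohens_kappa(resnet_cm(), "none"), 0.8125)
  expect_equal(altman_band(cohens_kappa(designed_cm())), "good")
  expect_equal(altman_band(cohens_kappa(resnet_cm())), "very good")
})

test_that("statistical independence gives kappa zero", {
  # rows proportional to the predicted marginals
  cm <- as_confusion_matrix(outer(c(10, 20, 30), c(2, 3, 5)))
  for (w in c("none", "linear", "quadratic")) {
    expect_lt(abs(cohens_kappa(cm, w)), 1e-12)
  }
})

test_that("balanced true classes make unweighted kappa an affine accuracy map", {
  set.seed(23)
  for (rep in 1:100) {
    m <- t(vapply(1:3, function(i) {
      v <- sample(0:20, 3, replace = TRUE)
      if (sum(v) == 0) v[1] <- 1
      v
    }, numeric(3)))
    # rescale rows to a common total (balanced true marginals)
    m <- t(apply(m, 1, function(r) {
      r2 <- floor(r / sum(r) * 60)
      r2[1] <- r2[1] + 60 - sum(r2)
      r2
    }))
    cm <- as_confusion_matrix(m)
    expect_equal(cohens_kappa(cm, "none"),
                 (overall_accuracy(cm) - 1 / 3) * 1.5, tolerance = 1e-12)
  }
})

test_that("all measures agree with brute-force re-derivations", {
  set.seed(29)
  for (rep in 1:300) {
    cm <- random_confusion()
    if (sum(cm) == 0) next
    cw <- classwise_metrics(cm)
    for (i in 1:3) {
      k <- oracle_ovr(cm, i)
      expect_equal(cw$tp[i] + cw$fp[i] + cw$fn[i] + cw$tn[i], sum(cm))
      expect_equal(cw$sensitivity[i],
                   if (k$tp + k$fn == 0) NA_real_ else k$tp / (k$tp + k$fn),
                   tolerance = 1e-12)
      expect_equal(cw$ppv[i],
                   if (k$tp + k$fp == 0) NA_real_ else k$tp / (k$tp + k$fp),
                   tolerance = 1e-12)
    }
    for (w in c("none", "linear", "quadratic")) {
      ok <- oracle_kappa(cm, w)
      if (is.finite(ok)) {
        expect_lt(abs(cohens_kappa(cm, w) - ok), 1e-12 * max(1, abs(ok)))
      }
    }
  }
})

test_that("Altman bands use upper-inclusive boundaries", {
  expect_equal(altman_band(0.71875), "good")
  expect_equal(altman_band(0.8125), "very good")
  expect_equal(altman_band(1.0), "very good")
  expect_equal(altman_band(0.20), "poor")
  expect_equal(altman_band(0.40), "fair")
  expect_equal(altman_band(0.60), "moderate")
  expect_equal(altman_band(0.80), "good")
  expect_equal(altman_band(-0.5), "poor")
  expect_error(altman_band(1.2), "kappa")
})

test_that("evaluation reports assemble every block consistently", {
  rep <- evaluation_report(designed_cm())
  expect_equal(rep$overall_accuracy, 0.8125)
  expect_equal(rep$kappa_unweighted, 0.71875)
  expect_equal(rep$altman_band, "good")
  expect_equal(nrow(rep$classwise), 3L)
  expect_equal(sum(rep$confusion), 96)
})
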