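test_that("fold assignment balances sizes and is seeded", {
  f <- assign_folds(45, 10, seed = 1)
  expect_length(f, 45L)
  expect_setequal(sort(unique(f)), 1:10)
  sizes <- tabulate(f, 10)
  expect_setequal(sizes, c(4, 5)) # five folds of 5, five of 4
  expect_equal(sum(sizes == 5), 5L)
  expect_identical(assign_folds(45, 10, seed = 1), f)
  expect_false(identical(assign_folds(45, 10, seed = 2), f))
  expect_error(assign_folds(5, 6, seed = 1), "exceed")
})

test_that("stratified folds spread the positives evenly", {
  labels <- c(rep(1, 23), rep(0, 22))
  f <- assign_folds(45, 10, labels = labels, seed = 3)
  pos_counts <- tabulate(f[labels == 1], 10)
  expect_lte(diff(range(pos_counts)), 1L)
  expect_lte(diff(range(tabulate(f, 10))), 1L)
})

test_that("cross-validation equals an explicit fold-by-fold loop", {
  set.seed(30)
  x <- toy_spectra(n = 12, p = 20, seed = 30)
  y <- rnorm(12, mean = 50, sd = 20)
  spec <- pretreatment_spec("snv")
  cv <- cross_validate(x, y, spec, max_lv = 3, folds = 4, seed = 9,
                       task = "regression")
  # brute-force oracle: refit pre-treatment and model per fold by hand
  fa <- assign_folds(12, 4, seed = 9)
  expect_identical(cv$fold_assignment, fa)
  preds <- matrix(NA_real_, 12, 3)
  for (k in 1:4) {
    tr <- which(fa != k); te <- which(fa == k)
    xtr <- snv_transform(subset_samples(x, tr))$absorbance
    xte <- snv_transform(subset_samples(x, te))$absorbance
    for (a in 1:3) {
      preds[te, a] <- pls_predict(pls1_fit(xtr, y[tr], a), xte)
    }
  }
  expect_equal(cv$predictions, preds, tolerance = 1e-10)
  expect_equal(cv$rmsecv_per_lv, sqrt(colMeans((preds - y)^2)))
  expect_length(cv$rmsecv_per_lv, 3L)
})

test_that("cross-validation is leak-free: held-out responses never train", {
  x <- toy_spectra(n = 12, p = 20, seed = 31)
  y <- rnorm(12, 50, 20)
  spec <- pretreatment_spec("autoscale")
  cv1 <- cross_validate(x, y, spec, 2, folds = 4, seed = 5, "regression")
  # corrupting one fold's reference values must leave that fold's own
  # predictions untouched (they are computed from the other folds only)
  victim <- which(cv1$fold_assignment == 2)
  y2 <- y
  y2[victim] <- y2[victim] + 50
  cv2 <- cross_validate(x, y2, spec, 2, folds = 4, seed = 5, "regression")
  expect_equal(cv2$predictions[victim, ], cv1$predictions[victim, ],
               tolerance = 1e-12)
  # while the folds that use them for training do move
  expect_false(isTRUE(all.equal(cv2$predictions[-victim, ],
                                cv1$predictions[-victim, ])))
})

test_that("noise-free linear data gives near-zero RMSECV at full rank", {
  cfg <- noiseless_config(seed = 32, mode = "MIDIR")
  e <- generate_endmembers(cfg)
  d <- build_mixture_design()
  synth <- synthesize_spectra(d, e, cfg)
  y <- synth$composition$proportions[, "RT2"]
  cv <- cross_validate(synth$spectra, y, pretreatment_spec("autoscale"),
                       max_lv = 8, folds = 10, seed = 1, "regression")
  expect_lt(min(cv$rmsecv_per_lv), 1e-6)
})

test_that("latent-variable selection prefers the simplest minimum", {
  expect_equal(select_n_latent(c(3, 2, 2, 4)), 2L)
  expect_equal(select_n_latent(c(5, 4, 3, 2)), 4L)
  expect_equal(select_n_latent(c(2, 2, 2)), 1L)
  expect_error(select_n_latent(numeric(0)), "empty")
})

test_that("classification metrics reproduce the published worked values", {
  # 40 correct of 45
  y_true <- rep(c(TRUE, FALSE), c(22, 23))
  y_pred <- y_true
  y_pred[1:3] <- FALSE # 3 false negatives
  y_pred[23:24] <- TRUE # 2 false positives
  m <- classification_metrics(y_true, y_pred)
  expect_equal(round(m$ccr, 2), 88.89)
  # confusion (tp, fn, fp, tn) = (20, 2, 3, 20)
  y_true2 <- rep(c(TRUE, FALSE), c(22, 23))
  y_pred2 <- c(rep(TRUE, 20), rep(FALSE, 2), rep(TRUE, 3), rep(FALSE, 20))
  m2 <- classification_metrics(y_true2, y_pred2)
  expect_equal(c(m2$tp, m2$fn, m2$fp, m2$tn), c(20, 2, 3, 20))
  expect_equal(round(m2$sensitivity, 2), 0.91)
  expect_equal(round(m2$specificity, 2), 0.87)
  expect_equal(round(m2$precision, 2), 0.87)
  all_right <- classification_metrics(y_true, y_true)
  expect_equal(all_right$ccr, 100)
  expect_equal(all_right$precision, 1)
  expect_equal(all_right$sensitivity, 1)
  expect_equal(all_right$specificity, 1)
})

test_that("classification metrics invariances and degenerate ratios", {
  set.seed(33)
  y_true <- runif(30) > 0.5
  y_pred <- runif(30) > 0.5
  m <- classification_metrics(y_true, y_pred)
  idx <- sample(30)
  mp <- classification_metrics(y_true[idx], y_pred[idx])
  expect_equal(mp, m)
  # swapping class labels swaps sensitivity and specificity
  ms <- classification_metrics(!y_true, !y_pred)
  expect_equal(ms$sensitivity, m$specificity)
  expect_equal(ms$specificity, m$sensitivity)
  expect_error(classification_metrics(y_true, y_pred[1:10]), "mismatch")
  # all-positive truth, all-negative prediction: both precision and
  # specificity are undefined and must warn, not report 0
  w <- capture_warnings(
    mz <- classification_metrics(c(TRUE, TRUE), c(FALSE, FALSE))
  )
  expect_match(w, "undefined", all = TRUE)
  expect_true(is.nan(mz$precision))
  expect_true(is.nan(mz$specificity))
  expect_equal(mz$sensitivity, 0)
})

test_that("regression metrics match hand arithmetic and definitions", {
  m <- regression_metrics(c(0, 50, 100), c(10, 50, 90))
  expect_equal(m$rmsep, sqrt(200 / 3))
  expect_equal(m$rer, 100 / sqrt(200 / 3)) # ~12.25
  expect_equal(round(m$rer, 2), 12.25)
  expect_equal(m$rer_band, "excellent")
  # reference SD equal to RMSEP gives RPD exactly 1
  y <- c(0, 2)
  m1 <- regression_metrics(y, y + sd(y))
  expect_equal(m1$rpd, 1)
  expect_equal(m1$rpd_band, "poor")
  # perfect prediction
  mp <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mp$rmsep, 0)
  expect_equal(mp$r2, 1)
  expect_true(is.infinite(mp$rpd) && is.infinite(mp$rer))
  expect_error(regression_metrics(c(5, 5), c(1, 2)), "zero variance")
})

test_that("RPD and RER invert to the SD and range of the references", {
  for (s in 1:5) {
    set.seed(s)
    y <- runif(11, 0, 100)
    yhat <- y + rnorm(11, sd = 5)
    m <- regression_metrics(y, yhat)
    expect_lt(abs(m$rpd * m$rmsep - sd(y)), 1e-10)
    expect_lt(abs(m$rer * m$rmsep - diff(range(y))), 1e-10)
  }
})

test_that("the pre-treatment sweep reports all six recipes and picks the best", {
  cfg <- noiseless_config(seed = 34, mode = "MIDIR")
  e <- generate_endmembers(cfg)
  d <- build_mixture_design()
  synth <- synthesize_spectra(d, e, cfg)
  y <- synth$composition$proportions[, "RT3"]
  keep <- which(y > 0)
  x <- subset_samples(synth$spectra, keep)
  y <- y[keep]
  sp <- duplex_split(x, round(0.2 * length(keep)))
  rep_ <- sweep_pretreatments(
    subset_samples(x, sp$train_indices),
    subset_samples(x, sp$test_indices),
    y[sp$train_indices], y[sp$test_indices],
    task = "regression", max_lv = 8, folds = 10, seed = 2
  )
  expect_equal(nrow(rep_$table), 6L)
  expect_setequal(rep_$table$pretreatment, pretreatment_names())
  expect_true(all(c("n_lv", "rmsep", "rmsecv", "r2cv") %in%
                    names(rep_$table)))
  # the chosen recipe minimizes RMSEP (to the 4-decimal tie tolerance)
  expect_lte(round(rep_$test_metrics$rmsep, 4),
             min(round(rep_$table$rmsep, 4)))
  # noise-free linear mixtures: the best model is essentially exact
  expect_lt(rep_$test_metrics$rmsep, 1e-6)
})

test_that("LOD follows the monotone-tail rule", {
  m <- fake_da_model()
  f <- fake_identity_fitted()
  levels <- c(1, 2, 5, 8)
  lod_of <- function(scores) {
    estimate_lod(m, f, score_spectra(scores), levels, variety = "V")
  }
  all_pos <- lod_of(c(0.9, 0.9, 0.9, 0.9))
  expect_equal(all_pos$lod, 1)
  expect_equal(all_pos$lod_label, "1%")
  none <- lod_of(c(0.1, 0.1, 0.1, 0.1))
  expect_true(is.na(none$lod))
  expect_equal(none$lod_label, ">8%")
  # (+,-,+,+): the isolated positive at 1% does not lower the LOD
  mixed <- lod_of(c(0.9, 0.1, 0.9, 0.9))
  expect_equal(mixed$lod, 5)
  expect_equal(mixed$positive_flags, c(TRUE, FALSE, TRUE, TRUE))
  expect_error(lod_of_bad <- estimate_lod(m, f, score_spectra(1:3),
                                          c(2, 1, 5)), "ascending")
})
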