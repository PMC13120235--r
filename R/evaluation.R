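#' Assign samples to cross-validation folds
#'
#' Seeded shuffle followed by (near-)equal fold sizes. When binary labels
#' are supplied the assignment is stratified: positives and negatives are
#' shuffled separately and dealt cyclically across folds, so each fold's
#' positive count differs by at most one from proportionality.
#'
#' @param n number of samples.
#' @param k number of folds, `k <= n`.
#' @param labels optional binary vector for stratification.
#' @param seed integer seed.
#' @return integer vector of fold ids (1..k), one per sample.
#' @export
assign_folds <- function(n, k, labels = NULL, seed) {
  n <- as.integer(n); k <- as.integer(k)
  if (k > n) stop("k must not exceed n")
  if (k < 2L) stop("need at least 2 folds")
  folds <- integer(n)
  with_local_seed(seed, {
    if (is.null(labels)) {
      perm <- sample.int(n)
      sizes <- rep(n %/% k, k)
      if (n %% k > 0L) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
      folds[perm] <- rep(seq_len(k), times = sizes)
    } else {
      labels <- as.logical(as.numeric(labels))
      if (length(labels) != n) stop("labels length must equal n")
      pos <- which(labels); neg <- which(!labels)
      pos <- pos[sample.int(length(pos))]
      neg <- neg[sample.int(length(neg))]
      cyc <- rep_len(seq_len(k), length(pos) + length(neg))
      folds[pos] <- cyc[seq_along(pos)]
      folds[neg] <- cyc[length(pos) + seq_along(neg)]
    }
  })
  folds
}

#' K-fold cross-validation of a pre-treatment + PLS pipeline
#'
#' For every fold, the pre-treatment statistics are re-fitted on the fold's
#' training part only (no leakage), a NIPALS model with `max_lv` components
#' is fitted, and held-out predictions are recorded for every component
#' count 1..`max_lv`. Pooled predictions give
#' `RMSECV(l) = sqrt(mean((yhat_cv - y)^2))` per component count.
#'
#' For classification the response is the 0/1 class coding; pooled CV scores
#' thresholded at 0.5 additionally yield CV class predictions. If a fold's
#' training part contains a single class, the assignment is retried once
#' with a re-seeded shuffle, then an error is raised.
#'
#' @param x a [spectra_set()] of raw (region-cut, un-pre-treated) spectra.
#' @param y numeric response, or binary labels for classification.
#' @param spec a [pretreatment_spec()].
#' @param max_lv largest latent-variable count to evaluate.
#' @param folds number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param task `"regression"` or `"classification"`.
#' @return an object of class `cv_result`: `rmsecv_per_lv` (numeric vector
#'   of length `max_lv`), `predictions` (n x max_lv matrix of pooled CV
#'   predictions), `fold_assignment`, `task`, `y`.
#' @export
cross_validate <- function(x, y, spec, max_lv, folds = 10L, seed,
                           task = c("regression", "classification")) {
  task <- match.arg(task)
  n <- nrow(x$absorbance)
  max_lv <- as.integer(max_lv)
  if (max_lv < 1L) stop("max_lv must be at least 1")
  is_cls <- task == "classification"
  yy <- if (is_cls) as.numeric(as.logical(as.numeric(y))) else as.numeric(y)
  fa <- assign_folds(n, folds, labels = if (is_cls) yy else NULL, seed)
  if (is_cls) {
    single <- function(f) {
      vapply(seq_len(max(f)),
             function(k) length(unique(yy[f != k])) < 2L, logical(1))
    }
    if (any(single(fa))) {
      fa <- assign_folds(n, folds, labels = yy, seed + 1L)
      if (any(single(fa))) {
        stop("a fold's training part is single-class even after reseeding")
      }
    }
  }
  preds <- matrix(NA_real_, n, max_lv)
  for (k in seq_len(max(fa))) {
    tr <- which(fa != k); te <- which(fa == k)
    pp <- apply_pretreatment(spec, subset_samples(x, tr),
                             list(subset_samples(x, te)))
    xtr <- pp$train$absorbance
    xte <- pp$others[[1L]]$absorbance
    lv_max_k <- min(max_lv, length(tr) - 1L, ncol(xtr))
    # probing beyond the data rank is routine here; the fewer-component
    # model is simply carried forward, so the early-stop warning is noise
    m <- withCallingHandlers(
      pls1_fit(xtr, yy[tr], lv_max_k),
      warning = function(w) {
        if (grepl("fully deflated", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    for (a in seq_len(m$n_lv)) {
      preds[te, a] <- pls_predict(m, xte, a)
    }
    if (m$n_lv < max_lv) { # early stop or fold cap: carry last column over
      for (a in (m$n_lv + 1L):max_lv) preds[te, a] <- preds[te, m$n_lv]
    }
  }
  rmsecv <- sqrt(colMeans((preds - yy)^2))
  structure(
    list(rmsecv_per_lv = rmsecv, predictions = preds,
         fold_assignment = fa, task = task, y = yy),
    class = "cv_result"
  )
}

#' Select the latent-variable count from a cross-validation result
#'
#' The component count minimizing RMSECV; on ties (within 1e-12 absolute)
#' the less complex model wins.
#'
#' @param cv a `cv_result` (or a bare RMSECV vector).
#' @return the selected number of latent variables.
#' @export
select_n_latent <- function(cv) {
  r <- if (inherits(cv, "cv_result")) cv$rmsecv_per_lv else as.numeric(cv)
  if (length(r) == 0L) stop("empty RMSECV vector")
  which(r <= min(r) + 1e-12)[1L]
}

#' Binary classification metrics
#'
#' Confusion counts and the derived rates: correct classification rate
#' `CCR = 100 (tp + tn) / n` (percent), `precision = tp/(tp+fp)`,
#' `specificity = tn/(tn+fp)`, `sensitivity = tp/(tp+fn)`. Ratios with a
#' zero denominator are reported as `NaN` (with a warning), never as 0.
#'
#' @param y_true,y_pred binary vectors (logical or 0/1) of equal length.
#' @return an object of class `class_metrics`: `tp`, `fp`, `tn`, `fn`,
#'   `n`, `ccr`, `precision`, `specificity`, `sensitivity`.
#' @export
classification_metrics <- function(y_true, y_pred) {
  y_true <- as.logical(as.numeric(y_true))
  y_pred <- as.logical(as.numeric(y_pred))
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  n <- length(y_true)
  if (n < 1L) stop("need at least one sample")
  tp <- sum(y_true & y_pred); fn <- sum(y_true & !y_pred)
  fp <- sum(!y_true & y_pred); tn <- sum(!y_true & !y_pred)
  ratio <- function(num, den, what) {
    if (den == 0L) {
      warning(what, " undefined (zero denominator); reporting NaN")
      return(NaN)
    }
    num / den
  }
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn, n = n,
         ccr = 100 * (tp + tn) / n,
         precision = ratio(tp, tp + fp, "precision"),
         specificity = ratio(tn, tn + fp, "specificity"),
         sensitivity = ratio(tp, tp + fn, "sensitivity")),
    class = "class_metrics"
  )
}

rpd_band <- function(rpd) {
  if (is.nan(rpd)) return(NA_character_)
  if (rpd < 1.5) "poor"
  else if (rpd < 2.0) "rough screening"
  else if (rpd < 2.5) "approximate"
  else if (rpd <= 3.0) "good"
  else "excellent"
}

rer_band <- function(rer) {
  if (is.nan(rer)) return(NA_character_)
  if (rer < 5) "poor"
  else if (rer <= 10) "acceptable"
  else "excellent"
}

#' Regression performance metrics
#'
#' `RMSEP = sqrt(mean((yhat - y)^2))`; `R2` is the squared Pearson
#' correlation of predicted vs reference; `RPD` is the standard deviation
#' (n-1) of the reference values divided by RMSEP; `RER` is the reference
#' range divided by RMSEP. Qualitative bands follow the usual reading: RPD
#' below 1.5 poor, 1.5-2.0 rough screening, 2.0-2.5 approximate, 2.5-3.0
#' good, above 3.0 excellent; RER below 5 poor, 5-10 acceptable, above 10
#' excellent. A perfect fit (RMSEP 0) reports `Inf` for both ratios.
#'
#' @param y_true reference values (e.g. percent proportions), at least 2,
#'   nonzero variance.
#' @param y_pred predicted values.
#' @return an object of class `reg_metrics`: `rmsep`, `r2`, `rpd`, `rer`,
#'   `rpd_band`, `rer_band`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2L) stop("need at least 2 samples")
  if (stats::var(y_true) == 0) stop("reference values have zero variance")
  rmsep <- sqrt(mean((y_pred - y_true)^2))
  r2 <- stats::cor(y_true, y_pred)^2
  rpd <- if (rmsep == 0) Inf else stats::sd(y_true) / rmsep
  rer <- if (rmsep == 0) Inf else diff(range(y_true)) / rmsep
  structure(
    list(rmsep = rmsep, r2 = r2, rpd = rpd, rer = rer,
         rpd_band = rpd_band(rpd), rer_band = rer_band(rer)),
    class = "reg_metrics"
  )
}

#' Sweep the six pre-treatments and select the best model
#'
#' For each pre-treatment: cross-validation on the training set selects the
#' latent-variable count (minimum RMSECV, less complex on ties); a final
#' model is fitted on the full training set and evaluated on the external
#' test set. The pre-treatment is then chosen primarily on the test
#' criterion (minimum RMSEP for regression, maximum CCR for
#' classification); ties -- equality after rounding to 4 decimals -- are
#' broken by the cross-validation criterion, then by fewer latent
#' variables. Selecting on the external test set re-uses it, which is
#' statistically optimistic but is the procedure replicated here.
#'
#' @param train,test [spectra_set()]s of raw spectra (disjoint samples, one
#'   grid).
#' @param y_train,y_test responses (numeric, or binary labels for
#'   classification).
#' @param task `"regression"` or `"classification"`.
#' @param specs list of [pretreatment_spec()]s (default: the six).
#' @param max_lv largest latent-variable count considered (default 15,
#'   capped at `n_train - ceiling(n_train/folds) - 1`).
#' @param folds CV folds (default 10).
#' @param seed integer seed for fold assignment.
#' @param positive_label class name for classification reports.
#' @return an object of class `selection_report`: `table` (one row per
#'   pre-treatment: name, n_lv, test and CV criteria), `chosen` (name),
#'   `chosen_n_lv`, `chosen_model` (`pls_model` or `da_model`),
#'   `chosen_fitted` (its `fitted_pretreatment`), `chosen_cv`
#'   (its `cv_result`), `test_metrics` and `cv_metrics` for the chosen
#'   model, and `task`.
#' @export
sweep_pretreatments <- function(train, test, y_train, y_test,
                                task = c("regression", "classification"),
                                specs = default_pretreatments(),
                                max_lv = 15L, folds = 10L, seed,
                                positive_label = "positive") {
  task <- match.arg(task)
  is_cls <- task == "classification"
  n_train <- nrow(train$absorbance)
  cap <- n_train - as.integer(ceiling(n_train / folds)) - 1L
  max_lv <- max(1L, min(as.integer(max_lv), cap))
  ytr <- if (is_cls) as.numeric(as.logical(as.numeric(y_train)))
         else as.numeric(y_train)
  yte <- if (is_cls) as.logical(as.numeric(y_test)) else as.numeric(y_test)

  rows <- list(); fits <- list()
  for (sname in names(specs)) {
    spec <- specs[[sname]]
    cv <- cross_validate(train, ytr, spec, max_lv, folds, seed, task)
    n_lv <- select_n_latent(cv)
    pp <- apply_pretreatment(spec, train, list(test))
    xtr <- pp$train$absorbance
    if (is_cls) {
      model <- plsda_fit(xtr, ytr, n_lv, positive_label)
      pred_te <- plsda_predict(model, pp$others[[1L]]$absorbance)
      mt <- classification_metrics(yte, pred_te$labels)
      mcv <- classification_metrics(ytr == 1, cv$predictions[, n_lv] > 0.5)
      rows[[sname]] <- data.frame(
        pretreatment = sname, n_lv = n_lv,
        ccr_test = mt$ccr, ccr_cv = mcv$ccr,
        rmsecv = cv$rmsecv_per_lv[n_lv],
        stringsAsFactors = FALSE
      )
      fits[[sname]] <- list(model = model, fitted = pp$fitted, cv = cv,
                            test_metrics = mt, cv_metrics = mcv)
    } else {
      model <- pls1_fit(xtr, ytr, n_lv)
      pred_te <- pls_predict(model, pp$others[[1L]]$absorbance)
      mt <- regression_metrics(yte, pred_te)
      r2cv <- stats::cor(ytr, cv$predictions[, n_lv])^2
      rows[[sname]] <- data.frame(
        pretreatment = sname, n_lv = n_lv,
        rmsep = mt$rmsep, r2p = mt$r2, rpd = mt$rpd, rer = mt$rer,
        rmsecv = cv$rmsecv_per_lv[n_lv], r2cv = r2cv,
        stringsAsFactors = FALSE
      )
      fits[[sname]] <- list(model = model, fitted = pp$fitted, cv = cv,
                            test_metrics = mt,
                            cv_metrics = list(rmsecv = cv$rmsecv_per_lv[n_lv],
                                              r2cv = r2cv))
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ord <- if (is_cls) {
    order(-round(tab$ccr_test, 4), -round(tab$ccr_cv, 4), tab$n_lv)
  } else {
    order(round(tab$rmsep, 4), round(tab$rmsecv, 4), tab$n_lv)
  }
  chosen <- tab$pretreatment[ord[1L]]
  structure(
    list(table = tab, chosen = chosen,
         chosen_n_lv = tab$n_lv[tab$pretreatment == chosen],
         chosen_model = fits[[chosen]]$model,
         chosen_fitted = fits[[chosen]]$fitted,
         chosen_cv = fits[[chosen]]$cv,
         test_metrics = fits[[chosen]]$test_metrics,
         cv_metrics = fits[[chosen]]$cv_metrics,
         task = task),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report> task =", x$task, "| chosen:", x$chosen,
      "with", x$chosen_n_lv, "LV\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Estimate the limit of detection from a trituration series
#'
#' Each trituration spectrum is pre-treated with the training statistics
#' and classified with the selected binary model. The LOD is the smallest
#' level L such that L and every level above it are classified positive
#' (the monotone-tail rule); isolated positives below L are reported in the
#' flags but do not lower the LOD. If no level qualifies the LOD is marked
#' as above the largest level tested.
#'
#' @param model a `da_model`.
#' @param fitted the model's `fitted_pretreatment`.
#' @param trituration_spectra a [spectra_set()] with one spectrum per
#'   level, in the same order as `levels`.
#' @param levels percentages tested, sorted ascending.
#' @param variety name of the targeted variety (for reporting).
#' @return an object of class `lod_result`: `variety`, `levels_tested`,
#'   `positive_flags`, `lod` (numeric, `NA` if above range) and
#'   `lod_label` (e.g. `"1%"` or `">8%"`).
#' @export
estimate_lod <- function(model, fitted, trituration_spectra, levels,
                         variety = model$positive_label) {
  if (is.unsorted(levels, strictly = TRUE)) {
    stop("levels must be sorted strictly ascending")
  }
  if (nrow(trituration_spectra$absorbance) != length(levels)) {
    stop("one trituration spectrum per level is required")
  }
  xp <- pretreat_apply(fitted, trituration_spectra)
  flags <- plsda_predict(model, xp$absorbance)$labels
  tail_ok <- rev(cumprod(rev(as.integer(flags)))) == 1L
  if (any(tail_ok)) {
    lod <- levels[which(tail_ok)[1L]]
    label <- paste0(lod, "%")
  } else {
    lod <- NA_real_
    label <- paste0(">", max(levels), "%")
  }
  structure(
    list(variety = variety, levels_tested = levels,
         positive_flags = flags, lod = lod, lod_label = label),
    class = "lod_result"
  )
}
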