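#' Fit a PLS1 regression model by NIPALS
#'
#' Partial least squares with a single response: latent variables are
#' extracted as linear combinations of the (mean-centered) channels that
#' maximize remaining covariance with the (mean-centered) response, with
#' deflation after each component. Per component a:
#' `w = X'y / ||X'y||`, `t = Xw`, `p = X't/(t't)`, `q = y't/(t't)`,
#' then `X <- X - tp'`, `y <- y - tq`. Regression coefficients are
#' `b = W (P'W)^{-1} q` with intercept `y_mean - x_mean' b`.
#'
#' If the response is fully deflated before `n_lv` components (weight
#' vector numerically zero), extraction stops early: the model keeps the
#' components found so far and carries `early_stop = TRUE`, with a warning.
#'
#' @param x numeric matrix (`n_samples x n_channels`) of pre-treated
#'   spectra.
#' @param y numeric response (e.g. percent proportion), nonzero variance.
#' @param n_lv number of latent variables,
#'   `1 <= n_lv <= min(n_samples - 1, n_channels)`.
#' @return an object of class `pls_model`: weights `W`, x-loadings `P`
#'   (`channels x n_lv`), y-loadings `q`, centering vectors `x_mean` /
#'   `y_mean`, `coefficients` (with `intercept` attribute), `n_lv`,
#'   `scores` (training score matrix) and `early_stop`.
#' @export
pls1_fit <- function(x, y, n_lv) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stop("length(y) must equal nrow(x)")
  n_lv <- as.integer(n_lv)
  if (n_lv < 1L) stop("n_lv must be at least 1")
  if (n_lv > min(n - 1L, p)) {
    stop("n_lv (", n_lv, ") exceeds min(n_samples - 1, n_channels) = ",
         min(n - 1L, p))
  }
  if (stats::var(y) == 0) stop("response has zero variance")
  x_mean <- colMeans(x); y_mean <- mean(y)
  X <- sweep(x, 2L, x_mean, "-")
  yc <- y - y_mean
  w_scale <- sqrt(sum(crossprod(X, yc)^2)) # reference scale for early stop
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  q <- numeric(n_lv); TT <- matrix(0, n, n_lv)
  early <- FALSE; a_done <- 0L
  for (a in seq_len(n_lv)) {
    w <- crossprod(X, yc)
    nw <- sqrt(sum(w^2))
    if (nw <= 1e-12 * max(w_scale, 1)) { early <- TRUE; break }
    w <- w / nw
    t_a <- as.numeric(X %*% w)
    tt <- sum(t_a^2)
    if (tt <= .Machine$double.eps * n) { early <- TRUE; break }
    p_a <- as.numeric(crossprod(X, t_a)) / tt
    q_a <- sum(yc * t_a) / tt
    X <- X - tcrossprod(t_a, p_a)
    yc <- yc - t_a * q_a
    W[, a] <- w; P[, a] <- p_a; q[a] <- q_a; TT[, a] <- t_a
    a_done <- a
  }
  if (early) {
    warning("response fully deflated after ", a_done,
            " latent variable(s); returning a smaller model")
    if (a_done == 0L) stop("no latent variable could be extracted")
    W <- W[, seq_len(a_done), drop = FALSE]
    P <- P[, seq_len(a_done), drop = FALSE]
    q <- q[seq_len(a_done)]
    TT <- TT[, seq_len(a_done), drop = FALSE]
  }
  m <- structure(
    list(n_lv = a_done, W = W, P = P, q = q,
         x_mean = x_mean, y_mean = y_mean, scores = TT,
         early_stop = early),
    class = "pls_model"
  )
  m$coefficients <- pls_coefficients(m)
  m
}

#' Regression coefficient vector of a PLS model
#'
#' @param m a `pls_model`.
#' @param n_lv number of latent variables to use (default: all in `m`).
#' @return per-channel coefficient vector with the intercept as attribute
#'   `"intercept"`.
#' @export
pls_coefficients <- function(m, n_lv = m$n_lv) {
  n_lv <- as.integer(n_lv)
  if (n_lv < 1L || n_lv > m$n_lv) stop("n_lv out of range for this model")
  Wa <- m$W[, seq_len(n_lv), drop = FALSE]
  Pa <- m$P[, seq_len(n_lv), drop = FALSE]
  qa <- m$q[seq_len(n_lv)]
  b <- as.numeric(Wa %*% solve(crossprod(Pa, Wa), qa))
  attr(b, "intercept") <- m$y_mean - sum(m$x_mean * b)
  b
}

#' Predict with a PLS model
#'
#' `yhat = (x - x_mean)' b + y_mean`, vectorized over samples.
#'
#' @param m a `pls_model`.
#' @param x matrix of pre-treated spectra with the model's channel count, or
#'   a [spectra_set()].
#' @param n_lv number of latent variables to use (default: all in `m`).
#' @return numeric vector of predictions.
#' @export
pls_predict <- function(m, x, n_lv = m$n_lv) {
  if (inherits(x, "spectra_set")) x <- x$absorbance
  x <- as.matrix(x)
  if (ncol(x) != length(m$x_mean)) {
    stop("channel mismatch: model has ", length(m$x_mean),
         " channels, data has ", ncol(x))
  }
  b <- if (n_lv == m$n_lv) m$coefficients else pls_coefficients(m, n_lv)
  as.numeric(x %*% b) + attr(b, "intercept")
}

#' Fit a binary PLS-DA model
#'
#' Labels are encoded positive = 1, negative = 0 and the encoded response is
#' fitted with [pls1_fit()]; the decision threshold is 0.5.
#'
#' @param x matrix of pre-treated spectra.
#' @param labels logical (or 0/1) vector; both classes must be present.
#' @param n_lv number of latent variables.
#' @param positive_label name of the positive class (for reporting).
#' @return an object of class `da_model`: list with `core` (the
#'   `pls_model`), `positive_label`, `threshold` (0.5).
#' @export
plsda_fit <- function(x, labels, n_lv, positive_label = "positive") {
  labels <- as.logical(as.numeric(labels))
  if (anyNA(labels)) stop("labels must be binary (logical or 0/1)")
  if (all(labels) || !any(labels)) {
    stop("both classes must be present to fit a binary model")
  }
  core <- pls1_fit(x, as.numeric(labels), n_lv)
  structure(
    list(core = core, positive_label = positive_label, threshold = 0.5),
    class = "da_model"
  )
}

#' Predict classes with a PLS-DA model
#'
#' A sample is labelled positive iff its continuous score strictly exceeds
#' the threshold (a score of exactly 0.5 is negative).
#'
#' @param m a `da_model`.
#' @param x matrix of pre-treated spectra or a [spectra_set()].
#' @param n_lv number of latent variables to use (default: all).
#' @return list with `labels` (logical vector) and `scores` (numeric).
#' @export
plsda_predict <- function(m, x, n_lv = m$core$n_lv) {
  scores <- pls_predict(m$core, x, n_lv)
  list(labels = scores > m$threshold, scores = scores)
}

#' Serialize a PLS or PLS-DA model to a text file
#'
#' Writes a versioned JSON representation (format tag `blendspec-model/1`)
#' holding the factors, centering vectors, threshold and, when supplied, the
#' fitted pre-treatment (grid, name, autoscaling statistics), so the model
#' round-trips through [read_model()].
#'
#' @param m a `pls_model` or `da_model`.
#' @param path destination path.
#' @param fitted optional `fitted_pretreatment` to store alongside.
#' @return `path`, invisibly.
#' @export
write_model <- function(m, path, fitted = NULL) {
  is_da <- inherits(m, "da_model")
  core <- if (is_da) m$core else m
  payload <- list(
    format = "blendspec-model/1",
    type = if (is_da) "da" else "pls",
    n_lv = core$n_lv,
    W = core$W, P = core$P, q = core$q,
    x_mean = core$x_mean, y_mean = core$y_mean,
    early_stop = core$early_stop,
    positive_label = if (is_da) m$positive_label else NULL,
    threshold = if (is_da) m$threshold else NULL,
    pretreatment = if (!is.null(fitted)) {
      list(name = fitted$spec$name, sg_window = fitted$spec$sg_window,
           sg_polyorder = fitted$spec$sg_polyorder, grid = fitted$grid,
           means = fitted$means, sds = fitted$sds)
    } else NULL
  )
  writeLines(jsonlite::serializeJSON(payload, digits = NA), path)
  invisible(path)
}

#' Read a serialized model written by [write_model()]
#'
#' @param path path to the model file.
#' @return list with `model` (a `pls_model` or `da_model`) and `fitted`
#'   (the stored `fitted_pretreatment`, or `NULL`).
#' @export
read_model <- function(path) {
  payload <- jsonlite::unserializeJSON(paste(readLines(path),
                                             collapse = "\n"))
  if (!identical(payload$format, "blendspec-model/1")) {
    stop("unrecognized model format tag: ", payload$format)
  }
  core <- structure(
    list(n_lv = payload$n_lv, W = payload$W, P = payload$P, q = payload$q,
         x_mean = payload$x_mean, y_mean = payload$y_mean,
         scores = NULL, early_stop = isTRUE(payload$early_stop)),
    class = "pls_model"
  )
  core$coefficients <- pls_coefficients(core)
  model <- if (identical(payload$type, "da")) {
    structure(list(core = core, positive_label = payload$positive_label,
                   threshold = payload$threshold), class = "da_model")
  } else core
  fitted <- NULL
  if (!is.null(payload$pretreatment)) {
    pp <- payload$pretreatment
    fitted <- structure(
      list(spec = pretreatment_spec(pp$name, pp$sg_window, pp$sg_polyorder),
           grid = pp$grid, means = pp$means, sds = pp$sds),
      class = "fitted_pretreatment"
    )
  }
  list(model = model, fitted = fitted)
}
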