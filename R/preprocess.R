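#' Pre-treatment recipe
#'
#' The six pre-treatment approaches explored before PLS modelling:
#' `autoscale` (per-channel centering and unit-variance scaling with
#' training statistics), `snv` (standard normal variate, per-spectrum),
#' `d1`/`d2` (Savitzky-Golay first/second derivative) and `snv_d1`/`snv_d2`
#' (SNV followed by the derivative).
#'
#' @param name one of `"autoscale"`, `"snv"`, `"d1"`, `"d2"`, `"snv_d1"`,
#'   `"snv_d2"`.
#' @param sg_window odd Savitzky-Golay window size (default 17).
#' @param sg_polyorder Savitzky-Golay polynomial order (default 2); must be
#'   less than `sg_window`.
#' @return an object of class `pretreatment_spec`.
#' @export
pretreatment_spec <- function(name, sg_window = 17L, sg_polyorder = 2L) {
  name <- match.arg(name, pretreatment_names())
  sg_window <- as.integer(sg_window)
  sg_polyorder <- as.integer(sg_polyorder)
  if (sg_window %% 2L == 0L) stop("sg_window must be odd")
  if (sg_window <= sg_polyorder) stop("sg_window must exceed sg_polyorder")
  structure(list(name = name, sg_window = sg_window,
                 sg_polyorder = sg_polyorder),
            class = "pretreatment_spec")
}

#' Names of the six pre-treatment approaches
#' @return character vector of the six spec names.
#' @export
pretreatment_names <- function() {
  c("autoscale", "snv", "d1", "d2", "snv_d1", "snv_d2")
}

#' The six default pre-treatment recipes
#' @param sg_window,sg_polyorder Savitzky-Golay parameters shared by the
#'   derivative-based recipes.
#' @return named list of six [pretreatment_spec()] objects.
#' @export
default_pretreatments <- function(sg_window = 17L, sg_polyorder = 2L) {
  specs <- lapply(pretreatment_names(), pretreatment_spec,
                  sg_window = sg_window, sg_polyorder = sg_polyorder)
  names(specs) <- pretreatment_names()
  specs
}

#' Standard normal variate transform
#'
#' Each spectrum (row) is centered by its own mean and scaled by its own
#' standard deviation (n-1 denominator), removing per-sample multiplicative
#' scatter and offset effects. The grid is unchanged.
#'
#' @param s a [spectra_set()].
#' @return the transformed `spectra_set`; every row has mean 0 and SD 1.
#' @export
snv_transform <- function(s) {
  x <- s$absorbance
  mu <- rowMeans(x)
  sdv <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1L))
  if (any(sdv == 0)) {
    stop("constant spectrum (zero SD) for sample '",
         s$sample_ids[which(sdv == 0)[1L]], "'")
  }
  spectra_set(s$grid, (x - mu) / sdv, s$sample_ids, s$meta)
}

#' Savitzky-Golay derivative of a spectra set
#'
#' Local least-squares polynomial differentiation using the central filter
#' coefficients from [signal::sgolay()], scaled per cm^-1 (so the result is
#' invariant to the grid spacing). Edge channels without a full window are
#' dropped: the output has `n_channels - (window - 1)` channels and a
#' correspondingly trimmed grid.
#'
#' @param s a [spectra_set()].
#' @param deriv derivative order, 1 or 2.
#' @param window odd window size (default 17).
#' @param polyorder polynomial order (default 2); SG of order 2 reproduces
#'   derivatives of quadratics exactly.
#' @return the differentiated `spectra_set` on the trimmed grid.
#' @export
savgol_derivative <- function(s, deriv, window = 17L, polyorder = 2L) {
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  deriv <- as.integer(deriv)
  if (!deriv %in% c(1L, 2L)) stop("deriv must be 1 or 2")
  if (window %% 2L == 0L) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  p <- length(s$grid)
  if (p < window) {
    stop("need at least ", window, " channels for window ", window,
         "; got ", p)
  }
  spacing <- grid_spacing(s)
  co <- signal::sgolay(p = polyorder, n = window, m = deriv,
                       ts = spacing)[(window + 1L) %/% 2L, ]
  co <- as.numeric(co)
  h <- (window - 1L) %/% 2L
  n_out <- p - 2L * h
  # band matrix applying the central filter at every full-window position
  W <- matrix(0, p, n_out)
  for (j in seq_len(n_out)) W[j:(j + window - 1L), j] <- co
  spectra_set(s$grid[(h + 1L):(p - h)], s$absorbance %*% W,
              s$sample_ids, s$meta)
}

#' Fit autoscaling statistics on a training set
#'
#' @param train a [spectra_set()] with at least 2 samples.
#' @return a `fitted_pretreatment` holding per-channel training means and
#'   standard deviations (n-1 denominator).
#' @export
autoscale_fit <- function(train) {
  if (nrow(train$absorbance) < 2L) {
    stop("autoscaling requires at least 2 training samples")
  }
  structure(
    list(spec = pretreatment_spec("autoscale"),
         grid = train$grid,
         means = colMeans(train$absorbance),
         sds = col_sds(train$absorbance)),
    class = "fitted_pretreatment"
  )
}

#' Apply fitted autoscaling to a spectra set
#'
#' Channels are centered and scaled with the *training* statistics;
#' zero-variance training channels map to 0 (they carry no information).
#'
#' @param f a `fitted_pretreatment` from [autoscale_fit()].
#' @param s a [spectra_set()] on the same grid.
#' @return the autoscaled `spectra_set`.
#' @export
autoscale_apply <- function(f, s) {
  if (length(f$grid) != length(s$grid) ||
      max(abs(f$grid - s$grid)) > 1e-9) {
    stop("grid mismatch between fitted pre-treatment and spectra")
  }
  x <- sweep(s$absorbance, 2L, f$means, "-")
  nz <- f$sds > 0
  x[, nz] <- sweep(x[, nz, drop = FALSE], 2L, f$sds[nz], "/")
  x[, !nz] <- 0
  spectra_set(s$grid, x, s$sample_ids, s$meta)
}

# sample-wise (statistics-free) part of a pre-treatment chain
pretreat_samplewise <- function(spec, s) {
  switch(spec$name,
    autoscale = s,
    snv = snv_transform(s),
    d1 = savgol_derivative(s, 1L, spec$sg_window, spec$sg_polyorder),
    d2 = savgol_derivative(s, 2L, spec$sg_window, spec$sg_polyorder),
    snv_d1 = savgol_derivative(snv_transform(s), 1L, spec$sg_window,
                               spec$sg_polyorder),
    snv_d2 = savgol_derivative(snv_transform(s), 2L, spec$sg_window,
                               spec$sg_polyorder)
  )
}

#' Apply a pre-treatment with strict train/test separation
#'
#' Sample-local steps (SNV, derivatives) are applied identically to every
#' set; the statistics-bearing step (autoscaling) is fitted on the training
#' set only and then applied to all sets. Composition order for the combined
#' recipes is SNV first, then the derivative.
#'
#' @param spec a [pretreatment_spec()].
#' @param train training [spectra_set()].
#' @param others list of further `spectra_set`s (e.g. the test set) on the
#'   same grid.
#' @return list with `train` (transformed), `others` (list, transformed) and
#'   `fitted` (a `fitted_pretreatment` usable on future data via
#'   [pretreat_apply()]).
#' @export
apply_pretreatment <- function(spec, train, others = list()) {
  tr <- pretreat_samplewise(spec, train)
  ot <- lapply(others, pretreat_samplewise, spec = spec)
  if (spec$name == "autoscale") {
    fitted <- autoscale_fit(tr)
    fitted$spec <- spec
    tr <- autoscale_apply(fitted, tr)
    ot <- lapply(ot, autoscale_apply, f = fitted)
  } else {
    fitted <- structure(
      list(spec = spec, grid = tr$grid, means = NULL, sds = NULL),
      class = "fitted_pretreatment"
    )
  }
  list(train = tr, others = ot, fitted = fitted)
}

#' Apply an already-fitted pre-treatment to new spectra
#'
#' @param fitted a `fitted_pretreatment` from [apply_pretreatment()] or
#'   [autoscale_fit()].
#' @param s a [spectra_set()] on the original (untrimmed) grid.
#' @return the transformed `spectra_set` on the fitted (possibly trimmed)
#'   grid.
#' @export
pretreat_apply <- function(fitted, s) {
  out <- pretreat_samplewise(fitted$spec, s)
  if (!is.null(fitted$means)) out <- autoscale_apply(fitted, out)
  out
}
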