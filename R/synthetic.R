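#' Default variety names
#'
#' Certified reference variety codes used throughout: flue-cured (RT2),
#' oriental (RT3), burley (RT4), dark air-cured (RT5, RT9) and
#' dark fire-cured (RT10).
#'
#' @return character vector of six variety names.
#' @export
default_varieties <- function() c("RT2", "RT3", "RT4", "RT5", "RT9", "RT10")

#' Synthetic spectra generator configuration
#'
#' Parameters of the endmember and blend-spectrum generator. The NIR grid is
#' 4000-10000 cm^-1 at 8 cm^-1 resolution; the MID-IR grid is the
#' 650-2000 cm^-1 fingerprint region at 4 cm^-1. Endmembers are sums of
#' Gaussian bands: a set of bands shared by all varieties plus a small
#' variety-specific set scaled by `similarity_delta`, so the six spectra are
#' highly similar (varieties of one plant species). Observed blend spectra
#' add a per-sample log-normal multiplicative scatter factor, a per-sample
#' affine baseline and white noise -- the artefacts the pre-treatments are
#' designed to remove.
#'
#' @param mode "NIR" or "MIDIR"; selects the wavenumber grid.
#' @param n_shared_bands number of Gaussian bands common to all endmembers.
#' @param n_specific_bands number of variety-specific bands per endmember.
#' @param band_width_range range (cm^-1) for Gaussian band standard widths.
#' @param similarity_delta scalar in \[0, 1\] scaling the variety-specific
#'   band amplitude; 0 makes all endmembers identical.
#' @param scatter_sigma std dev of the per-sample log multiplicative factor.
#' @param baseline_sigma std dev of the per-sample baseline offset and slope.
#' @param noise_sigma std dev of i.i.d. white noise, absorbance units.
#' @param n_replicates measurements per design row (default 1).
#' @param seed integer seed (mandatory); the generator is fully
#'   deterministic given the seed.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(mode = c("NIR", "MIDIR"),
                             n_shared_bands = 30L,
                             n_specific_bands = 8L,
                             band_width_range = c(20, 150),
                             similarity_delta = 0.15,
                             scatter_sigma = 0.05,
                             baseline_sigma = 0.01,
                             noise_sigma = 0.001,
                             n_replicates = 1L,
                             seed) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("seed is mandatory")
  sigmas <- c(scatter_sigma, baseline_sigma, noise_sigma)
  if (any(sigmas < 0)) stop("all sigmas must be >= 0")
  if (similarity_delta < 0 || similarity_delta > 1) {
    stop("similarity_delta must be in [0, 1]")
  }
  # NIR: 751 channels; MID-IR fingerprint: 338 channels (650..1998, the
  # last full 4 cm^-1 step below 2000)
  grid <- switch(mode,
    NIR = seq(4000, 10000, by = 8),
    MIDIR = seq(650, by = 4, length.out = 338)
  )
  structure(
    list(mode = mode, grid = grid,
         n_shared_bands = as.integer(n_shared_bands),
         n_specific_bands = as.integer(n_specific_bands),
         band_width_range = band_width_range,
         similarity_delta = similarity_delta,
         scatter_sigma = scatter_sigma,
         baseline_sigma = baseline_sigma,
         noise_sigma = noise_sigma,
         n_replicates = as.integer(n_replicates),
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# sum of Gaussian bands evaluated on grid
gaussian_band_sum <- function(grid, centers, widths, amps) {
  y <- numeric(length(grid))
  for (i in seq_along(centers)) {
    y <- y + amps[i] * exp(-0.5 * ((grid - centers[i]) / widths[i])^2)
  }
  y
}

#' Generate highly similar endmember spectra
#'
#' Each endmember is the shared band sum plus `similarity_delta` times its
#' own variety-specific band sum. All absorbances are non-negative and the
#' result is deterministic given `config$seed`.
#'
#' @param config a [generator_config()].
#' @param varieties variety names (default [default_varieties()]).
#' @return an object of class `endmember_set` with fields `grid`, `spectra`
#'   (`n_varieties x n_channels`), `variety_names`, `similarity_delta`.
#' @export
generate_endmembers <- function(config, varieties = default_varieties()) {
  grid <- config$grid
  lo <- min(grid); hi <- max(grid)
  wr <- config$band_width_range
  with_local_seed(config$seed, {
    shared <- gaussian_band_sum(
      grid,
      centers = stats::runif(config$n_shared_bands, lo, hi),
      widths  = stats::runif(config$n_shared_bands, wr[1L], wr[2L]),
      amps    = stats::runif(config$n_shared_bands, 0.1, 1)
    )
    spectra <- t(vapply(varieties, function(v) {
      specific <- gaussian_band_sum(
        grid,
        centers = stats::runif(config$n_specific_bands, lo, hi),
        widths  = stats::runif(config$n_specific_bands, wr[1L], wr[2L]),
        amps    = stats::runif(config$n_specific_bands, 0.1, 1)
      )
      shared + config$similarity_delta * specific
    }, numeric(length(grid))))
  })
  rownames(spectra) <- varieties
  structure(
    list(grid = grid, spectra = spectra, variety_names = varieties,
         similarity_delta = config$similarity_delta),
    class = "endmember_set"
  )
}

design_label_names <- c("pure", "binary", "ternary", "quaternary",
                        "quinary", "senary")

#' Enumerate the equal-proportion k-subset mixture design
#'
#' One row per nonempty subset of the varieties (k = 1..n), with every
#' present component at 100/k percent, in deterministic order: subset size
#' ascending, lexicographic (by variety position) within each size. For six
#' varieties this yields 63 rows: 6 pures, 15 binary, 20 ternary,
#' 15 quaternary, 6 quinary and 1 senary mixture.
#'
#' @param varieties character vector of at least 2 variety names.
#' @return a [composition_table()] whose `design` data.frame labels each row
#'   (`pure`, `binary`, ..., `senary`; `target` is `NA` for subset rows).
#' @export
build_mixture_design <- function(varieties = default_varieties()) {
  nv <- length(varieties)
  if (nv < 2L) stop("need at least 2 varieties")
  rows <- list(); ids <- character(0); labels <- character(0)
  for (k in seq_len(nv)) {
    subsets <- utils::combn(nv, k)
    for (j in seq_len(ncol(subsets))) {
      members <- subsets[, j]
      p <- numeric(nv)
      p[members] <- 100 / k
      rows[[length(rows) + 1L]] <- p
      ids <- c(ids, paste0("mix_", paste(varieties[members], collapse = "-")))
      labels <- c(labels, design_label_names[min(k, 6L)])
    }
  }
  composition_table(
    ids, varieties, do.call(rbind, rows),
    design = data.frame(label = labels, target = NA_character_,
                        stringsAsFactors = FALSE)
  )
}

#' Enumerate the trituration (serial-dilution) design
#'
#' For each variety v and level L, one blend with v at L percent and each of
#' the other varieties at (100 - L)/(n - 1) percent -- a dilution of v into
#' the equal background blend of the remaining varieties, used for
#' limit-of-detection estimation.
#'
#' @param varieties character vector of variety names.
#' @param levels percentages of the triturated variety, each in (0, 100).
#' @return a [composition_table()] with `length(varieties) * length(levels)`
#'   rows; the `design` data.frame marks each row `trituration` with
#'   `target` = the triturated variety.
#' @export
build_trituration_design <- function(varieties = default_varieties(),
                                     levels = c(1, 2, 5, 8)) {
  nv <- length(varieties)
  if (nv < 2L) stop("need at least 2 varieties")
  if (any(levels <= 0 | levels >= 100)) {
    stop("trituration levels must lie strictly between 0 and 100")
  }
  levels <- sort(levels)
  rows <- list(); ids <- character(0); targets <- character(0)
  for (v in seq_len(nv)) {
    for (L in levels) {
      p <- rep((100 - L) / (nv - 1L), nv)
      p[v] <- L
      rows[[length(rows) + 1L]] <- p
      ids <- c(ids, paste0("trit_", varieties[v], "_", L))
      targets <- c(targets, varieties[v])
    }
  }
  composition_table(
    ids, varieties, do.call(rbind, rows),
    design = data.frame(label = "trituration", target = targets,
                        stringsAsFactors = FALSE)
  )
}

#' Concatenate mixture designs
#'
#' @param ... [composition_table()] objects over the same varieties.
#' @return a single [composition_table()] with rows stacked in order.
#' @export
bind_designs <- function(...) {
  parts <- list(...)
  vars <- parts[[1L]]$varieties
  for (p in parts) {
    if (!identical(p$varieties, vars)) {
      stop("all designs must share the same variety set and order")
    }
  }
  composition_table(
    unlist(lapply(parts, `[[`, "sample_ids")),
    vars,
    do.call(rbind, lapply(parts, `[[`, "proportions")),
    design = do.call(rbind, lapply(parts, `[[`, "design"))
  )
}

#' Synthesize observed blend spectra from a design
#'
#' The clean spectrum of each sample is the Beer-Lambert linear combination
#' `sum_v (proportion_v / 100) * endmember_v`. The observed spectrum is
#' `exp(g) * clean + b0 + b1 * nu_scaled + eps` with, per sample,
#' `g ~ N(0, scatter_sigma^2)`, `b0, b1 ~ N(0, baseline_sigma^2)`, and
#' per channel `eps ~ N(0, noise_sigma^2)`; `nu_scaled` maps the grid to
#' \[0, 1\]. With all sigmas zero the observed spectra equal the exact linear
#' combination. Deterministic given `config$seed`.
#'
#' @param design a [composition_table()] (e.g. from
#'   [build_mixture_design()]).
#' @param endmembers an `endmember_set` over the same varieties.
#' @param config a [generator_config()].
#' @return list with elements `spectra` (a [spectra_set()]) and
#'   `composition` (the design, replicated if `n_replicates > 1`).
#' @export
synthesize_spectra <- function(design, endmembers, config) {
  if (!setequal(design$varieties, endmembers$variety_names)) {
    stop("design varieties do not match endmember varieties")
  }
  E <- endmembers$spectra[design$varieties, , drop = FALSE]
  grid <- endmembers$grid
  comp <- design
  if (config$n_replicates > 1L) {
    rep_idx <- rep(seq_along(design$sample_ids), each = config$n_replicates)
    comp <- composition_table(
      paste0(design$sample_ids[rep_idx], "_r",
             rep(seq_len(config$n_replicates), length(design$sample_ids))),
      design$varieties,
      design$proportions[rep_idx, , drop = FALSE],
      design = if (is.null(design$design)) NULL
               else design$design[rep_idx, , drop = FALSE]
    )
  }
  clean <- (comp$proportions / 100) %*% E
  n <- nrow(clean); p <- ncol(clean)
  nu <- if (p > 1L) (grid - min(grid)) / (max(grid) - min(grid)) else 0
  obs <- with_local_seed(config$seed + 1L, {
    g  <- stats::rnorm(n, 0, config$scatter_sigma)
    b0 <- stats::rnorm(n, 0, config$baseline_sigma)
    b1 <- stats::rnorm(n, 0, config$baseline_sigma)
    eps <- matrix(stats::rnorm(n * p, 0, config$noise_sigma), n, p)
    exp(g) * clean + outer(b0, rep(1, p)) + outer(b1, nu) + eps
  })
  spectra <- spectra_set(grid, obs, comp$sample_ids,
                         meta = comp$design)
  list(spectra = spectra, composition = comp)
}
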