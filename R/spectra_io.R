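#' Spectral data container
#'
#' A `spectra_set` couples a wavenumber grid with an absorbance matrix and
#' sample identifiers. The grid is stored strictly ascending with uniform
#' spacing (the convention of displaying IR spectra with wavenumber
#' decreasing is a presentation concern only).
#'
#' @param grid numeric vector of wavenumbers (cm^-1), strictly monotonic with
#'   uniform spacing.
#' @param absorbance numeric matrix, `n_samples x n_channels`, in absorbance
#'   units.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to the rownames of `absorbance`.
#' @param meta optional free-form per-sample metadata (list or data.frame).
#' @return an object of class `spectra_set` with fields `grid`, `absorbance`
#'   (rownames = sample ids), `sample_ids` and `meta`.
#' @export
spectra_set <- function(grid, absorbance, sample_ids = rownames(absorbance),
                        meta = NULL) {
  grid <- as.numeric(grid)
  absorbance <- as.matrix(absorbance)
  if (is.null(sample_ids)) {
    sample_ids <- paste0("S", seq_len(nrow(absorbance)))
  }
  sample_ids <- as.character(sample_ids)
  if (length(grid) != ncol(absorbance)) {
    stop("grid length (", length(grid), ") must equal the number of ",
         "absorbance columns (", ncol(absorbance), ")")
  }
  if (length(sample_ids) != nrow(absorbance)) {
    stop("sample_ids length must equal the number of absorbance rows")
  }
  if (anyDuplicated(sample_ids)) {
    dup <- sample_ids[duplicated(sample_ids)][1L]
    stop("duplicate sample id: '", dup, "'")
  }
  if (length(grid) > 1L) {
    d <- diff(grid)
    if (any(d == 0) || (any(d > 0) && any(d < 0))) {
      stop("wavenumber grid must be strictly monotonic")
    }
    if (d[1L] < 0) { # store ascending
      grid <- rev(grid)
      absorbance <- absorbance[, rev(seq_along(grid)), drop = FALSE]
      d <- diff(grid)
    }
    if (length(d) > 1L &&
        max(abs(d - d[1L])) > 1e-9 * abs(d[1L])) {
      stop("wavenumber grid spacing is not uniform")
    }
  }
  rownames(absorbance) <- sample_ids
  colnames(absorbance) <- format_wavenumbers(grid)
  structure(
    list(grid = grid, absorbance = absorbance,
         sample_ids = sample_ids, meta = meta),
    class = "spectra_set"
  )
}

format_wavenumbers <- function(grid) {
  vapply(grid, function(g) format(g, digits = 17, scientific = FALSE,
                                  trim = TRUE),
         character(1))
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", nrow(x$absorbance), " samples x ",
      length(x$grid), " channels, ",
      min(x$grid), "-", max(x$grid), " cm^-1 (step ",
      grid_spacing(x), ")\n", sep = "")
  invisible(x)
}

#' Grid spacing of a spectra set
#' @param s a `spectra_set`.
#' @return the (uniform) channel spacing in cm^-1.
#' @export
grid_spacing <- function(s) {
  if (length(s$grid) < 2L) return(NA_real_)
  s$grid[2L] - s$grid[1L]
}

#' Subset samples of a spectra set
#'
#' @param s a `spectra_set`.
#' @param idx integer, logical or character (sample id) index.
#' @return a `spectra_set` containing the selected samples, in `idx` order.
#' @export
subset_samples <- function(s, idx) {
  if (is.character(idx)) idx <- match(idx, s$sample_ids)
  ab <- s$absorbance[idx, , drop = FALSE]
  meta <- s$meta
  if (is.data.frame(meta)) meta <- meta[idx, , drop = FALSE]
  spectra_set(s$grid, ab, s$sample_ids[idx], meta)
}

#' Composition ground-truth table
#'
#' Per-sample percentages of each variety; each row must total 100.
#' Proportions are stored exactly (e.g. 100/3), never pre-rounded; rounding
#' to one decimal is done only for display.
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param varieties ordered character vector of variety names.
#' @param proportions numeric matrix (`n_samples x n_varieties`) of
#'   percentages in \[0, 100\]; rows must sum to 100 within 1e-6.
#' @param design optional data.frame with one row per sample describing the
#'   mixture design (columns `label`, `target`).
#' @return an object of class `composition_table`.
#' @export
composition_table <- function(sample_ids, varieties, proportions,
                              design = NULL) {
  proportions <- as.matrix(proportions)
  sample_ids <- as.character(sample_ids)
  varieties <- as.character(varieties)
  if (nrow(proportions) != length(sample_ids) ||
      ncol(proportions) != length(varieties)) {
    stop("proportions must be length(sample_ids) x length(varieties)")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: '",
         sample_ids[duplicated(sample_ids)][1L], "'")
  }
  neg <- which(proportions < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    stop("negative proportion for sample '", sample_ids[neg[1L, 1L]], "'")
  }
  sums <- rowSums(proportions)
  bad <- which(abs(sums - 100) > 1e-6)
  if (length(bad) > 0L) {
    stop("proportions for sample '", sample_ids[bad[1L]],
         "' sum to ", sums[bad[1L]], ", not 100")
  }
  if (!is.null(design) && nrow(design) != length(sample_ids)) {
    stop("design must have one row per sample")
  }
  rownames(proportions) <- sample_ids
  colnames(proportions) <- varieties
  structure(
    list(sample_ids = sample_ids, varieties = varieties,
         proportions = proportions, design = design),
    class = "composition_table"
  )
}

#' @export
print.composition_table <- function(x, ...) {
  cat("<composition_table> ", length(x$sample_ids), " samples x ",
      length(x$varieties), " varieties (",
      paste(x$varieties, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Read a wide-format spectra CSV
#'
#' Expects `sample_id,<wavenumber>,<wavenumber>,...` with one row per sample
#' (comma separator, `.` decimal, UTF-8, mandatory header). Columns are
#' reordered so the stored grid is ascending.
#'
#' @param path path to the CSV file.
#' @return a [spectra_set()].
#' @export
read_spectra_csv <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = ",", data.table = FALSE)
  if (ncol(dt) < 2L) stop("spectra CSV must have a sample id column plus ",
                          "at least one wavenumber column")
  ids <- as.character(dt[[1L]])
  heads <- names(dt)[-1L]
  grid <- suppressWarnings(as.numeric(heads))
  if (anyNA(grid)) {
    stop("non-numeric wavenumber header: '", heads[which(is.na(grid))[1L]],
         "'")
  }
  ab <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(ab) <- "double"
  spectra_set(grid, ab, ids)
}

#' Write a spectra set to CSV
#'
#' Values are written at full double precision so that
#' `read_spectra_csv(write_spectra_csv(s))` reproduces `s` bit-exactly.
#'
#' @param s a [spectra_set()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(s, path) {
  df <- data.frame(sample_id = s$sample_ids, stringsAsFactors = FALSE)
  # 17 significant digits: enough for doubles to round-trip bit-exactly
  ab <- as.data.frame(lapply(seq_along(s$grid), function(j) {
    sprintf("%.17g", s$absorbance[, j])
  }), optional = TRUE, stringsAsFactors = FALSE)
  if (nrow(ab) == 0L) ab <- ab[0L, seq_along(s$grid), drop = FALSE]
  names(ab) <- format_wavenumbers(s$grid)
  df <- cbind(df, ab)
  rownames(df) <- NULL
  data.table::fwrite(df, path, sep = ",", dec = ".", quote = FALSE)
  invisible(path)
}

#' Read a composition CSV
#'
#' Expects `sample_id,<variety>,<variety>,...` with percentages; every row
#' must sum to 100 within 1e-6 and contain no negative entries.
#'
#' @param path path to the CSV file.
#' @return a [composition_table()].
#' @export
read_composition_csv <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = ",", data.table = FALSE)
  if (ncol(dt) < 2L) stop("composition CSV must have a sample id column ",
                          "plus at least one variety column")
  ids <- as.character(dt[[1L]])
  mat <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  composition_table(ids, names(dt)[-1L], mat)
}

#' Write a composition table to CSV
#'
#' @param comp a [composition_table()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_composition_csv <- function(comp, path) {
  df <- data.frame(sample_id = comp$sample_ids, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(comp$proportions))
  rownames(df) <- NULL
  data.table::fwrite(df, path, sep = ",", dec = ".", quote = FALSE)
  invisible(path)
}

#' Restrict a spectra set to a wavenumber region
#'
#' Retains channels with `lo <= wavenumber <= hi` (inclusive on both ends,
#' matching the usual "from 650 to 2000 cm^-1" phrasing for the MID-IR
#' fingerprint region). Samples are never reordered or renamed.
#'
#' @param s a [spectra_set()].
#' @param lo,hi region bounds in cm^-1, `lo < hi`.
#' @return a `spectra_set` with only the channels inside the region.
#' @export
cut_region <- function(s, lo, hi) {
  if (lo >= hi) stop("lo must be strictly less than hi")
  keep <- s$grid >= lo & s$grid <= hi
  if (!any(keep)) stop("no channels in region [", lo, ", ", hi, "]")
  spectra_set(s$grid[keep], s$absorbance[, keep, drop = FALSE],
              s$sample_ids, s$meta)
}
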