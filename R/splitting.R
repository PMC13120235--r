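#' Duplex train/test partition
#'
#' Deterministic representative test-set selection in the original
#' (un-pre-treated) spectral data space. The pair of not-yet-assigned
#' samples with the largest Euclidean distance is assigned to the training
#' set, the next most-distant pair to the test set, the next to training,
#' and so on, until the test set holds `n_test` samples; every remaining
#' sample then joins the training set. Both sets thus span the data space,
#' and the globally most-distant pair is always in training.
#'
#' Tie rules (the procedure is otherwise silent on them): equal distances
#' prefer the lexicographically smaller index pair. When a single test slot
#' remains, the member of the current max-distance pair with the larger
#' minimum distance to the already-selected test samples is taken (lower
#' original index on ties); the other member is left for training.
#'
#' @param x numeric matrix of spectra (samples in rows) or a
#'   [spectra_set()].
#' @param n_test requested test-set size; must satisfy
#'   `1 <= n_test <= n - 2`.
#' @return an object of class `split_result`: list with sorted integer
#'   vectors `train_indices` and `test_indices` (disjoint, exhaustive).
#' @export
duplex_split <- function(x, n_test) {
  if (inherits(x, "spectra_set")) x <- x$absorbance
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4L) stop("duplex requires at least 4 samples")
  n_test <- as.integer(n_test)
  if (n_test < 1L || n_test > n - 2L) {
    stop("n_test must be between 1 and n_samples - 2")
  }
  D <- as.matrix(stats::dist(x))
  remaining <- rep(TRUE, n)
  train <- integer(0); test <- integer(0)
  to_train <- TRUE
  while (length(test) < n_test) {
    rem <- which(remaining)
    if (length(rem) < 2L) {
      stop("n_test too large: ran out of sample pairs before filling ",
           "the test set")
    }
    # max-distance pair among unassigned; ties -> smallest (i, j)
    Dsub <- D[rem, rem, drop = FALSE]
    mx <- max(Dsub)
    hits <- which(Dsub == mx, arr.ind = TRUE)
    hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    pair <- rem[hits[1L, ]]
    if (to_train) {
      train <- c(train, pair)
      remaining[pair] <- FALSE
    } else {
      need <- n_test - length(test)
      if (need >= 2L) {
        test <- c(test, pair)
        remaining[pair] <- FALSE
      } else {
        # one slot left: keep the pair member farther from the test set
        if (length(test) == 0L) {
          pick <- min(pair)
        } else {
          dmin <- vapply(pair, function(i) min(D[i, test]), numeric(1))
          pick <- if (dmin[1L] >= dmin[2L]) pair[1L] else pair[2L]
        }
        test <- c(test, pick)
        remaining[pick] <- FALSE
      }
    }
    to_train <- !to_train
  }
  train <- sort(c(train, which(remaining)))
  structure(list(train_indices = train, test_indices = sort(test)),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat("<split_result> ", length(x$train_indices), " train / ",
      length(x$test_indices), " test\n", sep = "")
  invisible(x)
}
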