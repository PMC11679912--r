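#' MAE interval scheme: classification bins and relaxed regression ranges
#'
#' The cascade discretises the slice-MAE axis into `n_classes` intervals
#' (default 4: low, medium-low, medium-high, high). Interior boundaries are
#' the empirical quartiles of the training-label distribution, which balances
#' the class sizes; the last bin is closed by a saturation bound. Each
#' regressor's training range is its classification bin widened by
#' `relaxation` HU on both sides (clamped to `[0, saturation]`) so that a
#' one-off classification error can still be recovered by the routed
#' regressor.
#'
#' @param boundaries ascending numeric vector of classification boundaries in
#'   HU, starting at 0 and ending at the saturation bound (length
#'   `n_classes + 1`).
#' @param relaxation HU half-width added to each bin for the regression
#'   ranges (default 5).
#' @param compute_ranges derive the regression ranges immediately (default
#'   `TRUE`).
#' @return A `bin_scheme` object: list with `boundaries`, `n_classes`,
#'   `saturation`, `relaxation`, and (once derived) `regression_ranges`, a
#'   tibble with columns `class`, `lo`, `hi`.
#' @export
bin_scheme <- function(boundaries, relaxation = 5, compute_ranges = TRUE) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 3L) stop("need at least 2 classes", call. = FALSE)
  if (boundaries[1] != 0) stop("first boundary must be 0", call. = FALSE)
  if (any(diff(boundaries) <= 0)) {
    stop("degenerate MAE distribution: boundaries must be strictly increasing",
         call. = FALSE)
  }
  if (!is.numeric(relaxation) || relaxation < 0) {
    stop("relaxation must be a nonnegative HU scalar", call. = FALSE)
  }
  scheme <- structure(
    list(boundaries = boundaries,
         n_classes = length(boundaries) - 1L,
         saturation = boundaries[length(boundaries)],
         relaxation = relaxation,
         regression_ranges = NULL),
    class = "bin_scheme")
  if (compute_ranges) scheme <- derive_regression_ranges(scheme)
  scheme
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat(sprintf("<bin_scheme> %d classes, saturation %g HU, relaxation +/-%g HU\n",
              x$n_classes, x$saturation, x$relaxation))
  cls <- paste(sprintf("[%g, %g)", utils::head(x$boundaries, -1),
                       utils::tail(x$boundaries, -1)), collapse = " ")
  cat("  classification:", cls, "(last bin closed)\n")
  if (!is.null(x$regression_ranges)) {
    rr <- paste(sprintf("[%g, %g]", x$regression_ranges$lo,
                        x$regression_ranges$hi), collapse = " ")
    cat("  regression:    ", rr, "\n")
  }
  invisible(x)
}

#' Derive classification bins from a training-label distribution
#'
#' Labels are saturated first, then the interior boundaries are set to the
#' `(k/n_classes)`-quantiles (linear interpolation between order statistics,
#' `stats::quantile` type 7) rounded to the nearest integer HU. Quantile
#' boundaries give each class an approximately equal share of the training
#' examples.
#'
#' @param mae_labels numeric vector of ground-truth slice MAEs in HU.
#' @param n_classes number of MAE intervals (default 4).
#' @param saturation upper bound of the high bin in HU; default `NULL` takes
#'   the maximum observed label rounded up to the nearest 10 HU.
#' @param relaxation regression relaxation in HU, stored on the scheme
#'   (default 5).
#' @return A [bin_scheme()] with regression ranges filled in.
#' @export
compute_classification_bins <- function(mae_labels, n_classes = 4,
                                        saturation = NULL, relaxation = 5) {
  mae_labels <- as.numeric(mae_labels)
  if (any(!is.finite(mae_labels)) || any(mae_labels < 0)) {
    stop("MAE labels must be finite and nonnegative", call. = FALSE)
  }
  if (length(unique(mae_labels)) < n_classes) {
    stop("degenerate MAE distribution: need at least ", n_classes,
         " distinct label values", call. = FALSE)
  }
  if (is.null(saturation)) saturation <- 10 * ceiling(max(mae_labels) / 10)
  labels <- as.numeric(saturate_mae(mae_labels, saturation))
  probs <- seq_len(n_classes - 1L) / n_classes
  q <- round(stats::quantile(labels, probs = probs, type = 7, names = FALSE))
  boundaries <- c(0, q, saturation)
  if (any(diff(boundaries) <= 0)) {
    stop("degenerate MAE distribution: rounded quantiles are not strictly increasing",
         call. = FALSE)
  }
  bin_scheme(boundaries, relaxation = relaxation)
}

#' Fill in the relaxed regression ranges of a scheme
#'
#' Range `k` is `[max(0, b_k - relaxation), min(saturation, b_{k+1} +
#' relaxation)]`, so consecutive ranges overlap by twice the relaxation
#' except at the clamped extremes.
#'
#' @param scheme a [bin_scheme()].
#' @return The scheme with `regression_ranges` filled.
#' @export
derive_regression_ranges <- function(scheme) {
  stopifnot(inherits(scheme, "bin_scheme"))
  b <- scheme$boundaries
  r <- scheme$relaxation
  k <- seq_len(scheme$n_classes)
  ranges <- tibble::tibble(
    class = k,
    lo = pmax(0, b[k] - r),
    hi = pmin(scheme$saturation, b[k + 1L] + r)
  )
  widths <- diff(b)
  if (r > min(widths)) {
    warning("relaxation (", r, " HU) exceeds the smallest bin width (",
            min(widths), " HU): regression ranges overlap heavily", call. = FALSE)
  }
  scheme$regression_ranges <- ranges
  scheme
}

#' Assign MAE values to classification bins
#'
#' Bins are half-open `[b_k, b_{k+1})` with the last bin closed at the
#' saturation bound; a value sitting exactly on an interior boundary belongs
#' to the upper bin.
#'
#' @param mae numeric vector of (saturated) MAE values in HU.
#' @param scheme a [bin_scheme()].
#' @return Integer class indices in `1..n_classes` (1 = low MAE).
#' @export
assign_class <- function(mae, scheme) {
  stopifnot(inherits(scheme, "bin_scheme"))
  if (any(!is.finite(mae)) || any(mae < 0) || any(mae > scheme$saturation)) {
    stop("MAE outside [0, saturation]; saturate labels first", call. = FALSE)
  }
  findInterval(mae, scheme$boundaries, rightmost.closed = TRUE)
}

#' Regression-range membership of an MAE value
#'
#' Because the regression ranges overlap, a slice can belong to the training
#' set of several regressors; membership uses closed intervals.
#'
#' @param mae a single MAE value in `[0, saturation]`.
#' @param scheme a [bin_scheme()] with ranges derived.
#' @return Integer vector of regressor indices (1-based) whose range contains
#'   `mae`.
#' @export
regression_membership <- function(mae, scheme) {
  stopifnot(inherits(scheme, "bin_scheme"), length(mae) == 1L)
  if (is.null(scheme$regression_ranges)) scheme <- derive_regression_ranges(scheme)
  if (!is.finite(mae) || mae < 0 || mae > scheme$saturation) {
    stop("MAE outside [0, saturation]", call. = FALSE)
  }
  rr <- scheme$regression_ranges
  rr$class[mae >= rr$lo & mae <= rr$hi]
}

#' Serialize a bin scheme to a JSON sidecar
#' @param scheme a [bin_scheme()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bin_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "bin_scheme"))
  if (is.null(scheme$regression_ranges)) scheme <- derive_regression_ranges(scheme)
  obj <- list(boundaries = scheme$boundaries, relaxation = scheme$relaxation,
              saturation = scheme$saturation,
              regression_ranges = as.data.frame(scheme$regression_ranges))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a bin scheme from its JSON sidecar
#' @param path sidecar path written by [write_bin_scheme()].
#' @return A [bin_scheme()].
#' @export
read_bin_scheme <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bin_scheme(obj$boundaries, relaxation = obj$relaxation)
}
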