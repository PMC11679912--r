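#' Per-slice mean absolute error between a GT-CT slice and an sCT slice
#'
#' The slice MAE is the pixel-to-pixel mean absolute HU difference,
#' `mean(|GT - sCT|)` over all n pixels of the axial plane. This is the
#' quality label the cascade learns to predict from the sCT alone.
#'
#' @param gt_slice,sct_slice 2D HU matrices of identical shape.
#' @return Nonnegative HU scalar.
#' @export
slice_mae <- function(gt_slice, sct_slice) {
  if (!identical(dim(gt_slice), dim(sct_slice))) {
    stop("shape mismatch between GT and sCT slice", call. = FALSE)
  }
  if (any(!is.finite(gt_slice)) || any(!is.finite(sct_slice))) {
    stop("slice contains non-finite values", call. = FALSE)
  }
  mean(abs(gt_slice - sct_slice))
}

#' Saturate an MAE value to an upper bound
#'
#' The open-ended high-MAE bin is closed by capping labels (and later,
#' predictions) at the scheme's saturation bound.
#'
#' @param mae nonnegative HU scalar or vector.
#' @param upper positive saturation bound in HU.
#' @return `pmin(mae, upper)`, with a logical attribute `saturated` marking
#'   the entries that were clipped (strictly above the bound).
#' @export
saturate_mae <- function(mae, upper) {
  if (!is.numeric(upper) || length(upper) != 1L || !is.finite(upper) || upper <= 0) {
    stop("saturation bound must be a positive scalar", call. = FALSE)
  }
  if (any(!is.finite(mae)) || any(mae < 0)) {
    stop("MAE must be finite and nonnegative", call. = FALSE)
  }
  out <- pmin(mae, upper)
  attr(out, "saturated") <- mae > upper
  out
}

#' Clamp HU values to the valid 12-bit CT range
#'
#' @param x numeric array of HU values.
#' @param lo,hi clamp bounds (default `[-1024, 3071]`).
#' @return `x` with out-of-range values clamped; warns when clamping occurs.
#' @export
clamp_hu <- function(x, lo = -1024, hi = 3071) {
  n_out <- sum(x < lo | x > hi)
  if (n_out > 0L) {
    warning(sprintf("%d voxel(s) outside [%g, %g] HU were clamped", n_out, lo, hi),
            call. = FALSE)
    x[] <- pmin(pmax(x, lo), hi)
  }
  x
}

body_fraction <- function(gt_slice, threshold = -500) {
  mean(gt_slice > threshold)
}

#' Assemble the training corpus of labeled sCT slices
#'
#' For every retained axial slice of every pair, computes the ground-truth
#' slice MAE ([slice_mae()]), optionally saturates it, and records the sCT
#' slice image with its provenance. Slices with almost no anatomy (body
#' fraction below `min_body_fraction`, where "body" means GT pixels above
#' `body_threshold` HU) are excluded: all-air slices carry near-zero MAE and
#' no information.
#'
#' @param pairs a `volume_pair` or list of them.
#' @param scheme optional [bin_scheme()]; when supplied, labels are saturated
#'   at `scheme$saturation` and class labels are attached.
#' @param saturation optional saturation bound in HU, used when no scheme is
#'   given (default `NULL`: labels are left unsaturated so a scheme can be
#'   fitted to them).
#' @param min_body_fraction minimum fraction of body pixels for a slice to be
#'   retained (default 0.02); set to 0 to keep every slice.
#' @param body_threshold HU threshold separating body from air (default -500).
#' @param mask_body if `TRUE`, the MAE is computed over body pixels only
#'   (default `FALSE`: all pixels of the slice, the conventional definition).
#' @param clamp if `TRUE` (default), HU values are clamped to `[-1024, 3071]`
#'   before the MAE with a warning when clamping occurs.
#' @return A tibble with one row per retained slice: `patient_id`, `modality`,
#'   `slice_index` (1-based), `image` (list of 2D sCT matrices), `mae_raw`,
#'   `mae_gt` (saturated when applicable), `saturated`, `body_fraction`, and
#'   `class` when a scheme is given. Rows are ordered by patient then slice.
#' @export
build_corpus <- function(pairs, scheme = NULL, saturation = NULL,
                         min_body_fraction = 0.02, body_threshold = -500,
                         mask_body = FALSE, clamp = TRUE) {
  if (inherits(pairs, "volume_pair")) pairs <- list(pairs)
  stopifnot(length(pairs) > 0L, all(vapply(pairs, inherits, TRUE, "volume_pair")))
  if (!is.null(scheme)) saturation <- scheme$saturation

  rows <- purrr::map(pairs, function(pair) {
    gt <- unclass(pair$gt)
    sct <- unclass(pair$sct)
    if (clamp) {
      gt <- clamp_hu(gt)
      sct <- clamp_hu(sct)
    }
    nz <- dim(gt)[3]
    purrr::map(seq_len(nz), function(i) {
      g <- gt[, , i, drop = TRUE]
      s <- sct[, , i, drop = TRUE]
      bf <- body_fraction(g, body_threshold)
      if (bf < min_body_fraction) return(NULL)
      mae <- if (mask_body) {
        m <- g > body_threshold
        mean(abs(g[m] - s[m]))
      } else {
        slice_mae(g, s)
      }
      tibble::tibble(patient_id = pair$patient_id, modality = pair$modality,
                     slice_index = i, image = list(s), mae_raw = mae,
                     body_fraction = bf)
    }) |> purrr::compact() |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  if (is.null(rows) || nrow(rows) == 0L) {
    stop("empty corpus: every slice was excluded by the inclusion rule",
         call. = FALSE)
  }
  if (!is.null(saturation)) {
    sat <- saturate_mae(rows$mae_raw, saturation)
    rows$mae_gt <- as.numeric(sat)
    rows$saturated <- attr(sat, "saturated")
  } else {
    rows$mae_gt <- rows$mae_raw
    rows$saturated <- FALSE
  }
  rows <- dplyr::arrange(rows, .data$patient_id, .data$slice_index)
  if (!is.null(scheme)) rows$class <- assign_class(rows$mae_gt, scheme)
  rows
}

#' Write a corpus manifest CSV
#'
#' Persists the tabular part of a corpus (everything except the pixel data)
#' with deterministic row order (patient, then slice index).
#'
#' @param corpus a corpus tibble from [build_corpus()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_corpus_manifest <- function(corpus, path) {
  keep <- setdiff(names(corpus), "image")
  man <- dplyr::arrange(corpus[keep], .data$patient_id, .data$slice_index)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}
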