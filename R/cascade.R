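#' Preprocessing specification shared by all five estimators
#'
#' Slices are resampled to the backbone's input size, windowed to a fixed HU
#' window, and mapped linearly to `[0, 1]`. The default window
#' `[-1000, 2000]` covers air through dental metal.
#'
#' @param input_size `(H, W)` in pixels (default 32x32, the tiny backbone).
#' @param window HU window `(lo, hi)` mapped to `[0, 1]` (values clipped).
#' @return A `preprocess_spec` list.
#' @export
preprocess_spec <- function(input_size = c(32L, 32L), window = c(-1000, 2000)) {
  stopifnot(length(input_size) == 2L, all(input_size >= 8L),
            length(window) == 2L, window[2] > window[1])
  structure(list(input_size = as.integer(input_size),
                 window = as.numeric(window)),
            class = "preprocess_spec")
}

# bilinear resampling on pixel-centre coordinates
resize_bilinear <- function(m, out_h, out_w) {
  h <- nrow(m); w <- ncol(m)
  if (h == out_h && w == out_w) return(m)
  ys <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  xs <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  y0 <- pmin(pmax(floor(ys), 1L), h); y1 <- pmin(y0 + 1L, h)
  x0 <- pmin(pmax(floor(xs), 1L), w); x1 <- pmin(x0 + 1L, w)
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  top <- m[y0, x0, drop = FALSE] * (1 - wy) + m[y1, x0, drop = FALSE] * wy
  bot <- m[y0, x1, drop = FALSE] * (1 - wy) + m[y1, x1, drop = FALSE] * wy
  sweep(top, 2L, 1 - wx, "*") + sweep(bot, 2L, wx, "*")
}

#' Preprocess one sCT slice for the estimators
#'
#' @param image 2D HU matrix.
#' @param spec a [preprocess_spec()].
#' @return Matrix of size `spec$input_size` with values in `[0, 1]`.
#' @export
preprocess_slice <- function(image, spec = preprocess_spec()) {
  if (any(!is.finite(image))) stop("slice contains non-finite pixels", call. = FALSE)
  x <- (image - spec$window[1]) / (spec$window[2] - spec$window[1])
  x <- pmin(pmax(x, 0), 1)
  resize_bilinear(x, spec$input_size[1], spec$input_size[2])
}

corpus_tensor <- function(corpus, pspec) {
  n <- nrow(corpus)
  x <- array(0, c(n, pspec$input_size[1], pspec$input_size[2], 1L))
  for (i in seq_len(n)) x[i, , , 1] <- preprocess_slice(corpus$image[[i]], pspec)
  x
}

#' Training configuration
#'
#' Defaults follow the clinical-scale recipe: learning rate `5e-5`, L1 and
#' L2 penalty weights both `4e-4`, 75/10/15 train/validation/test split at
#' patient level, mirroring plus random translations for augmentation.
#' [desk_train_config()] gives the settings used for the desk-scale phantom
#' experiments.
#'
#' @param learning_rate Adam learning rate.
#' @param l1_weight,l2_weight penalty weights on network weights (biases are
#'   not penalized).
#' @param max_epochs,batch_size epoch budget and mini-batch size.
#' @param split_fractions `(train, validation, test)` patient fractions,
#'   summing to 1.
#' @param k_folds folds for cross-validation workflows (default 5).
#' @param seed integer seed governing splits, initialization, shuffling and
#'   augmentation.
#' @param augment_mirror enable horizontal mirroring.
#' @param max_translation_px maximum random translation in pixels (applied
#'   to the input slice only; the scalar label is kept).
#' @param min_regression_samples minimum training-set size per regressor.
#' @param backbone `"tiny"` or `"vgg16"` (see [backbone_spec()]).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 5e-5, l1_weight = 4e-4,
                         l2_weight = 4e-4, max_epochs = 100L, batch_size = 32L,
                         split_fractions = c(0.75, 0.10, 0.15), k_folds = 5L,
                         seed = 1L, augment_mirror = TRUE,
                         max_translation_px = 8L,
                         min_regression_samples = 20L,
                         backbone = c("tiny", "vgg16")) {
  backbone <- match.arg(backbone)
  if (abs(sum(split_fractions) - 1) > 1e-8) {
    stop("split fractions must sum to 1", call. = FALSE)
  }
  structure(list(learning_rate = learning_rate, l1_weight = l1_weight,
                 l2_weight = l2_weight, max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 split_fractions = split_fractions, k_folds = as.integer(k_folds),
                 seed = as.integer(seed), augment_mirror = augment_mirror,
                 max_translation_px = as.integer(max_translation_px),
                 min_regression_samples = as.integer(min_regression_samples),
                 backbone = backbone),
            class = "train_config")
}

#' Desk-scale training configuration for phantom experiments
#'
#' Same structure as [train_config()] but tuned for the tiny backbone on
#' 32x32 phantom slices: Adam learning rate `1e-3`, 250 epochs, translations
#' of at most 2 px (about the same fraction of the field of view as 8 px on
#' a clinical grid).
#'
#' @param ... overrides passed to [train_config()].
#' @return A `train_config`.
#' @export
desk_train_config <- function(...) {
  args <- list(learning_rate = 1e-3, max_epochs = 250L, max_translation_px = 2L)
  override <- list(...)
  args[names(override)] <- override
  do.call(train_config, args)
}

#' Patient-level train/validation/test split
#'
#' Splits are always at patient level — a slice-level split would leak
#' near-identical adjacent-slice anatomy between sets.
#'
#' @param patient_ids character vector (one entry per slice is fine;
#'   duplicates collapse).
#' @param fractions `(train, val, test)` fractions summing to 1.
#' @param seed shuffle seed.
#' @return List of character vectors `train`, `val`, `test`.
#' @export
patient_split <- function(patient_ids, fractions = c(0.75, 0.10, 0.15),
                          seed = 1L) {
  ids <- unique(patient_ids)
  if (length(ids) < 3L) stop("need at least 3 patients to split", call. = FALSE)
  ids <- withr::with_seed(as.integer(seed), sample(ids))
  n <- length(ids)
  n_val <- max(1L, round(fractions[2] * n))
  n_test <- max(1L, round(fractions[3] * n))
  if (n_val + n_test >= n) stop("too few patients for the requested split", call. = FALSE)
  list(train = ids[seq_len(n - n_val - n_test)],
       val = ids[n - n_val - n_test + seq_len(n_val)],
       test = ids[n - n_test + seq_len(n_test)])
}

#' Class-distance-weighted classification accuracy
#'
#' Epoch-selection score for the classifier: misclassifications are penalized
#' in proportion to how many classes apart they are, so a one-class error is
#' preferred over a two- or three-class error (the routed regressor's relaxed
#' range can recover a near-miss, not a distant one). The score is
#' `1 - sum(|predicted - true|) / (N * (K - 1))`: 1 for perfect prediction,
#' 0 when every sample is misclassified by the maximal distance.
#'
#' @param true_classes,predicted_classes equal-length integer vectors with
#'   entries in `1..n_classes`.
#' @param n_classes number of classes.
#' @return Scalar in `[0, 1]`.
#' @export
weighted_classification_score <- function(true_classes, predicted_classes,
                                          n_classes = 4L) {
  if (length(true_classes) == 0L) stop("empty label vectors", call. = FALSE)
  if (length(true_classes) != length(predicted_classes)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  if (any(!true_classes %in% seq_len(n_classes)) ||
      any(!predicted_classes %in% seq_len(n_classes))) {
    stop("class labels must lie in 1..n_classes", call. = FALSE)
  }
  1 - sum(abs(predicted_classes - true_classes)) /
    (length(true_classes) * (n_classes - 1))
}

split_indices <- function(corpus, split) {
  list(train = which(corpus$patient_id %in% split$train),
       val = which(corpus$patient_id %in% split$val))
}

#' Train the MAE-interval classifier
#'
#' @param corpus corpus tibble from [build_corpus()] (saturated labels).
#' @param scheme a [bin_scheme()].
#' @param cfg a [train_config()].
#' @param split optional patient split (from [patient_split()]); derived from
#'   `cfg` when `NULL`.
#' @param pspec a [preprocess_spec()]; sized from the backbone when `NULL`.
#' @return An `estimator` (see [train_estimator()]).
#' @export
train_classifier <- function(corpus, scheme, cfg = train_config(),
                             split = NULL, pspec = NULL) {
  if (is.null(split)) split <- patient_split(corpus$patient_id,
                                             cfg$split_fractions, cfg$seed)
  pspec <- pspec %||% default_pspec(cfg)
  y <- assign_class(as.numeric(saturate_mae(corpus$mae_gt, scheme$saturation)),
                    scheme)
  idx <- split_indices(corpus, split)
  missing_cls <- setdiff(seq_len(scheme$n_classes), unique(y[idx$train]))
  if (length(missing_cls) > 0L) {
    stop("class(es) ", paste(missing_cls, collapse = ", "),
         " absent from the training split; enlarge or rebalance the corpus",
         call. = FALSE)
  }
  x <- corpus_tensor(corpus, pspec)
  spec <- backbone_spec(cfg$backbone, out_dim = scheme$n_classes,
                        input_size = pspec$input_size)
  train_estimator(x, y, task = "classification", spec = spec, cfg = cfg,
                  train_idx = idx$train, val_idx = idx$val,
                  seed = cfg$seed + 100L)
}

#' Train the four interval-specific regressors
#'
#' Regressor `k` sees only slices whose ground-truth MAE falls in the relaxed
#' regression range `k` (closed interval), so a slice near a quartile
#' boundary trains the regressors on both sides. Targets are mapped affinely
#' from the range to `[0, 1]` during training and inverted at inference.
#'
#' @inheritParams train_classifier
#' @return List of `estimator` objects, one per class.
#' @export
train_regressors <- function(corpus, scheme, cfg = train_config(),
                             split = NULL, pspec = NULL) {
  if (is.null(split)) split <- patient_split(corpus$patient_id,
                                             cfg$split_fractions, cfg$seed)
  pspec <- pspec %||% default_pspec(cfg)
  if (is.null(scheme$regression_ranges)) scheme <- derive_regression_ranges(scheme)
  mae <- as.numeric(saturate_mae(corpus$mae_gt, scheme$saturation))
  x <- corpus_tensor(corpus, pspec)
  idx <- split_indices(corpus, split)
  purrr::map(seq_len(scheme$n_classes), function(k) {
    rr <- scheme$regression_ranges[k, ]
    members <- which(mae >= rr$lo & mae <= rr$hi)
    tr <- intersect(members, idx$train)
    va <- intersect(members, idx$val)
    if (length(tr) < cfg$min_regression_samples) {
      stop(sprintf("regression bin %d [%g, %g] HU has only %d training samples (need %d)",
                   k, rr$lo, rr$hi, length(tr), cfg$min_regression_samples),
           call. = FALSE)
    }
    if (length(va) == 0L) {
      warning("regression bin ", k, " has no validation samples; ",
              "using training samples for epoch selection", call. = FALSE)
      va <- tr
    }
    ys <- (mae - rr$lo) / (rr$hi - rr$lo)
    spec <- backbone_spec(cfg$backbone, out_dim = 1L,
                          input_size = pspec$input_size)
    est <- train_estimator(x, ys, task = "regression", spec = spec, cfg = cfg,
                           train_idx = tr, val_idx = va,
                           seed = cfg$seed + 200L + k)
    est$range <- c(lo = rr$lo, hi = rr$hi)
    est
  })
}

default_pspec <- function(cfg) {
  if (cfg$backbone == "tiny") preprocess_spec(c(32L, 32L))
  else preprocess_spec(c(224L, 224L))
}

#' Train the full two-step cascade
#'
#' Fits the bin scheme (when not supplied), then trains the 4-way
#' MAE-interval classifier and the four interval-specific regressors — five
#' estimators in total, of which exactly two run per slice at inference.
#'
#' @param corpus corpus tibble from [build_corpus()].
#' @param scheme optional [bin_scheme()]; fitted to the corpus labels by
#'   [compute_classification_bins()] when `NULL`.
#' @param cfg a [train_config()].
#' @param pspec optional [preprocess_spec()].
#' @return A `cascade_model`: `scheme`, `classifier`, `regressors` (list of
#'   4), `preprocess`, `config`, `split`, and an inference-invocation
#'   counter.
#' @export
train_cascade <- function(corpus, scheme = NULL, cfg = train_config(),
                          pspec = NULL) {
  if (is.null(scheme)) scheme <- compute_classification_bins(corpus$mae_gt)
  if (is.null(scheme$regression_ranges)) scheme <- derive_regression_ranges(scheme)
  pspec <- pspec %||% default_pspec(cfg)
  split <- patient_split(corpus$patient_id, cfg$split_fractions, cfg$seed)
  classifier <- train_classifier(corpus, scheme, cfg, split = split, pspec = pspec)
  regressors <- train_regressors(corpus, scheme, cfg, split = split, pspec = pspec)
  structure(list(scheme = scheme, classifier = classifier,
                 regressors = regressors, preprocess = pspec, config = cfg,
                 split = split, counter = new.env(parent = emptyenv())),
            class = "cascade_model")
}

#' @export
print.cascade_model <- function(x, ...) {
  cat(sprintf("<cascade_model> %d-class cascade (%s backbone): 1 classifier + %d regressors\n",
              x$scheme$n_classes, x$config$backbone, length(x$regressors)))
  print(x$scheme)
  invisible(x)
}

invoke_estimator <- function(model, est, x) {
  n <- model$counter$n %||% 0L
  model$counter$n <- n + dim(x)[1]
  estimator_predict(est, x)
}

#' Inference invocation counter
#'
#' Counts estimator invocations (one per slice per estimator) since the
#' model was created or the counter was last reset; the cascade contract is
#' exactly 2 invocations per slice.
#'
#' @param model a `cascade_model`.
#' @return Integer count.
#' @export
cascade_invocations <- function(model) model$counter$n %||% 0L

#' @rdname cascade_invocations
#' @export
reset_invocations <- function(model) {
  model$counter$n <- 0L
  invisible(model)
}

check_trained <- function(model) {
  if (!inherits(model, "cascade_model") || is.null(model$classifier$params)) {
    stop("model is not a trained cascade", call. = FALSE)
  }
  if (length(model$regressors) != model$scheme$n_classes) {
    stop("cascade is missing regressors", call. = FALSE)
  }
}

predict_batch <- function(model, x) {
  probs <- invoke_estimator(model, model$classifier, x)
  cls <- max.col(probs, ties.method = "first")  # ties: lowest class index
  mae <- numeric(nrow(probs))
  for (k in sort(unique(cls))) {
    rows <- which(cls == k)
    est <- model$regressors[[k]]
    raw <- invoke_estimator(model, est, x[rows, , , , drop = FALSE])
    mae[rows] <- est$range["lo"] + raw * (est$range["hi"] - est$range["lo"])
  }
  tibble::tibble(class_predicted = cls,
                 mae_predicted = pmin(pmax(mae, 0), model$scheme$saturation))
}

#' Predict the MAE of a single sCT slice
#'
#' Runs the classifier, routes the slice to the arg-max class's regressor
#' (ties break toward the lowest class), and clips the regressed MAE to
#' `[0, saturation]`. Exactly two estimators are invoked.
#'
#' @param model a trained `cascade_model`.
#' @param image 2D HU matrix (an axial sCT slice).
#' @return One-row tibble: `class_predicted`, `mae_predicted`.
#' @export
predict_slice <- function(model, image) {
  check_trained(model)
  x <- array(preprocess_slice(image, model$preprocess),
             c(1L, model$preprocess$input_size, 1L))
  predict_batch(model, x)
}

#' Predict slice-wise MAE for a whole sCT volume
#'
#' @param model a trained `cascade_model`.
#' @param sct an sCT `hu_volume`.
#' @return A `pmae_prediction`: list with `records` (tibble: `slice_index`,
#'   `class_predicted`, `mae_predicted`) and `pmae` (the slice-constant
#'   overlay `hu_volume`, geometry copied from `sct`).
#' @export
predict_volume <- function(model, sct) {
  check_trained(model)
  stopifnot(inherits(sct, "hu_volume"))
  slices <- extract_axial_slices(sct)
  n <- length(slices)
  x <- array(0, c(n, model$preprocess$input_size, 1L))
  for (i in seq_len(n)) x[i, , , 1] <- preprocess_slice(slices[[i]], model$preprocess)
  rec <- predict_batch(model, x)
  rec <- tibble::tibble(slice_index = seq_len(n), rec)
  structure(list(records = rec,
                 pmae = write_pmae_volume(rec$mae_predicted, sct)),
            class = "pmae_prediction")
}

#' @export
print.pmae_prediction <- function(x, ...) {
  cat(sprintf("<pmae_prediction> %d slices, predicted MAE %.1f-%.1f HU (median %.1f)\n",
              nrow(x$records), min(x$records$mae_predicted),
              max(x$records$mae_predicted),
              stats::median(x$records$mae_predicted)))
  invisible(x)
}

#' Predict MAE for every slice of a labeled corpus
#'
#' Evaluation helper: runs the cascade on the stored sCT slices and carries
#' the ground-truth labels along, ready for [compute_deviations()].
#'
#' @param model a trained `cascade_model`.
#' @param corpus corpus tibble from [build_corpus()].
#' @return Tibble: `patient_id`, `modality`, `slice_index`, `mae_gt`,
#'   `class_predicted`, `mae_predicted`.
#' @export
predict_corpus <- function(model, corpus) {
  check_trained(model)
  x <- corpus_tensor(corpus, model$preprocess)
  rec <- predict_batch(model, x)
  tibble::tibble(corpus[c("patient_id", "modality", "slice_index", "mae_gt")],
                 rec)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-estimator summary of a trained cascade
#'
#' @param x a `cascade_model`.
#' @param ... unused.
#' @return Tibble with one row per estimator: `role`, `task`, `best_epoch`,
#'   `val_metric`, `n_params`, and the regression range where applicable.
#' @method tidy cascade_model
#' @export
tidy.cascade_model <- function(x, ...) {
  rows <- c(
    list(tibble::tibble(role = "classifier", task = "classification",
                        best_epoch = x$classifier$best_epoch,
                        val_metric = x$classifier$best_metric,
                        n_params = n_params(x$classifier),
                        range_lo = NA_real_, range_hi = NA_real_)),
    purrr::imap(x$regressors, function(est, k) {
      tibble::tibble(role = paste0("regressor_", k), task = "regression",
                     best_epoch = est$best_epoch, val_metric = est$best_metric,
                     n_params = n_params(est),
                     range_lo = est$range[["lo"]], range_hi = est$range[["hi"]])
    })
  )
  purrr::list_rbind(rows)
}

#' One-row summary of a trained cascade
#'
#' @param x a `cascade_model`.
#' @param ... unused.
#' @return One-row tibble: estimator count, class count, saturation,
#'   relaxation, backbone, seed.
#' @method glance cascade_model
#' @export
glance.cascade_model <- function(x, ...) {
  tibble::tibble(n_estimators = 1L + length(x$regressors),
                 n_classes = x$scheme$n_classes,
                 saturation = x$scheme$saturation,
                 relaxation = x$scheme$relaxation,
                 backbone = x$config$backbone,
                 seed = x$config$seed)
}

## ---- persistence ----------------------------------------------------------

params_to_list <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) NULL
    else list(W = list(dim = dim(p$W), values = as.numeric(p$W)),
              b = as.numeric(p$b))
  })
}

params_from_list <- function(lst) {
  lapply(lst, function(p) {
    if (is.null(p) || length(p) == 0L) NULL
    else list(W = matrix(p$W$values, p$W$dim[1], p$W$dim[2]), b = p$b)
  })
}

write_estimator <- function(est, path) {
  obj <- list(task = est$task, backbone = est$spec$backbone,
              input_size = est$spec$input_size, out_dim = est$spec$out_dim,
              best_epoch = est$best_epoch, best_metric = est$best_metric,
              range = if (!is.null(est$range)) as.numeric(est$range),
              params = params_to_list(est$params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

read_estimator <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  spec <- backbone_spec(obj$backbone, out_dim = obj$out_dim,
                        input_size = obj$input_size)
  est <- structure(list(task = obj$task, spec = spec,
                        params = params_from_list(obj$params),
                        best_epoch = obj$best_epoch,
                        best_metric = obj$best_metric,
                        log = NULL),
                   class = "estimator")
  if (!is.null(obj$range) && length(obj$range) == 2L) {
    est$range <- c(lo = obj$range[1], hi = obj$range[2])
  }
  est
}

#' Persist a trained cascade to a directory
#'
#' Writes the bin-scheme sidecar, preprocessing spec, resolved training
#' config, five estimator checkpoints (JSON, full precision) and the
#' per-estimator training logs.
#'
#' @param model a trained `cascade_model`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_cascade <- function(model, dir) {
  check_trained(model)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bin_scheme(model$scheme, file.path(dir, "scheme.json"))
  jsonlite::write_json(unclass(model$preprocess),
                       file.path(dir, "preprocess.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(model$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  write_estimator(model$classifier, file.path(dir, "classifier.json"))
  for (k in seq_along(model$regressors)) {
    write_estimator(model$regressors[[k]],
                    file.path(dir, sprintf("regressor_%d.json", k)))
  }
  logs <- c(list(classifier = model$classifier$log),
            stats::setNames(purrr::map(model$regressors, "log"),
                            paste0("regressor_", seq_along(model$regressors))))
  for (nm in names(logs)) {
    if (!is.null(logs[[nm]])) {
      utils::write.csv(logs[[nm]],
                       file.path(dir, sprintf("training_log_%s.csv", nm)),
                       row.names = FALSE)
    }
  }
  invisible(dir)
}

#' Load a cascade persisted by [save_cascade()]
#'
#' @param dir directory written by [save_cascade()].
#' @return A `cascade_model`.
#' @export
load_cascade <- function(dir) {
  scheme <- read_bin_scheme(file.path(dir, "scheme.json"))
  pp <- jsonlite::read_json(file.path(dir, "preprocess.json"),
                            simplifyVector = TRUE)
  pspec <- preprocess_spec(pp$input_size, pp$window)
  cfgl <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  cfg <- do.call(train_config, cfgl[names(cfgl) %in% names(formals(train_config))])
  files <- c("classifier.json",
             sprintf("regressor_%d.json", seq_len(scheme$n_classes)))
  for (f in files) {
    if (!file.exists(file.path(dir, f))) {
      stop("missing checkpoint file: ", f, call. = FALSE)
    }
  }
  structure(list(scheme = scheme,
                 classifier = read_estimator(file.path(dir, "classifier.json")),
                 regressors = purrr::map(seq_len(scheme$n_classes), function(k) {
                   read_estimator(file.path(dir, sprintf("regressor_%d.json", k)))
                 }),
                 preprocess = pspec, config = cfg, split = NULL,
                 counter = new.env(parent = emptyenv())),
            class = "cascade_model")
}
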