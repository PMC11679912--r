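#' Prediction deviation (PD) and absolute prediction deviation (APD)
#'
#' PD is the signed difference `MAE_GT - MAE_predicted` per slice; APD is its
#' absolute value. Both the ground-truth and the predicted MAE are saturated
#' to the scheme's upper bound before the deviations are taken, so the
#' open-ended high bin cannot inflate them.
#'
#' @param records tibble with columns `mae_gt` and `mae_predicted` (e.g. from
#'   [predict_corpus()]).
#' @param scheme the governing [bin_scheme()] (provides the saturation
#'   bound).
#' @return The records tibble with columns `pd` and `apd` added.
#' @export
compute_deviations <- function(records, scheme) {
  stopifnot(inherits(scheme, "bin_scheme"))
  if (!all(c("mae_gt", "mae_predicted") %in% names(records))) {
    stop("records must carry mae_gt and mae_predicted", call. = FALSE)
  }
  if (any(is.na(records$mae_gt))) {
    stop("missing ground-truth MAE in records", call. = FALSE)
  }
  gt <- as.numeric(saturate_mae(records$mae_gt, scheme$saturation))
  pred <- as.numeric(saturate_mae(records$mae_predicted, scheme$saturation))
  dplyr::mutate(records, pd = gt - pred, apd = abs(gt - pred))
}

eval_percentiles <- c(5, 25, 50, 75, 95)

summary_row <- function(v, prefix) {
  q <- stats::quantile(v, probs = eval_percentiles / 100, type = 7, names = FALSE)
  out <- tibble::tibble(q[1], q[2], q[3], q[4], q[5])
  names(out) <- paste0(prefix, "_p", eval_percentiles)
  names(out)[3] <- paste0(prefix, "_median")
  out
}

#' Percentile summary of PD and APD
#'
#' Reports, per group, the 5th/25th/median/75th/95th percentiles of both the
#' signed and the absolute prediction deviation, plus slice and patient
#' counts. Percentiles use linear interpolation and the result does not
#' depend on record order.
#'
#' @param records tibble with `pd`/`apd` (from [compute_deviations()]).
#' @param ... optional grouping columns (tidy-select), e.g. `pipeline,
#'   modality`.
#' @return A tibble with one row per group.
#' @export
summarize_deviations <- function(records, ...) {
  if (nrow(records) == 0L) stop("no records to summarize", call. = FALSE)
  stopifnot(all(c("pd", "apd") %in% names(records)))
  grouped <- dplyr::group_by(records, ...)
  dplyr::summarise(
    grouped,
    n_slices = dplyr::n(),
    n_patients = dplyr::n_distinct(.data$patient_id),
    summary_row(.data$pd, "pd"),
    summary_row(.data$apd, "apd"),
    .groups = "drop"
  )
}

#' Compare two pipelines' prediction accuracy with the rank-sum test
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test on the per-slice absolute
#' prediction deviations of two pipelines run over the same test data. Exact
#' enumeration is used for small untied samples, the normal approximation
#' with tie correction otherwise.
#'
#' @param apd_a,apd_b numeric vectors of per-slice APD (or any per-slice
#'   accuracy measure) from the two pipelines.
#' @param exact force (`TRUE`) or suppress (`FALSE`) exact enumeration;
#'   `NULL` (default) lets `stats::wilcox.test` decide.
#' @return One-row tibble: `statistic` (rank-sum W), `p_value`, `method`,
#'   `n_a`, `n_b`.
#' @export
compare_pipelines <- function(apd_a, apd_b, exact = NULL) {
  if (length(apd_a) == 0L || length(apd_b) == 0L) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  if (length(unique(c(apd_a, apd_b))) == 1L) {
    warning("all pooled values identical; no rank information", call. = FALSE)
    return(tibble::tibble(statistic = length(apd_a) * length(apd_b) / 2,
                          p_value = 1, method = "degenerate",
                          n_a = length(apd_a), n_b = length(apd_b)))
  }
  ht <- suppressWarnings(stats::wilcox.test(apd_a, apd_b, exact = exact,
                                            alternative = "two.sided"))
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 method = ht$method, n_a = length(apd_a), n_b = length(apd_b))
}

#' Run the four-experiment evaluation matrix
#'
#' Executes exactly the four experiments of the study design — the
#' CBCT-trained pipeline on CBCT-derived sCTs, the MR-trained pipeline on
#' MR-derived sCTs, and the mixed-trained pipeline on each — and the two
#' single-modality-versus-mixed comparisons (rank-sum on per-slice APD).
#' Combinations outside this matrix (e.g. the CBCT pipeline on MR data) are
#' rejected.
#'
#' @param pipelines named list of trained `cascade_model`s: `cbct`, `mr`,
#'   `mixed`.
#' @param test_corpora named list of labeled test corpora (tibbles from
#'   [build_corpus()]): `cbct`, `mr`.
#' @param experiments experiment labels to run; must be a subset of the
#'   four-experiment matrix (default: all four).
#' @return An `sctqc_eval` object: `records` (all per-slice records with
#'   `pipeline`/`test_set` labels), `summaries` (percentile tables, one row
#'   per experiment), `comparisons` (two rank-sum rows).
#' @export
run_experiment_matrix <- function(pipelines, test_corpora,
                                  experiments = c("cbct->cbct", "mr->mr",
                                                  "mixed->cbct", "mixed->mr")) {
  allowed <- c("cbct->cbct", "mr->mr", "mixed->cbct", "mixed->mr")
  bad <- setdiff(experiments, allowed)
  if (length(bad) > 0L) {
    stop("experiment(s) outside the evaluation matrix: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  stopifnot(all(c("cbct", "mr", "mixed") %in% names(pipelines)),
            all(c("cbct", "mr") %in% names(test_corpora)))
  records <- purrr::map(experiments, function(ex) {
    parts <- strsplit(ex, "->", fixed = TRUE)[[1]]
    model <- pipelines[[parts[1]]]
    corpus <- test_corpora[[parts[2]]]
    rec <- predict_corpus(model, corpus)
    rec <- compute_deviations(rec, model$scheme)
    dplyr::mutate(rec, pipeline = parts[1], test_set = parts[2],
                  experiment = ex, .before = 1L)
  }) |> purrr::list_rbind()

  summaries <- summarize_deviations(records, .data$experiment, .data$pipeline,
                                    .data$test_set)

  comp <- purrr::map(c("cbct", "mr"), function(m) {
    single <- dplyr::filter(records, .data$experiment == paste0(m, "->", m))
    mixed <- dplyr::filter(records, .data$experiment == paste0("mixed->", m))
    if (nrow(single) == 0L || nrow(mixed) == 0L) return(NULL)
    dplyr::mutate(compare_pipelines(single$apd, mixed$apd),
                  test_set = m, contrast = paste0(m, " vs mixed"), .before = 1L)
  }) |> purrr::compact() |> purrr::list_rbind()

  structure(list(records = records, summaries = summaries, comparisons = comp),
            class = "sctqc_eval")
}

#' @export
print.sctqc_eval <- function(x, ...) {
  cat("<sctqc_eval>", dplyr::n_distinct(x$records$experiment),
      "experiment(s),", nrow(x$records), "slice records\n")
  med <- dplyr::select(x$summaries, "experiment", "apd_median", "pd_median")
  print(as.data.frame(med), row.names = FALSE)
  if (!is.null(x$comparisons) && nrow(x$comparisons) > 0L) {
    cat("comparisons (rank-sum on APD):\n")
    print(as.data.frame(dplyr::select(x$comparisons, "contrast", "p_value")),
          row.names = FALSE)
  }
  invisible(x)
}

#' @method tidy sctqc_eval
#' @export
tidy.sctqc_eval <- function(x, ...) x$summaries

#' @method glance sctqc_eval
#' @export
glance.sctqc_eval <- function(x, ...) {
  tibble::tibble(n_experiments = dplyr::n_distinct(x$records$experiment),
                 n_slices = nrow(x$records),
                 n_comparisons = if (is.null(x$comparisons)) 0L else nrow(x$comparisons))
}

#' Write an evaluation report directory
#'
#' Emits `summary_pd.csv`, `summary_apd.csv`, `comparisons.csv` (numbers in
#' HU, 2 decimals) and PD/APD distribution plots.
#'
#' @param eval_result an `sctqc_eval` from [run_experiment_matrix()].
#' @param dir output directory.
#' @param plots write PNG box plots (default `TRUE`).
#' @return `dir`, invisibly.
#' @export
write_evaluation_report <- function(eval_result, dir, plots = TRUE) {
  stopifnot(inherits(eval_result, "sctqc_eval"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- eval_result$summaries
  fmt <- function(df) {
    num <- vapply(df, is.numeric, TRUE) & !names(df) %in% c("n_slices", "n_patients")
    df[num] <- lapply(df[num], function(v) sprintf("%.2f", v))
    df
  }
  base_cols <- intersect(c("experiment", "pipeline", "test_set", "n_slices",
                           "n_patients"), names(s))
  utils::write.csv(fmt(s[c(base_cols, grep("^pd_", names(s), value = TRUE))]),
                   file.path(dir, "summary_pd.csv"), row.names = FALSE)
  utils::write.csv(fmt(s[c(base_cols, grep("^apd_", names(s), value = TRUE))]),
                   file.path(dir, "summary_apd.csv"), row.names = FALSE)
  if (!is.null(eval_result$comparisons)) {
    utils::write.csv(eval_result$comparisons, file.path(dir, "comparisons.csv"),
                     row.names = FALSE)
  }
  if (plots) {
    p <- autoplot.sctqc_eval(eval_result)
    ggplot2::ggsave(file.path(dir, "deviations.png"), p,
                    width = 8, height = 4, dpi = 150)
  }
  invisible(dir)
}
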