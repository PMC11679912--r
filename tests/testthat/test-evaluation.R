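test_that("PD/APD follow the saturate-then-subtract rule", {
  sch <- bin_scheme(c(0, 25, 50, 75, 100))
  rec <- tibble::tibble(patient_id = "a", mae_gt = c(50, 120, 30),
                        mae_predicted = c(44, 95, 30))
  out <- compute_deviations(rec, sch)
  expect_equal(out$pd, c(6, 5, 0))   # 120 saturates to 100 before subtracting
  expect_equal(out$apd, c(6, 5, 0))
  expect_true(all(out$apd == abs(out$pd)))
  expect_error(compute_deviations(tibble::tibble(mae_gt = 1), sch), "mae_predicted")
  expect_error(compute_deviations(
    tibble::tibble(mae_gt = NA_real_, mae_predicted = 1), sch), "missing")
})

test_that("percentile summaries match a sort-based oracle and ignore order", {
  withr::with_seed(8, {
    rec <- tibble::tibble(patient_id = sample(letters[1:5], 1000, TRUE),
                          pd = rnorm(1000), apd = abs(rnorm(1000)))
  })
  s <- summarize_deviations(rec)
  expect_equal(s$pd_median, median(rec$pd))
  # sort-based oracle for the interpolated percentile
  oracle_q <- function(v, p) {
    v <- sort(v); h <- (length(v) - 1) * p + 1
    lo <- floor(h); v[lo] + (h - lo) * (v[min(lo + 1, length(v))] - v[lo])
  }
  expect_equal(s$apd_p5, oracle_q(rec$apd, 0.05))
  expect_equal(s$pd_p95, oracle_q(rec$pd, 0.95))
  expect_true(all(diff(unlist(s[paste0("apd_", c("p5", "p25", "median",
                                                 "p75", "p95"))])) >= 0))
  shuffled <- rec[withr::with_seed(1, sample(nrow(rec))), ]
  expect_equal(summarize_deviations(shuffled), s)

  simple <- tibble::tibble(patient_id = "x", pd = c(-2, -1, 0, 1, 2),
                           apd = abs(c(-2, -1, 0, 1, 2)))
  ss <- summarize_deviations(simple)
  expect_equal(ss$pd_median, 0)
  expect_equal(ss$apd_median, 1)
})

test_that("rank-sum comparison is exact for tiny samples", {
  res <- compare_pipelines(c(1, 2), c(3, 4))
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  expect_warning(same <- compare_pipelines(rep(2, 5), rep(2, 5)), "identical")
  expect_equal(same$p_value, 1)
  expect_equal(same$statistic, 12.5)  # mn/2, the null centre
})

test_that("normal approximation agrees with exact enumeration at n = 8", {
  withr::with_seed(19, {
    a <- round(rnorm(8, 5, 2), 3)
    b <- round(rnorm(8, 6, 2), 3)
  })
  # enumeration oracle: all C(16, 8) allocations of pooled ranks
  pooled <- c(a, b)
  r <- rank(pooled)
  combs <- utils::combn(16, 8)
  w_obs <- sum(r[1:8]) - 8 * 9 / 2
  w_all <- colSums(matrix(r[combs], nrow = 8)) - 8 * 9 / 2
  p_exact <- mean(pmin(w_all, 64 - w_all) <= min(w_obs, 64 - w_obs))
  res_exact <- compare_pipelines(a, b, exact = TRUE)
  expect_equal(res_exact$p_value, p_exact, tolerance = 1e-9)
  res_approx <- compare_pipelines(a, b, exact = FALSE)
  expect_lt(abs(res_approx$p_value - p_exact), 0.02)
})

test_that("the experiment matrix is structurally complete and closed", {
  model <- mini_model()
  corp <- mini_corpus()
  pipelines <- list(cbct = model, mr = model, mixed = model)
  test_corpora <- list(cbct = corp, mr = corp)
  res <- run_experiment_matrix(pipelines, test_corpora)
  expect_s3_class(res, "sctqc_eval")
  expect_equal(nrow(res$summaries), 4L)
  expect_setequal(res$summaries$experiment,
                  c("cbct->cbct", "mr->mr", "mixed->cbct", "mixed->mr"))
  expect_equal(nrow(res$comparisons), 2L)
  expect_true(all(res$comparisons$p_value >= 0 & res$comparisons$p_value <= 1))
  expect_error(run_experiment_matrix(pipelines, test_corpora,
                                     experiments = "cbct->mr"),
               "outside the evaluation matrix")
  # report writing
  dir <- withr::local_tempdir()
  write_evaluation_report(res, dir, plots = FALSE)
  expect_true(all(file.exists(file.path(dir, c("summary_pd.csv",
                                               "summary_apd.csv",
                                               "comparisons.csv")))))
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(glance(res)$n_comparisons, 2L)
})
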