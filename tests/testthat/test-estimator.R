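# a compact architecture exercising every layer type, for gradient checks
check_spec <- function(out_dim) {
  structure(list(backbone = "check", layers = list(
    list(type = "stem"),
    list(type = "conv", k = 3L, n_in = 2L, n_out = 3L),
    list(type = "relu"),
    list(type = "maxpool"),
    list(type = "conv", k = 1L, n_in = 3L, n_out = 4L),
    list(type = "relu"),
    list(type = "gap"),
    list(type = "dense", n_in = 4L, n_out = out_dim)
  ), input_size = c(8L, 8L), out_dim = as.integer(out_dim)),
  class = "net_spec")
}

numeric_grad_worst <- function(task, spec, params, x, y, n_probe = 6) {
  fw <- sctqc:::net_forward(spec, params, x, keep_cache = TRUE)
  lg <- sctqc:::loss_grad(task, fw$out, y)
  grads <- sctqc:::net_backward(spec, params, fw$caches, lg$dout)
  loss_at <- function(p) sctqc:::loss_grad(task, sctqc:::net_forward(spec, p, x)$out, y)$loss
  eps <- 1e-6
  worst <- 0
  for (li in seq_along(params)) {
    if (is.null(params[[li]])) next
    for (nm in c("W", "b")) {
      arr <- params[[li]][[nm]]
      for (j in sample(seq_along(arr), min(n_probe, length(arr)))) {
        up <- params; up[[li]][[nm]][j] <- arr[j] + eps
        dn <- params; dn[[li]][[nm]][j] <- arr[j] - eps
        g_num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
        worst <- max(worst, abs(g_num - grads[[li]][[nm]][j]) /
                       max(1e-4, abs(g_num)))
      }
    }
  }
  worst
}

test_that("backpropagation matches finite differences through every layer", {
  withr::with_seed(3, {
    spec_c <- check_spec(3L)
    params <- sctqc:::init_params(spec_c, seed = 3)
    x <- array(runif(5 * 8 * 8), c(5, 8, 8, 1))
    expect_lt(numeric_grad_worst("classification", spec_c, params, x,
                                 sample(1:3, 5, TRUE)), 1e-4)
    spec_r <- check_spec(1L)
    params_r <- sctqc:::init_params(spec_r, seed = 4)
    expect_lt(numeric_grad_worst("regression", spec_r, params_r, x, runif(5)),
              1e-4)
  })
})

test_that("classification head emits proper probabilities", {
  spec <- backbone_spec("tiny", out_dim = 4)
  params <- sctqc:::init_params(spec, seed = 9)
  x <- withr::with_seed(9, array(runif(3 * 32 * 32), c(3, 32, 32, 1)))
  est <- structure(list(task = "classification", spec = spec, params = params),
                   class = "estimator")
  p <- estimator_predict(est, x)
  expect_equal(dim(p), c(3L, 4L))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 3))
})

test_that("vgg16 spec builds the 13-conv + 3-dense stack", {
  spec <- backbone_spec("vgg16", out_dim = 4, input_size = c(32, 32))
  types <- vapply(spec$layers, `[[`, "", "type")
  expect_equal(sum(types == "conv"), 13L)
  expect_equal(sum(types == "dense"), 3L)
  expect_equal(sum(types == "maxpool"), 5L)
  expect_error(backbone_spec("vgg16", 4, input_size = c(50, 50)), "divisible")
})

test_that("training is deterministic under a fixed seed and logs epochs", {
  withr::with_seed(5, {
    n <- 24
    x <- array(runif(n * 32 * 32), c(n, 32, 32, 1))
    y <- runif(n)
  })
  spec <- backbone_spec("tiny", out_dim = 1)
  cfg <- mini_cfg(epochs = 5)
  run <- function() train_estimator(x, y, "regression", spec, cfg,
                                    train_idx = 1:18, val_idx = 19:24,
                                    seed = 42)
  a <- run(); b <- run()
  expect_identical(a$params, b$params)
  expect_identical(a$log, b$log)
  expect_equal(nrow(a$log), 5L)
  # best-epoch contract: the kept checkpoint attains the optimal logged metric
  expect_equal(a$best_metric, min(a$log$val_metric))
  expect_equal(a$log$val_metric[a$best_epoch], a$best_metric)
})

test_that("L1+L2 regularization shrinks weight norms", {
  withr::with_seed(6, {
    n <- 30
    x <- array(runif(n * 32 * 32), c(n, 32, 32, 1))
    y <- runif(n)
  })
  spec <- backbone_spec("tiny", out_dim = 1)
  norm_of <- function(est) {
    sqrt(sum(unlist(lapply(est$params, function(p) if (is.null(p)) 0 else sum(p$W^2)))))
  }
  base <- list(max_epochs = 40, augment_mirror = FALSE, max_translation_px = 0L,
               min_regression_samples = 4L, learning_rate = 1e-3)
  cfg_plain <- do.call(train_config, c(base, list(l1_weight = 0, l2_weight = 0)))
  cfg_reg <- do.call(train_config, c(base, list(l1_weight = 4e-3, l2_weight = 4e-3)))
  e_plain <- train_estimator(x, y, "regression", spec, cfg_plain,
                             train_idx = 1:24, val_idx = 25:30, seed = 8)
  e_reg <- train_estimator(x, y, "regression", spec, cfg_reg,
                           train_idx = 1:24, val_idx = 25:30, seed = 8)
  expect_false(isTRUE(all.equal(norm_of(e_plain), norm_of(e_reg))))
  expect_lt(norm_of(e_reg), norm_of(e_plain))
})

test_that("augmentation preserves tensor shape and fills with air", {
  x <- array(1, c(4, 8, 8, 1))
  withr::with_seed(2, {
    out <- sctqc:::augment_batch(x, mirror = TRUE, max_translation = 3L)
  })
  expect_identical(dim(out), dim(x))
  expect_true(all(out %in% c(0, 1)))      # shifted-in pixels are air (0)
  expect_true(any(out == 0))              # some translation happened
})
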