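## Compact neural-network trainer used by both cascade steps.
##
## Tensors are base-R arrays [B, H, W, C] (batch fastest-varying), so every
## layer reduces to matrix algebra that BLAS handles well at desk scale.
## Supported layers: a fixed two-channel stem (intensity + local roughness),
## k x k "same" convolution, ReLU, 2x2 max pooling, global average pooling,
## flatten, dense. Losses: softmax cross-entropy (classification) and MSE
## (regression), both with optional L1+L2 penalties on weights (not biases).
## Optimizer: Adam. All randomness is seeded by the caller.

as_batch_matrix <- function(x, cols) {
  dim(x) <- c(length(x) / cols, cols)
  x
}

# local roughness: mean |difference| to the 4-neighbourhood, replicate padding
roughness_channel <- function(x) {
  d <- dim(x)  # [B,H,W]
  h <- d[2]; w <- d[3]
  up    <- x[, c(1, seq_len(h - 1)), , drop = FALSE]
  down  <- x[, c(seq_len(h - 1) + 1, h), , drop = FALSE]
  left  <- x[, , c(1, seq_len(w - 1)), drop = FALSE]
  right <- x[, , c(seq_len(w - 1) + 1, w), drop = FALSE]
  (abs(x - up) + abs(x - down) + abs(x - left) + abs(x - right)) / 4
}

stem_forward <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L, d[4] == 1L)
  v <- array(0, c(d[1], d[2], d[3], 2L))
  v[, , , 1] <- x[, , , 1]
  v[, , , 2] <- roughness_channel(array(x, d[1:3]))
  v
}

pad_hw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + 2L * p, d[3] + 2L * p, d[4]))
  out[, p + seq_len(d[2]), p + seq_len(d[3]), ] <- x
  out
}

im2col <- function(xp, h, w, k) {
  d <- dim(xp)  # padded [B, h+2p, w+2p, C]
  b <- d[1]; cc <- d[4]
  cols <- matrix(0, b * h * w, k * k * cc)
  blk <- 1L
  for (dx in seq_len(k)) {
    for (dy in seq_len(k)) {
      sl <- xp[, dy + seq_len(h) - 1L, dx + seq_len(w) - 1L, , drop = FALSE]
      cols[, (blk - 1L) * cc + seq_len(cc)] <- as_batch_matrix(sl, cc)
      blk <- blk + 1L
    }
  }
  cols
}

col2im <- function(dcols, b, h, w, cc, k) {
  p <- (k - 1L) %/% 2L
  dxp <- array(0, c(b, h + 2L * p, w + 2L * p, cc))
  blk <- 1L
  for (dx in seq_len(k)) {
    for (dy in seq_len(k)) {
      piece <- array(dcols[, (blk - 1L) * cc + seq_len(cc)], c(b, h, w, cc))
      dxp[, dy + seq_len(h) - 1L, dx + seq_len(w) - 1L, ] <-
        dxp[, dy + seq_len(h) - 1L, dx + seq_len(w) - 1L, , drop = FALSE] + piece
      blk <- blk + 1L
    }
  }
  dxp[, p + seq_len(h), p + seq_len(w), , drop = FALSE]
}

conv_forward <- function(x, par, k) {
  d <- dim(x)
  # 1x1 convolution is a pointwise dense map: no im2col needed
  cols <- if (k == 1L) as_batch_matrix(x, d[4])
          else im2col(pad_hw(x, (k - 1L) %/% 2L), d[2], d[3], k)
  y <- cols %*% par$W
  y <- y + rep(par$b, each = nrow(y))
  list(out = array(y, c(d[1], d[2], d[3], ncol(par$W))),
       cache = list(cols = cols, in_dim = d))
}

conv_backward <- function(dy, par, cache, k) {
  d <- cache$in_dim
  dmat <- as_batch_matrix(dy, ncol(par$W))
  dW <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dx <- if (k == 1L) array(dmat %*% t(par$W), d)
        else col2im(dmat %*% t(par$W), d[1], d[2], d[3], d[4], k)
  list(dx = dx, grad = list(W = dW, b = db))
}

maxpool_forward <- function(x) {
  d <- dim(x)
  stopifnot(d[2] %% 2L == 0L, d[3] %% 2L == 0L)
  io <- seq(1L, d[2], 2L); jo <- seq(1L, d[3], 2L)
  cand <- array(0, c(d[1] * (d[2] / 2) * (d[3] / 2) * d[4], 4L))
  cand[, 1] <- x[, io, jo, , drop = FALSE]
  cand[, 2] <- x[, io + 1L, jo, , drop = FALSE]
  cand[, 3] <- x[, io, jo + 1L, , drop = FALSE]
  cand[, 4] <- x[, io + 1L, jo + 1L, , drop = FALSE]
  amax <- max.col(cand, ties.method = "first")
  y <- cand[cbind(seq_len(nrow(cand)), amax)]
  list(out = array(y, c(d[1], d[2] / 2, d[3] / 2, d[4])),
       cache = list(amax = amax, in_dim = d))
}

maxpool_backward <- function(dy, cache) {
  d <- cache$in_dim
  io <- seq(1L, d[2], 2L); jo <- seq(1L, d[3], 2L)
  parts <- matrix(0, length(cache$amax), 4L)
  parts[cbind(seq_along(cache$amax), cache$amax)] <- as.numeric(dy)
  dx <- array(0, d)
  dx[, io, jo, ] <- array(parts[, 1], c(d[1], d[2] / 2, d[3] / 2, d[4]))
  dx[, io + 1L, jo, ] <- array(parts[, 2], c(d[1], d[2] / 2, d[3] / 2, d[4]))
  dx[, io, jo + 1L, ] <- array(parts[, 3], c(d[1], d[2] / 2, d[3] / 2, d[4]))
  dx[, io + 1L, jo + 1L, ] <- array(parts[, 4], c(d[1], d[2] / 2, d[3] / 2, d[4]))
  dx
}

#' Backbone architecture specification
#'
#' `"tiny"` is the desk-scale backbone: a fixed two-channel stem (windowed
#' intensity plus local roughness), three 1x1-convolution blocks of 16
#' feature maps, global average pooling, and a small dense head. Pointwise
#' features pooled over the plane match the structure of the target (the
#' slice MAE is itself a spatial mean of per-pixel deviations) and make the
#' estimator translation invariant. `"vgg16"` is the clinical-scale
#' configuration: 13 3x3 convolutional layers in 5 blocks with 2x2 max
#' pooling, then 3 fully connected layers; it is defined in the same engine
#' but is far too heavy to train in this package's tests.
#'
#' @param backbone `"tiny"` or `"vgg16"`.
#' @param out_dim output dimension (number of classes, or 1 for regression).
#' @param input_size `(H, W)` in pixels; default 32x32 for tiny, 224x224 for
#'   vgg16 (must be divisible by 32).
#' @return A `net_spec` object (list of layer descriptors).
#' @export
backbone_spec <- function(backbone = c("tiny", "vgg16"), out_dim,
                          input_size = NULL) {
  backbone <- match.arg(backbone)
  if (backbone == "tiny") {
    input_size <- input_size %||% c(32L, 32L)
    layers <- list(
      list(type = "stem"),
      list(type = "conv", k = 1L, n_in = 2L, n_out = 16L),
      list(type = "relu"),
      list(type = "conv", k = 1L, n_in = 16L, n_out = 16L),
      list(type = "relu"),
      list(type = "conv", k = 1L, n_in = 16L, n_out = 16L),
      list(type = "relu"),
      list(type = "gap"),
      list(type = "dense", n_in = 16L, n_out = 16L),
      list(type = "relu"),
      list(type = "dense", n_in = 16L, n_out = as.integer(out_dim))
    )
  } else {
    input_size <- input_size %||% c(224L, 224L)
    if (any(input_size %% 32L != 0L)) {
      stop("vgg16 input size must be divisible by 32", call. = FALSE)
    }
    widths <- list(c(64, 64), c(128, 128), c(256, 256, 256),
                   c(512, 512, 512), c(512, 512, 512))
    layers <- list()
    n_in <- 1L
    for (blk in widths) {
      for (n_out in blk) {
        layers <- c(layers, list(list(type = "conv", k = 3L, n_in = n_in,
                                      n_out = as.integer(n_out)),
                                 list(type = "relu")))
        n_in <- as.integer(n_out)
      }
      layers <- c(layers, list(list(type = "maxpool")))
    }
    flat <- as.integer(512 * prod(input_size / 32L))
    layers <- c(layers, list(
      list(type = "flatten", n_out = flat),
      list(type = "dense", n_in = flat, n_out = 4096L),
      list(type = "relu"),
      list(type = "dense", n_in = 4096L, n_out = 4096L),
      list(type = "relu"),
      list(type = "dense", n_in = 4096L, n_out = as.integer(out_dim))
    ))
  }
  structure(list(backbone = backbone, layers = layers,
                 input_size = as.integer(input_size),
                 out_dim = as.integer(out_dim)),
            class = "net_spec")
}

#' Initialize network parameters (He initialization, seeded)
#' @param spec a [backbone_spec()] or bare `net_spec`.
#' @param seed integer seed.
#' @return List of per-layer parameter lists (`NULL` for parameter-free
#'   layers).
#' @export
init_params <- function(spec, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    lapply(spec$layers, function(ly) {
      if (ly$type == "conv") {
        fan_in <- ly$k^2 * ly$n_in
        list(W = matrix(stats::rnorm(fan_in * ly$n_out, sd = sqrt(2 / fan_in)),
                        fan_in, ly$n_out),
             b = numeric(ly$n_out))
      } else if (ly$type == "dense") {
        list(W = matrix(stats::rnorm(ly$n_in * ly$n_out, sd = sqrt(2 / ly$n_in)),
                        ly$n_in, ly$n_out),
             b = numeric(ly$n_out))
      } else NULL
    })
  })
}

net_forward <- function(spec, params, x, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(spec$layers)) else NULL
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (ly$type == "stem") {
      if (keep_cache) caches[[i]] <- dim(x)
      x <- stem_forward(x)
    } else if (ly$type == "conv") {
      r <- conv_forward(x, params[[i]], ly$k)
      if (keep_cache) caches[[i]] <- r$cache
      x <- r$out
    } else if (ly$type == "relu") {
      if (keep_cache) caches[[i]] <- x > 0
      x <- x * (x > 0)
    } else if (ly$type == "maxpool") {
      r <- maxpool_forward(x)
      if (keep_cache) caches[[i]] <- r$cache
      x <- r$out
    } else if (ly$type == "gap") {
      d <- dim(x)
      if (keep_cache) caches[[i]] <- d
      m <- array(x, c(d[1], d[2] * d[3], d[4]))
      x <- vapply(seq_len(d[4]),
                  function(cc) rowMeans(matrix(m[, , cc], d[1], d[2] * d[3])),
                  numeric(d[1]))
      dim(x) <- c(d[1], d[4])
    } else if (ly$type == "flatten") {
      if (keep_cache) caches[[i]] <- dim(x)
      x <- as_batch_matrix(x, prod(dim(x)[-1]))
    } else if (ly$type == "dense") {
      if (keep_cache) caches[[i]] <- x
      x <- x %*% params[[i]]$W
      x <- x + rep(params[[i]]$b, each = nrow(x))
    } else stop("unknown layer type: ", ly$type)
  }
  list(out = x, caches = caches)
}

net_backward <- function(spec, params, caches, dout) {
  grads <- vector("list", length(spec$layers))
  dy <- dout
  for (i in rev(seq_along(spec$layers))) {
    ly <- spec$layers[[i]]
    if (ly$type == "stem") {
      dy <- NULL  # input gradient not needed
    } else if (ly$type == "conv") {
      r <- conv_backward(dy, params[[i]], caches[[i]], ly$k)
      grads[[i]] <- r$grad
      dy <- r$dx
    } else if (ly$type == "relu") {
      dy <- dy * caches[[i]]
    } else if (ly$type == "maxpool") {
      dy <- maxpool_backward(dy, caches[[i]])
    } else if (ly$type == "gap") {
      d <- caches[[i]]
      s <- matrix(dy, d[1], d[4]) / (d[2] * d[3])
      # spread each (batch, channel) gradient uniformly over the plane
      dy <- array(vapply(seq_len(d[4]),
                         function(cc) rep(s[, cc], d[2] * d[3]),
                         numeric(d[1] * d[2] * d[3])),
                  d)
    } else if (ly$type == "flatten") {
      dy <- array(dy, caches[[i]])
    } else if (ly$type == "dense") {
      xin <- caches[[i]]
      grads[[i]] <- list(W = crossprod(xin, dy), b = colSums(dy))
      dy <- dy %*% t(params[[i]]$W)
    }
  }
  grads
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# loss + dlogits for one batch
loss_grad <- function(task, out, y) {
  n <- nrow(out)
  if (task == "classification") {
    p <- softmax_rows(out)
    idx <- cbind(seq_len(n), y)
    list(loss = -mean(log(pmax(p[idx], 1e-12))),
         dout = { g <- p; g[idx] <- g[idx] - 1; g / n })
  } else {
    r <- out[, 1] - y
    list(loss = mean(r^2), dout = matrix(2 * r / n, n, 1))
  }
}

penalty_value <- function(params, l1, l2) {
  s <- 0
  for (p in params) if (!is.null(p)) s <- s + l1 * sum(abs(p$W)) + l2 * sum(p$W^2)
  s
}

add_penalty_grads <- function(grads, params, l1, l2) {
  for (i in seq_along(params)) {
    if (!is.null(params[[i]])) {
      grads[[i]]$W <- grads[[i]]$W + l1 * sign(params[[i]]$W) +
        2 * l2 * params[[i]]$W
    }
  }
  grads
}

adam_init <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) NULL else list(mW = p$W * 0, vW = p$W * 0,
                                   mb = p$b * 0, vb = p$b * 0)
  })
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  for (i in seq_along(params)) {
    if (is.null(params[[i]])) next
    st <- state[[i]]
    st$mW <- beta1 * st$mW + (1 - beta1) * grads[[i]]$W
    st$vW <- beta2 * st$vW + (1 - beta2) * grads[[i]]$W^2
    st$mb <- beta1 * st$mb + (1 - beta1) * grads[[i]]$b
    st$vb <- beta2 * st$vb + (1 - beta2) * grads[[i]]$b^2
    params[[i]]$W <- params[[i]]$W - lr * (st$mW / corr1) /
      (sqrt(st$vW / corr2) + eps)
    params[[i]]$b <- params[[i]]$b - lr * (st$mb / corr1) /
      (sqrt(st$vb / corr2) + eps)
    state[[i]] <- st
  }
  list(params = params, state = state)
}

# mirror + integer translation with zero (air) fill; labels are unchanged
augment_batch <- function(x, mirror = TRUE, max_translation = 0L) {
  d <- dim(x)
  if (mirror) {
    flip <- stats::runif(d[1]) < 0.5
    if (any(flip)) x[flip, , , ] <- x[flip, , rev(seq_len(d[3])), , drop = FALSE]
  }
  if (max_translation > 0L) {
    for (b in seq_len(d[1])) {
      dy <- sample.int(2L * max_translation + 1L, 1L) - max_translation - 1L
      dx <- sample.int(2L * max_translation + 1L, 1L) - max_translation - 1L
      if (dy == 0L && dx == 0L) next
      sl <- x[b, , , 1]
      out <- matrix(0, d[2], d[3])
      ys <- seq_len(d[2]); xs <- seq_len(d[3])
      ydst <- ys + dy; xdst <- xs + dx
      keepy <- ydst >= 1L & ydst <= d[2]
      keepx <- xdst >= 1L & xdst <= d[3]
      out[ydst[keepy], xdst[keepx]] <- sl[ys[keepy], xs[keepx]]
      x[b, , , 1] <- out
    }
  }
  x
}

#' Train a single estimator (classifier or regressor)
#'
#' Mini-batch Adam on softmax cross-entropy (classification) or MSE
#' (regression) with L1+L2 penalties on weights. After every epoch the
#' validation metric is computed — the class-distance-weighted accuracy
#' ([weighted_classification_score()]) for classification, the MSE for
#' regression — and the parameters of the best epoch (max weighted score /
#' min MSE) are returned.
#'
#' @param x tensor `[n, H, W, 1]` of preprocessed slices.
#' @param y integer class labels (1-based) or numeric regression targets.
#' @param task `"classification"` or `"regression"`.
#' @param spec a [backbone_spec()].
#' @param cfg a [train_config()].
#' @param train_idx,val_idx row indices of the training and validation sets.
#' @param seed seed for initialization, shuffling and augmentation.
#' @return An `estimator` object: `params` (best epoch), `spec`, `task`,
#'   `log` (tibble: epoch, train_loss, val_metric), `best_epoch`.
#' @export
train_estimator <- function(x, y, task = c("classification", "regression"),
                            spec, cfg, train_idx, val_idx, seed = 1L) {
  task <- match.arg(task)
  stopifnot(length(train_idx) > 0L, length(val_idx) > 0L)
  withr::with_seed(as.integer(seed), {
    params <- lapply(init_params(spec, seed = sample.int(1e6, 1)), identity)
    state <- adam_init(params)
    xval <- x[val_idx, , , , drop = FALSE]
    yval <- y[val_idx]
    best <- list(metric = if (task == "classification") -Inf else Inf,
                 params = params, epoch = 0L)
    log <- vector("list", cfg$max_epochs)
    t_step <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(train_idx)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_loss <- 0
      for (bi in batches) {
        xb <- augment_batch(x[bi, , , , drop = FALSE],
                            mirror = cfg$augment_mirror,
                            max_translation = cfg$max_translation_px)
        fw <- net_forward(spec, params, xb, keep_cache = TRUE)
        lg <- loss_grad(task, fw$out, y[bi])
        grads <- net_backward(spec, params, fw$caches, lg$dout)
        grads <- add_penalty_grads(grads, params, cfg$l1_weight, cfg$l2_weight)
        t_step <- t_step + 1L
        upd <- adam_step(params, grads, state, cfg$learning_rate, t_step)
        params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + (lg$loss + penalty_value(params, cfg$l1_weight,
                                                      cfg$l2_weight)) * length(bi)
      }
      vout <- net_forward(spec, params, xval)$out
      if (task == "classification") {
        vm <- weighted_classification_score(yval, max.col(vout, "first"),
                                            n_classes = spec$out_dim)
        improved <- vm > best$metric
      } else {
        vm <- mean((vout[, 1] - yval)^2)
        improved <- vm < best$metric
      }
      if (improved) best <- list(metric = vm, params = params, epoch = epoch)
      log[[epoch]] <- tibble::tibble(epoch = epoch,
                                     train_loss = ep_loss / length(train_idx),
                                     val_metric = vm)
    }
    structure(list(task = task, spec = spec, params = best$params,
                   best_epoch = best$epoch, best_metric = best$metric,
                   log = purrr::list_rbind(log)),
              class = "estimator")
  })
}

#' @export
print.estimator <- function(x, ...) {
  cat(sprintf("<estimator> %s, %s backbone, best epoch %d (val metric %.4g)\n",
              x$task, x$spec$backbone, x$best_epoch, x$best_metric))
  invisible(x)
}

#' Run an estimator on a batch of preprocessed slices
#'
#' @param est an `estimator` from [train_estimator()].
#' @param x tensor `[n, H, W, 1]`.
#' @return For classification, a matrix of class probabilities (rows sum to
#'   1); for regression, a numeric vector.
#' @export
estimator_predict <- function(est, x) {
  out <- net_forward(est$spec, est$params, x)$out
  if (est$task == "classification") softmax_rows(out) else out[, 1]
}

n_params <- function(est) {
  sum(vapply(est$params, function(p) if (is.null(p)) 0L else length(p$W) + length(p$b),
             integer(1)))
}
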