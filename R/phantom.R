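#' Configuration for the head-like digital phantom
#'
#' The phantom emulates head-and-neck axial anatomy at desk scale: an
#' elliptical soft-tissue body on an air background, a bone rim (skull), and
#' randomized air cavities concentrated near the cranial/caudal ends of the
#' volume (the nasal-cavity-like region where sCT conversion typically
#' degrades). The paired pseudo-sCT is the same anatomy plus an additive
#' corruption field whose magnitude is rescaled so the per-slice MAE equals a
#' requested target exactly — the phantom's job is to exercise the pipeline
#' with known labels, not to simulate artifact physics.
#'
#' @param shape integer vector `(H, W, n_slices)` (default `c(32, 32, 20)`).
#' @param hu_air,hu_soft,hu_bone tissue HU values (defaults -1000, 40, 700).
#' @param corr_length spatial correlation length (pixels) of the smooth
#'   corruption field (default 3).
#' @param modality_style `"CBCT"` (smooth field + streaks + cupping, shorter
#'   correlation) or `"MR"` (smooth bias field only, doubled correlation).
#' @param seed integer seed; same seed and config give bit-identical volumes.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape = c(32, 32, 20), hu_air = -1000, hu_soft = 40,
                           hu_bone = 700, corr_length = 3,
                           modality_style = c("CBCT", "MR"), seed = 1L) {
  modality_style <- match.arg(modality_style)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, shape[3] >= 0L)
  if (shape[1] < 16L || shape[2] < 16L) {
    stop("phantom shape too small: need at least 16x16 in-plane", call. = FALSE)
  }
  structure(list(shape = shape, hu_air = hu_air, hu_soft = hu_soft,
                 hu_bone = hu_bone, corr_length = corr_length,
                 modality_style = modality_style, seed = as.integer(seed)),
            class = "phantom_config")
}

# Dense separable Gaussian smoothing of a white-noise field.
smooth_field <- function(h, w, sigma) {
  kmat <- function(n) {
    d <- outer(seq_len(n), seq_len(n), function(i, j) (i - j)^2)
    k <- exp(-d / (2 * sigma^2))
    k / rowSums(k)
  }
  noise <- matrix(stats::rnorm(h * w), h, w)
  kmat(h) %*% noise %*% t(kmat(w))
}

#' Generate the ground-truth phantom CT
#'
#' @param config a [phantom_config()].
#' @return An [hu_volume()] with air background, soft-tissue body interior,
#'   bone rim, and randomized cavities.
#' @export
generate_gt <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  h <- config$shape[1]; w <- config$shape[2]; nz <- config$shape[3]
  withr::with_seed(config$seed, {
    arr <- array(config$hu_air, config$shape)
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    # per-patient anatomy jitter
    a0 <- h * stats::runif(1, 0.33, 0.40)
    b0 <- w * stats::runif(1, 0.28, 0.36)
    rim <- max(1.5, 0.07 * min(h, w))
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (i in seq_len(nz)) {
      # body tapers toward the cranial end
      taper <- 0.85 + 0.15 * sin(pi * (i - 0.5) / max(nz, 1))
      a <- a0 * taper; b <- b0 * taper
      r_out <- ((yy - cy) / a)^2 + ((xx - cx) / b)^2
      r_in <- ((yy - cy) / (a - rim))^2 + ((xx - cx) / (b - rim))^2
      sl <- matrix(config$hu_air, h, w)
      sl[r_out <= 1] <- config$hu_bone          # skull rim
      sl[r_in <= 1] <- config$hu_soft           # soft-tissue interior
      # air cavities, denser near the volume ends (nasal-cavity analogue)
      edge <- min(i, nz - i + 1) / max(nz, 1)
      n_cav <- stats::rpois(1, lambda = if (edge < 0.25) 2 else 0.5)
      for (k in seq_len(n_cav)) {
        ky <- cy + stats::runif(1, -0.4, 0.4) * a
        kx <- cx + stats::runif(1, -0.4, 0.4) * b
        kr <- stats::runif(1, 0.05, 0.12) * min(h, w)
        cav <- (yy - ky)^2 + (xx - kx)^2 <= kr^2 & r_in <= 1
        sl[cav] <- config$hu_air
      }
      arr[, , i] <- sl
    }
    hu_volume(arr)
  })
}

# One corruption texture slice, before centering/rescaling.
corruption_texture <- function(h, w, config) {
  sigma <- config$corr_length
  if (config$modality_style == "MR") {
    # smooth bias field, longer range
    smooth_field(h, w, 2 * sigma)
  } else {
    yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    theta <- stats::runif(1, 0, pi)
    lambda <- stats::runif(1, 3, 6)
    phase <- stats::runif(1, 0, 2 * pi)
    streaks <- sin(2 * pi * (cos(theta) * yy + sin(theta) * xx) / lambda + phase)
    r2 <- ((yy - (h + 1) / 2) / h)^2 + ((xx - (w + 1) / 2) / w)^2
    cupping <- r2 - mean(r2)
    f <- smooth_field(h, w, sigma)
    f / stats::sd(f) + 0.6 * streaks + 1.5 * cupping
  }
}

#' Corrupt a phantom to hit per-slice MAE targets exactly
#'
#' Adds, per slice, a zero-centered corruption field rescaled so that
#' `mean(|field|)` equals the requested target, hence
#' `slice_mae(gt_i, sct_i) == targets[i]` to numerical precision. Field signs
#' are flipped pixel-wise where the sum would leave the valid HU range
#' `[-1024, 3071]`; a sign flip preserves `|field|` and therefore the MAE.
#'
#' @param gt ground-truth `hu_volume` from [generate_gt()].
#' @param targets numeric vector of per-slice MAE targets in HU, one per
#'   axial slice, all nonnegative.
#' @param config the [phantom_config()] (texture + modality style).
#' @param seed seed for the corruption fields (default `config$seed + 1`).
#' @return The pseudo-sCT `hu_volume`.
#' @export
corrupt_to_target_mae <- function(gt, targets, config, seed = NULL) {
  stopifnot(inherits(gt, "hu_volume"), inherits(config, "phantom_config"))
  nz <- n_axial_slices(gt)
  if (length(targets) != nz) {
    stop(sprintf("expected %d per-slice targets, got %d", nz, length(targets)),
         call. = FALSE)
  }
  if (any(!is.finite(targets)) || any(targets < 0)) {
    stop("MAE targets must be finite and nonnegative", call. = FALSE)
  }
  if (is.null(seed)) seed <- config$seed + 1L
  h <- dim(gt)[1]; w <- dim(gt)[2]
  withr::with_seed(as.integer(seed), {
    sct <- unclass(gt) + 0
    for (i in seq_len(nz)) {
      if (targets[i] == 0) next
      f <- corruption_texture(h, w, config)
      f <- f - mean(f)
      m <- mean(abs(f))
      while (m < 1e-12) {            # pathologically flat draw; redraw
        f <- corruption_texture(h, w, config)
        f <- f - mean(f)
        m <- mean(abs(f))
      }
      f <- f * (targets[i] / m)
      g <- sct[, , i]
      flip <- (g + f < -1024) | (g + f > 3071)
      f[flip] <- -f[flip]
      sct[, , i] <- g + f
    }
    hu_volume(sct, spacing = vol_spacing(gt), origin = vol_origin(gt))
  })
}

#' Generate a paired phantom dataset with known per-slice MAE
#'
#' Draws per-slice MAE targets from `mae_sampler`, builds one GT/sCT pair per
#' patient, and records every true MAE in a manifest. Per-patient seeds are
#' derived deterministically from `seed`.
#'
#' @param n_patients number of phantom patients (>= 1).
#' @param config a [phantom_config()] template; its `seed` is overridden per
#'   patient.
#' @param mae_sampler function `n -> n` nonnegative HU values (default
#'   uniform on `[0, 100]`, spanning the label range used throughout).
#' @param seed master seed.
#' @param dir optional directory; when given, writes `<id>_gt.nii.gz`,
#'   `<id>_sct.nii.gz` per patient plus `manifest.csv`.
#' @return A list with `pairs` (list of `volume_pair`) and `manifest`
#'   (tibble: `patient_id`, `modality`, `slice_index`, `mae_true`, and source
#'   paths when written).
#' @export
make_phantom_dataset <- function(n_patients, config = phantom_config(),
                                 mae_sampler = function(n) stats::runif(n, 0, 100),
                                 seed = 1L, dir = NULL) {
  stopifnot(n_patients >= 1L, inherits(config, "phantom_config"))
  nz <- config$shape[3]
  modality <- config$modality_style
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  res <- purrr::map(seq_len(n_patients), function(p) {
    pid <- sprintf("PH%s%03d", modality, p)
    pc <- config
    pc$seed <- as.integer((seed * 1000L + p * 2L) %% .Machine$integer.max)
    gt <- generate_gt(pc)
    targets <- withr::with_seed(pc$seed + 1L, mae_sampler(nz))
    if (any(!is.finite(targets)) || any(targets < 0)) {
      stop("mae_sampler must return finite nonnegative values", call. = FALSE)
    }
    sct <- corrupt_to_target_mae(gt, targets, pc, seed = pc$seed + 2L)
    pair <- volume_pair(gt, sct, patient_id = pid, modality = modality)
    man <- tibble::tibble(patient_id = pid, modality = modality,
                          slice_index = seq_len(nz), mae_true = targets)
    if (!is.null(dir)) {
      gt_path <- file.path(dir, paste0(pid, "_gt.nii.gz"))
      sct_path <- file.path(dir, paste0(pid, "_sct.nii.gz"))
      # doubles on disk so relabeling from file reproduces the targets exactly
      write_volume(gt, gt_path, datatype = "double")
      write_volume(sct, sct_path, datatype = "double")
      man$gt_path <- gt_path
      man$sct_path <- sct_path
    }
    list(pair = pair, manifest = man)
  })
  manifest <- purrr::list_rbind(purrr::map(res, "manifest"))
  if (!is.null(dir)) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(pairs = purrr::map(res, "pair"), manifest = manifest)
}
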