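#' Training configuration for the U-net regressor
#'
#' Defaults follow the standard recipe for this task: RMSprop at an initial
#' learning rate of 1e-4, mini-batches of 4 slices, mean-squared-error loss,
#' learning-rate decay by 0.2 after 10 epochs without validation improvement,
#' early stopping after 15, and the best-validation-epoch weights kept.
#'
#' @param initial_lr initial learning rate.
#' @param batch_size mini-batch size (slices).
#' @param plateau_factor learning-rate multiplier on plateau, in (0, 1).
#' @param plateau_patience epochs without validation improvement before the
#'   learning rate drops.
#' @param early_stop_patience epochs without validation improvement before
#'   training halts.
#' @param max_epochs epoch cap (early stopping normally fires first).
#' @param validation_fraction fraction of subjects held out for validation;
#'   0 validates on the training samples themselves (overfitting sanity runs).
#' @param augment_flip,augment_rotate,augment_scale,augment_shift enable each
#'   augmentation (each is applied with probability 1/2 per sample per epoch).
#' @param rotate_deg,scale_frac,shift_px augmentation ranges (plus/minus).
#' @param masked_loss restrict the MSE to in-lung pixels instead of the whole
#'   slice (off by default: labels are simply zero outside the lung).
#' @param seed training seed (shuffling, dropout, augmentation).
#' @return An object of class `ventimap_train_config`.
#' @export
train_config <- function(initial_lr = 1e-4, batch_size = 4L,
                         plateau_factor = 0.2, plateau_patience = 10L,
                         early_stop_patience = 15L, max_epochs = 300L,
                         validation_fraction = 0.2,
                         augment_flip = TRUE, augment_rotate = TRUE,
                         augment_scale = TRUE, augment_shift = TRUE,
                         rotate_deg = 10, scale_frac = 0.1, shift_px = 10,
                         masked_loss = FALSE, seed = 1L) {
  if (plateau_factor <= 0 || plateau_factor >= 1)
    vm_stop("plateau_factor must lie in (0, 1)", "ventimap_config_error")
  if (plateau_patience < 1 || early_stop_patience < 1)
    vm_stop("patiences must be positive", "ventimap_config_error")
  structure(list(initial_lr = initial_lr, batch_size = as.integer(batch_size),
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 early_stop_patience = as.integer(early_stop_patience),
                 max_epochs = as.integer(max_epochs),
                 validation_fraction = validation_fraction,
                 augment_flip = augment_flip, augment_rotate = augment_rotate,
                 augment_scale = augment_scale, augment_shift = augment_shift,
                 rotate_deg = rotate_deg, scale_frac = scale_frac,
                 shift_px = shift_px, masked_loss = masked_loss,
                 seed = as.integer(seed)),
            class = "ventimap_train_config")
}

# Scale CBCT intensities into the unit-order range used as network input.
scale_intensity <- function(hu) pmin(pmax((hu + 1000) / 1000, 0), 2)

# In-plane crop window (low offsets) used for both sampling and prediction.
crop_window <- function(d, size) {
  off <- (d[1:2] - size) %/% 2L
  list(xi = seq.int(off[1] + 1L, off[1] + size),
       yi = seq.int(off[2] + 1L, off[2] + size), off = off)
}

# Channel stack of one axial slice of a phase series, per the input mode.
slice_channels <- function(series, z, mode, xi, yi) {
  nz <- series$geometry$shape[3]
  get <- function(ph, zz) series$phases[[ph]]$values[xi, yi, min(max(zz, 1L), nz)]
  labels <- names(series$phases)
  chans <- switch(
    mode,
    phases2 = list(get("T00", z), get("T50", z)),
    phases10 = lapply(labels, function(ph) get(ph, z)),
    phases10_adjacent = do.call(c, lapply(labels, function(ph)
      list(get(ph, z - 1L), get(ph, z), get(ph, z + 1L)))))
  x <- array(0, dim = c(length(xi), length(yi), length(chans)))
  for (c in seq_along(chans)) x[, , c] <- scale_intensity(chans[[c]])
  x
}

#' Extract slice training samples from subjects
#'
#' One sample per axial slice intersecting the exhale lung mask. Inputs are
#' the requested phase-channel stack, centre-cropped to the model's in-plane
#' size and scaled as `(HU + 1000)/1000` clipped to `[0, 2]`. Labels are the
#' subject's reference ventilation (degraded SPECT-like map by default, or
#' the analytic truth), normalised by its in-mask 90th percentile per subject
#' and zeroed outside the lung.
#'
#' @param subjects list of `ventimap_phantom_subject` objects.
#' @param config a [model_config()].
#' @param label_source `"spect"` (default) or `"truth"`.
#' @return A list of slice samples (`input`, `label`, `mask`, `subject_id`,
#'   `slice_index`).
#' @export
make_samples <- function(subjects, config, label_source = c("spect", "truth")) {
  label_source <- match.arg(label_source)
  samples <- list()
  for (sub in subjects) {
    d <- sub$series$geometry$shape
    if (any(d[1:2] < config$in_plane_size))
      vm_stop("subject in-plane size is smaller than the model input",
              "ventimap_geometry_error")
    cw <- crop_window(d, config$in_plane_size)
    m <- sub$exhale_mask$values
    ref <- if (label_source == "spect") sub$spect_like$values
           else sub$true_ventilation$values
    p90 <- vm_percentile(ref[m], 90)
    if (!is.finite(p90) || p90 <= 0)
      vm_stop("reference normalisation percentile is nonpositive",
              "ventimap_data_error")
    lab3 <- ref / p90
    lab3[!m] <- 0
    zsel <- which(apply(m[cw$xi, cw$yi, , drop = FALSE], 3, any))
    if (length(zsel) == 0L)
      vm_stop(sprintf("subject %s has no lung-intersecting slices", sub$id),
              "ventimap_data_error")
    for (z in zsel) {
      samples[[length(samples) + 1L]] <- list(
        input = slice_channels(sub$series, z, config$input_mode, cw$xi, cw$yi),
        label = lab3[cw$xi, cw$yi, z],
        mask = m[cw$xi, cw$yi, z],
        subject_id = sub$id, slice_index = z)
    }
  }
  samples
}

bilinear_2d <- function(mat, ix, iy, fill = 0) {
  d <- dim(mat)
  inside <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2]
  x0 <- pmin(pmax(floor(ix), 1), d[1] - 1L)
  y0 <- pmin(pmax(floor(iy), 1), d[2] - 1L)
  fx <- ix - x0; fy <- iy - y0
  out <- mat[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    mat[cbind(x0 + 1L, y0)] * fx * (1 - fy) +
    mat[cbind(x0, y0 + 1L)] * (1 - fx) * fy +
    mat[cbind(x0 + 1L, y0 + 1L)] * fx * fy
  out[!inside] <- fill
  out
}

#' Randomly augment a slice sample
#'
#' Draws an independent subset of the enabled augmentations (each with
#' probability 1/2) — horizontal flip, rotation within the configured range,
#' isotropic scaling, in-plane shift — and applies the same geometric
#' transform to every input channel, the label and the lung mask (bilinear
#' for intensities, with the label re-zeroed outside the transformed lung).
#' Uses the current RNG stream.
#'
#' @param sample a slice sample from [make_samples()].
#' @param config a [train_config()].
#' @return The augmented sample.
#' @export
augment <- function(sample, config) {
  do_flip <- config$augment_flip && runif(1) < 0.5
  theta <- if (config$augment_rotate && runif(1) < 0.5)
    runif(1, -config$rotate_deg, config$rotate_deg) * pi / 180 else 0
  sc <- if (config$augment_scale && runif(1) < 0.5)
    1 + runif(1, -config$scale_frac, config$scale_frac) else 1
  sh <- if (config$augment_shift && runif(1) < 0.5)
    runif(2, -config$shift_px, config$shift_px) else c(0, 0)
  if (!do_flip && theta == 0 && sc == 1 && all(sh == 0)) return(sample)
  d <- dim(sample$label)
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  gx <- rep(seq_len(d[1]), times = d[2]) - cx
  gy <- rep(seq_len(d[2]), each = d[1]) - cy
  # output pixel -> source pixel (inverse map)
  ct <- cos(-theta); st <- sin(-theta)
  sx <- (gx - sh[1]) / sc; sy <- (gy - sh[2]) / sc
  ix <- ct * sx - st * sy + cx
  iy <- st * sx + ct * sy + cy
  if (do_flip) ix <- d[1] + 1 - ix
  warp2 <- function(mat) matrix(bilinear_2d(mat, ix, iy, 0), d[1], d[2])
  inp <- sample$input
  for (c in seq_len(dim(inp)[3])) inp[, , c] <- warp2(sample$input[, , c])
  mask_t <- warp2(sample$mask + 0) >= 0.5
  lab <- warp2(sample$label)
  lab[!mask_t] <- 0
  sample$input <- inp
  sample$label <- lab
  sample$mask <- mask_t
  sample
}

batch_arrays <- function(samples, idx) {
  s1 <- samples[[idx[1]]]
  d <- dim(s1$input)
  x <- array(0, dim = c(d[1], d[2], d[3], length(idx)))
  y <- array(0, dim = c(d[1], d[2], 1L, length(idx)))
  w <- array(1, dim = dim(y))
  for (b in seq_along(idx)) {
    x[, , , b] <- samples[[idx[b]]]$input
    y[, , 1, b] <- samples[[idx[b]]]$label
    w[, , 1, b] <- samples[[idx[b]]]$mask
  }
  list(x = x, y = y, w = w)
}

batch_loss <- function(out, y, w, masked) {
  if (masked) {
    sw <- sum(w)
    list(loss = sum(w * (out - y)^2) / sw, dout = 2 * w * (out - y) / sw)
  } else {
    n <- length(y)
    list(loss = mean((out - y)^2), dout = 2 * (out - y) / n)
  }
}

eval_loss <- function(model, samples, idx, masked, batch_size = 8L) {
  total <- 0; denom <- 0
  for (chunk in split(idx, ceiling(seq_along(idx) / batch_size))) {
    ba <- batch_arrays(samples, chunk)
    fw <- unet_forward(model, ba$x, train = FALSE, keep_cache = FALSE)
    bl <- batch_loss(fw$out, ba$y, ba$w, masked)
    total <- total + bl$loss * length(chunk)
    denom <- denom + length(chunk)
  }
  total / denom
}

#' Train a U-net on slice samples
#'
#' Splits subjects 80/20 into training and validation (by subject, never by
#' slice, to avoid leakage), then optimises the mean-squared error with
#' RMSprop under the configured schedule: learning-rate decay by
#' `plateau_factor` after `plateau_patience` epochs without validation
#' improvement, early stopping after `early_stop_patience`, weights restored
#' from the best validation epoch.
#'
#' @param samples from [make_samples()].
#' @param model a [build_unet()] model.
#' @param config a [train_config()].
#' @param verbose print one line per epoch.
#' @return A list: `model` (weights of the best validation epoch),
#'   `final_model` (weights of the last epoch run), `history` (data frame of
#'   epoch, train/validation loss, learning rate), `train_ids`, `val_ids`.
#' @export
train <- function(samples, model, config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "ventimap_unet"),
            inherits(config, "ventimap_train_config"))
  ids <- unique(vapply(samples, `[[`, character(1), "subject_id"))
  sample_ids <- vapply(samples, `[[`, character(1), "subject_id")
  with_seed(derive_seed(config$seed, "train"), {
    if (config$validation_fraction > 0) {
      if (length(ids) < 2L)
        vm_stop("subject-level train/validation split needs >= 2 subjects",
                "ventimap_split_error")
      n_val <- max(1L, round(config$validation_fraction * length(ids)))
      val_ids <- sample(ids, n_val)
      train_idx <- which(!(sample_ids %in% val_ids))
      val_idx <- which(sample_ids %in% val_ids)
    } else {
      val_ids <- ids
      train_idx <- seq_along(samples)
      val_idx <- seq_along(samples)
    }
    augment_on <- config$augment_flip || config$augment_rotate ||
      config$augment_scale || config$augment_shift
    r_cache <- lapply(model$params, function(l)
      list(rW = 0 * l$W, rb = 0 * l$b))
    lr <- config$initial_lr
    best_val <- Inf
    best_params <- model$params
    best_epoch <- 0L
    since_best <- 0L
    since_lr <- 0L
    hist <- vector("list", config$max_epochs)
    rho <- 0.9; eps <- 1e-7
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(train_idx)
      tl <- 0; tn <- 0
      for (chunk in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        smp <- samples[chunk]
        if (augment_on) smp <- lapply(smp, augment, config = config)
        ba <- batch_arrays(smp, seq_along(smp))
        fw <- unet_forward(model, ba$x, train = TRUE)
        bl <- batch_loss(fw$out, ba$y, ba$w, config$masked_loss)
        grads <- unet_backward(model, fw, bl$dout)
        for (nm in names(grads)) {
          g <- grads[[nm]]
          rc <- r_cache[[nm]]
          rc$rW <- rho * rc$rW + (1 - rho) * g$dW^2
          rc$rb <- rho * rc$rb + (1 - rho) * g$db^2
          model$params[[nm]]$W <- model$params[[nm]]$W -
            lr * g$dW / (sqrt(rc$rW) + eps)
          model$params[[nm]]$b <- model$params[[nm]]$b -
            lr * g$db / (sqrt(rc$rb) + eps)
          r_cache[[nm]] <- rc
        }
        tl <- tl + bl$loss * length(chunk)
        tn <- tn + length(chunk)
      }
      train_loss <- tl / tn
      val_loss <- eval_loss(model, samples, val_idx, config$masked_loss)
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                  val_loss = val_loss, lr = lr)
      if (verbose)
        message(sprintf("epoch %3d train %.5f val %.5f lr %.2g",
                        epoch, train_loss, val_loss, lr))
      if (val_loss < best_val - 1e-12) {
        best_val <- val_loss
        best_params <- model$params
        best_epoch <- epoch
        since_best <- 0L
        since_lr <- 0L
      } else {
        since_best <- since_best + 1L
        since_lr <- since_lr + 1L
      }
      if (since_best >= config$early_stop_patience) break
      if (since_lr >= config$plateau_patience) {
        lr <- lr * config$plateau_factor
        since_lr <- 0L
      }
    }
    final_model <- model
    model$params <- best_params
    list(model = model, final_model = final_model,
         history = do.call(rbind, hist),
         best_epoch = best_epoch, best_val = best_val,
         train_ids = setdiff(ids, if (config$validation_fraction > 0) val_ids
                             else character(0)),
         val_ids = val_ids)
  })
}

#' Predict a ventilation image for a subject
#'
#' Runs slice-wise inference over every axial slice, reassembles the slices
#' on the exhale grid, and applies the standard post-processing chain (lung
#' mask, 90th-percentile normalisation, box median filter).
#'
#' @param trained a trained `ventimap_unet` (from [train()]`$model`).
#' @param subject a phantom subject (or any list with `series` and
#'   `exhale_mask`).
#' @param filter_size,norm_percentile passed to [postprocess()].
#' @return A normalised [new_ventilation_image()] with provenance `"DL"`.
#' @export
predict_volume <- function(trained, subject, filter_size = 9L,
                           norm_percentile = 90) {
  cfg <- trained$config
  d <- subject$series$geometry$shape
  if (any(d[1:2] < cfg$in_plane_size))
    vm_stop("subject in-plane size is smaller than the model input",
            "ventimap_geometry_error")
  cw <- crop_window(d, cfg$in_plane_size)
  out <- array(0, dim = d)
  zs <- seq_len(d[3])
  for (chunk in split(zs, ceiling(seq_along(zs) / 8L))) {
    x <- array(0, dim = c(cfg$in_plane_size, cfg$in_plane_size, cfg$channels,
                          length(chunk)))
    for (b in seq_along(chunk))
      x[, , , b] <- slice_channels(subject$series, chunk[b], cfg$input_mode,
                                   cw$xi, cw$yi)
    fw <- unet_forward(trained, x, train = FALSE, keep_cache = FALSE)
    for (b in seq_along(chunk))
      out[cw$xi, cw$yi, chunk[b]] <- fw$out[, , 1, b]
  }
  vi <- new_ventilation_image(out, subject$exhale_mask, provenance = "DL",
                              spacing = subject$series$phases[[1]]$spacing,
                              origin = subject$series$phases[[1]]$origin)
  postprocess(vi, subject$exhale_mask, norm_percentile = norm_percentile,
              filter_size = filter_size)
}

#' Randomly partition subject ids into k folds
#'
#' @param subject_ids character vector of ids.
#' @param k number of folds.
#' @param seed partition seed.
#' @return A list of k character vectors (sizes differing by at most 1).
#' @export
make_fold_split <- function(subject_ids, k, seed = 1L) {
  if (k > length(subject_ids))
    vm_stop("k exceeds the number of subjects", "ventimap_split_error")
  if (anyDuplicated(subject_ids))
    vm_stop("subject ids must be unique", "ventimap_split_error")
  shuffled <- with_seed(derive_seed(seed, "fold_split"),
                        sample(subject_ids))
  split(shuffled, rep_len(seq_len(k), length(shuffled)))
}

#' Audit a fold split for subject-level leakage
#'
#' Asserts that the folds are pairwise disjoint and exhaustive over the
#' supplied ids — i.e. every subject is tested exactly once and no test
#' subject can appear in any training set.
#'
#' @param split a [make_fold_split()] result.
#' @param subject_ids the full id set the split was made from.
#' @return `TRUE` invisibly; errors on any violation.
#' @export
audit_fold_split <- function(split, subject_ids) {
  all_ids <- unlist(split, use.names = FALSE)
  if (anyDuplicated(all_ids))
    vm_stop("a subject appears in more than one fold", "ventimap_split_error")
  if (!setequal(all_ids, subject_ids))
    vm_stop("folds do not cover the subject set", "ventimap_split_error")
  invisible(TRUE)
}

#' k-fold patient-level cross-validation of the U-net
#'
#' Randomly partitions subjects into `k` folds; for each fold trains on the
#' remaining subjects (with the internal subject-level 80/20 validation
#' split) and predicts/evaluates the held-out subjects against their
#' reference ventilation. An id audit asserts that no test subject leaks
#' into its fold's training set.
#'
#' @param subjects list of phantom subjects.
#' @param k number of folds.
#' @param mconfig a [model_config()].
#' @param tconfig a [train_config()].
#' @param seed partition seed (training seeds are derived per fold).
#' @param label_source passed to [make_samples()].
#' @param reference `"spect"` or `"truth"`: what predictions are evaluated
#'   against.
#' @param filter_size post-processing median filter edge.
#' @param verbose print per-fold progress.
#' @return A list: `per_subject` data frame (fold, subject, Spearman, Dice
#'   per region and average), `per_fold` aggregate data frame, `folds`.
#' @export
crossvalidate <- function(subjects, k = 7L, mconfig, tconfig, seed = 1L,
                          label_source = c("spect", "truth"),
                          reference = c("spect", "truth"),
                          filter_size = 9L, verbose = FALSE) {
  label_source <- match.arg(label_source)
  reference <- match.arg(reference)
  ids <- vapply(subjects, `[[`, character(1), "id")
  names(subjects) <- ids
  folds <- make_fold_split(ids, k, seed)
  audit_fold_split(folds, ids)
  rows <- list()
  for (f in seq_along(folds)) {
    test_ids <- folds[[f]]
    train_subjects <- subjects[setdiff(ids, test_ids)]
    stopifnot(!any(test_ids %in% names(train_subjects))) # leakage audit
    samples <- make_samples(train_subjects, mconfig, label_source)
    stopifnot(!any(vapply(samples, `[[`, character(1), "subject_id")
                   %in% test_ids))
    tconfig$seed <- derive_seed(seed, paste0("fold", f))
    model <- build_unet(mconfig, seed = tconfig$seed)
    fit <- train(samples, model, tconfig, verbose = FALSE)
    for (sid in test_ids) {
      sub <- subjects[[sid]]
      vi <- predict_volume(fit$model, sub, filter_size = filter_size)
      ref <- if (reference == "spect")
        new_ventilation_image(sub$spect_like$values, sub$exhale_mask, "REF",
                              spacing = sub$spect_like$spacing,
                              origin = sub$spect_like$origin)
      else sub$true_ventilation
      ev <- evaluate_subject(list(DL = vi), ref, sub$exhale_mask)
      ev$fold <- f
      ev$subject_id <- sid
      rows[[length(rows) + 1L]] <- ev
    }
    if (verbose) message(sprintf("fold %d/%d done", f, length(folds)))
  }
  per_subject <- do.call(rbind, rows)
  agg <- stats::aggregate(per_subject[c("spearman", "dsc_hfl", "dsc_mfl",
                                        "dsc_lfl", "dsc_avg")],
                          by = list(fold = per_subject$fold), FUN = mean)
  list(per_subject = per_subject, per_fold = agg, folds = folds)
}
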