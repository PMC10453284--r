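# The three-stage pipeline: vessel extraction -> A/V extraction on the
# concatenation of the raw RGB image and the vessel probability -> fusion.
# Both losses backpropagate jointly from the first step (end-to-end).

#' Full pipeline configuration
#'
#' Defaults follow the published training setup where stated: Adam with
#' learning rate 0.001, 100 epochs, 256-pixel patches, base width 64 with
#' four channel subsets.  Batch size and steps per epoch are not stated and
#' default to desk-friendly values.
#'
#' @param base_width,depth,n_subsets vessel/A-V network scaffold (see
#'   [mve_config()])
#' @param cot_groups,cot_key_kernel,cot_attn_kernel contextual-attention
#'   settings (see [cot_config()])
#' @param use_mfi enable the fusion module; when FALSE the A/V network's own
#'   logits are the final output (ablation toggle)
#' @param mve_block `"res2net"` or `"conv"` (plain U-Net encoder, ablation)
#' @param mae_attention use contextual-attention blocks (FALSE = plain U-Net)
#' @param mfi_hidden hidden width of the fusion head
#' @param lr,epochs,steps_per_epoch,batch_size,patch_size,seed training setup
#' @param noise_sd_max augmentation noise bound (normalized intensity)
#' @param clahe_clip,clahe_grid CLAHE parameters for the vessel input
#' @param val_fraction held-out fraction for checkpoint selection
#' @param reduction `"mean"` or `"sum"` pixel reduction in the losses
#' @param aux_mae_supervision also apply the A/V loss to the pre-fusion
#'   logits (off by default: the final output alone is supervised)
#' @return an `msc_config` list, serializable to YAML
#' @export
msc_config <- function(base_width = 64, depth = 4, n_subsets = 4,
                       cot_groups = 4, cot_key_kernel = 3, cot_attn_kernel = 3,
                       use_mfi = TRUE, mve_block = "res2net",
                       mae_attention = TRUE, mfi_hidden = 16,
                       lr = 0.001, epochs = 100, steps_per_epoch = 50,
                       batch_size = 4, patch_size = 256, seed = 1,
                       noise_sd_max = 0.02, clahe_clip = 2,
                       clahe_grid = c(8, 8), val_fraction = 0.2,
                       reduction = "mean", aux_mae_supervision = FALSE) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "msc_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file
#' @export
msc_config_read <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(msc_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(msc_config, vals)
}

#' @rdname msc_config_read
#' @param config an `msc_config`
#' @export
msc_config_write <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Build an untrained pipeline model
#'
#' Weight initialization is He-normal and seeded by `config$seed`.
#' @param config an [msc_config()]
#' @return an `msc_model` list with components `mve`, `mae`, `mfi`, `config`
#' @export
msc_new <- function(config = msc_config()) {
  stopifnot(inherits(config, "msc_config"))
  with_seed(config$seed, {
    mve <- mve_new(mve_config(config$base_width, config$depth,
                              config$n_subsets, block = config$mve_block),
                   in_channels = 1L)
    mae <- mae_new(mae_config(config$base_width, config$depth,
                              config$cot_key_kernel, config$cot_groups,
                              config$cot_attn_kernel,
                              attention = config$mae_attention),
                   in_channels = 4L)
    mfi <- mfi_new(feat_channels = config$base_width,
                   hidden = config$mfi_hidden)
    structure(list(mve = mve, mae = mae, mfi = mfi, config = config),
              class = "msc_model")
  })
}

#' @export
print.msc_model <- function(x, ...) {
  cat(sprintf(paste0("<msc_model> base width %d, depth %d, %s encoder, ",
                     "attention %s, fusion %s; %d parameters\n"),
              x$config$base_width, x$config$depth, x$config$mve_block,
              if (x$config$mae_attention) "on" else "off",
              if (x$config$use_mfi) "on" else "off", count_params(x)))
  invisible(x)
}

# core forward on prepared batches: rgb (H,W,3,N) in [0,1], vin (H,W,1,N)
forward_batch <- function(model, rgb, vin, training = FALSE) {
  pv <- mve_forward(model$mve, vin, training)
  r <- mae_forward(model$mae, nn_concat(list(node_new(rgb), pv)), training)
  final <- if (model$config$use_mfi) {
    mfi_fwd(model$mfi, r$logits, r$features, nn_enhance(pv), training)
  } else {
    r$logits
  }
  list(vessel = pv, mae_logits = r$logits, features = r$features, final = final)
}

prepare_inputs <- function(model, image) {
  list(rgb = image / 255,
       vin = vessel_input_channels(image, clip = model$config$clahe_clip,
                                   grid = model$config$clahe_grid))
}

#' Run the full pipeline on one image
#'
#' The vessel branch consumes the CLAHE-equalized green channel, the A/V
#' branch the raw RGB concatenated with the vessel probability, and the
#' fusion head refines the A/V logits with the enhanced vessel map.  The
#' image size must be divisible by 2^depth (use [msc_predict()] for tiled
#' inference on arbitrary sizes).
#'
#' @param model an [msc_new()] model
#' @param image H x W x 3 array on the 0..255 scale
#' @return list with `vessel_prob` (H x W matrix in [0,1]), `av_logits`
#'   (H x W x 3), `mae_logits`, and `av_classes` (full argmax map)
#' @export
msc_forward <- function(model, image) {
  inp <- prepare_inputs(model, image)
  d <- dim(image)
  dim(inp$rgb) <- c(d[1], d[2], 3L, 1L)
  dim(inp$vin) <- c(d[1], d[2], 1L, 1L)
  r <- forward_batch(model, inp$rgb, inp$vin, training = FALSE)
  logits <- array(r$final$v, dim = c(d[1], d[2], 3L))
  list(vessel_prob = matrix(r$vessel$v, d[1], d[2]),
       av_logits = logits,
       mae_logits = array(r$mae_logits$v, dim = c(d[1], d[2], 3L)),
       av_classes = av_argmax(logits))
}

# build (p, p, c, B) batches from aligned crops
stack_crops <- function(crops, field, channels) {
  p <- dim(crops[[1]][[field]])[1]
  out <- array(0, dim = c(p, p, channels, length(crops)))
  for (i in seq_along(crops)) out[, , , i] <- crops[[i]][[field]]
  out
}

#' Train the pipeline
#'
#' Each step samples aligned random patches from the training split, applies
#' rotation/noise augmentation, and takes one Adam step on the joint loss
#' (vessel BCE + 0.1 Dice, plus the A/V cross-entropy on the final logits).
#' The best checkpoint by validation loss is kept when `ckpt_path` is given.
#' Fully seeded: identical inputs and seeds give identical runs.
#'
#' @param samples list of [fundus_sample()]s (all with vessel and A/V
#'   labels), or a manifest list / `manifest.json` path
#' @param config an [msc_config()]
#' @param total_steps optional cap on optimizer steps (overrides
#'   `epochs * steps_per_epoch`)
#' @param ckpt_path optional path for the best checkpoint (RDS)
#' @param verbose print per-epoch losses
#' @return list with `model`, `log` (per-epoch data frame) and `best_val`
#' @export
msc_train <- function(samples, config = msc_config(), total_steps = NULL,
                      ckpt_path = NULL, verbose = FALSE) {
  if (is.character(samples) || (is.list(samples) && !is.null(samples[[1]]$image) &&
                                is.character(samples[[1]]$image))) {
    samples <- read_manifest(samples)
  }
  for (s in samples) {
    if (is.null(s$vessel_mask) || is.null(s$av_labels)) {
      stop("sample '", s$sample_id, "' lacks vessel or A/V labels required for training")
    }
  }
  model <- msc_new(config)
  params <- collect_params(model)
  p <- config$patch_size
  if (p %% 2L^config$depth != 0L) {
    stop(sprintf("patch_size %d must be divisible by 2^depth = %d",
                 p, 2L^config$depth))
  }

  # validation split for checkpoint selection
  n <- length(samples)
  nval <- if (n >= 3) max(1L, round(config$val_fraction * n)) else 0L
  idx <- with_seed(config$seed, sample.int(n))
  val <- if (nval > 0) samples[idx[seq_len(nval)]] else list()
  trn <- samples[idx[(nval + 1):n]]

  prep <- lapply(trn, function(s) prepare_inputs(model, s$image))
  steps_total <- if (is.null(total_steps)) config$epochs * config$steps_per_epoch
                 else total_steps
  n_epochs <- ceiling(steps_total / config$steps_per_epoch)

  log <- data.frame()
  best_val <- Inf
  best_snapshot <- NULL
  step <- 0L
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(n_epochs)) {
      ep_terms <- c(l_bce = 0, l_dice = 0, l_a = 0, total = 0)
      ep_steps <- 0L
      while (ep_steps < config$steps_per_epoch && step < steps_total) {
        step <- step + 1L; ep_steps <- ep_steps + 1L
        crops <- lapply(seq_len(config$batch_size), function(b) {
          si <- sample.int(length(trn), 1L)
          cr <- random_patches(trn[[si]], 1L, patch = p,
                               rng_seed = sample.int(1e9, 1L))[[1]]
          # stack the CLAHE channel with RGB so augmentation transforms and
          # adds noise to all image channels jointly, labels untouched
          r0 <- cr$origin[1]; c0 <- cr$origin[2]
          vin <- prep[[si]]$vin[r0:(r0 + p - 1), c0:(c0 + p - 1), 1]
          img4 <- array(c(cr$image, vin * 255), dim = c(p, p, 4L))
          a <- augment(list(image = img4, mask = cr$mask, av = cr$av),
                       rng_seed = sample.int(1e9, 1L),
                       noise_sd_max = config$noise_sd_max)
          list(rgb = a$image[, , 1:3, drop = FALSE] / 255,
               vin = a$image[, , 4, drop = FALSE] / 255,
               mask = a$mask, av = a$av)
        })
        rgb <- stack_crops(crops, "rgb", 3L)
        vin <- stack_crops(crops, "vin", 1L)
        mask <- array(vapply(crops, function(cr) cr$mask, matrix(0L, p, p)),
                      dim = c(p, p, 1L, config$batch_size))
        av <- array(vapply(crops, function(cr) cr$av, matrix(0L, p, p)),
                    dim = c(p, p, config$batch_size))

        tape_start()
        out <- forward_batch(model, rgb, vin, training = TRUE)
        lb <- nn_bce(out$vessel, mask, config$reduction)
        ld <- nn_dice(out$vessel, mask)
        la <- nn_ce_av(out$final, av, config$reduction)
        loss <- nn_add(nn_add(lb, nn_scale(ld, 0.1)), la)
        if (config$aux_mae_supervision && model$config$use_mfi) {
          loss <- nn_add(loss, nn_ce_av(out$mae_logits, av, config$reduction))
        }
        nn_backward(loss)
        tape_stop()
        adam_step(params, config$lr, step)

        ep_terms <- ep_terms + c(lb$v, ld$v, la$v, loss$v)
      }
      ep_terms <- ep_terms / ep_steps
      vl <- if (length(val)) validation_loss(model, val, p) else NA_real_
      log <- rbind(log, data.frame(epoch = epoch, steps = step,
                                   l_bce = ep_terms[1], l_dice = ep_terms[2],
                                   l_a = ep_terms[3], total = ep_terms[4],
                                   val_loss = vl, row.names = NULL))
      if (verbose) {
        message(sprintf("epoch %d (step %d): loss %.4f, val %.4f",
                        epoch, step, ep_terms[4], vl))
      }
      if (!is.na(vl) && vl < best_val) {
        best_val <- vl
        if (!is.null(ckpt_path)) best_snapshot <- freeze_model(model)
      }
      if (step >= steps_total) break
    }
  })
  if (!is.null(ckpt_path)) {
    saveRDS(best_snapshot %||% freeze_model(model), ckpt_path)
  }
  list(model = model, log = log, best_val = best_val)
}

validation_loss <- function(model, val, p) {
  tot <- 0
  for (s in val) {
    d <- dim(s$image)
    r0 <- max(1L, (d[1] - p) %/% 2L); c0 <- max(1L, (d[2] - p) %/% 2L)
    img <- s$image[r0:(r0 + p - 1), c0:(c0 + p - 1), , drop = FALSE]
    mask <- s$vessel_mask[r0:(r0 + p - 1), c0:(c0 + p - 1)]
    av <- s$av_labels[r0:(r0 + p - 1), c0:(c0 + p - 1)]
    inp <- prepare_inputs(model, img)
    dim(inp$rgb) <- c(p, p, 3L, 1L); dim(inp$vin) <- c(p, p, 1L, 1L)
    out <- forward_batch(model, inp$rgb, inp$vin, training = FALSE)
    lt <- total_loss(as.vector(out$vessel$v), as.vector(mask),
                     array(out$final$v, c(p, p, 3L)), av,
                     model$config$reduction)
    tot <- tot + lt$total
  }
  tot / length(val)
}

#' Tiled inference on an image of arbitrary size
#'
#' The image is cropped into patches in raster order, each patch runs
#' through the full pipeline, and the per-patch outputs are stitched back
#' (the prediction is the connection of all patch results).
#'
#' @param model a trained [msc_new()] model
#' @param image H x W x 3 array (0..255) or a [fundus_sample()]
#' @param patch_size tile side; defaults to the training patch size, and
#'   must be divisible by 2^depth
#' @return as [msc_forward()], plus `av_restricted` (artery-vs-vein argmax
#'   at every pixel, the map used for A/V evaluation)
#' @export
msc_predict <- function(model, image, patch_size = NULL) {
  if (inherits(image, "fundus_sample")) image <- image$image
  p <- patch_size %||% model$config$patch_size
  if (p %% 2L^model$config$depth != 0L) {
    stop(sprintf("patch_size %d must be divisible by 2^depth = %d",
                 p, 2L^model$config$depth))
  }
  d <- dim(image)
  inp <- prepare_inputs(model, image)
  trgb <- tile(inp$rgb, p)
  tvin <- tile(array(inp$vin, dim = d[1:2]), p)
  nt <- length(trgb$patches)
  vessel_out <- vector("list", nt)
  logit_out <- vector("list", nt)
  bs <- 4L
  for (start in seq(1L, nt, by = bs)) {
    ids <- start:min(start + bs - 1L, nt)
    rgb <- array(0, dim = c(p, p, 3L, length(ids)))
    vin <- array(0, dim = c(p, p, 1L, length(ids)))
    for (j in seq_along(ids)) {
      rgb[, , , j] <- trgb$patches[[ids[j]]]
      vin[, , 1, j] <- tvin$patches[[ids[j]]]
    }
    r <- forward_batch(model, rgb, vin, training = FALSE)
    for (j in seq_along(ids)) {
      vessel_out[[ids[j]]] <- matrix(r$vessel$v[, , 1, j], p, p)
      logit_out[[ids[j]]] <- r$final$v[, , , j]
    }
  }
  vessel <- stitch(trgb$grid, vessel_out)
  logits <- stitch(trgb$grid, logit_out)
  list(vessel_prob = vessel, av_logits = logits,
       av_classes = av_argmax(logits),
       av_restricted = av_argmax(logits, av_only = TRUE))
}

#' Evaluate a model on labeled samples
#'
#' Confusion counts are pooled over all samples and turned into metrics
#' once.  Vessel convention: probability thresholded at 0.5, every pixel
#' evaluated.  A/V convention: artery-vs-vein argmax at pixels whose ground
#' truth is artery or vein.
#'
#' @param model a trained model
#' @param samples list of labeled [fundus_sample()]s
#' @param patch_size tile side for inference
#' @return list with `vessel` and `av` metric lists plus pooled `counts`
#' @export
evaluate_model <- function(model, samples, patch_size = NULL) {
  vc <- list(); ac <- list()
  for (s in samples) {
    pr <- msc_predict(model, s, patch_size)
    vc[[length(vc) + 1L]] <- confusion((pr$vessel_prob >= 0.5) * 1L, s, "vessel")
    ac[[length(ac) + 1L]] <- confusion(pr$av_restricted, s, "av")
  }
  vp <- pool_counts(vc); ap <- pool_counts(ac)
  list(vessel = compute_metrics(vp), av = compute_metrics(ap),
       counts = list(vessel = vp, av = ap))
}

#' Evaluate written predictions against a ground-truth manifest
#'
#' Reads the PNGs written by [write_prediction()] for each manifest entry
#' (matching on sample id) and pools confusion counts as in
#' [evaluate_model()].
#'
#' @param pred_dir directory of prediction PNGs
#' @param manifest dataset manifest (list or `manifest.json` path)
#' @return as [evaluate_model()]
#' @export
evaluate_predictions <- function(pred_dir, manifest) {
  gts <- read_manifest(manifest)
  vc <- list(); ac <- list()
  for (s in gts) {
    mask_p <- file.path(pred_dir, paste0(s$sample_id, "_vessel_mask.png"))
    av_p <- file.path(pred_dir, paste0(s$sample_id, "_av.png"))
    if (!file.exists(mask_p) || !file.exists(av_p)) {
      stop("no prediction files for sample id '", s$sample_id, "' in ", pred_dir)
    }
    pred_mask <- decode_mask(read_image(mask_p))
    pred_av <- decode_av(read_image(av_p))
    vc[[length(vc) + 1L]] <- confusion(pred_mask, s, "vessel")
    ac[[length(ac) + 1L]] <- confusion(pred_av, s, "av")
  }
  vp <- pool_counts(vc); ap <- pool_counts(ac)
  list(vessel = compute_metrics(vp), av = compute_metrics(ap),
       counts = list(vessel = vp, av = ap))
}

# ---- checkpointing ----

freeze_model <- function(x) {
  if (is_param(x)) return(structure(list(v = x$v), class = "frozen_param"))
  if (inherits(x, "nn_bn")) {
    return(structure(list(gamma = x$gamma$v, beta = x$beta$v, rm = x$rm,
                          rv = x$rv, momentum = x$momentum, eps = x$eps),
                     class = "frozen_bn"))
  }
  if (inherits(x, "msc_config") || inherits(x, "mve_config") ||
      inherits(x, "mae_config") || inherits(x, "cot_config")) return(x)
  if (is.list(x)) {
    out <- lapply(x, freeze_model)
    attributes(out) <- attributes(x)
    return(out)
  }
  x
}

thaw_model <- function(x) {
  if (inherits(x, "frozen_param")) return(nn_param(x$v))
  if (inherits(x, "frozen_bn")) {
    st <- bn_new(length(x$gamma), x$momentum, x$eps)
    st$gamma$v <- x$gamma; st$beta$v <- x$beta
    st$rm <- x$rm; st$rv <- x$rv
    return(st)
  }
  if (inherits(x, "msc_config") || inherits(x, "mve_config") ||
      inherits(x, "mae_config") || inherits(x, "cot_config")) return(x)
  if (is.list(x)) {
    out <- lapply(x, thaw_model)
    attributes(out) <- attributes(x)
    return(out)
  }
  x
}

#' Save / load a model checkpoint
#' @param model an `msc_model`
#' @param path checkpoint file (RDS)
#' @export
msc_save <- function(model, path) {
  saveRDS(freeze_model(model), path)
  invisible(path)
}

#' @rdname msc_save
#' @export
msc_load <- function(path) {
  thaw_model(readRDS(path))
}
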