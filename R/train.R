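# Alternating adversarial training of the generator and discriminator,
# per-vertebra reconstruction, spine re-assembly and metric evaluation.

#' Training configuration
#'
#' Defaults follow the published training protocol: 100 epochs, batch size
#' 8, Adam with initial learning rate 1e-4 decaying to one tenth every 20
#' epochs, 120-voxel patches.
#'
#' @param epochs Number of passes over the training pairs.
#' @param batch_size Samples per optimisation step.
#' @param lr Initial learning rate.
#' @param lr_decay_every Decay interval in epochs (default 20).
#' @param lr_decay_factor Multiplicative decay (default 0.1).
#' @param beta1,beta2 Adam moment coefficients (GAN-standard 0.5 / 0.9).
#' @param seed Integer seed governing every source of randomness.
#' @param patch_size Patch edge length S.
#' @param loss_weights A [loss_weights()].
#' @param focal A [focal_params()].
#' @param hausdorff A [hausdorff_params()].
#' @param generator A [generator_config()] (defaults to one matching
#'   `patch_size`).
#' @param discriminator A [discriminator_config()].
#' @param max_steps Optional cap on the total number of optimisation steps.
#' @param ablate Character vector of components to disable: any of
#'   `"centroid"`, `"nonlocal"`, `"dice"`, `"focal_hausdorff"`,
#'   `"adversarial"`.
#' @param device Descriptive device-policy string (single-process CPU
#'   execution; kept for provenance in run manifests).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 8L, lr = 1e-4,
                         lr_decay_every = 20L, lr_decay_factor = 0.1,
                         beta1 = 0.5, beta2 = 0.9, seed = 1L,
                         patch_size = 120L,
                         loss_weights = vertebra3d::loss_weights(),
                         focal = focal_params(),
                         hausdorff = hausdorff_params(),
                         generator = NULL, discriminator = NULL,
                         max_steps = Inf, ablate = character(0),
                         device = "cpu") {
  if (!is_count(epochs) || !is_count(batch_size))
    stopf("epochs and batch_size must be positive integers")
  if (lr <= 0) stopf("lr must be positive")
  bad <- setdiff(ablate, c("centroid", "nonlocal", "dice",
                           "focal_hausdorff", "adversarial"))
  if (length(bad)) stopf("unknown ablation axis: %s", paste(bad, collapse = ", "))
  if (is.null(generator))
    generator <- if (patch_size <= 48) desk_generator_config(patch_size = patch_size)
                 else generator_config(patch_size = patch_size)
  if (is.null(discriminator))
    discriminator <- if (patch_size <= 48)
      desk_discriminator_config(patch_size = patch_size)
    else discriminator_config(patch_size = patch_size)
  if ("centroid" %in% ablate) generator$use_centroid_mask <- FALSE
  if ("nonlocal" %in% ablate) generator$use_nonlocal <- FALSE
  if ("dice" %in% ablate) loss_weights$lambda <- 0
  if ("focal_hausdorff" %in% ablate) {
    loss_weights$beta <- 0
    loss_weights$alpha_w <- 0
  }
  if ("adversarial" %in% ablate) loss_weights$gamma_adv <- 0
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_decay_every = as.integer(lr_decay_every),
                 lr_decay_factor = lr_decay_factor,
                 beta1 = beta1, beta2 = beta2, seed = as.integer(seed),
                 patch_size = as.integer(patch_size),
                 loss_weights = loss_weights, focal = focal,
                 hausdorff = hausdorff, generator = generator,
                 discriminator = discriminator, max_steps = max_steps,
                 ablate = ablate, device = device),
            class = "train_config")
}

#' Desk-scale training preset
#'
#' 32-voxel patches, small networks, batch size 2 — sized so that a few
#' hundred optimisation steps complete in minutes on one CPU core.
#'
#' @param seed Integer seed.
#' @param max_steps Step cap (default 200).
#' @param ... Further overrides passed to [train_config()].
#' @export
desk_train_config <- function(seed = 1L, max_steps = 200L, ...) {
  train_config(epochs = 1000L, batch_size = 2L, patch_size = 32L,
               seed = seed, max_steps = max_steps, ...)
}

# Learning rate at a 1-based epoch index under the step-decay schedule.
lr_at_epoch <- function(config, epoch) {
  config$lr * config$lr_decay_factor^((epoch - 1) %/% config$lr_decay_every)
}

#' Train the generator and discriminator adversarially
#'
#' Per step: the discriminator is updated on (real mask, detached fake)
#' with the least-squares objective, then the generator is updated on the
#' integrated loss (weighted Dice + distance-transform Hausdorff + focal +
#' adversarial).  Deterministic given the seed under single-threaded
#' execution.
#'
#' @param config A [train_config()].
#' @param pairs Nonempty list of [patch_pair()]s with targets.
#' @param checkpoint_dir Optional directory; when given, generator and
#'   discriminator checkpoints are written after every epoch.
#' @param verbose Print a line per epoch.
#' @return List with `generator`, `discriminator` (weight objects) and
#'   `log` (the per-step training log data frame).
#' @export
train <- function(config, pairs, checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  if (!length(pairs)) stopf("training requires a nonempty list of pairs")
  if (any(vapply(pairs, function(p) is.null(p$target), TRUE)))
    stopf("every training pair needs a target volume")
  lw <- config$loss_weights
  use_adv <- lw$gamma_adv > 0
  G <- init_generator(config$generator, seed = config$seed)
  D <- init_discriminator(config$discriminator, seed = config$seed + 1L)
  genv <- list2env(G$params)
  denv <- list2env(D$params)
  g_opt <- adam_init(G$params[trainable_names(G$params)])
  d_opt <- adam_init(D$params[trainable_names(D$params)])
  n <- length(pairs)
  log_rows <- list()
  step <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      if (step >= config$max_steps) break
      lr <- lr_at_epoch(config, epoch)
      order <- sample(n)
      nb <- max(1L, n %/% config$batch_size)
      for (b in seq_len(nb)) {
        if (step >= config$max_steps) break
        step <- step + 1L
        idx <- order[((b - 1L) * config$batch_size) %% n +
                       seq_len(min(config$batch_size, n))]
        idx <- idx[!is.na(idx)]
        batch <- pairs[idx]
        fwd <- lapply(batch, function(p)
          gen_fwd(genv, config$generator, p, training = TRUE))
        # ---- discriminator update (detached fakes) ----
        d_loss <- NA_real_
        if (use_adv) {
          d_grads <- NULL
          d_loss <- 0
          for (i in seq_along(batch)) {
            fr <- disc_fwd(denv, config$discriminator, batch[[i]]$target,
                           training = TRUE)
            ff <- disc_fwd(denv, config$discriminator, fwd[[i]]$out,
                           training = TRUE)
            ls <- lsgan_losses(ff$out, fr$out)
            d_loss <- d_loss + ls$d_loss
            gb_r <- disc_bwd(fr$cache, 2 * (fr$out - 1) / length(fr$out))
            gb_f <- disc_bwd(ff$cache, 2 * ff$out / length(ff$out))
            d_grads <- accumulate_grads(d_grads,
                                        add_grads(gb_r$grads, gb_f$grads))
          }
          d_loss <- d_loss / length(batch)
          d_grads <- scale_grads(d_grads, 1 / length(batch))
          upd <- adam_step(as.list(denv)[names(d_grads)], d_grads, d_opt,
                           lr, config$beta1, config$beta2)
          d_opt <- upd$state
          for (nm in names(upd$params)) denv[[nm]] <- upd$params[[nm]]
        }
        # ---- generator update ----
        g_grads <- NULL
        comp <- c(dice = 0, hausdorff = 0, focal = 0, adv = 0)
        for (i in seq_along(batch)) {
          p <- fwd[[i]]$out
          q <- batch[[i]]$target
          l_dice <- dice_loss(p, q)
          hw <- hausdorff_dt_weight(p, q, config$hausdorff)
          l_haus <- mean((p - q)^2 * hw)
          l_focal <- focal_loss(p, q, config$focal)
          dprob <- lw$lambda * dice_loss_grad(p, q) +
            lw$alpha_w * hausdorff_dt_loss_grad(p, q, hw) +
            lw$beta * focal_loss_grad(p, q, config$focal)
          l_adv <- 0
          if (use_adv) {
            ff <- disc_fwd(denv, config$discriminator, p, training = FALSE)
            l_adv <- mean((ff$out - 1)^2)
            db <- disc_bwd(ff$cache, 2 * (ff$out - 1) / length(ff$out))
            dprob <- dprob + lw$gamma_adv * db$dx
          }
          comp <- comp + c(l_dice, l_haus, l_focal, l_adv)
          g_grads <- accumulate_grads(g_grads, gen_bwd(fwd[[i]]$cache, dprob))
        }
        comp <- comp / length(batch)
        g_grads <- scale_grads(g_grads, 1 / length(batch))
        g_loss <- integrated_loss(comp["dice"], comp["hausdorff"],
                                  comp["focal"], comp["adv"], lw)
        if (!is.finite(g_loss) || (use_adv && !is.finite(d_loss)))
          stopf("training diverged at step %d (non-finite loss)", step)
        upd <- adam_step(as.list(genv)[names(g_grads)], g_grads, g_opt,
                         lr, config$beta1, config$beta2)
        g_opt <- upd$state
        for (nm in names(upd$params)) genv[[nm]] <- upd$params[[nm]]
        log_rows[[step]] <- data.frame(
          epoch = epoch, step = step, lr = lr,
          dice_loss = unname(comp["dice"]),
          hausdorff_loss = unname(comp["hausdorff"]),
          focal_loss = unname(comp["focal"]),
          adv_g_loss = unname(comp["adv"]),
          g_loss = unname(g_loss), d_loss = d_loss)
      }
      if (verbose)
        message(sprintf("epoch %d step %d g_loss %.4f", epoch, step,
                        log_rows[[step]]$g_loss))
      if (!is.null(checkpoint_dir)) {
        if (!dir.exists(checkpoint_dir)) dir.create(checkpoint_dir, TRUE)
        save_checkpoint(rebuild_weights(G, genv),
                        file.path(checkpoint_dir,
                                  sprintf("generator_epoch%03d.rds", epoch)))
        save_checkpoint(rebuild_weights(D, denv),
                        file.path(checkpoint_dir,
                                  sprintf("discriminator_epoch%03d.rds", epoch)))
      }
    }
  })
  list(generator = rebuild_weights(G, genv),
       discriminator = rebuild_weights(D, denv),
       log = do.call(rbind, log_rows))
}

rebuild_weights <- function(tpl, env) {
  tpl$params <- mget(names(tpl$params), envir = env)
  tpl
}

add_grads <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}
accumulate_grads <- function(acc, g) if (is.null(acc)) g else add_grads(acc, g)
scale_grads <- function(g, s) lapply(g, function(x) x * s)

#' Write a training log and run manifest
#'
#' @param result A [train()] result.
#' @param config The [train_config()] used.
#' @param dir Output directory.
#' @return Invisibly, the log CSV path.
#' @export
write_train_log <- function(result, config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  log_path <- file.path(dir, "train_log.csv")
  write.csv(result$log, log_path, row.names = FALSE)
  cfg_flat <- c(epochs = config$epochs, batch_size = config$batch_size,
                lr = config$lr, seed = config$seed,
                patch_size = config$patch_size,
                ablate = paste(config$ablate, collapse = "+"))
  cfg_str <- paste(deparse(config), collapse = "")
  manifest <- c(sprintf("%s: %s", names(cfg_flat), cfg_flat),
                sprintf("config_hash: %d", sum(utf8ToInt(cfg_str)) %% 1000003L))
  writeLines(manifest, file.path(dir, "run_manifest.txt"))
  invisible(log_path)
}

#' Reconstruct a binary vertebra volume
#'
#' Runs the generator and binarises the occupancy probabilities.
#'
#' @param weights A `generator_weights` object.
#' @param pair A [patch_pair()].
#' @param threshold Binarisation threshold in `[0, 1]`, default 0.5.
#' @return Binary 3D array (`S`^3) with attributes `prob` (the probability
#'   volume), `vertebra_label` and `crop_offset`; an all-background result
#'   carries attribute `empty = TRUE`.
#' @export
reconstruct <- function(weights, pair, threshold = 0.5) {
  prob <- generator_forward(pair, weights)
  mask <- (prob >= threshold) * 1
  attr(mask, "prob") <- prob
  attr(mask, "vertebra_label") <- pair$vertebra_label
  attr(mask, "crop_offset") <- pair$crop_offset
  if (!any(mask > 0)) attr(mask, "empty") <- TRUE
  mask
}

#' Assemble reconstructed vertebrae into a labelled spine volume
#'
#' Pastes each vertebra's voxels at its crop offset with its integer
#' label.  Overlapping claims are resolved in favour of the higher
#' generator probability, ties going to the later-indexed vertebra.
#' Windows may partially exceed the canvas (crop windows of edge vertebrae
#' are zero-padded); the outside part is clipped.  A window lying entirely
#' outside the canvas is rejected.
#'
#' @param recons List of entries, each a list with `label` (integer id),
#'   `mask` (binary 3D array), `offset` (1-based voxel triple of the
#'   window's first voxel, possibly negative for zero-padded edge windows)
#'   and optionally `prob` (probability volume; defaults to 1 inside the
#'   mask).
#' @param canvas_shape Integer triple of the output volume extent.
#' @return Integer-labelled 3D array.
#' @export
assemble_spine <- function(recons, canvas_shape) {
  canvas <- array(0L, dim = canvas_shape)
  best <- array(-Inf, dim = canvas_shape)
  for (i in seq_along(recons)) {
    r <- recons[[i]]
    dmm <- dim(r$mask)
    off <- as.integer(r$offset)
    if (any(off > canvas_shape) || any(off + dmm - 1L < 1L))
      stopf("vertebra %d's window lies outside the canvas", i)
    prob <- r$prob
    if (is.null(prob)) prob <- attr(r$mask, "prob")
    if (is.null(prob)) prob <- array(1, dim = dmm)
    sel <- which(r$mask > 0, arr.ind = TRUE)
    if (!nrow(sel)) next
    dst <- sweep(sel, 2, off - 1L, `+`)
    inside <- dst[, 1] >= 1 & dst[, 1] <= canvas_shape[1] &
      dst[, 2] >= 1 & dst[, 2] <= canvas_shape[2] &
      dst[, 3] >= 1 & dst[, 3] <= canvas_shape[3]
    sel <- sel[inside, , drop = FALSE]
    dst <- dst[inside, , drop = FALSE]
    if (!nrow(sel)) next
    pv <- prob[sel]
    win <- pv >= best[dst]
    canvas[dst[win, , drop = FALSE]] <- as.integer(r$label)
    best[dst[win, , drop = FALSE]] <- pv[win]
  }
  canvas
}

#' Evaluate reconstructions against targets
#'
#' Reconstructs every pair, computes Dice, HD95 and NSD per vertebra and
#' appends aggregate rows (overall and per vertebra position: mean and
#' quartiles of Dice, mean HD95/NSD).
#'
#' @param weights A `generator_weights` object (ignored when `predict_fn`
#'   is given).
#' @param pairs List of [patch_pair()]s with targets.
#' @param spacing Voxel spacing (mm) for the surface metrics.
#' @param nsd_tol_mm NSD agreement tolerance in mm.
#' @param threshold Binarisation threshold.
#' @param predict_fn Optional function `pair -> binary volume` replacing
#'   the generator (e.g. an oracle in tests).
#' @return Data frame (`metrics_table`): per-vertebra rows
#'   (`row_type == "vertebra"`) followed by aggregate rows.  Empty
#'   predictions score Dice 0 with HD95/NSD flagged `NA` and are excluded
#'   from surface-distance aggregation.
#' @export
evaluate <- function(weights, pairs, spacing = c(1, 1, 1), nsd_tol_mm = 1,
                     threshold = 0.5, predict_fn = NULL) {
  if (is.null(predict_fn))
    predict_fn <- function(pair) reconstruct(weights, pair, threshold)
  rows <- lapply(pairs, function(p) {
    pred <- predict_fn(p)
    data.frame(row_type = "vertebra", subject_id = p$subject_id,
               vertebra_label = p$vertebra_label,
               dice = dice_coeff(pred, p$target),
               hd95 = hd95(pred, p$target, spacing),
               nsd = nsd(pred, p$target, nsd_tol_mm, spacing),
               dice_q1 = NA_real_, dice_median = NA_real_,
               dice_q3 = NA_real_, stringsAsFactors = FALSE)
  })
  per_v <- do.call(rbind, rows)
  agg_for <- function(d, label) {
    qs <- quantile(d$dice, c(0.25, 0.5, 0.75))
    data.frame(row_type = "aggregate", subject_id = "ALL",
               vertebra_label = label, dice = mean(d$dice),
               hd95 = mean(d$hd95, na.rm = TRUE),
               nsd = mean(d$nsd, na.rm = TRUE),
               dice_q1 = unname(qs[1]), dice_median = unname(qs[2]),
               dice_q3 = unname(qs[3]), stringsAsFactors = FALSE)
  }
  aggs <- lapply(split(per_v, per_v$vertebra_label), function(d)
    agg_for(d, d$vertebra_label[1]))
  out <- rbind(per_v, do.call(rbind, unname(aggs)), agg_for(per_v, "ALL"))
  rownames(out) <- NULL
  class(out) <- c("metrics_table", "data.frame")
  out
}

#' Write a metrics table as CSV
#'
#' @param table A `metrics_table` from [evaluate()].
#' @param path Output CSV path.
#' @export
write_metrics_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Run the ablation grid
#'
#' Trains one variant per requested ablation axis (plus the full model)
#' under a shared configuration and evaluates each on held-out pairs.
#'
#' @param config Base [train_config()].
#' @param train_pairs,test_pairs Lists of [patch_pair()]s.
#' @param ablations Character vector of axes (default all five).
#' @return Named list, one entry per variant, each with `log` and
#'   `metrics`.
#' @export
run_ablation_grid <- function(config, train_pairs, test_pairs,
                              ablations = c("centroid", "nonlocal", "dice",
                                            "focal_hausdorff",
                                            "adversarial")) {
  variants <- c(list(full = character(0)),
                setNames(as.list(ablations), ablations))
  lapply(variants, function(ab) {
    cfg <- train_config(epochs = config$epochs,
                        batch_size = config$batch_size, lr = config$lr,
                        lr_decay_every = config$lr_decay_every,
                        lr_decay_factor = config$lr_decay_factor,
                        beta1 = config$beta1, beta2 = config$beta2,
                        seed = config$seed, patch_size = config$patch_size,
                        loss_weights = config$loss_weights,
                        focal = config$focal, hausdorff = config$hausdorff,
                        max_steps = config$max_steps, ablate = ab)
    res <- train(cfg, train_pairs)
    list(log = res$log,
         metrics = evaluate(res$generator, test_pairs))
  })
}
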