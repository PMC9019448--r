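# Two-stage training: stage 1 fits the intraslice 2D network on slices;
# stage 2 freezes it and fits the 3D DenseUNet plus fusion head on volume
# patches. Ablation modes: "A" (2D only), "A+B" (2D probabilities + 3D
# network with its auxiliary head), "A+B+C" (full hybrid with HFF).

#' Training configuration
#'
#' Optimiser defaults follow the published recipe: SGD with initial learning
#' rate 0.008, weight decay 0.00005 and momentum 0.9; data expansion by
#' random scaling in 0.8-1.2 and random flips.
#'
#' @param lr learning rate.
#' @param weight_decay L2 penalty.
#' @param momentum SGD momentum.
#' @param batch_slices slices per stage-1 minibatch.
#' @param max_epochs epoch cap.
#' @param max_steps optional hard cap on gradient steps (overrides epochs).
#' @param patience early-stopping patience on validation DSC, in epochs.
#' @param augment apply random scaling (`scale_range`) and flips.
#' @param scale_range augmentation scale range.
#' @param patch_shape stage-2 patch size (H, W, D); H, W divisible by 32,
#'   D by 4.
#' @param ablation_mode one of "A", "A+B", "A+B+C".
#' @param fg_patch_prob probability that a stage-2 patch is centred on
#'   foreground (the structure occupies well under 1% of voxels, so uniform
#'   patches would rarely see it).
#' @param seed integer; seeds weight init, shuffling and augmentation.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 0.008, weight_decay = 5e-5, momentum = 0.9,
                         batch_slices = 16L, max_epochs = 100L,
                         max_steps = NULL, patience = 15L,
                         augment = TRUE, scale_range = c(0.8, 1.2),
                         patch_shape = c(224L, 224L, 8L),
                         ablation_mode = c("A+B+C", "A+B", "A"),
                         fg_patch_prob = 0.9, seed = 1L) {
  ablation_mode <- match.arg(ablation_mode)
  structure(list(optimizer = "sgd", lr = lr, weight_decay = weight_decay,
                 momentum = momentum, batch_slices = as.integer(batch_slices),
                 max_epochs = as.integer(max_epochs),
                 max_steps = if (!is.null(max_steps)) as.integer(max_steps),
                 patience = as.integer(patience), augment = isTRUE(augment),
                 scale_range = scale_range,
                 patch_shape = as.integer(patch_shape),
                 ablation_mode = ablation_mode,
                 fg_patch_prob = fg_patch_prob, seed = as.integer(seed)),
            class = "train_config")
}

normalize_cases <- function(cases) {
  lapply(cases, function(cs) {
    if (!cs$volume$normalized) cs$volume <- window_normalize(cs$volume)
    cs
  })
}

split_cases <- function(cases, split) {
  Filter(function(cs) cs$split == split, cases)
}

# gather every (slice, label) pair of the given cases
collect_slices <- function(cases) {
  out <- list()
  for (cs in cases) {
    d <- dim(cs$volume$data)
    for (k in seq_len(d[3])) {
      out[[length(out) + 1L]] <- list(x = cs$volume$data[, , k],
                                      y = cs$mask$labels[, , k])
    }
  }
  out
}

onehot5 <- function(labels_hw1n, n_classes = 2L) {
  d <- dim(labels_hw1n)  # H,W,1,N (or H,W,D,N)
  y <- array(0, c(d[1], d[2], d[3], n_classes, d[4]))
  y[, , , 1, ] <- 1 - labels_hw1n
  y[, , , 2, ] <- labels_hw1n
  y
}

predict_slices_2d <- function(net, vol_arr) {
  d <- dim(vol_arr)
  slices <- aperm(array(vol_arr, c(d, 1L)), c(3, 1, 2, 4))
  out <- ag_no_grad(forward_2d(net, feature_stack(slices, "slices"), FALSE))
  lv <- t5(ag_val(out$logits5))               # H,W,1,C,N
  probs <- softmax_channels(lv)
  array(as.integer(probs[, , 1, 2, ] > 0.5), d)
}

#' Train stage 1: the intraslice 2D network
#'
#' Trains the 2D network alone with class-weighted cross-entropy on all
#' slices of the training split, tracking per-epoch loss and validation DSC,
#' with early stopping; the best-validation state is kept.
#'
#' @param cases list of cases (see [load_dataset()]); a case is
#'   `list(case_id, volume, mask, split)`. Volumes in HU are windowed
#'   automatically.
#' @param cfg a [train_config()].
#' @param net_cfg a [net2d_config()].
#' @return a checkpoint: `list(type = "net2d", net_cfg, in_channels, cfg,
#'   class_weights, state, log)` where `log` has per-epoch loss and val DSC.
#' @export
train_stage1_2d <- function(cases, cfg = train_config(), net_cfg = net2d_config()) {
  set.seed(cfg$seed)
  cases <- normalize_cases(cases)
  train <- split_cases(cases, "train")
  val <- split_cases(cases, "val")
  if (length(train) == 0) stop("train_stage1_2d: empty training split")
  w <- class_weights_from_masks(lapply(train, `[[`, "mask"))
  net <- net2d_new(net_cfg, in_channels = 1L)
  params <- collect_params(net)
  opt <- sgd_new(params, cfg$lr, cfg$momentum, cfg$weight_decay)
  pool <- collect_slices(train)
  nb <- cfg$batch_slices
  steps_per_epoch <- max(1L, ceiling(length(pool) / nb))
  log <- data.frame()
  best <- list(dsc = -Inf, state = NULL, epoch = 0L)
  total_steps <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    order_ <- sample.int(length(pool))
    losses <- c()
    for (s in seq_len(steps_per_epoch)) {
      idx <- order_[((s - 1L) * nb + 1L):min(s * nb, length(pool))]
      batch <- pool[idx]
      if (cfg$augment) {
        batch <- lapply(batch, function(b) {
          a <- augment(array(b$x, c(dim(b$x), 1L)), array(b$y, c(dim(b$y), 1L)),
                       scale_range = cfg$scale_range, flip = c(TRUE, TRUE, FALSE))
          list(x = a$patch[, , 1], y = a$patch_mask[, , 1])
        })
      }
      d2 <- dim(batch[[1]]$x)
      xs <- array(0, c(length(batch), d2[1], d2[2], 1L))
      yb <- array(0, c(d2[1], d2[2], 1L, length(batch)))
      for (i in seq_along(batch)) {
        xs[i, , , 1] <- batch[[i]]$x
        yb[, , 1, i] <- batch[[i]]$y
      }
      ag_tape_start()
      out <- forward_2d(net, feature_stack(xs, "slices"), training = TRUE)
      loss <- op_wce_logits(out$logits5, onehot5(yb), w)
      lval <- ag_val(loss)
      ag_backward(loss)
      sgd_step(opt)
      losses <- c(losses, lval)
      total_steps <- total_steps + 1L
      if (!is.null(cfg$max_steps) && total_steps >= cfg$max_steps) break
    }
    val_dsc <- if (length(val) > 0) {
      mean(vapply(val, function(cs) {
        dsc(predict_slices_2d(net, cs$volume$data), cs$mask$labels)
      }, numeric(1)))
    } else NA_real_
    log <- rbind(log, data.frame(epoch = epoch, loss = mean(losses),
                                 val_dsc = val_dsc))
    track <- if (is.na(val_dsc)) -log$loss[nrow(log)] else val_dsc
    if (track > best$dsc) {
      best <- list(dsc = track, state = net_state(net), epoch = epoch)
    }
    if (!is.null(cfg$max_steps) && total_steps >= cfg$max_steps) break
    if (epoch - best$epoch >= cfg$patience) break
  }
  if (!is.null(best$state)) net_load_state(net, best$state)
  list(type = "net2d", net_cfg = net_cfg, in_channels = 1L, cfg = cfg,
       class_weights = w, state = net_state(net), log = log)
}

# sample one training patch, biased towards containing foreground
sample_patch <- function(cs, patch_shape, fg_prob) {
  d <- dim(cs$volume$data)
  ps <- pmin(patch_shape, d)
  m <- cs$mask$labels
  if (runif(1) < fg_prob && sum(m) > 0) {
    fg <- which(m == 1L, arr.ind = TRUE)
    ctr <- fg[sample.int(nrow(fg), 1L), ]
    lo <- pmin(pmax(ctr - ps %/% 2L, 1L), d - ps + 1L)
  } else {
    lo <- 1L + vapply(1:3, function(a) sample.int(d[a] - ps[a] + 1L, 1L) - 1L,
                      integer(1))
  }
  sel <- lapply(1:3, function(a) lo[a] + seq_len(ps[a]) - 1L)
  list(x = cs$volume$data[sel[[1]], sel[[2]], sel[[3]], drop = FALSE],
       y = m[sel[[1]], sel[[2]], sel[[3]], drop = FALSE])
}

#' Train stage 2: the 3D DenseUNet and fusion head
#'
#' Restores the stage-1 2D network and freezes it; trains the 3D network
#' (and, in mode "A+B+C", the HFF head) with class-weighted cross-entropy on
#' foreground-biased volume patches. In mode "A+B" the HFF head is bypassed
#' and the 3D network's auxiliary 2-class head provides the logits.
#'
#' @param cases list of cases (see [train_stage1_2d()]).
#' @param net2d_ckpt stage-1 checkpoint.
#' @param cfg a [train_config()]; `cfg$ablation_mode` selects "A+B" or
#'   "A+B+C".
#' @param net3d_cfg a [densunet3d_config()].
#' @param hff_cfg an [hff_config()].
#' @return a checkpoint: `list(type = "hybrid", ..., state, log)`.
#' @export
train_stage2_3d_hff <- function(cases, net2d_ckpt, cfg = train_config(),
                                net3d_cfg = densunet3d_config(),
                                hff_cfg = hff_config()) {
  if (is.null(net2d_ckpt$state)) stop("train_stage2_3d_hff: missing stage-1 checkpoint")
  mode <- cfg$ablation_mode
  if (mode == "A") stop("train_stage2_3d_hff: mode A has no stage 2; use the stage-1 model")
  set.seed(cfg$seed + 1L)
  cases <- normalize_cases(cases)
  train <- split_cases(cases, "train")
  if (length(train) == 0) stop("train_stage2_3d_hff: empty training split")
  w <- net2d_ckpt$class_weights %||% class_weights_from_masks(lapply(train, `[[`, "mask"))
  n2 <- net2d_new(net2d_ckpt$net_cfg, net2d_ckpt$in_channels)
  net_load_state(n2, net2d_ckpt$state)
  n3 <- densunet3d_new(net3d_cfg, in_channels = 2L)
  hf <- hff_new(hff_cfg)
  model <- hybrid_model(n2, n3, hf)
  params <- c(collect_params(n3), if (mode == "A+B+C") collect_params(hf))
  opt <- sgd_new(params, cfg$lr, cfg$momentum, cfg$weight_decay)
  n_steps <- cfg$max_steps %||% (cfg$max_epochs * length(train))
  log <- data.frame()
  for (step in seq_len(n_steps)) {
    cs <- train[[sample.int(length(train), 1L)]]
    p <- sample_patch(cs, cfg$patch_shape, cfg$fg_patch_prob)
    if (cfg$augment) {
      a <- augment(p$x, p$y, scale_range = cfg$scale_range)
      p <- list(x = a$patch, y = a$patch_mask)
    }
    ag_tape_start()
    out <- hybrid_forward(model, p$x, training = TRUE, freeze_2d = TRUE,
                          mode = mode)
    y5 <- onehot5(array(p$y, c(dim(p$y), 1L)))
    loss <- op_wce_logits(out$logits5, y5, w)
    lval <- ag_val(loss)
    ag_backward(loss)
    sgd_step(opt)
    log <- rbind(log, data.frame(step = step, loss = lval))
  }
  list(type = "hybrid", mode = mode,
       net2d_cfg = net2d_ckpt$net_cfg, in_channels2d = net2d_ckpt$in_channels,
       net3d_cfg = net3d_cfg, hff_cfg = hff_cfg, cfg = cfg, class_weights = w,
       state = list(net2d = net_state(n2), net3d = net_state(n3),
                    hff = net_state(hf)),
       log = log)
}

#' Rebuild a model from a checkpoint
#'
#' Checkpoints embed their configurations, so the model is reconstructed
#' structurally and the stored parameters are loaded back.
#'
#' @param ckpt checkpoint from [train_stage1_2d()], [train_stage2_3d_hff()]
#'   or [load_checkpoint()].
#' @return a `net2d` or `hybrid_model`.
#' @export
restore_model <- function(ckpt) {
  if (ckpt$type == "net2d") {
    net <- net2d_new(ckpt$net_cfg, ckpt$in_channels)
    net_load_state(net, ckpt$state)
    return(net)
  }
  if (ckpt$type == "hybrid") {
    n2 <- net2d_new(ckpt$net2d_cfg, ckpt$in_channels2d)
    net_load_state(n2, ckpt$state$net2d)
    n3 <- densunet3d_new(ckpt$net3d_cfg, in_channels = 2L)
    net_load_state(n3, ckpt$state$net3d)
    hf <- hff_new(ckpt$hff_cfg)
    net_load_state(hf, ckpt$state$hff)
    return(hybrid_model(n2, n3, hf))
  }
  stop("restore_model: unknown checkpoint type ", ckpt$type)
}

#' Save / load a checkpoint
#' @param ckpt checkpoint list.
#' @param path file path (RDS).
#' @return `path` / the checkpoint.
#' @export
save_checkpoint <- function(ckpt, path) {
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

# predict a mask for one case under a given ablation mode
predict_case <- function(model, cs, patch_shape, mode) {
  vol <- if (cs$volume$normalized) cs$volume else window_normalize(cs$volume)
  if (mode == "A") {
    net <- if (inherits(model, "hybrid_model")) model$net2d else model
    predict_volume_2d(vol, net)
  } else {
    # overlap-averaged prediction (half-patch stride)
    predict_volume(vol, model, patch_shape, pmax(patch_shape %/% 2L, 1L),
                   mode = mode)
  }
}

#' Run the three-way ablation and tabulate segmentation performance
#'
#' Trains mode A (stage 1 only) once, then stage 2 twice (modes "A+B" and
#' "A+B+C") from the same stage-1 checkpoint, evaluates all three on the
#' requested split and reports DSC (%), ASD (mm) and AVD (mm) per mode.
#'
#' @param cases list of cases with train/val/test splits.
#' @param cfg a [train_config()].
#' @param net2d_cfg,net3d_cfg,hff_cfg network configurations.
#' @param eval_split which split to evaluate ("test"; falls back to "train"
#'   for overfit-style runs if the split is empty).
#' @return list with `table` (3 x 4 data.frame: method, dsc_pct, asd_mm,
#'   avd_mm) and the three checkpoints.
#' @export
run_ablation <- function(cases, cfg = train_config(),
                         net2d_cfg = net2d_config(),
                         net3d_cfg = densunet3d_config(),
                         hff_cfg = hff_config(),
                         eval_split = "test") {
  ck1 <- train_stage1_2d(cases, cfg, net2d_cfg)
  cfg_ab <- cfg; cfg_ab$ablation_mode <- "A+B"
  ck2 <- train_stage2_3d_hff(cases, ck1, cfg_ab, net3d_cfg, hff_cfg)
  cfg_abc <- cfg; cfg_abc$ablation_mode <- "A+B+C"
  ck3 <- train_stage2_3d_hff(cases, ck1, cfg_abc, net3d_cfg, hff_cfg)
  eval_cases <- split_cases(normalize_cases(cases), eval_split)
  if (length(eval_cases) == 0) eval_cases <- split_cases(normalize_cases(cases), "train")
  models <- list(A = restore_model(ck1), `A+B` = restore_model(ck2),
                 `A+B+C` = restore_model(ck3))
  rows <- lapply(names(models), function(mode) {
    preds <- lapply(eval_cases, function(cs) {
      predict_case(models[[mode]], cs, cfg$patch_shape, mode)
    })
    rep_ <- metrics_report(preds, lapply(eval_cases, `[[`, "mask"))
    m <- rep_[rep_$case_id == "mean", ]
    data.frame(method = mode, dsc_pct = 100 * m$dsc, asd_mm = m$asd_mm,
               avd_mm = m$avd_mm, stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows),
       checkpoints = list(A = ck1, `A+B` = ck2, `A+B+C` = ck3))
}
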