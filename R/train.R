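#' Training configuration
#'
#' @param epochs number of passes over the training split (>= 1).
#' @param batch_size scenes per optimizer step (gradient accumulation).
#' @param lr base Adam learning rate; decayed x0.1 at 60% and 85% of the
#'   epoch budget.
#' @param backbone,input_size network architecture (see [build_net()]).
#' @param flip_augment random horizontal/vertical flips (the defocus
#'   patterns are radially symmetric and z is flip-invariant).
#' @param dilate_targets supervise the offset/depth heads on the 3x3
#'   neighbourhood of each center cell (offsets re-expressed per cell), so
#'   peaks decoded one cell off the truth still reconstruct exact
#'   coordinates and calibrated depth.
#' @param ema_decay exponential-moving-average decay for the evaluated
#'   weights (per optimizer step); small-batch trajectories are noisy and
#'   the averaged weights are the ones evaluated and checkpointed.  Set 0
#'   to evaluate the raw weights.
#' @param loss a [loss_weights()].
#' @param gate_um,score_threshold evaluation-time matching gate (um) and
#'   detection threshold.
#' @param seed training seed (shuffling, augmentation, initialization).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 60L, batch_size = 4L, lr = 1e-3,
                         backbone = "tiny", input_size = 256L,
                         flip_augment = TRUE, dilate_targets = TRUE,
                         ema_decay = 0.995, loss = loss_weights(),
                         gate_um = 2, score_threshold = 0.3, seed = 1L) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (input_size %% 32L != 0L) stop("input_size must be divisible by 32")
  stopifnot(batch_size >= 1, lr > 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, backbone = backbone, input_size = as.integer(input_size),
                 flip_augment = isTRUE(flip_augment),
                 dilate_targets = isTRUE(dilate_targets),
                 ema_decay = ema_decay, loss = loss,
                 gate_um = gate_um, score_threshold = score_threshold,
                 seed = as.integer(seed)),
            class = "train_config")
}

# rescale annotation coordinates when the image is resized to the net input
scale_annotations <- function(ann, from_size, to_size) {
  if (from_size != to_size) {
    f <- to_size / from_size
    ann$x_px <- (ann$x_px + 0.5) * f - 0.5
    ann$y_px <- (ann$y_px + 0.5) * f - 0.5
  }
  ann
}

# Train-time label dilation: supervise the offset and depth heads on the
# 3x3 neighbourhood of each center cell, with the offset re-expressed
# relative to each neighbour (so a peak decoded one cell off still
# reconstructs the exact sub-pixel center and a calibrated depth).  True
# center cells take priority over neighbour writes; neighbour collisions
# keep the first (arbitrary but deterministic) writer.
dilate_regression_targets <- function(maps) {
  mask <- maps$center_mask
  Hs <- nrow(mask); Ws <- ncol(mask)
  centers <- which(mask, arr.ind = TRUE)
  if (!nrow(centers)) return(maps)
  out <- maps
  for (r in seq_len(nrow(centers))) {
    cy <- centers[r, 1]; cx <- centers[r, 2]
    ox <- maps$offset[cy, cx, 1]; oy <- maps$offset[cy, cx, 2]
    d <- maps$depth[cy, cx]
    for (dy in -1:1) for (dx in -1:1) {
      ny <- cy + dy; nx <- cx + dx
      if (ny < 1 || ny > Hs || nx < 1 || nx > Ws) next
      if (mask[ny, nx] || out$center_mask[ny, nx]) next
      out$offset[ny, nx, 1] <- ox - dx
      out$offset[ny, nx, 2] <- oy - dy
      out$depth[ny, nx] <- d
      out$center_mask[ny, nx] <- TRUE
    }
  }
  out
}

flip_record <- function(image, ann, fh, fv) {
  n <- nrow(image)
  if (fh) {
    image <- image[, n:1]
    if (nrow(ann)) ann$x_px <- (n - 1) - ann$x_px
  }
  if (fv) {
    image <- image[n:1, ]
    if (nrow(ann)) ann$y_px <- (n - 1) - ann$y_px
  }
  list(image = image, ann = ann)
}

#' Train the localization network on a composed dataset
#'
#' Full-batch-free training loop: scenes are shuffled each epoch (seeded),
#' gradients are accumulated over `batch_size` scenes and applied with
#' Adam, the learning rate decays x0.1 at 60% and 85% of the epoch budget,
#' and the evaluation split is scored after every epoch.  The checkpoint
#' with the best evaluation score (horizontal + vertical MAE, um) is
#' retained alongside the final state.  Identical seeds reproduce the loss
#' history exactly on one device.  A non-finite loss aborts training and
#' returns the last finite state with a warning.
#'
#' @param manifest dataset manifest from [build_dataset()] /
#'   [read_manifest()].
#' @param config a [train_config()].
#' @param eval_split evaluation split name (`NULL` to skip evaluation; the
#'   final state is then the retained one).
#' @param out_dir optional run directory; if given, `checkpoint_best.rds`,
#'   `checkpoint_last.rds` and `history.csv` are written there.
#' @param verbose print one line per epoch.
#' @return List with `net` (best), `net_last`, `history` (data.frame),
#'   `best_epoch`.
#' @export
train <- function(manifest, config = train_config(), eval_split = "eval",
                  out_dir = NULL, verbose = FALSE) {
  records <- load_split(manifest, "train")
  if (!length(records)) stop("training split is empty")
  eval_records <- if (!is.null(eval_split) &&
                      !is.null(manifest$splits[[eval_split]]))
    load_split(manifest, eval_split)
  optical <- do.call(optical_config, manifest$optical)
  classes <- lapply(manifest$bead_classes, function(b)
    bead_class(b$label, b$radius_um, b$patch_size_px, b$pattern))
  names(classes) <- vapply(classes, `[[`, "", "label")
  net <- build_net(config$backbone, config$input_size, classes, optical,
                   seed = config$seed)
  S <- net$meta$stride
  px_scale <- optical$pixel_scale_um

  # cache resized images and input-frame annotations
  prep <- lapply(records, function(rec) {
    list(image = resize_bilinear(rec$image, config$input_size),
         ann = scale_annotations(rec$annotations, nrow(rec$image),
                                 config$input_size))
  })

  state <- adam_new(net$params)
  use_ema <- config$ema_decay > 0
  ema <- if (use_ema) net$params
  history <- list()
  best <- list(score = Inf, params = net$params, epoch = 0L)
  decay_at <- ceiling(config$epochs * c(0.6, 0.85))
  aborted <- FALSE

  for (epoch in seq_len(config$epochs)) {
    lr <- config$lr * 0.1^sum(epoch > decay_at)
    ep_seed <- substream_seed(config$seed, sprintf("epoch/%d", epoch))
    plan_draws <- with_seed(ep_seed, {
      ord <- sample.int(length(prep))
      flips <- if (config$flip_augment)
        matrix(runif(2 * length(prep)) < 0.5, ncol = 2) else
        matrix(FALSE, length(prep), 2)
      list(ord = ord, flips = flips)
    })
    ep_losses <- c(total = 0, heat = 0, off = 0, depth = 0)
    batch_acc <- NULL; in_batch <- 0L
    for (t in seq_along(plan_draws$ord)) {
      i <- plan_draws$ord[t]
      fr <- flip_record(prep[[i]]$image, prep[[i]]$ann,
                        plan_draws$flips[t, 1], plan_draws$flips[t, 2])
      target <- encode_targets(fr$ann, config$input_size, S, classes, optical)
      if (config$dilate_targets) target <- dilate_regression_targets(target)
      out <- net_forward(net, fr$image, cache = TRUE)
      ls <- total_loss(out$raw, target, config$loss, grads = TRUE)
      if (!is.finite(ls$total)) {
        warning("non-finite loss at epoch ", epoch, "; aborting with last finite state")
        aborted <- TRUE
        break
      }
      ep_losses <- ep_losses +
        c(ls$total, ls$heat, ls$off, ls$depth) / length(prep)
      hg <- setNames(
        list(ls$grads$heat_logits, ls$grads$offset, ls$grads$depth),
        as.character(unlist(net$plan$outputs)))
      g <- net_graph_backward(net$plan, net$params, out$fwd, hg)
      batch_acc <- grads_axpy(batch_acc, g, 1 / config$batch_size)
      in_batch <- in_batch + 1L
      if (in_batch == config$batch_size || t == length(plan_draws$ord)) {
        upd <- adam_step(net$params, batch_acc, state, lr)
        net$params <- upd$params; state <- upd$state
        if (use_ema) {
          d <- config$ema_decay
          for (id in seq_along(ema)) {
            if (is.null(ema[[id]])) next
            ema[[id]]$W <- d * ema[[id]]$W + (1 - d) * net$params[[id]]$W
            ema[[id]]$b <- d * ema[[id]]$b + (1 - d) * net$params[[id]]$b
          }
        }
        batch_acc <- NULL; in_batch <- 0L
      }
    }
    if (aborted) break
    row <- data.frame(epoch = epoch, lr = lr, loss_total = ep_losses[1],
                      loss_heat = ep_losses[2], loss_off = ep_losses[3],
                      loss_depth = ep_losses[4],
                      eval_h_mae_um = NA_real_, eval_v_mae_um = NA_real_,
                      matched = NA_integer_, missed = NA_integer_,
                      spurious = NA_integer_)
    net_eval <- net
    if (use_ema) net_eval$params <- ema
    if (!is.null(eval_records)) {
      rep <- evaluate_records(net_eval, eval_records, px_scale,
                              gate_px = config$gate_um / px_scale,
                              score_threshold = config$score_threshold,
                              z_min = optical$z_min, z_max = optical$z_max)
      row$eval_h_mae_um <- rep$horizontal_mae_um
      row$eval_v_mae_um <- rep$vertical_mae_um
      row$matched <- rep$n_matched; row$missed <- rep$n_missed
      row$spurious <- rep$n_spurious
      score <- if (rep$undefined) Inf else
        rep$horizontal_mae_um + rep$vertical_mae_um +
        (rep$n_missed + rep$n_spurious) / max(1, rep$n_matched)
      if (score < best$score)
        best <- list(score = score, params = net_eval$params, epoch = epoch)
    }
    history[[epoch]] <- row
    if (verbose)
      message(sprintf(
        "epoch %3d  loss %.4f (heat %.4f off %.4f depth %.4f)  eval h %.3f v %.3f um",
        epoch, row$loss_total, row$loss_heat, row$loss_off, row$loss_depth,
        row$eval_h_mae_um, row$eval_v_mae_um))
  }
  history <- do.call(rbind, history)
  net_last <- net
  if (use_ema) net_last$params <- ema
  net_best <- net_last
  if (is.finite(best$score)) net_best$params <- best$params
  rownames(history) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_checkpoint(net_best, file.path(out_dir, "checkpoint_best.rds"))
    save_checkpoint(net_last, file.path(out_dir, "checkpoint_last.rds"))
    write.csv(history, file.path(out_dir, "history.csv"), row.names = FALSE)
  }
  list(net = net_best, net_last = net_last, history = history,
       best_epoch = if (is.finite(best$score)) best$epoch else nrow(history))
}
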