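# Model fitting: the bilight() entry point wires dataset splitting, feature
# extraction through the frozen backbones, per-epoch stain jitter, AdamW
# with the warmup-cosine schedule, early stopping on validation loss with
# best-weight restoration, and history logging.

#' Training configuration
#'
#' Defaults follow the reference protocol: batch size 16, AdamW at peak
#' learning rate 5e-4 with decoupled weight decay 1e-4, 3 warmup epochs of
#' a 100-epoch warmup-cosine horizon capped at 1500 steps per epoch,
#' dropout 0.30, label smoothing 0, early stopping with patience 8 on
#' validation loss, stratified 80/10/10 split, and soft H&E stain jitter on
#' training tiles only.
#'
#' @param backbone_a,backbone_b Registered backbone names.
#' @param input_size Network input side length (default 224).
#' @param batch_size Mini-batch size (default 16).
#' @param epochs Maximum number of epochs to run (default 100).
#' @param schedule_epochs Horizon of the warmup-cosine schedule in epochs
#'   (default 100, independent of how long training actually runs, so that
#'   short runs under the reference protocol keep its learning-rate
#'   trajectory).
#' @param warmup_epochs Linear warmup duration (default 3).
#' @param steps_cap Maximum optimizer steps per epoch (default 1500).
#' @param lr Peak learning rate (default 5e-4).
#' @param weight_decay Decoupled weight decay (default 1e-4).
#' @param dropout Head dropout rate (default 0.30).
#' @param label_smoothing Cross-entropy smoothing (default 0).
#' @param patience Early-stopping patience in epochs (default 8).
#' @param split Train/validation/test fractions (default 0.8/0.1/0.1).
#' @param jitter Stain-jitter ranges ([jitter_ranges()]) or `NULL` to
#'   disable augmentation.
#' @param seed Master seed for splitting, initialization, shuffling,
#'   dropout and jitter.
#' @param checkpoint_dir Directory for best-weight checkpoints and the run
#'   log, or `NULL`.
#' @return Named list of class `bilight_config`.
#' @export
bilight_config <- function(backbone_a = "effnetv2_b0",
                           backbone_b = "mobilenetv3_small",
                           input_size = 224L, batch_size = 16L,
                           epochs = 100L, schedule_epochs = 100L,
                           warmup_epochs = 3L,
                           steps_cap = 1500L, lr = 5e-4,
                           weight_decay = 1e-4, dropout = 0.30,
                           label_smoothing = 0, patience = 8L,
                           split = c(0.8, 0.1, 0.1),
                           jitter = jitter_ranges(), seed = 42L,
                           checkpoint_dir = NULL) {
  cfg <- list(backbone_a = backbone_a, backbone_b = backbone_b,
              input_size = as.integer(input_size),
              batch_size = as.integer(batch_size),
              epochs = as.integer(epochs),
              schedule_epochs = as.integer(max(schedule_epochs, epochs)),
              warmup_epochs = as.integer(warmup_epochs),
              steps_cap = as.integer(steps_cap), lr = lr,
              weight_decay = weight_decay, dropout = dropout,
              label_smoothing = label_smoothing,
              patience = as.integer(patience), split = split,
              jitter = jitter, seed = as.integer(seed),
              checkpoint_dir = checkpoint_dir)
  stopifnot(cfg$batch_size >= 1, cfg$epochs >= 1,
            cfg$warmup_epochs >= 1, cfg$lr > 0, cfg$weight_decay >= 0,
            cfg$dropout >= 0, cfg$dropout < 1, cfg$patience >= 1,
            abs(sum(cfg$split) - 1) < 1e-8)
  structure(cfg, class = "bilight_config")
}

# features for a list of in-memory tiles, with optional per-tile jitter
extract_split_features <- function(model, imgs, cfg, jitter_seeds = NULL) {
  if (!is.null(jitter_seeds))
    imgs <- lapply(seq_along(imgs), function(i)
      jitter_tile(imgs[[i]], cfg$jitter, seed = jitter_seeds[i]))
  list(FA = extract_features(imgs, model$backbone_a),
       FB = extract_features(imgs, model$backbone_b))
}

load_split <- function(manifest, cfg)
  lapply(manifest$path, load_tile, input_size = cfg$input_size)

slice4 <- function(F4, idx) F4[idx, , , , drop = FALSE]

eval_on_features <- function(par, FA, FB, y, smoothing) {
  fw <- head_forward(par, FA, FB, training = FALSE,
                     label_smoothing = smoothing, labels = y)
  list(loss = fw$loss, acc = mean(max.col(fw$probs) == y), probs = fw$probs)
}

#' Fit the dual-branch classifier
#'
#' End-to-end fit from a class-per-folder image directory (or a manifest
#' data frame): stratified split, frozen-backbone feature extraction,
#' trainable-head optimization with AdamW under the warmup-cosine schedule,
#' per-epoch stain jitter on training tiles, early stopping on validation
#' loss (best weights restored), and a per-epoch history log. Identically
#' seeded runs on identical data produce identical splits, histories and
#' weights.
#'
#' @param data Dataset directory, manifest CSV path, or manifest data
#'   frame (columns `path`, `class`).
#' @param config A [bilight_config()].
#' @param verbose Print per-epoch progress.
#' @return An object of class `bilight`: the fitted model, history,
#'   splits, and configuration.
#' @export
bilight <- function(data, config = bilight_config(), verbose = FALSE) {
  manifest <- if (is.character(data)) read_manifest(data) else data
  stopifnot(all(c("path", "class") %in% names(manifest)))
  classes <- sort(unique(manifest$class))
  splits <- split_dataset(manifest, config$split, config$seed)
  model <- bilight_model(config$backbone_a, config$backbone_b,
                         input_size = config$input_size, classes = classes,
                         dropout = config$dropout,
                         label_smoothing = config$label_smoothing,
                         seed = config$seed)
  fit <- with_seed(config$seed, function()
    train_loop(model, splits, config, verbose))
  structure(list(model = fit$model, history = fit$history, splits = splits,
                 config = config, classes = classes,
                 best_epoch = fit$best_epoch),
            class = "bilight")
}

train_loop <- function(model, splits, cfg, verbose = FALSE) {
  classes <- model$classes
  y_tr <- match(splits$train$class, classes)
  y_va <- match(splits$val$class, classes)
  n_tr <- length(y_tr)
  stopifnot(n_tr > 0, length(y_va) > 0)
  spe <- min(ceiling(n_tr / cfg$batch_size), cfg$steps_cap)
  sched <- schedule_config(cfg$lr, warmup_steps = cfg$warmup_epochs * spe,
                           total_steps = max(cfg$schedule_epochs,
                                             cfg$warmup_epochs + 1L) * spe,
                           weight_decay = cfg$weight_decay)
  par <- model$par
  state <- adamw_init(par)
  imgs_tr <- load_split(splits$train, cfg)
  # validation features are fixed (never jittered): extract once
  vf <- extract_split_features(model, load_split(splits$val, cfg), cfg)
  # clean (unjittered) training features, used for the precise-BN pass so
  # evaluation statistics match the un-augmented inference distribution
  tf_clean <- extract_split_features(model, imgs_tr, cfg)
  tf_cached <- if (is.null(cfg$jitter)) tf_clean
  history <- NULL
  best <- list(loss = Inf, par = par, epoch = 0L)
  since_best <- 0L
  step <- 0L
  if (!is.null(cfg$checkpoint_dir))
    dir.create(cfg$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n_tr)
    tf <- if (is.null(cfg$jitter)) tf_cached else
      extract_split_features(model, imgs_tr, cfg,
                             jitter_seeds = mix_seed(cfg$seed, epoch) +
                               seq_len(n_tr))
    losses <- accs <- numeric(0)
    lr <- 0
    for (b in seq_len(spe)) {
      idx <- ord[((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size, n_tr)]
      FA <- slice4(tf$FA, idx); FB <- slice4(tf$FB, idx)
      yb <- y_tr[idx]
      fw <- head_forward(par, FA, FB, training = TRUE, dropout = cfg$dropout,
                         label_smoothing = cfg$label_smoothing, labels = yb)
      Ys <- onehot(yb, length(classes)) * (1 - cfg$label_smoothing) +
        cfg$label_smoothing / length(classes)
      dLOG <- (fw$probs - Ys) / length(yb)
      bw <- head_backward(par, fw, dLOG)
      step <- step + 1L
      lr <- lr_at(step, sched)
      upd <- adamw_step(par, bw$grads, state, lr, cfg$weight_decay)
      par <- upd$par; state <- upd$state
      par <- bn_update_running(par, fw)
      losses <- c(losses, fw$loss)
      accs <- c(accs, mean(max.col(fw$probs) == yb))
    }
    # precise-BN pass: pin the running statistics to the exact moments of
    # the clean training features before validation
    par <- bn_recalibrate(par, tf_clean$FA, tf_clean$FB)
    ev <- eval_on_features(par, vf$FA, vf$FB, y_va, cfg$label_smoothing)
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, train_loss = mean(losses),
      train_acc = mean(accs), val_loss = ev$loss, val_acc = ev$acc))
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  acc %.4f  val_loss %.4f  val_acc %.4f",
                      epoch, lr, mean(losses), mean(accs), ev$loss, ev$acc))
    if (ev$loss < best$loss) {
      best <- list(loss = ev$loss, par = par, epoch = epoch)
      since_best <- 0L
      if (!is.null(cfg$checkpoint_dir))
        saveRDS(par, file.path(cfg$checkpoint_dir, "best_weights.rds"))
    } else {
      since_best <- since_best + 1L
      if (since_best >= cfg$patience) break
    }
  }
  model$par <- best$par            # restore_best_weights
  if (!is.null(cfg$checkpoint_dir))
    utils::write.csv(history, file.path(cfg$checkpoint_dir, "history.csv"),
                     row.names = FALSE)
  list(model = model, history = history, best_epoch = best$epoch)
}

#' @export
print.bilight <- function(x, ...) {
  cat(sprintf("<bilight> fit: %s + %s, %d classes, %d epochs (best %d)\n",
              x$config$backbone_a, x$config$backbone_b, length(x$classes),
              nrow(x$history), x$best_epoch))
  h <- x$history[x$best_epoch, ]
  cat(sprintf("  best val_loss %.4f, val_acc %.4f\n", h$val_loss, h$val_acc))
  invisible(x)
}

#' @export
summary.bilight <- function(object, ...) {
  print(object)
  print(audit_parameters(object$model))
  cat(sprintf("splits: train %d / val %d / test %d\n",
              nrow(object$splits$train), nrow(object$splits$val),
              nrow(object$splits$test)))
  invisible(object)
}

#' @export
coef.bilight <- function(object, ...) object$model$par

#' @export
plot.bilight <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "loss", ylim = range(c(h$train_loss, h$val_loss)))
  graphics::lines(h$epoch, h$val_loss, lty = 2)
  graphics::legend("topright", c("train", "val"), lty = 1:2, bty = "n")
  graphics::plot(h$epoch, h$train_acc, type = "l", xlab = "epoch",
                 ylab = "accuracy", ylim = range(c(h$train_acc, h$val_acc)))
  graphics::lines(h$epoch, h$val_acc, lty = 2)
  invisible(x)
}

#' Predict class probabilities or labels
#'
#' @param object A fitted `bilight` object.
#' @param newdata Dataset directory, manifest data frame, a single
#'   (H, W, 3) array, an (N, H, W, 3) array, or a list of arrays.
#' @param type `"prob"` for the (N, C) probability matrix, `"class"` for
#'   predicted labels.
#' @param ... Unused.
#' @return Probability matrix with class columns, or a character vector.
#' @export
predict.bilight <- function(object, newdata,
                            type = c("prob", "class"), ...) {
  type <- match.arg(type)
  model <- object$model
  imgs <- if (is.character(newdata) || is.data.frame(newdata)) {
    mf <- if (is.character(newdata)) read_manifest(newdata) else newdata
    lapply(mf$path, load_tile, input_size = object$config$input_size)
  } else as_image_list(newdata)
  FA <- extract_features(imgs, model$backbone_a)
  FB <- extract_features(imgs, model$backbone_b)
  probs <- head_forward(model$par, FA, FB, training = FALSE)$probs
  colnames(probs) <- object$classes
  if (type == "prob") probs else object$classes[max.col(probs)]
}

#' Evaluate a fitted model
#'
#' Computes the confusion matrix, per-class and global metrics, and ROC/PR
#' AUCs on a stored split (`"test"`, `"val"`, `"train"`, or `"all"` for
#' their union) or on any manifest data frame.
#'
#' @param object A fitted `bilight` object.
#' @param split Split name or manifest data frame.
#' @param out_dir Optional directory to write the report to (CSV + JSON).
#' @return A `bilight_report`.
#' @export
evaluate <- function(object, split = "test", out_dir = NULL) {
  stopifnot(inherits(object, "bilight"))
  mf <- if (is.data.frame(split)) split
        else if (identical(split, "all")) do.call(rbind, object$splits)
        else if (split %in% names(object$splits)) object$splits[[split]]
        else stop("unknown split: ", split, call. = FALSE)
  probs <- predict(object, mf, type = "prob")
  pred <- object$classes[max.col(probs)]
  rep <- metric_report(mf$class, pred, scores = probs,
                       classes = object$classes)
  if (!is.null(out_dir)) write_report(rep, out_dir)
  rep
}
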