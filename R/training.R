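# Training: seeded splits, ED-ES window clip sampling, and the Adam/MSE
# loop with step learning-rate decay. Loss is mean squared error on EF in
# percent units. One clip is sampled per training video per epoch.

#' Training configuration
#'
#' Defaults are the reference training recipe: 45 epochs, mini-batches of
#' 28 clips, initial learning rate 1e-4 decayed by a factor 0.1 every 16
#' epochs, Adam with weight decay 1e-4, clips of 16 frames, 80/10/10 splits.
#'
#' @param epochs Number of epochs.
#' @param batch_size Clips per mini-batch.
#' @param lr0 Initial learning rate.
#' @param lr_gamma Multiplicative step decay factor.
#' @param lr_step Epochs between decay steps.
#' @param weight_decay L2 weight decay coupled into the Adam update.
#' @param clip_len Training clip length in frames (16 by default; the frame
#'   count ablations 36/64/128 are plain overrides).
#' @param split_fractions TRAIN/VAL/TEST fractions, summing to 1.
#' @param seed Master seed for init, shuffling, sampling and augmentation.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 45L, batch_size = 28L, lr0 = 1e-4,
                         lr_gamma = 0.1, lr_step = 16L, weight_decay = 1e-4,
                         clip_len = 16L, split_fractions = c(0.8, 0.1, 0.1),
                         seed = 1L) {
  if (abs(sum(split_fractions) - 1) > 1e-9) {
    stop_efnet("split fractions must sum to 1", class = "efnet_config_error")
  }
  if (clip_len < 1) stop_efnet("clip_len must be >= 1", class = "efnet_config_error")
  if (lr0 <= 0 || lr_gamma <= 0 || batch_size < 1 || epochs < 1) {
    stop_efnet("rates and sizes must be positive", class = "efnet_config_error")
  }
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr0 = lr0, lr_gamma = lr_gamma, lr_step = as.integer(lr_step),
                 weight_decay = weight_decay, clip_len = as.integer(clip_len),
                 split_fractions = split_fractions, seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Step decay: `lr0 * lr_gamma ^ floor(epoch / lr_step)` (0-based epochs).
#'
#' @param epoch 0-based epoch index.
#' @param config A [train_config()].
#' @return The learning rate in effect during `epoch`.
#' @export
lr_at <- function(epoch, config = train_config()) {
  stopifnot(all(epoch >= 0))
  config$lr0 * config$lr_gamma^(epoch %/% config$lr_step)
}

#' Assign TRAIN/VAL/TEST splits
#'
#' Seeded shuffle followed by a contiguous partition. VAL and TEST take
#' `floor(n * fraction)` records each; remainders go to TRAIN, so for
#' n = 100 and fractions (0.8, 0.1, 0.1) the sizes are exactly 80/10/10.
#' The assignment is a pure function of the record ids, fractions and seed.
#'
#' @param records Records data frame (see [read_manifest()]).
#' @param fractions TRAIN/VAL/TEST fractions, summing to 1.
#' @param seed Integer seed.
#' @return Character vector of split labels aligned with `records` rows.
#' @export
make_splits <- function(records, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop_efnet("fractions must sum to 1", class = "efnet_config_error")
  }
  n <- nrow(records)
  if (n == 0) return(character(0))
  n_val <- floor(n * fractions[2])
  n_test <- floor(n * fractions[3])
  n_train <- n - n_val - n_test
  ord <- with_seed(seed, sample.int(n))
  split <- character(n)
  split[ord[seq_len(n_train)]] <- "TRAIN"
  if (n_val > 0) split[ord[n_train + seq_len(n_val)]] <- "VAL"
  if (n_test > 0) split[ord[n_train + n_val + seq_len(n_test)]] <- "TEST"
  split
}

#' Sample a training clip from the ED-ES window
#'
#' Training clips consist of `clip_len` consecutive frames drawn from the
#' inclusive window `[min(ed, es), max(ed, es)]`. When the window is long
#' enough, the start frame is uniform over all in-window positions. A window
#' shorter than `clip_len` is extended symmetrically into the full video;
#' a video shorter than `clip_len` is padded by repeating its last frame.
#' The clip is normalized to `[-1, 1]`.
#'
#' @param video A `gray_video`.
#' @param record One row of the records data frame (ED/ES indices, 0-based).
#' @param clip_len Clip length in frames.
#' @return Normalized clip, array `H x W x clip_len x 1`.
#' @export
sample_clip <- function(video, record, clip_len = 16L) {
  if (clip_len < 1) stop_efnet("clip_len must be >= 1", class = "efnet_config_error")
  T0 <- dim(video$pixels)[3]
  lo <- min(record$ed_frame, record$es_frame)
  hi <- max(record$ed_frame, record$es_frame)
  wlen <- hi - lo + 1L
  if (wlen >= clip_len) {
    start <- lo + sample.int(wlen - clip_len + 1L, 1L) - 1L
    idx <- start + seq_len(clip_len) - 1L
  } else if (T0 >= clip_len) {
    extra <- clip_len - wlen
    lo2 <- lo - extra %/% 2L
    lo2 <- max(0L, min(lo2, T0 - clip_len))
    idx <- lo2 + seq_len(clip_len) - 1L
  } else {
    idx <- c(seq_len(T0) - 1L, rep(T0 - 1L, clip_len - T0))
  }
  normalize_frames(video$pixels[, , idx + 1L, drop = FALSE])
}

# --- Adam --------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * g
    state$v[[nm]] <- state$beta2 * state$v[[nm]] + (1 - state$beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + state$eps)
  }
  list(params = params, state = state)
}

# --- dataset cache -----------------------------------------------------------

# Load the videos of the requested splits into memory (phantom-scale data is
# small; per-epoch disk decoding would dominate the training loop).
load_split_videos <- function(root, records, splits) {
  keep <- records$split %in% splits
  ids <- records$video_id[keep]
  vids <- lapply(ids, function(id) read_video(video_path(root, id)))
  names(vids) <- ids
  vids
}

# --- fit ---------------------------------------------------------------------

#' Train an EFNet on a dataset
#'
#' Per epoch: one clip is sampled (and optionally augmented) per training
#' video, mini-batches are formed, and Adam minimizes the MSE between
#' predicted and labelled EF (percent units) at the learning rate given by
#' [lr_at()]. After each epoch, validation videos are scored with
#' segment-averaged patient-level predictions ([predict_patient()]); the
#' parameters with minimum validation MAE are retained as the result.
#' The whole run is a pure function of the dataset and the two seeds.
#'
#' @param root Dataset root directory.
#' @param model_config An [efnet_config()].
#' @param config A [train_config()].
#' @param augment An [augment_config()], or `NULL` to train without
#'   augmentation. Augmentation is applied to TRAIN clips only.
#' @param resplit Overwrite the split labels stored in the manifest with a
#'   fresh [make_splits()] assignment (fractions and seed from `config`).
#'   By default the stored labels are respected.
#' @param verbose Print one line per epoch.
#' @return An `efnet_fit`: list with `model` (best-validation parameters),
#'   `logs` (per-epoch data frame: epoch, lr, train_mse, val_mse, val_mae),
#'   `best_epoch`, and the configs.
#' @export
fit <- function(root, model_config, config = train_config(),
                augment = augment_config(), resplit = FALSE, verbose = FALSE) {
  records <- read_dataset(root)
  if (resplit) {
    records$split <- make_splits(records, config$split_fractions,
                                 seed = derive_seed(config$seed, "resplit"))
  }
  train_idx <- which(records$split == "TRAIN")
  val_idx <- which(records$split == "VAL")
  if (length(train_idx) == 0) {
    stop_efnet("TRAIN split is empty", class = "efnet_config_error")
  }
  videos <- load_split_videos(root, records, c("TRAIN", "VAL"))
  clip_len <- config$clip_len
  stopifnot(clip_len == model_config$clip_len)

  set.seed(config$seed)
  model <- build_efnet(model_config)
  state <- adam_init(model$params)
  logs <- data.frame()
  best <- list(mae = Inf, params = NULL, buffers = NULL, epoch = NA_integer_)

  for (epoch in seq_len(config$epochs) - 1L) {
    lr <- lr_at(epoch, config)
    ord <- train_idx[sample.int(length(train_idx))]
    mse_accum <- 0; nb <- 0L
    for (b0 in seq(1, length(ord), by = config$batch_size)) {
      ids <- ord[b0:min(length(ord), b0 + config$batch_size - 1L)]
      nB <- length(ids)
      xb <- NULL
      yb <- records$ef[ids]
      for (j in seq_len(nB)) {
        rec <- records[ids[j], ]
        clip <- sample_clip(videos[[rec$video_id]], rec, clip_len)
        if (!is.null(augment)) clip <- augment_clip(clip, augment)
        if (is.null(xb)) {
          xb <- array(0, c(dim(clip)[1:3], 1L, nB))
        }
        xb[, , , 1L, j] <- clip
      }
      cache <- new.env(parent = emptyenv())
      pred <- efnet_forward(model, xb, training = TRUE, cache_env = cache)
      err <- pred - yb
      loss <- mean(err^2)
      if (!is.finite(loss)) {
        stop_efnet("non-finite training loss at epoch %d (lr %.2g)", epoch, lr,
                   class = "efnet_numeric_error")
      }
      grads <- efnet_backward(model, 2 * err / nB, cache)
      upd <- adam_step(model$params, grads, state, lr, config$weight_decay)
      model$params <- upd$params
      state <- upd$state
      mse_accum <- mse_accum + loss * nB
      nb <- nb + nB
    }
    train_mse <- mse_accum / nb

    val_mse <- val_mae <- NA_real_
    if (length(val_idx) > 0) {
      vp <- vapply(val_idx, function(i) {
        predict_patient(videos[[records$video_id[i]]], model, clip_len)
      }, numeric(1))
      verr <- vp - records$ef[val_idx]
      val_mse <- mean(verr^2); val_mae <- mean(abs(verr))
      if (val_mae < best$mae) {
        best <- list(mae = val_mae, params = model$params,
                     buffers = model$buffers, epoch = epoch)
      }
    }
    logs <- rbind(logs, data.frame(epoch = epoch, lr = lr,
                                   train_mse = train_mse,
                                   val_mse = val_mse, val_mae = val_mae))
    if (verbose) {
      message(sprintf("epoch %2d  lr %.2g  train MSE %8.2f  val MSE %8.2f  val MAE %6.2f",
                      epoch, lr, train_mse, val_mse, val_mae))
    }
  }
  if (!is.null(best$params)) {
    model$params <- best$params
    model$buffers <- best$buffers
  }
  structure(list(model = model, logs = logs, best_epoch = best$epoch,
                 model_config = model_config, train_config = config),
            class = "efnet_fit")
}

#' @export
print.efnet_fit <- function(x, ...) {
  cat(sprintf("<efnet_fit> %d epochs; best validation MAE %.3f at epoch %s\n",
              nrow(x$logs), min(x$logs$val_mae, na.rm = TRUE),
              as.character(x$best_epoch)))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is the flat map of named parameter arrays, the batch-norm
#' running moments and the model configuration.
#'
#' @param model An `efnet_model` or `efnet_fit`.
#' @param path Destination file.
#' @return `save_checkpoint`: `path`, invisibly. `load_checkpoint`: the
#'   restored `efnet_model`.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "efnet_fit")) model <- model$model
  saveRDS(list(config = model$config, params = model$params,
               buffers = model$buffers), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- new.env(parent = emptyenv())
  model$config <- ck$config
  model$params <- ck$params
  model$buffers <- ck$buffers
  class(model) <- "efnet_model"
  model
}
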