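# Patient-level inference and the regression metric suite.

#' Segment-averaged patient-level EF prediction
#'
#' All frames of the video are partitioned into `floor(T0 / clip_len)`
#' consecutive non-overlapping segments (a trailing remainder shorter than
#' one segment is dropped); each segment is normalized, forwarded through
#' the network, and the scalar outputs are arithmetically averaged. A video
#' shorter than one segment is padded by repeating its last frame.
#'
#' @param video A `gray_video`.
#' @param model An `efnet_model`, or a function `video -> EF` (useful as an
#'   oracle in tests).
#' @param clip_len Segment length in frames (defaults to the model's).
#' @return A single EF prediction in percent.
#' @export
predict_patient <- function(video, model, clip_len = NULL) {
  if (is.function(model)) return(model(video))
  clip_len <- clip_len %||% model$config$clip_len
  T0 <- dim(video$pixels)[3]
  if (T0 < 1) stop_efnet("video has no frames", class = "efnet_io_error")
  if (T0 < clip_len) {
    idx <- c(seq_len(T0), rep(T0, clip_len - T0))
    segs <- list(idx)
  } else {
    k <- T0 %/% clip_len
    segs <- lapply(seq_len(k), function(i) (i - 1L) * clip_len + seq_len(clip_len))
  }
  d <- dim(video$pixels)
  xb <- array(0, c(d[1], d[2], clip_len, 1L, length(segs)))
  for (i in seq_along(segs)) {
    xb[, , , 1L, i] <- normalize_frames(video$pixels[, , segs[[i]], drop = FALSE])
  }
  mean(efnet_forward(model, xb, training = FALSE))
}

#' Regression metrics for EF prediction
#'
#' Computes MSE, RMSE, MAE, MAPE (as a fraction, not x100), the coefficient
#' of determination R², and the F1 score of the binary reduced-EF task where
#' positives are EF < 40% in both truth and prediction.
#'
#' @param y_true,y_pred Equal-length vectors of EF values in percent;
#'   `y_true` must be positive (MAPE is undefined at 0).
#' @return An `ef_metrics` list: `mse, rmse, mae, mape, r2, f1_lt40`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) == 0) {
    stop_efnet("y_true and y_pred must have equal nonzero length",
               class = "efnet_input_error")
  }
  if (any(y_true <= 0)) {
    stop_efnet("y_true must be positive for MAPE", class = "efnet_input_error")
  }
  err <- y_pred - y_true
  mse <- mean(err^2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  r2 <- if (ss_tot == 0) {
    warning("zero-variance y_true: R2 undefined")
    NaN
  } else 1 - sum(err^2) / ss_tot
  tp <- sum(y_true < 40 & y_pred < 40)
  fp <- sum(y_true >= 40 & y_pred < 40)
  fn <- sum(y_true < 40 & y_pred >= 40)
  f1 <- if (2 * tp + fp + fn == 0) {
    warning("no EF<40 cases in truth or prediction: F1 undefined")
    NaN
  } else 2 * tp / (2 * tp + fp + fn)
  structure(list(mse = mse, rmse = sqrt(mse), mae = mean(abs(err)),
                 mape = mean(abs(err) / y_true), r2 = r2, f1_lt40 = f1),
            class = "ef_metrics")
}

#' @export
print.ef_metrics <- function(x, ...) {
  cat(sprintf("MSE %.2f  RMSE %.2f  MAE %.2f  MAPE %.4f  R2 %.2f  F1<40%% %.2f\n",
              x$mse, x$rmse, x$mae, x$mape, x$r2, x$f1_lt40))
  invisible(x)
}

#' Evaluate a model on one dataset split
#'
#' Runs [predict_patient()] on every video of the split and aggregates with
#' [compute_metrics()].
#'
#' @param root Dataset root directory.
#' @param model An `efnet_model` (or oracle function; see
#'   [predict_patient()]).
#' @param split One of `"TRAIN"`, `"VAL"`, `"TEST"`.
#' @param clip_len Segment length; defaults to the model's clip length.
#' @return List with `metrics` (an `ef_metrics`) and `table`, the per-patient
#'   data frame of `(video_id, ef_true, ef_pred)`.
#' @export
evaluate_split <- function(root, model, split = "TEST", clip_len = NULL) {
  records <- read_dataset(root)
  records <- records[records$split == split, , drop = FALSE]
  if (nrow(records) == 0) {
    stop_efnet("split %s is empty", split, class = "efnet_input_error")
  }
  preds <- vapply(seq_len(nrow(records)), function(i) {
    v <- read_video(video_path(root, records$video_id[i]))
    predict_patient(v, model, clip_len)
  }, numeric(1))
  list(metrics = compute_metrics(records$ef, preds),
       table = data.frame(video_id = records$video_id, ef_true = records$ef,
                          ef_pred = preds, stringsAsFactors = FALSE))
}
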