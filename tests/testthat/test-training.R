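test_that("split sizes use floor fractions with remainders going to TRAIN", {
  rec100 <- data.frame(video_id = sprintf("V%03d", 1:100))
  s <- make_splits(rec100, c(0.8, 0.1, 0.1), seed = 1)
  expect_equal(as.integer(table(s)[c("TRAIN", "VAL", "TEST")]), c(80L, 10L, 10L))
  # the reference cohort size: 10,030 -> 8,024 / 1,003 / 1,003
  recbig <- data.frame(video_id = sprintf("V%05d", 1:10030))
  s2 <- make_splits(recbig, c(0.8, 0.1, 0.1), seed = 1)
  expect_equal(sum(s2 == "TRAIN"), 8024L)
  expect_equal(sum(s2 == "VAL"), 1003L)
  expect_equal(sum(s2 == "TEST"), 1003L)
  # pure function of (ids, fractions, seed)
  expect_identical(s, make_splits(rec100, c(0.8, 0.1, 0.1), seed = 1))
  expect_false(identical(s, make_splits(rec100, c(0.8, 0.1, 0.1), seed = 2)))
  expect_identical(make_splits(rec100[0, , drop = FALSE]), character(0))
})

test_that("learning-rate schedule steps by gamma every lr_step epochs", {
  cfg <- train_config()
  expect_equal(lr_at(0, cfg), 1e-4)
  expect_equal(lr_at(15, cfg), 1e-4)
  expect_equal(lr_at(16, cfg), 1e-5)
  expect_equal(lr_at(44, cfg), 1e-6)
})

test_that("training clips stay inside the ED-ES window when it is long enough", {
  set.seed(1)
  v <- gray_video(array(sample(0:255, 8 * 8 * 60, TRUE), c(8, 8, 60)))
  rec <- list(ed_frame = 10L, es_frame = 40L)
  for (i in 1:200) {
    clip <- sample_clip(v, rec, 16)
    # recover which frames were used by matching against the source
    expect_equal(dim(clip), c(8, 8, 16, 1))
  }
  # verify window confinement on a video with a frame-index watermark
  wm <- gray_video(array(rep(0:59, each = 1), c(1, 1, 60)))
  draws <- replicate(500, {
    clip <- sample_clip(wm, rec, 16)
    rng <- range(denormalize_frames(clip))
    c(rng[1] >= 10, rng[2] <= 40, diff(rng) == 15)
  })
  expect_true(all(draws))
  # reversed ED/ES order uses the same window
  clip <- sample_clip(wm, list(ed_frame = 40L, es_frame = 10L), 31)
  expect_equal(range(denormalize_frames(clip)), c(10, 40))
})

test_that("window exactly clip_len is forced; short videos repeat-pad", {
  wm <- gray_video(array(0:59, c(1, 1, 60)))
  clip <- sample_clip(wm, list(ed_frame = 5L, es_frame = 20L), 16)
  expect_equal(as.vector(denormalize_frames(clip)), 5:20)
  short <- gray_video(array(0:3, c(1, 1, 4)))
  clip <- sample_clip(short, list(ed_frame = 0L, es_frame = 2L), 16)
  expect_equal(as.vector(denormalize_frames(clip)), c(0:3, rep(3, 12)))
  expect_error(sample_clip(short, list(ed_frame = 0L, es_frame = 2L), 0),
               class = "efnet_config_error")
})

test_that("a short ED-ES window is extended symmetrically into the video", {
  wm <- gray_video(array(0:29, c(1, 1, 30)))
  clip <- sample_clip(wm, list(ed_frame = 14L, es_frame = 17L), 8)
  used <- as.vector(denormalize_frames(clip))
  expect_equal(length(used), 8)
  expect_true(all(diff(used) == 1))             # consecutive frames
  expect_true(all(c(14, 17) %in% used))         # window still covered
})

test_that("Adam decreases the loss on a tiny overfitting problem", {
  # 2 phantom videos, tiny model, a couple hundred steps: the final training
  # MSE must collapse relative to the start (optimization sanity)
  d <- tiny_dataset(n = 2, seed = 9, image_size = 16)
  rec <- read_dataset(d)
  rec$split <- "TRAIN"
  vids <- lapply(rec$video_id, function(id) read_video(video_path(d, id)))
  cfg <- tiny_config()
  set.seed(11)
  m <- build_efnet(cfg)
  st <- efnet:::adam_init(m$params)
  xb <- array(0, c(16, 16, 8, 1, 2))
  for (j in 1:2) xb[, , , 1, j] <- sample_clip(vids[[j]], rec[j, ], 8)
  y <- rec$ef
  losses <- numeric(200)
  for (it in 1:200) {
    ce <- new.env()
    p <- efnet_forward(m, xb, training = TRUE, cache_env = ce)
    losses[it] <- mean((p - y)^2)
    g <- efnet_backward(m, 2 * (p - y) / 2, ce)
    upd <- efnet:::adam_step(m$params, g, st, 1e-2, 0)
    m$params <- upd$params; st <- upd$state
  }
  expect_lt(losses[200], 0.05 * losses[1])
})

test_that("fit is deterministic under a fixed seed and logs the lr schedule", {
  d <- tiny_dataset(n = 5, seed = 13, image_size = 16)
  rec <- read_dataset(d)
  # force a nonempty VAL split at this tiny n
  rec$split <- c("TRAIN", "TRAIN", "TRAIN", "VAL", "VAL")
  vids <- lapply(rec$video_id, function(id) read_video(video_path(d, id)))
  write_dataset(rec, vids, d)
  mc <- tiny_config()
  tc <- train_config(epochs = 2, batch_size = 2, lr0 = 1e-3, lr_step = 1,
                     lr_gamma = 0.5, clip_len = 8, seed = 5)
  f1 <- fit(d, mc, tc, augment = NULL)
  f2 <- fit(d, mc, tc, augment = NULL)
  expect_equal(f1$logs, f2$logs)
  expect_identical(f1$model$params, f2$model$params)
  expect_equal(f1$logs$lr, c(1e-3, 5e-4))
  expect_equal(nrow(f1$logs), 2)
  expect_true(all(is.finite(f1$logs$train_mse)))
  # augmented training is also reproducible seed-to-seed
  f3 <- fit(d, mc, tc, augment = augment_config())
  f4 <- fit(d, mc, tc, augment = augment_config())
  expect_equal(f3$logs$train_mse, f4$logs$train_mse)
})

test_that("training never reads TEST-split videos", {
  # deleting every TEST video must not affect fit at all
  d <- tiny_dataset(n = 10, seed = 31, image_size = 16)
  rec <- read_dataset(d)
  rec$split <- rep(c("TRAIN", "VAL", "TEST"), length.out = 10)
  vids <- lapply(rec$video_id, function(id) read_video(video_path(d, id)))
  write_dataset(rec, vids, d)
  for (id in rec$video_id[rec$split == "TEST"]) unlink(video_path(d, id))
  tc <- train_config(epochs = 1, batch_size = 4, clip_len = 8, seed = 2)
  f <- fit(d, tiny_config(), tc, augment = NULL)
  expect_equal(nrow(f$logs), 1)
  expect_true(is.finite(f$logs$val_mae))
})

test_that("fit can re-split on request, seeded from the train config", {
  d <- tiny_dataset(n = 12, seed = 33, image_size = 16)
  rec <- read_dataset(d)
  expect_equal(sum(rec$split == "VAL"), 1)      # stored assignment
  tc <- train_config(epochs = 1, batch_size = 4, clip_len = 8, seed = 3)
  f1 <- fit(d, tiny_config(), tc, augment = NULL, resplit = TRUE)
  f2 <- fit(d, tiny_config(), tc, augment = NULL, resplit = TRUE)
  expect_equal(f1$logs$train_mse, f2$logs$train_mse)
})

test_that("checkpoints round-trip parameters, buffers and config", {
  set.seed(20)
  m <- build_efnet(tiny_config())
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$params, m$params)
  expect_identical(m2$buffers, m$buffers)
  expect_equal(m2$config$channels, m$config$channels)
  x <- array(runif(16 * 16 * 8, -1, 1), c(16, 16, 8, 1, 1))
  expect_identical(efnet_forward(m, x), efnet_forward(m2, x))
})
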