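test_that("config invariants are enforced", {
  expect_error(efnet_config(clip_len = 12), class = "efnet_config_error")
  expect_error(efnet_config(height = 100), class = "efnet_config_error")
  expect_error(efnet_config(channels = c(8, 8, 9, 16, 32), n_heads = 4),
               class = "efnet_config_error")
  expect_error(efnet_config(rtm_stages = "conv2"), class = "efnet_config_error")
})

test_that("stage shapes follow the symbolic size table for any valid geometry", {
  for (geom in list(c(16, 112, 112), c(8, 32, 48), c(24, 64, 16))) {
    cfg <- efnet_config(clip_len = geom[1], height = geom[2], width = geom[3],
                        channels = c(4L, 4L, 4L, 8L, 8L), n_heads = 2)
    sh <- efnet_stage_shapes(cfg)
    expect_equal(unname(sh$conv1[1:3]), c(geom[1], geom[2] / 2, geom[3] / 2))
    expect_equal(unname(sh$conv3[1:3]), c(geom[1] / 2, geom[2] / 4, geom[3] / 4))
    expect_equal(unname(sh$conv5[1:3]), c(geom[1] / 8, geom[2] / 16, geom[3] / 16))
    # realized feature maps match the symbolic table
    set.seed(1)
    m <- build_efnet(cfg)
    x <- array(runif(prod(geom) * 2, -1, 1), c(geom[2], geom[3], geom[1], 1, 2))
    y <- efnet_forward(m, x, collect_shapes = TRUE)
    got <- attr(y, "shapes")
    for (stage in names(got)) {
      expect_equal(unname(got[[stage]][c(3, 1, 2, 4)]),
                   unname(c(sh[[stage]][1:3], sh[[stage]]["D"])),
                   info = stage)
    }
    expect_length(as.vector(y), 2)              # one EF per batch element
    expect_true(all(is.finite(y)))
  }
})

test_that("parameter count matches a closed-form per-layer summation", {
  # independent analytic count for the tiny configuration:
  # stem + stage conv2 (no projection) + conv3..conv5 (projection, first
  # block) with RTMs replacing the second block of conv3/conv5
  analytic_basic <- function(cin, cout, proj) {
    n <- 27 * cin * cout + 27 * cout * cout + 4 * cout
    if (proj) n <- n + cin * cout + 2 * cout
    n
  }
  analytic_rtm <- function(D, T, H, W) {
    27 * D * D + 2 * D +                        # conv + bn1
      3 * (D * D + D) +                         # q/k/v projections with bias
      (T + H + W) * D +                         # rpe tables
      2 * D                                     # bn2
  }
  cfg <- tiny_config()
  m <- build_efnet(cfg)
  expected <- 7 * 7 * 3 * 1 * 4 + 2 * 4 +                  # stem conv + bn
    analytic_basic(4, 4, FALSE) + analytic_basic(4, 4, FALSE) +
    analytic_basic(4, 4, TRUE) + analytic_rtm(4, 4, 4, 4) + # conv3 at T/2,H/4,W/4
    analytic_basic(4, 8, TRUE) + analytic_basic(8, 8, FALSE) +
    analytic_basic(8, 8, TRUE) + analytic_rtm(8, 1, 1, 1) + # conv5 at T/8,H/16,W/16
    8 * 1 + 1                                               # fc head
  expect_equal(count_parameters(m), expected)
  # the FC head alone holds in_features + 1 scalars
  expect_equal(length(m$params$fc.w) + length(m$params$fc.b), 8 + 1)
})

test_that("RTM substitution changes the count exactly by MHSA - conv terms", {
  base <- build_efnet(efnet_config(clip_len = 16, height = 32, width = 32,
                                   channels = c(8L, 8L, 16L, 32L, 64L),
                                   n_heads = 4, rtm_stages = character(0)))
  rtm <- build_efnet(efnet_config(clip_len = 16, height = 32, width = 32,
                                  channels = c(8L, 8L, 16L, 32L, 64L),
                                  n_heads = 4))
  delta <- -27 * 16 * 16 - 27 * 64 * 64 +       # removed second 3x3x3 convs
    3 * (16 * 16 + 16) + 3 * (64 * 64 + 64) +   # qkv projections
    (8 + 8 + 8) * 16 + (2 + 2 + 2) * 64         # rpe tables at stage extents
  expect_equal(count_parameters(rtm), count_parameters(base) + delta)
})

test_that("rtm_block is the literal composition conv, BN, ReLU, skip, MHSA, BN", {
  set.seed(2)
  cfg <- tiny_config()
  m <- build_efnet(cfg)
  x <- array(rnorm(4 * 4 * 4 * 4 * 2), c(4, 4, 4, 4, 2))
  ce <- new.env()
  y <- efnet:::rtm_block_forward(m, "conv3.2.", x, training = TRUE, cache_env = ce)
  expect_equal(dim(y), dim(x))
  # manual composition from the same parameters
  p <- m$params
  a <- efnet:::conv3d_forward(x, p[["conv3.2.conv1.w"]], c(3, 3, 3), c(1, 1, 1), c(1, 1, 1))
  bn1 <- efnet:::batchnorm_forward(a, p[["conv3.2.bn1.gamma"]], p[["conv3.2.bn1.beta"]],
                                   rep(0, 4), rep(1, 4), training = TRUE)
  s <- pmax(bn1$y, 0) + x
  w <- list(wq = p[["conv3.2.attn.wq"]], wk = p[["conv3.2.attn.wk"]],
            wv = p[["conv3.2.attn.wv"]], bq = p[["conv3.2.attn.bq"]],
            bk = p[["conv3.2.attn.bk"]], bv = p[["conv3.2.attn.bv"]])
  rpe <- list(rt = p[["conv3.2.rpe.rt"]], rh = p[["conv3.2.rpe.rh"]],
              rw = p[["conv3.2.rpe.rw"]])
  mh <- mhsa3d(s, w, rpe, cfg$n_heads)
  bn2 <- efnet:::batchnorm_forward(mh, p[["conv3.2.bn2.gamma"]], p[["conv3.2.bn2.beta"]],
                                   rep(0, 4), rep(1, 4), training = TRUE)
  expect_equal(y, bn2$y, tolerance = 1e-10)
  # standalone entry point: shape contract
  set.seed(3)
  z <- rtm_block(array(rnorm(2 * 2 * 8 * 8), c(2, 2, 8, 8, 1)), n_heads = 2)
  expect_equal(dim(z), c(2, 2, 8, 8, 1))
})

test_that("gradients flow to every parameter group including the RPE tables", {
  set.seed(4)
  # geometry with a conv5 attention grid larger than one token, so the deep
  # RPE tables participate in the softmax (a single token has no geometry)
  cfg <- efnet_config(clip_len = 16L, height = 32L, width = 32L,
                      channels = c(4L, 4L, 4L, 8L, 8L), n_heads = 2L,
                      fc_bias_init = 0)
  m <- build_efnet(cfg)
  x <- array(tanh(rnorm(32 * 32 * 16 * 2)), c(32, 32, 16, 1, 2))
  ce <- new.env()
  pred <- efnet_forward(m, x, training = TRUE, cache_env = ce)
  g <- efnet_backward(m, 2 * (pred - c(40, 70)) / 2, ce)
  for (nm in c("conv3.2.rpe.rt", "conv3.2.rpe.rh", "conv3.2.rpe.rw",
               "conv5.2.rpe.rt", "conv1.w", "fc.w", "conv3.2.attn.wq")) {
    expect_gt(max(abs(g[[nm]])), 0, label = paste("grad", nm))
  }
  # spot finite-difference agreement on one deep parameter
  nm <- "conv3.2.attn.wq"; i <- 5L; eps <- 1e-4
  lossat <- function(delta) {
    m2 <- build_efnet(cfg)
    m2$params <- m$params; m2$buffers <- m$buffers
    m2$params[[nm]][i] <- m2$params[[nm]][i] + delta
    ce2 <- new.env()
    p <- efnet_forward(m2, x, training = TRUE, cache_env = ce2)
    mean((p - c(40, 70))^2)
  }
  num <- (lossat(eps) - lossat(-eps)) / (2 * eps)
  expect_lt(abs(num - g[[nm]][i]), 1e-4 + 1e-2 * abs(num))
})

test_that("model output stays finite at initialization on [-1,1] inputs", {
  set.seed(5)
  m <- build_efnet(tiny_config())
  x <- array(runif(16 * 16 * 8 * 3, -1, 1), c(16, 16, 8, 1, 3))
  y <- efnet_forward(m, x)
  expect_true(all(is.finite(y)))
  expect_error(efnet_forward(m, array(0, c(16, 16, 4, 1, 1))),
               class = "efnet_shape_error")
})
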