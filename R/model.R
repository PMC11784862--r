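# The EFNet architecture: a 3D ResNet-18 video-regression backbone whose
# second residual block in stages conv3 and conv5 is a Residual Transformer
# Module (RTM): y = BN(MHSA(ReLU(BN(Conv(x))) + x)). The stem is a 3x7x7
# convolution (64 channels, stride 1x2x2) over a single-channel input; each
# stage holds two blocks; stages conv3-conv5 downsample by 2 in T, H and W
# with a 1x1x1 projection shortcut; the head is global average pooling
# followed by a fully connected layer to one EF output. Convolutions carry
# no bias (each is paired with batch norm); the FC layer has a bias.

#' Model configuration
#'
#' @param clip_len Input clip length `T0` in frames; must be divisible by 8.
#' @param height,width Frame size; both must be divisible by 16 (these
#'   divisibilities make every stage's output extent integral).
#' @param channels Five channel counts: stem and stages conv2..conv5.
#' @param rtm_stages Stages whose second block is an RTM; subset of
#'   `c("conv3", "conv5")`.
#' @param n_heads Attention heads per MHSA; must divide the RTM stage channels.
#' @param rpe_init_sd Init scale of the positional tables.
#' @param fc_bias_init Initial value of the regression head bias. The default
#'   50 puts the head at mid EF scale so optimization starts near the target
#'   range rather than at zero.
#' @return An `efnet_config` list.
#' @export
efnet_config <- function(clip_len = 16L, height = 112L, width = 112L,
                         channels = c(64L, 64L, 128L, 256L, 512L),
                         rtm_stages = c("conv3", "conv5"), n_heads = 4L,
                         rpe_init_sd = 0.02, fc_bias_init = 50) {
  if (clip_len %% 8 != 0) {
    stop_efnet("clip_len (%d) must be divisible by 8", clip_len,
               class = "efnet_config_error")
  }
  if (height %% 16 != 0 || width %% 16 != 0) {
    stop_efnet("height (%d) and width (%d) must be divisible by 16",
               height, width, class = "efnet_config_error")
  }
  if (length(channels) != 5) {
    stop_efnet("channels must list stem + 4 stage widths", class = "efnet_config_error")
  }
  if (!all(rtm_stages %in% c("conv3", "conv5"))) {
    stop_efnet("rtm_stages must be a subset of {conv3, conv5}",
               class = "efnet_config_error")
  }
  rtm_ch <- channels[match(rtm_stages, c("conv2", "conv3", "conv4", "conv5")) + 1L]
  if (any(rtm_ch %% n_heads != 0)) {
    stop_efnet("RTM stage channels (%s) must be divisible by n_heads (%d)",
               paste(rtm_ch, collapse = ", "), n_heads,
               class = "efnet_config_error")
  }
  structure(list(clip_len = as.integer(clip_len), height = as.integer(height),
                 width = as.integer(width), channels = as.integer(channels),
                 rtm_stages = rtm_stages, n_heads = as.integer(n_heads),
                 rpe_init_sd = rpe_init_sd, fc_bias_init = fc_bias_init),
            class = "efnet_config")
}

#' Symbolic stage output sizes
#'
#' The per-stage feature-map extents for a given input geometry:
#' conv1/conv2 at `(T0, H0/2, W0/2)`, then each later stage halves T, H, W.
#'
#' @param config An [efnet_config()].
#' @return Named list of `c(T, H, W, D)` per stage (`conv1` .. `conv5`).
#' @export
efnet_stage_shapes <- function(config) {
  T0 <- config$clip_len; H0 <- config$height; W0 <- config$width
  ch <- config$channels
  list(conv1 = c(T = T0, H = H0 / 2, W = W0 / 2, D = ch[1]),
       conv2 = c(T = T0, H = H0 / 2, W = W0 / 2, D = ch[2]),
       conv3 = c(T = T0 / 2, H = H0 / 4, W = W0 / 4, D = ch[3]),
       conv4 = c(T = T0 / 4, H = H0 / 8, W = W0 / 8, D = ch[4]),
       conv5 = c(T = T0 / 8, H = H0 / 16, W = W0 / 16, D = ch[5]))
}

.stage_names <- c("conv2", "conv3", "conv4", "conv5")

#' Build an EFNet model
#'
#' Initializes all trainable parameters (He init for convolutions, unit/zero
#' batch-norm affine pairs, zero-mean normal positional tables) using the
#' current RNG stream.
#'
#' @param config An [efnet_config()].
#' @return An `efnet_model` environment holding `config`, `params` (named
#'   list of trainable arrays) and `buffers` (batch-norm running moments).
#' @export
build_efnet <- function(config) {
  stopifnot(inherits(config, "efnet_config"))
  ch <- config$channels
  shapes <- efnet_stage_shapes(config)
  params <- list(); buffers <- list()
  add_bn <- function(prefix, C) {
    params[[paste0(prefix, ".gamma")]] <<- rep(1, C)
    params[[paste0(prefix, ".beta")]] <<- rep(0, C)
    buffers[[paste0(prefix, ".mean")]] <<- rep(0, C)
    buffers[[paste0(prefix, ".var")]] <<- rep(1, C)
  }
  params[["conv1.w"]] <- conv_weight_init(7, 7, 3, 1, ch[1])
  add_bn("bn1", ch[1])
  cin <- ch[1]
  for (s in seq_along(.stage_names)) {
    stage <- .stage_names[s]
    cout <- ch[s + 1]
    stride <- if (s == 1) 1L else 2L
    is_rtm <- stage %in% config$rtm_stages
    p1 <- paste0(stage, ".1.")
    params[[paste0(p1, "conv1.w")]] <- conv_weight_init(3, 3, 3, cin, cout)
    add_bn(paste0(p1, "bn1"), cout)
    params[[paste0(p1, "conv2.w")]] <- conv_weight_init(3, 3, 3, cout, cout)
    add_bn(paste0(p1, "bn2"), cout)
    if (stride != 1 || cin != cout) {
      params[[paste0(p1, "down.w")]] <- conv_weight_init(1, 1, 1, cin, cout)
      add_bn(paste0(p1, "downbn"), cout)
    }
    p2 <- paste0(stage, ".2.")
    params[[paste0(p2, "conv1.w")]] <- conv_weight_init(3, 3, 3, cout, cout)
    add_bn(paste0(p2, "bn1"), cout)
    if (is_rtm) {
      sh <- shapes[[stage]]
      mw <- mhsa_weight_init(cout)
      for (nm in names(mw)) params[[paste0(p2, "attn.", nm)]] <- mw[[nm]]
      rp <- rpe_init(sh["T"], sh["H"], sh["W"], cout, config$rpe_init_sd)
      params[[paste0(p2, "rpe.rt")]] <- rp$rt
      params[[paste0(p2, "rpe.rh")]] <- rp$rh
      params[[paste0(p2, "rpe.rw")]] <- rp$rw
      add_bn(paste0(p2, "bn2"), cout)
    } else {
      params[[paste0(p2, "conv2.w")]] <- conv_weight_init(3, 3, 3, cout, cout)
      add_bn(paste0(p2, "bn2"), cout)
    }
    cin <- cout
  }
  params[["fc.w"]] <- matrix(rnorm(ch[5], sd = 0.01), ch[5], 1)
  params[["fc.b"]] <- config$fc_bias_init
  model <- new.env(parent = emptyenv())
  model$config <- config
  model$params <- params
  model$buffers <- buffers
  class(model) <- "efnet_model"
  model
}

#' Count trainable parameters
#'
#' Sums every trainable scalar: convolution weights, batch-norm affine pairs,
#' attention projections and biases, positional tables, and the FC head.
#' Batch-norm running moments are buffers, not parameters.
#'
#' @param model An `efnet_model`.
#' @return Integer-valued count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# --- forward -----------------------------------------------------------------

bn_apply <- function(model, prefix, x, training, cache_env) {
  p <- model$params; b <- model$buffers
  out <- batchnorm_forward(x, p[[paste0(prefix, ".gamma")]],
                           p[[paste0(prefix, ".beta")]],
                           b[[paste0(prefix, ".mean")]],
                           b[[paste0(prefix, ".var")]], training = training)
  if (training) {
    model$buffers[[paste0(prefix, ".mean")]] <- out$rmean
    model$buffers[[paste0(prefix, ".var")]] <- out$rvar
  }
  if (!is.null(cache_env)) cache_env[[prefix]] <- out$cache
  out$y
}

basic_block_forward <- function(model, prefix, x, stride, training, cache_env) {
  p <- model$params
  has_down <- !is.null(p[[paste0(prefix, "down.w")]])
  s3 <- c(stride, stride, stride)
  a <- conv3d_forward(x, p[[paste0(prefix, "conv1.w")]], c(3, 3, 3), s3, c(1, 1, 1))
  a <- bn_apply(model, paste0(prefix, "bn1"), a, training, cache_env)
  r1 <- relu_forward(a)
  b <- conv3d_forward(r1$y, p[[paste0(prefix, "conv2.w")]], c(3, 3, 3),
                      c(1, 1, 1), c(1, 1, 1))
  b <- bn_apply(model, paste0(prefix, "bn2"), b, training, cache_env)
  if (has_down) {
    sh <- conv3d_forward(x, p[[paste0(prefix, "down.w")]], c(1, 1, 1), s3, c(0, 0, 0))
    sh <- bn_apply(model, paste0(prefix, "downbn"), sh, training, cache_env)
  } else sh <- x
  r2 <- relu_forward(b + sh)
  if (!is.null(cache_env)) {
    cache_env[[paste0(prefix, "ctx")]] <-
      list(x = x, relu1 = r1$mask, relu1y = r1$y, relu2 = r2$mask,
           stride = stride, has_down = has_down)
  }
  r2$y
}

# RTM: y = BN2( MHSA( ReLU(BN1(Conv(x))) + x ) ); stride 1, channel-preserving.
rtm_block_forward <- function(model, prefix, x, training, cache_env,
                              max_positions = 50000) {
  p <- model$params
  a <- conv3d_forward(x, p[[paste0(prefix, "conv1.w")]], c(3, 3, 3),
                      c(1, 1, 1), c(1, 1, 1))
  a <- bn_apply(model, paste0(prefix, "bn1"), a, training, cache_env)
  r1 <- relu_forward(a)
  s <- r1$y + x
  w <- list(wq = p[[paste0(prefix, "attn.wq")]], wk = p[[paste0(prefix, "attn.wk")]],
            wv = p[[paste0(prefix, "attn.wv")]], bq = p[[paste0(prefix, "attn.bq")]],
            bk = p[[paste0(prefix, "attn.bk")]], bv = p[[paste0(prefix, "attn.bv")]])
  rpe <- list(rt = p[[paste0(prefix, "rpe.rt")]], rh = p[[paste0(prefix, "rpe.rh")]],
              rw = p[[paste0(prefix, "rpe.rw")]])
  m <- mhsa3d(s, w, rpe, model$config$n_heads, with_cache = !is.null(cache_env),
              max_positions = max_positions)
  mc <- attr(m, "cache"); attr(m, "cache") <- NULL
  y <- bn_apply(model, paste0(prefix, "bn2"), m, training, cache_env)
  if (!is.null(cache_env)) {
    cache_env[[paste0(prefix, "ctx")]] <-
      list(x = x, relu1 = r1$mask, s = s, mhsa = mc, w = w, rpe = rpe)
  }
  y
}

#' Run an RTM block on a feature map
#'
#' Standalone access to one Residual Transformer Module (the literal
#' composition conv 3x3x3 -> BN -> ReLU -> add skip -> 3D MHSA -> BN) with
#' freshly initialized parameters, for inspection and testing.
#'
#' @param x Feature map `(H, W, T, D, N)`.
#' @param n_heads Attention heads (must divide D).
#' @param rpe_init_sd Positional table init scale.
#' @param training Batch-statistics mode for the two batch norms.
#' @return Feature map shaped like `x`.
#' @export
rtm_block <- function(x, n_heads = 4L, rpe_init_sd = 0.02, training = TRUE) {
  d <- dim(x); D <- d[4]
  if (D %% n_heads != 0) {
    stop_efnet("channels %d not divisible by n_heads %d", D, n_heads,
               class = "efnet_config_error")
  }
  m <- new.env(parent = emptyenv())
  m$config <- list(n_heads = n_heads)
  params <- list()
  params[["rtm.conv1.w"]] <- conv_weight_init(3, 3, 3, D, D)
  params[["rtm.bn1.gamma"]] <- rep(1, D); params[["rtm.bn1.beta"]] <- rep(0, D)
  mw <- mhsa_weight_init(D)
  for (nm in names(mw)) params[[paste0("rtm.attn.", nm)]] <- mw[[nm]]
  rp <- rpe_init(d[3], d[1], d[2], D, rpe_init_sd)
  params[["rtm.rpe.rt"]] <- rp$rt; params[["rtm.rpe.rh"]] <- rp$rh
  params[["rtm.rpe.rw"]] <- rp$rw
  params[["rtm.bn2.gamma"]] <- rep(1, D); params[["rtm.bn2.beta"]] <- rep(0, D)
  m$params <- params
  m$buffers <- list("rtm.bn1.mean" = rep(0, D), "rtm.bn1.var" = rep(1, D),
                    "rtm.bn2.mean" = rep(0, D), "rtm.bn2.var" = rep(1, D))
  rtm_block_forward(m, "rtm.", x, training = training, cache_env = NULL)
}

#' Forward pass
#'
#' @param model An `efnet_model`.
#' @param x Input batch, array `(H, W, T, 1, N)` of normalized pixels.
#' @param training Use batch statistics (and update running moments).
#' @param cache_env Environment collecting backward caches, or `NULL`.
#' @param collect_shapes Record each stage's output dimensions.
#' @return Length-`N` vector of EF predictions; with `collect_shapes`, the
#'   per-stage dims are attached as attribute `"shapes"`.
#' @export
efnet_forward <- function(model, x, training = FALSE, cache_env = NULL,
                          collect_shapes = FALSE) {
  cfg <- model$config
  d <- dim(x)
  if (length(d) != 5 || d[4] != 1) {
    stop_efnet("input must be (H, W, T, 1, N)", class = "efnet_shape_error")
  }
  if (d[1] != cfg$height || d[2] != cfg$width || d[3] != cfg$clip_len) {
    stop_efnet("input %dx%dx%d does not match config %dx%dx%d",
               d[1], d[2], d[3], cfg$height, cfg$width, cfg$clip_len,
               class = "efnet_shape_error")
  }
  shapes <- list()
  h <- conv3d_forward(x, model$params[["conv1.w"]], c(7, 7, 3), c(2, 2, 1), c(3, 3, 1))
  h <- bn_apply(model, "bn1", h, training, cache_env)
  r0 <- relu_forward(h)
  if (!is.null(cache_env)) cache_env[["stem.ctx"]] <- list(x = x, relu = r0$mask)
  h <- r0$y
  if (collect_shapes) shapes$conv1 <- dim(h)
  for (s in seq_along(.stage_names)) {
    stage <- .stage_names[s]
    stride <- if (s == 1) 1L else 2L
    h <- basic_block_forward(model, paste0(stage, ".1."), h, stride,
                             training, cache_env)
    if (stage %in% cfg$rtm_stages) {
      h <- rtm_block_forward(model, paste0(stage, ".2."), h, training, cache_env)
    } else {
      h <- basic_block_forward(model, paste0(stage, ".2."), h, 1L,
                               training, cache_env)
    }
    if (collect_shapes) shapes[[stage]] <- dim(h)
  }
  f <- gap_forward(h)
  if (!is.null(cache_env)) cache_env[["head.ctx"]] <- list(f = f, hdim = dim(h))
  y <- fc_forward(f, model$params[["fc.w"]], model$params[["fc.b"]])
  if (collect_shapes) attr(y, "shapes") <- shapes
  y
}

# --- backward ----------------------------------------------------------------

basic_block_backward <- function(model, prefix, dy, cache_env, grads) {
  p <- model$params
  ctx <- cache_env[[paste0(prefix, "ctx")]]
  dsum <- relu_backward(dy, ctx$relu2)
  bb <- batchnorm_backward(dsum, cache_env[[paste0(prefix, "bn2")]])
  grads[[paste0(prefix, "bn2.gamma")]] <- bb$dgamma
  grads[[paste0(prefix, "bn2.beta")]] <- bb$dbeta
  s3 <- rep(ctx$stride, 3)
  cb <- conv3d_backward(bb$dx, ctx$relu1y, p[[paste0(prefix, "conv2.w")]],
                        c(3, 3, 3), c(1, 1, 1), c(1, 1, 1))
  grads[[paste0(prefix, "conv2.w")]] <- cb$dw
  dr1 <- relu_backward(cb$dx, ctx$relu1)
  b1 <- batchnorm_backward(dr1, cache_env[[paste0(prefix, "bn1")]])
  grads[[paste0(prefix, "bn1.gamma")]] <- b1$dgamma
  grads[[paste0(prefix, "bn1.beta")]] <- b1$dbeta
  c1 <- conv3d_backward(b1$dx, ctx$x, p[[paste0(prefix, "conv1.w")]],
                        c(3, 3, 3), s3, c(1, 1, 1))
  grads[[paste0(prefix, "conv1.w")]] <- c1$dw
  dx <- c1$dx
  if (ctx$has_down) {
    bd <- batchnorm_backward(dsum, cache_env[[paste0(prefix, "downbn")]])
    grads[[paste0(prefix, "downbn.gamma")]] <- bd$dgamma
    grads[[paste0(prefix, "downbn.beta")]] <- bd$dbeta
    cd <- conv3d_backward(bd$dx, ctx$x, p[[paste0(prefix, "down.w")]],
                          c(1, 1, 1), s3, c(0, 0, 0))
    grads[[paste0(prefix, "down.w")]] <- cd$dw
    dx <- dx + cd$dx
  } else {
    dx <- dx + dsum
  }
  list(dx = dx, grads = grads)
}

rtm_block_backward <- function(model, prefix, dy, cache_env, grads) {
  p <- model$params
  ctx <- cache_env[[paste0(prefix, "ctx")]]
  b2 <- batchnorm_backward(dy, cache_env[[paste0(prefix, "bn2")]])
  grads[[paste0(prefix, "bn2.gamma")]] <- b2$dgamma
  grads[[paste0(prefix, "bn2.beta")]] <- b2$dbeta
  mb <- mhsa3d_backward(b2$dx, ctx$w, ctx$rpe, ctx$mhsa)
  grads[[paste0(prefix, "attn.wq")]] <- mb$dwq
  grads[[paste0(prefix, "attn.wk")]] <- mb$dwk
  grads[[paste0(prefix, "attn.wv")]] <- mb$dwv
  grads[[paste0(prefix, "attn.bq")]] <- mb$dbq
  grads[[paste0(prefix, "attn.bk")]] <- mb$dbk
  grads[[paste0(prefix, "attn.bv")]] <- mb$dbv
  grads[[paste0(prefix, "rpe.rt")]] <- mb$drt
  grads[[paste0(prefix, "rpe.rh")]] <- mb$drh
  grads[[paste0(prefix, "rpe.rw")]] <- mb$drw
  ds <- mb$dx                       # gradient at s = relu1 + x
  dr1 <- relu_backward(ds, ctx$relu1)
  b1 <- batchnorm_backward(dr1, cache_env[[paste0(prefix, "bn1")]])
  grads[[paste0(prefix, "bn1.gamma")]] <- b1$dgamma
  grads[[paste0(prefix, "bn1.beta")]] <- b1$dbeta
  c1 <- conv3d_backward(b1$dx, ctx$x, p[[paste0(prefix, "conv1.w")]],
                        c(3, 3, 3), c(1, 1, 1), c(1, 1, 1))
  grads[[paste0(prefix, "conv1.w")]] <- c1$dw
  list(dx = c1$dx + ds, grads = grads)
}

#' Backward pass
#'
#' Given the gradient of the loss with respect to the network output,
#' accumulates gradients for every trainable parameter.
#'
#' @param model An `efnet_model`.
#' @param dy Length-`N` gradient vector at the output.
#' @param cache_env The cache environment filled by [efnet_forward()].
#' @return Named list of gradients (one entry per entry of `model$params`).
#' @export
efnet_backward <- function(model, dy, cache_env) {
  grads <- list()
  head <- cache_env[["head.ctx"]]
  fb <- fc_backward(dy, head$f, model$params[["fc.w"]])
  grads[["fc.w"]] <- fb$dw
  grads[["fc.b"]] <- fb$db
  dh <- gap_backward(fb$df, head$hdim)
  cfg <- model$config
  for (s in rev(seq_along(.stage_names))) {
    stage <- .stage_names[s]
    if (stage %in% cfg$rtm_stages) {
      out <- rtm_block_backward(model, paste0(stage, ".2."), dh, cache_env, grads)
    } else {
      out <- basic_block_backward(model, paste0(stage, ".2."), dh, cache_env, grads)
    }
    dh <- out$dx; grads <- out$grads
    out <- basic_block_backward(model, paste0(stage, ".1."), dh, cache_env, grads)
    dh <- out$dx; grads <- out$grads
  }
  stem <- cache_env[["stem.ctx"]]
  dh <- relu_backward(dh, stem$relu)
  b0 <- batchnorm_backward(dh, cache_env[["bn1"]])
  grads[["bn1.gamma"]] <- b0$dgamma
  grads[["bn1.beta"]] <- b0$dbeta
  c0 <- conv3d_backward(b0$dx, stem$x, model$params[["conv1.w"]],
                        c(7, 7, 3), c(2, 2, 1), c(3, 3, 1))
  grads[["conv1.w"]] <- c0$dw
  grads
}

#' @export
print.efnet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<efnet_model> clip %d x %dx%d, channels %s, RTM at {%s}, %d heads\n",
              cfg$clip_len, cfg$height, cfg$width,
              paste(cfg$channels, collapse = "/"),
              paste(cfg$rtm_stages, collapse = ", "), cfg$n_heads))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}
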