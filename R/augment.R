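# Clip-level training augmentations. One transform parameter set is drawn
# per clip and applied identically to every frame (temporal coherence: the
# motion signal EF depends on must survive augmentation). Everything runs on
# the normalized [-1, 1] clip; frame size is never changed.

#' Augmentation configuration
#'
#' Defaults are the training-time augmentations used for echo clips:
#' rotation in ±25 degrees, horizontal flip with probability 0.5, Gaussian
#' blur with probability 0.5, picture (JPEG) compression with probability
#' 0.1, and random brightness/contrast. Magnitudes that the probabilities do
#' not determine are package choices: blur sigma from `[0.3, 1.5]` px, JPEG
#' quality from `[30, 90]`, brightness delta ±0.2 (on the `[0, 1]` intensity
#' scale), contrast factor `[0.8, 1.2]`.
#'
#' @param rotation_deg Length-2 rotation range in degrees (symmetric).
#' @param p_hflip,p_blur,p_compress Transform probabilities in `[0, 1]`.
#' @param brightness_delta Length-2 additive brightness range.
#' @param contrast_factor Length-2 multiplicative contrast range.
#' @param blur_sigma Length-2 Gaussian blur sigma range (px).
#' @param jpeg_quality Length-2 JPEG quality range.
#' @return An `augment_config` list.
#' @export
augment_config <- function(rotation_deg = c(-25, 25), p_hflip = 0.5,
                           p_blur = 0.5, p_compress = 0.1,
                           brightness_delta = c(-0.2, 0.2),
                           contrast_factor = c(0.8, 1.2),
                           blur_sigma = c(0.3, 1.5),
                           jpeg_quality = c(30, 90)) {
  probs <- c(p_hflip, p_blur, p_compress)
  if (any(probs < 0 | probs > 1)) {
    stop_efnet("probabilities must lie in [0, 1]", class = "efnet_config_error")
  }
  if (abs(rotation_deg[1] + rotation_deg[2]) > 1e-9 &&
      !(rotation_deg[1] == 0 && rotation_deg[2] == 0)) {
    stop_efnet("rotation range must be symmetric about 0", class = "efnet_config_error")
  }
  structure(list(rotation_deg = rotation_deg, p_hflip = p_hflip,
                 p_blur = p_blur, p_compress = p_compress,
                 brightness_delta = brightness_delta,
                 contrast_factor = contrast_factor,
                 blur_sigma = blur_sigma, jpeg_quality = jpeg_quality),
            class = "augment_config")
}

#' The identity augmentation configuration
#' @return An `augment_config` under which [augment_clip()] is the identity.
#' @export
augment_identity <- function() {
  augment_config(rotation_deg = c(0, 0), p_hflip = 0, p_blur = 0, p_compress = 0,
                 brightness_delta = c(0, 0), contrast_factor = c(1, 1))
}

# Bilinear rotation of all frames about the frame center, zero-filled
# outside (zero on the [0,1] scale = the black cone background).
# u: H x W x T array on [0, 1].
rotate_frames <- function(u, angle_deg) {
  if (abs(angle_deg) < 1e-12) return(u)
  d <- dim(u); H <- d[1]; W <- d[2]; T0 <- d[3]
  th <- angle_deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  r <- matrix(seq_len(H), H, W); c <- matrix(seq_len(W), H, W, byrow = TRUE)
  # inverse map: source coords that land on (r, c)
  sr <- cy + cos(th) * (r - cy) - sin(th) * (c - cx)
  sc <- cx + sin(th) * (r - cy) + cos(th) * (c - cx)
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  um <- matrix(u, H * W, T0)
  pick <- function(ri, ci) {
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    idx <- ifelse(ok, ri + (ci - 1) * H, 1L)
    v <- um[idx, , drop = FALSE]
    v[!ok, ] <- 0
    v
  }
  out <- pick(r0, c0) * as.vector((1 - fr) * (1 - fc)) +
    pick(r0 + 1L, c0) * as.vector(fr * (1 - fc)) +
    pick(r0, c0 + 1L) * as.vector((1 - fr) * fc) +
    pick(r0 + 1L, c0 + 1L) * as.vector(fr * fc)
  array(out, d)
}

blur_frames <- function(u, sigma) {
  d <- dim(u)
  for (t in seq_len(d[3])) {
    u[, , t] <- EBImage::imageData(EBImage::gblur(u[, , t], sigma = sigma))
  }
  u
}

jpeg_frames <- function(u, quality) {
  d <- dim(u)
  f <- tempfile(fileext = ".jpg")
  on.exit(unlink(f))
  for (t in seq_len(d[3])) {
    EBImage::writeImage(EBImage::Image(clamp(u[, , t], 0, 1)), f,
                        quality = as.integer(quality))
    u[, , t] <- EBImage::imageData(EBImage::readImage(f))
  }
  u
}

#' Augment one training clip
#'
#' Draws one parameter set from `config` (rotation angle, flip/blur/compress
#' coin flips, brightness delta, contrast factor) using the current RNG
#' stream and applies it to every frame of the clip. Output is clipped back
#' to `[-1, 1]`; shape is preserved.
#'
#' @param clip Normalized clip, array `H x W x T x 1` with values in `[-1, 1]`.
#' @param config An [augment_config()].
#' @return Augmented clip of identical shape.
#' @export
augment_clip <- function(clip, config = augment_config()) {
  d <- dim(clip)
  u <- array((as.double(clip) + 1) / 2, d[1:3])   # to [0, 1]

  angle <- runif(1, config$rotation_deg[1], config$rotation_deg[2])
  do_flip <- runif(1) < config$p_hflip
  delta <- runif(1, config$brightness_delta[1], config$brightness_delta[2])
  factor <- runif(1, config$contrast_factor[1], config$contrast_factor[2])
  do_blur <- runif(1) < config$p_blur
  sigma <- runif(1, config$blur_sigma[1], config$blur_sigma[2])
  do_jpeg <- runif(1) < config$p_compress
  quality <- runif(1, config$jpeg_quality[1], config$jpeg_quality[2])

  u <- rotate_frames(u, angle)
  if (do_flip) u <- u[, dim(u)[2]:1, , drop = FALSE]
  if (factor != 1) u <- (u - 0.5) * factor + 0.5
  if (delta != 0) u <- u + delta
  if (do_blur) u <- blur_frames(u, sigma)
  if (do_jpeg) u <- jpeg_frames(u, quality)

  out <- array(u * 2 - 1, d)
  clamp(out, -1, 1)
}
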