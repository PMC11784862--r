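# Network building blocks with explicit forward/backward passes. All feature
# maps are dense arrays of dim (H, W, T, C, N); position flattening order is
# h fastest, then w, then t. Convolution weights are stored as a
# (kh*kw*kt*Cin) x Cout matrix whose row order matches the im2col patch
# layout, so forward is a single GEMM per temporal slab.

conv_weight_init <- function(kh, kw, kt, cin, cout) {
  fan_in <- kh * kw * kt * cin
  matrix(rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout)
}

# kdim/stride/pad are (h, w, t) triples.
conv3d_forward <- function(x, w, kdim, stride, pad) {
  d <- dim(x); H <- d[1]; W <- d[2]; T0 <- d[3]; C <- d[4]; N <- d[5]
  kh <- kdim[1]; kw <- kdim[2]; kt <- kdim[3]
  cout <- ncol(w)
  Ho <- (H + 2 * pad[1] - kh) %/% stride[1] + 1
  Wo <- (W + 2 * pad[2] - kw) %/% stride[2] + 1
  To <- (T0 + 2 * pad[3] - kt) %/% stride[3] + 1
  if (nrow(w) != kh * kw * kt * C) {
    stop_efnet("conv weight expects %d input channels", nrow(w) / (kh * kw * kt),
               class = "efnet_shape_error")
  }
  # temporal slab size keeping the patch matrix under ~32 MB
  slab <- max(1L, min(To, as.integer(4e6 / max(1, nrow(w) * Ho * Wo))))
  out <- array(0, c(Ho, Wo, To, cout, N))
  for (n in seq_len(N)) {
    xn <- x[, , , , n]
    t0 <- 0L
    while (t0 < To) {
      t1 <- min(To, t0 + slab)
      col <- im2col3d(as.double(xn), H, W, T0, C, kh, kw, kt,
                      stride[1], stride[2], stride[3],
                      pad[1], pad[2], pad[3], Ho, Wo, t0, t1)
      out[, , (t0 + 1L):t1, , n] <- crossprod(col, w)
      t0 <- t1
    }
  }
  out
}

# Returns list(dx, dw). Patch matrices are recomputed rather than cached so
# training memory stays flat.
conv3d_backward <- function(dout, x, w, kdim, stride, pad) {
  d <- dim(x); H <- d[1]; W <- d[2]; T0 <- d[3]; C <- d[4]; N <- d[5]
  kh <- kdim[1]; kw <- kdim[2]; kt <- kdim[3]
  do_ <- dim(dout); Ho <- do_[1]; Wo <- do_[2]; To <- do_[3]; cout <- do_[4]
  dw <- matrix(0, nrow(w), cout)
  dx <- array(0, d)
  slab <- max(1L, min(To, as.integer(4e6 / max(1, nrow(w) * Ho * Wo))))
  for (n in seq_len(N)) {
    xn <- x[, , , , n]
    dxn <- numeric(H * W * T0 * C)
    t0 <- 0L
    while (t0 < To) {
      t1 <- min(To, t0 + slab)
      col <- im2col3d(as.double(xn), H, W, T0, C, kh, kw, kt,
                      stride[1], stride[2], stride[3],
                      pad[1], pad[2], pad[3], Ho, Wo, t0, t1)
      dslab <- matrix(dout[, , (t0 + 1L):t1, , n], ncol = cout)
      dw <- dw + col %*% dslab
      dcol <- tcrossprod(w, dslab)
      dxn <- dxn + col2im3d(dcol, H, W, T0, C, kh, kw, kt,
                            stride[1], stride[2], stride[3],
                            pad[1], pad[2], pad[3], Ho, Wo, t0, t1)
      t0 <- t1
    }
    dx[, , , , n] <- dxn
  }
  list(dx = dx, dw = dw)
}

# Batch normalization over (H, W, T, N) per channel. Returns the output,
# a backward cache, and updated running moments.
batchnorm_forward <- function(x, gamma, beta, rmean, rvar,
                              training = TRUE, momentum = 0.1, eps = 1e-5) {
  d <- dim(x); S <- d[1] * d[2] * d[3]; C <- d[4]; N <- d[5]
  M <- matrix(x, S, C * N)
  if (training) {
    cs <- .colMeans(M, S, C * N)
    mu <- rowMeans(matrix(cs, C, N))
    cs2 <- .colMeans(M * M, S, C * N)
    v <- rowMeans(matrix(cs2, C, N)) - mu^2
    v <- pmax(v, 0)
    m <- S * N
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * v * m / max(1, m - 1)
  } else {
    mu <- rmean; v <- rvar
  }
  invstd <- 1 / sqrt(v + eps)
  ecol <- function(p) rep(rep(p, times = N), each = S)
  xhat <- (as.double(M) - ecol(mu)) * ecol(invstd)
  y <- array(xhat * ecol(gamma) + ecol(beta), d)
  list(y = y, cache = list(xhat = xhat, invstd = invstd, gamma = gamma,
                           dims = d, training = training),
       rmean = rmean, rvar = rvar)
}

batchnorm_backward <- function(dy, cache) {
  d <- cache$dims; S <- d[1] * d[2] * d[3]; C <- d[4]; N <- d[5]
  dyv <- as.double(dy)
  xhat <- cache$xhat
  perchan <- function(v) {
    cs <- .colSums(matrix(v, S, C * N), S, C * N)
    rowSums(matrix(cs, C, N))
  }
  dgamma <- perchan(dyv * xhat)
  dbeta <- perchan(dyv)
  ecol <- function(p) rep(rep(p, times = N), each = S)
  g_is <- ecol(cache$gamma * cache$invstd)
  if (cache$training) {
    m <- S * N
    dx <- g_is * (dyv - ecol(dbeta / m) - xhat * ecol(dgamma / m))
  } else {
    dx <- g_is * dyv
  }
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}
relu_backward <- function(dy, mask) dy * mask

# Global average pooling over (H, W, T): (H,W,T,C,N) -> C x N matrix.
gap_forward <- function(x) {
  d <- dim(x); S <- d[1] * d[2] * d[3]
  matrix(.colMeans(matrix(x, S, d[4] * d[5]), S, d[4] * d[5]), d[4], d[5])
}
gap_backward <- function(dy, xdim) {
  S <- xdim[1] * xdim[2] * xdim[3]
  array(rep(as.double(dy), each = S) / S, xdim)
}

# Fully connected head: f (C x N) -> length-N vector of EF predictions.
fc_forward <- function(f, w, b) as.double(crossprod(f, w)) + b
fc_backward <- function(dy, f, w) {
  list(dw = f %*% matrix(dy, ncol = 1), db = sum(dy),
       df = tcrossprod(w, matrix(dy, ncol = 1)))
}
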