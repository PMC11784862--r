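# 3D multi-head self-attention with decomposed relative positional encoding.
# Feature maps (H, W, T, D, N) are flattened to P = H*W*T tokens of dimension
# D. Q, K, V come from 1x1x1 convolutions (token-wise D x D projections with
# bias). The positional term r = Rt + Rh + Rw (broadcast over the grid) is
# applied to both queries and keys: per head i the logits are
#   (Qi Ki^T + Qi ri^T + ri Ki^T) / sqrt(d),     d = D / n_heads.

#' Relative positional encoding tables
#'
#' Learned free tables `Rt` (T x D), `Rh` (H x D), `Rw` (W x D) whose
#' broadcast sum gives one D-vector per spatiotemporal position.
#'
#' @param T,H,W Attention grid extents.
#' @param D Channel count.
#' @param init_sd Zero-mean normal init scale (0 gives all-zero tables).
#' @return List with elements `rt`, `rh`, `rw`.
#' @export
rpe_init <- function(T, H, W, D, init_sd = 0.02) {
  draw <- function(n) {
    if (init_sd == 0) matrix(0, n, D) else matrix(rnorm(n * D, sd = init_sd), n, D)
  }
  list(rt = draw(T), rh = draw(H), rw = draw(W))
}

# Broadcast r = Rt + Rh + Rw to a P x D matrix in (h fastest, w, t) order.
rpe_expand <- function(rpe, H, W, T) {
  hidx <- rep_len(seq_len(H), H * W * T)
  widx <- rep(rep(seq_len(W), each = H), times = T)
  tidx <- rep(seq_len(T), each = H * W)
  rpe$rh[hidx, , drop = FALSE] + rpe$rw[widx, , drop = FALSE] +
    rpe$rt[tidx, , drop = FALSE]
}

mhsa_weight_init <- function(D) {
  pr <- function() matrix(rnorm(D * D, sd = sqrt(1 / D)), D, D)
  list(wq = pr(), wk = pr(), wv = pr(),
       bq = numeric(D), bk = numeric(D), bv = numeric(D))
}

#' 3D multi-head self-attention
#'
#' @param x Feature map, array `(H, W, T, D, N)`.
#' @param w Projection weights: list `wq, wk, wv` (each `D x D`) and biases
#'   `bq, bk, bv` (length `D`).
#' @param rpe Positional tables from [rpe_init()] with extents matching `x`.
#' @param n_heads Number of attention heads; must divide `D`.
#' @param with_cache Keep the intermediates needed by [mhsa3d_backward()].
#' @param return_attention Also return the per-head attention matrices
#'   (small inputs only; used for diagnostics).
#' @param max_positions Guard against accidental quadratic blow-up: error if
#'   `H*W*T` exceeds this unless raised explicitly.
#' @return Array shaped like `x` (plus attributes when caching/diagnosing).
#' @export
mhsa3d <- function(x, w, rpe, n_heads, with_cache = FALSE,
                   return_attention = FALSE, max_positions = 50000) {
  d <- dim(x); H <- d[1]; W <- d[2]; T0 <- d[3]; D <- d[4]; N <- d[5]
  if (D %% n_heads != 0) {
    stop_efnet("channel count %d not divisible by n_heads %d", D, n_heads,
               class = "efnet_config_error")
  }
  if (nrow(rpe$rt) != T0 || nrow(rpe$rh) != H || nrow(rpe$rw) != W ||
      ncol(rpe$rt) != D) {
    stop_efnet("RPE tables (%dx%d t, %d h, %d w) do not match feature map %dx%dx%dx%d",
               nrow(rpe$rt), ncol(rpe$rt), nrow(rpe$rh), nrow(rpe$rw),
               H, W, T0, D, class = "efnet_shape_error")
  }
  P <- H * W * T0
  if (P > max_positions) {
    stop_efnet("attention over %d positions exceeds the guard (%d)", P,
               max_positions, class = "efnet_config_error")
  }
  dh <- D %/% n_heads
  scale <- 1 / sqrt(dh)
  r <- rpe_expand(rpe, H, W, T0)
  y <- array(0, d)
  caches <- if (with_cache) vector("list", N) else NULL
  attn <- if (return_attention) vector("list", N) else NULL
  for (n in seq_len(N)) {
    X <- matrix(x[, , , , n], P, D)
    Q <- X %*% w$wq + matrix(w$bq, P, D, byrow = TRUE)
    K <- X %*% w$wk + matrix(w$bk, P, D, byrow = TRUE)
    V <- X %*% w$wv + matrix(w$bv, P, D, byrow = TRUE)
    O <- matrix(0, P, D)
    An <- if (return_attention) vector("list", n_heads) else NULL
    Alist <- if (with_cache) vector("list", n_heads) else NULL
    for (i in seq_len(n_heads)) {
      cols <- ((i - 1) * dh + 1):(i * dh)
      Qi <- Q[, cols, drop = FALSE]; Ki <- K[, cols, drop = FALSE]
      ri <- r[, cols, drop = FALSE]
      L <- (tcrossprod(Qi, Ki) + tcrossprod(Qi, ri) + tcrossprod(ri, Ki)) * scale
      L <- L - apply(L, 1, max)
      A <- exp(L); A <- A / rowSums(A)
      O[, cols] <- A %*% V[, cols, drop = FALSE]
      if (return_attention) An[[i]] <- A
      if (with_cache) Alist[[i]] <- A
    }
    y[, , , , n] <- O
    if (with_cache) caches[[n]] <- list(X = X, Q = Q, K = K, V = V, A = Alist)
    if (return_attention) attn[[n]] <- An
  }
  if (with_cache) {
    attr(y, "cache") <- list(per_sample = caches, r = r, dims = d,
                             n_heads = n_heads, dh = dh, scale = scale)
  }
  if (return_attention) attr(y, "attention") <- attn
  y
}

# Backward pass. Returns dx plus gradients for all projection weights and
# the three RPE tables.
mhsa3d_backward <- function(dy, w, rpe, cache) {
  d <- cache$dims; H <- d[1]; W <- d[2]; T0 <- d[3]; D <- d[4]; N <- d[5]
  P <- H * W * T0
  dh <- cache$dh; scale <- cache$scale; n_heads <- cache$n_heads
  r <- cache$r
  dx <- array(0, d)
  dwq <- matrix(0, D, D); dwk <- matrix(0, D, D); dwv <- matrix(0, D, D)
  dbq <- numeric(D); dbk <- numeric(D); dbv <- numeric(D)
  dr <- matrix(0, P, D)
  for (n in seq_len(N)) {
    cs <- cache$per_sample[[n]]
    dO <- matrix(dy[, , , , n], P, D)
    dQ <- matrix(0, P, D); dK <- matrix(0, P, D); dV <- matrix(0, P, D)
    for (i in seq_len(n_heads)) {
      cols <- ((i - 1) * dh + 1):(i * dh)
      A <- cs$A[[i]]
      Qi <- cs$Q[, cols, drop = FALSE]; Ki <- cs$K[, cols, drop = FALSE]
      Vi <- cs$V[, cols, drop = FALSE]; ri <- r[, cols, drop = FALSE]
      dOi <- dO[, cols, drop = FALSE]
      dA <- tcrossprod(dOi, Vi)
      dV[, cols] <- crossprod(A, dOi)
      dL <- A * (dA - rowSums(dA * A)) * scale
      dQ[, cols] <- dL %*% (Ki + ri)
      dK[, cols] <- crossprod(dL, Qi + ri)
      dr[, cols] <- dr[, cols] + crossprod(dL, Qi) + dL %*% Ki
    }
    X <- cs$X
    dwq <- dwq + crossprod(X, dQ); dbq <- dbq + colSums(dQ)
    dwk <- dwk + crossprod(X, dK); dbk <- dbk + colSums(dK)
    dwv <- dwv + crossprod(X, dV); dbv <- dbv + colSums(dV)
    dx[, , , , n] <- tcrossprod(dQ, w$wq) + tcrossprod(dK, w$wk) +
      tcrossprod(dV, w$wv)
  }
  # fold the broadcast r gradient back onto the three tables
  hidx <- rep_len(seq_len(H), P)
  widx <- rep(rep(seq_len(W), each = H), times = T0)
  tidx <- rep(seq_len(T0), each = H * W)
  list(dx = dx, dwq = dwq, dwk = dwk, dwv = dwv, dbq = dbq, dbk = dbk,
       dbv = dbv,
       drt = rowsum(dr, tidx, reorder = TRUE),
       drh = rowsum(dr, hidx, reorder = TRUE),
       drw = rowsum(dr, widx, reorder = TRUE))
}

#' Loop-based reference for [mhsa3d()]
#'
#' Computes the identical quantity with explicit nested loops over query and
#' key positions and scalar softmax accumulation, sharing no code with the
#' vectorized path. Intended as an independent oracle on tiny inputs.
#'
#' @inheritParams mhsa3d
#' @return Array shaped like `x`.
#' @export
mhsa3d_reference <- function(x, w, rpe, n_heads) {
  d <- dim(x); H <- d[1]; W <- d[2]; T0 <- d[3]; D <- d[4]; N <- d[5]
  P <- H * W * T0
  if (P > 512) {
    stop_efnet("reference oracle is for tiny inputs (P <= 512)",
               class = "efnet_config_error")
  }
  dh <- D %/% n_heads
  # position p (1-based, h fastest, then w, then t) -> (h, w, t)
  pos <- function(p) {
    p0 <- p - 1L
    c(h = p0 %% H + 1L, w = (p0 %/% H) %% W + 1L, t = p0 %/% (H * W) + 1L)
  }
  feat <- function(n, p) {
    g <- pos(p)
    sapply(seq_len(D), function(cc) x[g["h"], g["w"], g["t"], cc, n])
  }
  rvec <- function(p) {
    g <- pos(p)
    sapply(seq_len(D), function(cc) {
      rpe$rt[g["t"], cc] + rpe$rh[g["h"], cc] + rpe$rw[g["w"], cc]
    })
  }
  proj <- function(f, wm, b) {
    out <- numeric(D)
    for (j in seq_len(D)) {
      s <- b[j]
      for (k in seq_len(D)) s <- s + f[k] * wm[k, j]
      out[j] <- s
    }
    out
  }
  y <- array(0, d)
  for (n in seq_len(N)) {
    Q <- K <- V <- R <- matrix(0, P, D)
    for (p in seq_len(P)) {
      f <- feat(n, p)
      Q[p, ] <- proj(f, w$wq, w$bq)
      K[p, ] <- proj(f, w$wk, w$bk)
      V[p, ] <- proj(f, w$wv, w$bv)
      R[p, ] <- rvec(p)
    }
    for (i in seq_len(n_heads)) {
      cols <- ((i - 1) * dh + 1):(i * dh)
      for (p in seq_len(P)) {
        logits <- numeric(P)
        for (q in seq_len(P)) {
          s <- 0
          for (cc in cols) {
            s <- s + Q[p, cc] * K[q, cc] + Q[p, cc] * R[q, cc] + R[p, cc] * K[q, cc]
          }
          logits[q] <- s / sqrt(dh)
        }
        ex <- exp(logits - max(logits))
        a <- ex / sum(ex)
        for (cc in cols) {
          acc <- 0
          for (q in seq_len(P)) acc <- acc + a[q] * V[q, cc]
          g <- pos(p)
          y[g["h"], g["w"], g["t"], cc, n] <- acc
        }
      }
    }
  }
  y
}
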