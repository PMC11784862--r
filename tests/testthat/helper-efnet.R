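# Shared fixtures: everything is generated in code at test time.

# A tiny but structurally complete model configuration (RTMs in both
# stages, divisibility constraints satisfied).
tiny_config <- function(...) {
  efnet_config(clip_len = 8L, height = 16L, width = 16L,
               channels = c(4L, 4L, 4L, 8L, 8L), n_heads = 2L,
               fc_bias_init = 0, ...)
}

# Deterministic little phantom dataset on disk; returns its root.
tiny_dataset <- function(n = 6, seed = 42, image_size = 32,
                         dir = tempfile("efds")) {
  generate_phantom_dataset(n, dir, seed = seed,
                           sampler = phantom_sampler(image_size = image_size))
  dir
}

# Random feature map + matching MHSA weights/RPE for attention tests.
random_attention_case <- function(H, W, T, D, N = 1, n_heads = 1,
                                  rpe_sd = 0.1) {
  list(x = array(rnorm(H * W * T * D * N), c(H, W, T, D, N)),
       w = efnet:::mhsa_weight_init(D),
       rpe = rpe_init(T, H, W, D, rpe_sd),
       n_heads = n_heads)
}

# Central finite difference against an analytic gradient at a few indices.
max_grad_err <- function(f, x, grad, idx, eps = 1e-5) {
  max(abs(vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps) - grad[i]
  }, numeric(1))))
}
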