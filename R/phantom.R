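# Synthetic echocardiogram phantoms: a pulsating elliptical blood pool inside
# a bright myocardial ring, seen through an ultrasound scan cone with
# multiplicative speckle. The per-frame ventricular volume trace is analytic,
# so every phantom has an exactly known EF and known ED/ES frames, and the
# whole dataset is written in the same on-disk layout as real data.

#' Phantom simulation parameters
#'
#' @param target_ef Target ejection fraction in percent, in (5, 85).
#' @param edv End-diastolic volume in mL, in `[40, 250]`.
#' @param cycle_frames Frames per cardiac cycle (>= 8).
#' @param n_cycles Number of cycles in the loop (>= 1).
#' @param fps Frame rate written to the container.
#' @param image_size Square frame edge in pixels.
#' @param cone_half_angle Scan-cone half angle in degrees.
#' @param speckle_sigma Multiplicative speckle scale (0 disables noise).
#' @param pool_brightness,myocardium_brightness,tissue_brightness Gray levels
#'   of the blood pool, the myocardial ring and the surrounding tissue.
#' @param volume_exponent Sharpness `p` of the volume waveform
#'   `V(t) = ESV + (EDV-ESV) * ((1+cos(2*pi*t/cycle_frames))/2)^p`.
#' @param seed Optional RNG seed for the speckle stream.
#' @return A `phantom_params` list; `esv` is derived from `target_ef` and `edv`.
#' @export
phantom_params <- function(target_ef = 55.7, edv = 91.0, cycle_frames = 16L,
                           n_cycles = 2L, fps = 50, image_size = 112L,
                           cone_half_angle = 36, speckle_sigma = 0.05,
                           pool_brightness = 25, myocardium_brightness = 200,
                           tissue_brightness = 120, volume_exponent = 1,
                           seed = NULL) {
  if (!is.finite(target_ef) || target_ef <= 0 || target_ef >= 100) {
    stop_efnet("target_ef must lie in (0, 100)", class = "efnet_domain_error")
  }
  if (edv <= 0) stop_efnet("edv must be positive", class = "efnet_domain_error")
  if (cycle_frames < 8 || cycle_frames %% 2 != 0) {
    # even so the mid-cycle frame attains ESV exactly (the ES annotation)
    stop_efnet("cycle_frames must be an even integer >= 8",
               class = "efnet_domain_error")
  }
  esv <- edv * (1 - target_ef / 100)
  structure(list(target_ef = target_ef, edv = edv, esv = esv,
                 cycle_frames = as.integer(cycle_frames),
                 n_cycles = as.integer(n_cycles), fps = fps,
                 image_size = as.integer(image_size),
                 cone_half_angle = cone_half_angle,
                 speckle_sigma = speckle_sigma,
                 pool_brightness = pool_brightness,
                 myocardium_brightness = myocardium_brightness,
                 tissue_brightness = tissue_brightness,
                 volume_exponent = volume_exponent, seed = seed),
            class = "phantom_params")
}

#' Per-frame ventricular volume trace
#'
#' Raised-cosine volume waveform: frame 0 of every cycle attains EDV, the
#' mid-cycle frame attains ESV, and the trace repeats every `cycle_frames`.
#'
#' @param params A [phantom_params()] object.
#' @return Numeric vector of per-frame volumes (mL), length
#'   `cycle_frames * n_cycles`.
#' @export
make_volume_trace <- function(params) {
  t <- seq_len(params$cycle_frames * params$n_cycles) - 1
  shape <- ((1 + cos(2 * pi * t / params$cycle_frames)) / 2)^params$volume_exponent
  params$esv + (params$edv - params$esv) * shape
}

# Scan-cone mask: apex centered near the top edge, opening downwards,
# truncated at a maximum depth just inside the frame.
cone_mask <- function(size, half_angle_deg) {
  apex_r <- -0.04 * size; apex_c <- (size + 1) / 2
  r <- matrix(seq_len(size), size, size)
  c <- matrix(seq_len(size), size, size, byrow = TRUE)
  depth <- r - apex_r
  lateral <- abs(c - apex_c)
  within_angle <- lateral <= tan(half_angle_deg * pi / 180) * depth
  within_depth <- sqrt(depth^2 + lateral^2) <= 1.06 * size
  within_angle & within_depth & depth > 0
}

#' Render one phantom frame
#'
#' Draws a dark elliptical blood pool (pixel area proportional to
#' `volume^(2/3)`, the cross-section of a volume) inside a bright myocardial
#' ring, over speckled tissue, masked by the scan cone (outside-cone pixels
#' are 0).
#'
#' @param volume Instantaneous ventricular volume in mL.
#' @param params A [phantom_params()] object.
#' @return Integer matrix `image_size x image_size` with values in `[0, 255]`.
#' @export
render_frame <- function(volume, params) {
  if (!is.finite(volume) || volume < 0) {
    stop_efnet("volume must be non-negative", class = "efnet_domain_error")
  }
  n <- params$image_size
  # Pool cross-section area: calibrated so the largest supported volume
  # (250 mL) fills an ellipse with long axis ~55% of the frame.
  area_max <- pi * (0.275 * n) * (0.275 * n / 1.5)
  area <- area_max * (volume / 250)^(2 / 3)
  b <- sqrt(area * 1.5 / pi)      # semi-axis along image rows (long axis)
  a <- b / 1.5                    # semi-axis along image columns
  tau <- 0.12                     # myocardial wall thickness, relative

  cy <- 0.55 * n; cx <- 0.5 * n
  r <- matrix(seq_len(n), n, n)
  c <- matrix(seq_len(n), n, n, byrow = TRUE)
  # anti-aliased elliptical coverage: ~1 px soft edge, so frame statistics
  # vary smoothly (and strictly monotonically) with volume
  cov_ellipse <- function(sa, sb) {
    rn <- sqrt(((r - cy) / sb)^2 + ((c - cx) / sa)^2)
    clamp(0.5 - (rn - 1) * min(sa, sb), 0, 1)
  }
  cov_out <- cov_ellipse(a * (1 + tau), b * (1 + tau))
  cov_in <- cov_ellipse(a, b)
  img <- params$tissue_brightness * (1 - cov_out) +
    params$myocardium_brightness * cov_out
  img <- img * (1 - cov_in) + params$pool_brightness * cov_in
  if (params$speckle_sigma > 0) {
    img <- img * (1 + params$speckle_sigma * matrix(rnorm(n * n), n, n))
  }
  img[!cone_mask(n, params$cone_half_angle)] <- 0
  matrix(as.integer(round(clamp(img, 0, 255))), n, n)
}

# Full loop for one phantom: returns gray_video + its volume trace.
render_phantom_video <- function(params) {
  run <- function() {
    vols <- make_volume_trace(params)
    n <- params$image_size
    px <- array(0L, c(n, n, length(vols)))
    for (t in seq_along(vols)) px[, , t] <- render_frame(vols[t], params)
    list(video = gray_video(px, fps = params$fps), volumes = vols)
  }
  if (is.null(params$seed)) run() else with_seed(params$seed, run())
}

#' Default phantom parameter sampler
#'
#' Draws EF uniformly on (15, 80) and EDV from a normal with the cohort
#' moments of the reference dataset (mean 91.0, SD 45.7 mL) truncated to
#' `[40, 250]`; all remaining parameters come from [phantom_params()]
#' defaults overridden by `...`.
#'
#' @param ... Fixed overrides passed to [phantom_params()] for every draw.
#' @return A function of no arguments returning a `phantom_params` object
#'   (consumes the current RNG stream).
#' @export
phantom_sampler <- function(...) {
  fixed <- list(...)
  function() {
    ef <- runif(1, 15, 80)
    repeat {
      edv <- rnorm(1, 91.0, 45.7)
      if (edv >= 40 && edv <= 250) break
    }
    do.call(phantom_params, c(list(target_ef = ef, edv = edv), fixed))
  }
}

#' Generate a phantom dataset on disk
#'
#' Renders `n_videos` phantoms and writes them in the layout that
#' [read_dataset()] consumes. Each record's EF/EDV/ESV come from its analytic
#' volume trace; `ed_frame` is the frame of maximal volume and `es_frame` the
#' first minimal-volume frame after it within the first cycle. Splits are
#' assigned 80/10/10 by a seeded shuffle. The whole dataset is a pure
#' function of `(n_videos, sampler, seed)`.
#'
#' @param n_videos Number of phantoms (>= 1).
#' @param out_dir Output directory.
#' @param seed Integer RNG seed.
#' @param sampler A parameter sampler as returned by [phantom_sampler()].
#' @param split_fractions TRAIN/VAL/TEST fractions (sum to 1).
#' @return Invisibly, the dataset root.
#' @export
generate_phantom_dataset <- function(n_videos, out_dir, seed = 1L,
                                     sampler = phantom_sampler(),
                                     split_fractions = c(0.8, 0.1, 0.1)) {
  if (n_videos < 1) stop_efnet("n_videos must be >= 1", class = "efnet_domain_error")
  with_seed(seed, {
    records <- empty_records()
    videos <- vector("list", n_videos)
    for (i in seq_len(n_videos)) {
      p <- sampler()
      out <- render_phantom_video(p)
      vols <- out$volumes
      ed <- which.max(vols) - 1L
      after <- which(seq_along(vols) - 1L > ed & seq_along(vols) - 1L < p$cycle_frames)
      es <- after[which.min(vols[after + 1L])] - 0L
      es <- as.integer(es)
      records[i, ] <- list(sprintf("PH%04d", i), compute_ef(max(vols), min(vols)),
                           max(vols), min(vols), p$fps, length(vols),
                           ed, es, "TRAIN")
      videos[[i]] <- out$video
    }
    records$split <- make_splits(records, split_fractions,
                                 seed = derive_seed(seed, "split"))
    write_dataset(records, videos, out_dir)
  })
  invisible(out_dir)
}
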