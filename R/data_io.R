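# Dataset I/O in the EchoNet-Dynamic directory layout:
#   <root>/Videos/<FileName>.avi
#   <root>/FileList.csv     (FileName, EF, ESV, EDV, FPS, NumberOfFrames, Split)
#   <root>/EDESFrames.csv   (FileName, ED_Frame, ES_Frame)
# Frame indices are 0-based throughout.

#' Ejection fraction from end-diastolic and end-systolic volumes
#'
#' `EF = (EDV - ESV) / EDV * 100`, the fraction of the end-diastolic blood
#' volume ejected during one beat, in percent.
#'
#' @param edv End-diastolic volume in mL; must be positive.
#' @param esv End-systolic volume in mL; must satisfy `0 <= esv <= edv`.
#' @return EF in percent, in `[0, 100]`. Vectorized over both arguments.
#' @examples
#' compute_ef(91.0, 43.3)
#' @export
compute_ef <- function(edv, esv) {
  if (any(!is.finite(edv)) || any(edv <= 0)) {
    stop_efnet("edv must be positive and finite", class = "efnet_domain_error")
  }
  if (any(!is.finite(esv)) || any(esv < 0) || any(esv > edv)) {
    stop_efnet("esv must satisfy 0 <= esv <= edv", class = "efnet_domain_error")
  }
  (edv - esv) / edv * 100
}

#' Read a grayscale cine loop from an AVI file
#'
#' Reads an uncompressed AVI container; RGB frames are converted to grayscale
#' with the ITU-R 601 luma weights (0.299, 0.587, 0.114).
#'
#' @param path Path to an AVI file holding uncompressed 8-bit or 24-bit frames.
#' @return A `gray_video`: list with `pixels` (integer array `H x W x T`,
#'   values in `[0, 255]`) and `fps`.
#' @export
read_video <- function(path) {
  v <- read_avi_gray(path)
  structure(v, class = "gray_video")
}

#' @export
print.gray_video <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<gray_video> %d frames of %dx%d px, %.1f fps\n",
              d[3], d[1], d[2], x$fps))
  invisible(x)
}

#' Construct a grayscale video object
#'
#' @param pixels Integer array `H x W x T` of pixel values in `[0, 255]`.
#' @param fps Frames per second.
#' @return A `gray_video`.
#' @export
gray_video <- function(pixels, fps = 50) {
  stopifnot(length(dim(pixels)) == 3)
  structure(list(pixels = pixels, fps = fps), class = "gray_video")
}

#' Normalize video frames to the network input range
#'
#' Applies the affine pixel map
#' `(image - mean * max_pixel_value) / (std * max_pixel_value)` to every
#' frame and inserts a channel axis of size 1. With the defaults
#' `mean = std = 0.5` and 8-bit pixels the output range is exactly
#' `[-1, 1]`.
#'
#' @param video A `gray_video` or an `H x W x T` array of pixel values.
#' @param mean,std Normalization fractions; `std` must be positive.
#' @param max_pixel_value Pixel full-scale value (255 for 8-bit video).
#' @return A clip: numeric array of dim `H x W x T x 1`.
#' @export
normalize_frames <- function(video, mean = 0.5, std = 0.5, max_pixel_value = 255) {
  if (!is.numeric(std) || length(std) != 1 || std <= 0) {
    stop_efnet("std must be a single positive number", class = "efnet_config_error")
  }
  if (max_pixel_value <= 0) {
    stop_efnet("max_pixel_value must be positive", class = "efnet_config_error")
  }
  px <- if (inherits(video, "gray_video")) video$pixels else video
  out <- (as.double(px) - mean * max_pixel_value) / (std * max_pixel_value)
  array(out, c(dim(px)[1:3], 1L))
}

#' Invert [normalize_frames()]
#'
#' @param clip Array produced by [normalize_frames()].
#' @inheritParams normalize_frames
#' @return Numeric array `H x W x T` on the original pixel scale.
#' @export
denormalize_frames <- function(clip, mean = 0.5, std = 0.5, max_pixel_value = 255) {
  d <- dim(clip)
  array(as.double(clip) * std * max_pixel_value + mean * max_pixel_value, d[1:3])
}

.filelist_cols <- c("FileName", "EF", "ESV", "EDV", "FPS", "NumberOfFrames", "Split")
.tracing_cols <- c("FileName", "ED_Frame", "ES_Frame")

# Enforce the per-record invariants. `df` is a joined manifest data frame.
validate_records <- function(df) {
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx)) {
      stop_efnet("%s for video(s): %s", what,
                 paste(df$FileName[idx], collapse = ", "),
                 class = "efnet_validation_error")
    }
  }
  bad(df$EF < 0 | df$EF > 100, "EF outside [0, 100]")
  bad(df$EDV <= 0, "EDV not positive")
  bad(df$ESV < 0 | df$ESV > df$EDV, "ESV outside [0, EDV]")
  both <- is.finite(df$EDV) & is.finite(df$ESV)
  bad(both & abs(df$EF - compute_ef(pmax(df$EDV, 1e-12), pmin(df$ESV, df$EDV))) > 0.5,
      "EF inconsistent with (EDV - ESV)/EDV * 100 by more than 0.5")
  bad(!(df$Split %in% c("TRAIN", "VAL", "TEST")), "Split not in {TRAIN, VAL, TEST}")
  bad(df$ED_Frame < 0 | df$ED_Frame >= df$NumberOfFrames, "ED frame out of range")
  bad(df$ES_Frame < 0 | df$ES_Frame >= df$NumberOfFrames, "ES frame out of range")
  bad(df$ED_Frame == df$ES_Frame, "ED and ES frames coincide")
  invisible(df)
}

#' Read the dataset manifests
#'
#' Joins the file list (per-video EF/ESV/EDV/FPS/frame-count/split) with the
#' ED/ES frame-annotation table on `FileName`. Videos without an ED/ES
#' annotation cannot anchor training clips and are dropped with a warning.
#'
#' @param filelist_path CSV with columns
#'   `FileName, EF, ESV, EDV, FPS, NumberOfFrames, Split`.
#' @param tracings_path CSV with columns `FileName, ED_Frame, ES_Frame`
#'   (0-based frame indices).
#' @return A data frame of video records (one row per annotated video) with
#'   columns `video_id, ef, edv, esv, fps, n_frames, ed_frame, es_frame, split`.
#' @export
read_manifest <- function(filelist_path, tracings_path) {
  # FileName must never be numeric-coerced (ids like 0X100E... parse as hex)
  fl <- read.csv(filelist_path, stringsAsFactors = FALSE,
                 colClasses = c(FileName = "character"))
  tr <- read.csv(tracings_path, stringsAsFactors = FALSE,
                 colClasses = c(FileName = "character"))
  miss <- setdiff(.filelist_cols, names(fl))
  if (length(miss)) {
    stop_efnet("file list is missing column(s): %s", paste(miss, collapse = ", "),
               class = "efnet_schema_error")
  }
  miss <- setdiff(.tracing_cols, names(tr))
  if (length(miss)) {
    stop_efnet("tracings table is missing column(s): %s", paste(miss, collapse = ", "),
               class = "efnet_schema_error")
  }
  if (nrow(fl) == 0) return(empty_records())
  fl$FileName <- sub("\\.avi$", "", fl$FileName)
  tr$FileName <- sub("\\.avi$", "", tr$FileName)
  df <- merge(fl, tr[, .tracing_cols], by = "FileName", all.x = TRUE, sort = FALSE)
  unann <- !is.finite(df$ED_Frame) | !is.finite(df$ES_Frame)
  if (any(unann)) {
    warning(sprintf("dropping %d video(s) without ED/ES annotation: %s",
                    sum(unann), paste(head(df$FileName[unann], 5), collapse = ", ")))
    df <- df[!unann, , drop = FALSE]
  }
  if (nrow(df) == 0) return(empty_records())
  validate_records(df)
  data.frame(video_id = df$FileName, ef = df$EF, edv = df$EDV, esv = df$ESV,
             fps = df$FPS, n_frames = df$NumberOfFrames,
             ed_frame = as.integer(df$ED_Frame), es_frame = as.integer(df$ES_Frame),
             split = df$Split, stringsAsFactors = FALSE)
}

empty_records <- function() {
  data.frame(video_id = character(), ef = double(), edv = double(),
             esv = double(), fps = double(), n_frames = integer(),
             ed_frame = integer(), es_frame = integer(), split = character(),
             stringsAsFactors = FALSE)
}

#' Write a dataset in the EchoNet-Dynamic layout
#'
#' Creates `Videos/` with one uncompressed AVI per record plus the two CSV
#' manifests accepted by [read_manifest()]. The uncompressed codec makes
#' read-back pixel-identical.
#'
#' @param records Data frame as returned by [read_manifest()].
#' @param videos List of `gray_video` objects, same length/order as `records`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `filelist` and `tracings` paths and `root`.
#' @export
write_dataset <- function(records, videos, out_dir) {
  if (nrow(records) != length(videos)) {
    stop_efnet("records (%d) and videos (%d) differ in length",
               nrow(records), length(videos), class = "efnet_validation_error")
  }
  vdir <- file.path(out_dir, "Videos")
  dir.create(vdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(vdir)) {
    stop_efnet("cannot create %s", vdir, class = "efnet_io_error")
  }
  for (i in seq_along(videos)) {
    v <- videos[[i]]
    write_avi_gray(v$pixels, file.path(vdir, paste0(records$video_id[i], ".avi")),
                   fps = v$fps)
  }
  fl <- data.frame(FileName = records$video_id, EF = records$ef,
                   ESV = records$esv, EDV = records$edv, FPS = records$fps,
                   NumberOfFrames = records$n_frames, Split = records$split)
  tr <- data.frame(FileName = records$video_id, ED_Frame = records$ed_frame,
                   ES_Frame = records$es_frame)
  fl_path <- file.path(out_dir, "FileList.csv")
  tr_path <- file.path(out_dir, "EDESFrames.csv")
  write.csv(fl, fl_path, row.names = FALSE, quote = FALSE)
  write.csv(tr, tr_path, row.names = FALSE, quote = FALSE)
  invisible(list(filelist = fl_path, tracings = tr_path, root = out_dir))
}

#' Read a dataset root directory
#'
#' Convenience wrapper: reads both manifests from `root` and returns records.
#'
#' @param root Dataset root containing `FileList.csv`, `EDESFrames.csv`, `Videos/`.
#' @return Records data frame; see [read_manifest()].
#' @export
read_dataset <- function(root) {
  read_manifest(file.path(root, "FileList.csv"), file.path(root, "EDESFrames.csv"))
}

#' Path of one video inside a dataset root
#' @param root Dataset root directory.
#' @param video_id Record id (file name without extension).
#' @return The AVI file path.
#' @export
video_path <- function(root, video_id) file.path(root, "Videos", paste0(video_id, ".avi"))
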