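# Minimal RIFF/AVI container support for uncompressed device-independent
# bitmap ('DIB ') video streams. This is all the echocardiogram pipeline
# needs: fixture and phantom files are written with the uncompressed 24-bit
# BI_RGB codec so read/write round-trips are bit-exact, and reading supports
# 8-bit palettized and 24-bit BI_RGB frames (top-down or bottom-up).
# Compressed streams are rejected with a format error.

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
.fcc <- function(s) charToRaw(s)

.rd_u32 <- function(b, off) {
  v <- as.double(as.integer(b[off + 1:4]))
  v[1] + 256 * v[2] + 65536 * v[3] + 16777216 * v[4]
}
.rd_u16 <- function(b, off) {
  v <- as.integer(b[off + 1:2]); v[1] + 256L * v[2]
}
.rd_i32 <- function(b, off) {
  v <- .rd_u32(b, off); if (v >= 2^31) v - 2^32 else v
}
.rd_fcc <- function(b, off) rawToChar(b[off + 1:4])

.riff_chunk <- function(id, payload) {
  n <- length(payload)
  c(.fcc(id), .u32(n), payload, if (n %% 2L == 1L) as.raw(0L))
}
.riff_list <- function(type, payload) .riff_chunk("LIST", c(.fcc(type), payload))

# frames: integer array (H, W, T) with values in [0, 255]
write_avi_gray <- function(frames, path, fps = 50) {
  stopifnot(length(dim(frames)) == 3)
  d <- dim(frames); H <- d[1]; W <- d[2]; T0 <- d[3]
  if (any(frames < 0 | frames > 255)) {
    stop_efnet("pixel values outside [0, 255]", class = "efnet_format_error")
  }
  w3 <- W * 3L
  pad <- (4L - w3 %% 4L) %% 4L
  rowbytes <- w3 + pad
  framebytes <- rowbytes * H

  frame_raw <- function(t) {
    m <- frames[H:1, , t, drop = TRUE]          # bottom-up scanlines
    bytes <- matrix(0L, rowbytes, H)
    bytes[seq_len(w3), ] <- matrix(rep(as.integer(t(m)), each = 3L), w3, H)
    as.raw(bytes)
  }

  rate <- as.integer(round(fps * 1000)); scale <- 1000L
  avih <- c(.u32(round(1e6 / fps)), .u32(framebytes * ceiling(fps)),
            .u32(0), .u32(16),       # AVIF_HASINDEX
            .u32(T0), .u32(0), .u32(1), .u32(framebytes),
            .u32(W), .u32(H), .u32(0), .u32(0), .u32(0), .u32(0))
  strh <- c(.fcc("vids"), .fcc("DIB "), .u32(0), .u16(0), .u16(0),
            .u32(0), .u32(scale), .u32(rate), .u32(0), .u32(T0),
            .u32(framebytes), .u32(0), .u32(0),
            .u16(0), .u16(0), .u16(W), .u16(H))
  strf <- c(.u32(40), .u32(W), .u32(H), .u16(1), .u16(24), .u32(0),
            .u32(framebytes), .u32(0), .u32(0), .u32(0), .u32(0))
  hdrl <- .riff_list("hdrl", c(
    .riff_chunk("avih", avih),
    .riff_list("strl", c(.riff_chunk("strh", strh), .riff_chunk("strf", strf)))
  ))

  movi_payload <- .fcc("movi")
  idx <- raw(0)
  offset <- 4L                                 # from the 'movi' fourcc
  for (t in seq_len(T0)) {
    movi_payload <- c(movi_payload, .riff_chunk("00db", frame_raw(t)))
    idx <- c(idx, .fcc("00db"), .u32(16), .u32(offset), .u32(framebytes))
    offset <- offset + 8L + framebytes
  }
  movi <- .riff_chunk("LIST", movi_payload)
  body <- c(.fcc("AVI "), hdrl, movi, .riff_chunk("idx1", idx))

  con <- file(path, "wb"); on.exit(close(con))
  writeBin(c(.fcc("RIFF"), .u32(length(body)), body), con)
  invisible(path)
}

.luma <- function(r, g, b) as.integer(round(0.299 * r + 0.587 * g + 0.114 * b))

read_avi_gray <- function(path) {
  if (!file.exists(path)) {
    stop_efnet("video file not found: %s", path, class = "efnet_io_error")
  }
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 12 || .rd_fcc(bytes, 0) != "RIFF" || .rd_fcc(bytes, 8) != "AVI ") {
    stop_efnet("not a RIFF/AVI file: %s", path, class = "efnet_format_error")
  }

  width <- height <- bitcount <- compression <- NULL
  palette <- NULL
  fps <- NA_real_
  frames_raw <- list()

  walk <- function(pos, end) {
    while (pos + 8 <= end) {
      id <- .rd_fcc(bytes, pos)
      sz <- .rd_u32(bytes, pos + 4)
      data0 <- pos + 8
      if (id == "LIST") {
        type <- .rd_fcc(bytes, data0)
        walk(data0 + 4, data0 + sz)
      } else if (id == "strh") {
        if (.rd_fcc(bytes, data0) == "vids" && is.na(fps)) {
          scl <- .rd_u32(bytes, data0 + 20); rate <- .rd_u32(bytes, data0 + 24)
          if (scl > 0) fps <<- rate / scl
        }
      } else if (id == "strf" && is.null(width)) {
        width <<- .rd_i32(bytes, data0 + 4)
        height <<- .rd_i32(bytes, data0 + 8)
        bitcount <<- .rd_u16(bytes, data0 + 14)
        compression <<- .rd_u32(bytes, data0 + 16)
        if (bitcount == 8 && sz >= 40 + 4 * 256) {
          pal <- matrix(as.integer(bytes[data0 + 40 + seq_len(4 * 256)]), 4, 256)
          palette <<- .luma(pal[3, ], pal[2, ], pal[1, ])   # entries are BGRX
        }
      } else if (grepl("^..(db|dc)$", id) && substr(id, 1, 2) == "00" && sz > 0) {
        frames_raw[[length(frames_raw) + 1L]] <<- bytes[data0 + seq_len(sz)]
      }
      pos <- data0 + sz + (sz %% 2)
    }
  }
  walk(12, length(bytes))

  if (is.null(width)) {
    stop_efnet("no video stream format in %s", path, class = "efnet_format_error")
  }
  if (!is.null(compression) && compression != 0) {
    stop_efnet("compressed AVI codec (biCompression=%d) not supported: %s",
               compression, path, class = "efnet_format_error")
  }
  if (length(frames_raw) == 0) {
    stop_efnet("AVI container holds zero frames: %s", path, class = "efnet_format_error")
  }

  topdown <- height < 0
  H <- abs(height); W <- width
  decode <- function(fr) {
    if (bitcount == 24) {
      rowbytes <- (W * 3 + 3) %/% 4 * 4
      m <- matrix(as.integer(fr[seq_len(rowbytes * H)]), rowbytes, H)
      bg <- m[seq(1, W * 3, by = 3), ]; gg <- m[seq(2, W * 3, by = 3), ]
      rg <- m[seq(3, W * 3, by = 3), ]
      img <- matrix(.luma(t(rg), t(gg), t(bg)), H, W)   # rows = scanlines
      if (!topdown) img <- img[H:1, , drop = FALSE]
      img
    } else if (bitcount == 8) {
      rowbytes <- (W + 3) %/% 4 * 4
      m <- matrix(as.integer(fr[seq_len(rowbytes * H)]), rowbytes, H)
      pix <- m[seq_len(W), , drop = FALSE]
      img <- t(if (is.null(palette)) pix else matrix(palette[pix + 1L], W, H))
      if (!topdown) img <- img[H:1, , drop = FALSE]
      img
    } else {
      stop_efnet("unsupported bit depth %d in %s", bitcount, path,
                 class = "efnet_format_error")
    }
  }
  arr <- array(0L, c(H, W, length(frames_raw)))
  for (t in seq_along(frames_raw)) arr[, , t] <- decode(frames_raw[[t]])
  list(pixels = arr, fps = fps)
}
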