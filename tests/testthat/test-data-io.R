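test_that("AVI round trip through the uncompressed codec is pixel-identical", {
  set.seed(1)
  px <- array(sample(0:255, 112 * 112 * 3, replace = TRUE), c(112, 112, 3))
  path <- tempfile(fileext = ".avi")
  efnet:::write_avi_gray(px, path, fps = 50.9)
  v <- read_video(path)
  expect_s3_class(v, "gray_video")
  expect_identical(dim(v$pixels), c(112L, 112L, 3L))
  expect_identical(v$pixels, px)
  expect_equal(v$fps, 50.9)
})

test_that("RGB frames reduce to ITU-R 601 luma (equal channels stay put)", {
  # all channels equal to 200 -> gray 200
  expect_equal(efnet:::.luma(200, 200, 200), 200L)
  expect_equal(efnet:::.luma(255, 0, 0), as.integer(round(0.299 * 255)))
})

test_that("missing files and empty containers raise typed errors", {
  expect_error(read_video(tempfile(fileext = ".avi")), class = "efnet_io_error")
  bogus <- tempfile(fileext = ".avi")
  writeBin(charToRaw("not an avi file at all"), bogus)
  expect_error(read_video(bogus), class = "efnet_format_error")
})

test_that("normalization maps the 8-bit range onto [-1, 1] exactly", {
  v <- gray_video(array(c(0, 127.5, 255), c(1, 1, 3)))
  clip <- normalize_frames(v)
  expect_equal(dim(clip), c(1, 1, 3, 1))
  expect_equal(as.vector(clip), c(-1, 0, 1))
  expect_error(normalize_frames(v, std = 0), class = "efnet_config_error")
})

test_that("normalize/denormalize is the identity on the full pixel range", {
  px <- array(0:255, c(16, 16, 1))
  back <- denormalize_frames(normalize_frames(px))
  expect_equal(as.vector(back), as.vector(px), tolerance = 1e-12)
})

test_that("EF formula: cohort means, boundary cases, monotonicity", {
  expect_equal(compute_ef(91.0, 43.3), (91.0 - 43.3) / 91.0 * 100, tolerance = 1e-12)
  expect_equal(compute_ef(91.0, 43.3), 52.4176, tolerance = 1e-4)
  expect_equal(compute_ef(100, 0), 100)
  expect_equal(compute_ef(100, 100), 0)
  expect_error(compute_ef(0, 0), class = "efnet_domain_error")
  expect_error(compute_ef(50, 60), class = "efnet_domain_error")
  # strictly decreasing in esv for fixed edv
  esv <- seq(0, 90, by = 5)
  expect_true(all(diff(compute_ef(rep(90, length(esv)), esv)) < 0))
})

test_that("manifest reader joins the two CSVs and enforces invariants", {
  dir <- tempfile(); dir.create(dir)
  ids <- c("0X100E3B8D3280BEC5", "0X100E491B3CD58DE2", "0X100F044876B98F90",
           "0X1002E8FBACD08477", "0X1005D03EED19C65B")
  fl <- data.frame(FileName = ids, EF = c(55, 60, 45, 70, 35),
                   ESV = c(45, 40, 55, 30, 65),
                   EDV = c(100, 100, 100, 100, 100),
                   FPS = 50, NumberOfFrames = 100, Split = "TRAIN")
  tr <- data.frame(FileName = ids, ED_Frame = 0, ES_Frame = 40)
  flp <- file.path(dir, "FileList.csv"); trp <- file.path(dir, "EDESFrames.csv")
  write.csv(fl, flp, row.names = FALSE)
  write.csv(tr, trp, row.names = FALSE)
  rec <- read_manifest(flp, trp)
  expect_equal(nrow(rec), 5)
  expect_true("0X100E3B8D3280BEC5" %in% rec$video_id)

  # empty data section -> empty records, no error
  write.csv(fl[0, ], flp, row.names = FALSE)
  expect_equal(nrow(read_manifest(flp, trp)), 0)

  # ESV > EDV -> validation error naming the video
  fl2 <- fl; fl2$ESV[2] <- 150
  write.csv(fl2, flp, row.names = FALSE)
  err <- tryCatch(read_manifest(flp, trp), error = identity)
  expect_s3_class(err, "efnet_validation_error")
  expect_match(conditionMessage(err), ids[2], fixed = TRUE)

  # EF inconsistent with the volume formula
  fl3 <- fl; fl3$EF[1] <- 90
  write.csv(fl3, flp, row.names = FALSE)
  expect_error(read_manifest(flp, trp), class = "efnet_validation_error")

  # missing column -> schema error
  write.csv(fl[, -2], flp, row.names = FALSE)
  expect_error(read_manifest(flp, trp), class = "efnet_schema_error")

  # unannotated videos are dropped with a warning
  write.csv(fl, flp, row.names = FALSE)
  write.csv(tr[1:3, ], trp, row.names = FALSE)
  expect_warning(rec <- read_manifest(flp, trp), "without ED/ES")
  expect_equal(nrow(rec), 3)
})

test_that("write_dataset + read_dataset round-trips records and pixels", {
  set.seed(2)
  vids <- lapply(1:2, function(i) gray_video(array(sample(0:255, 16 * 16 * 5,
                                                          TRUE), c(16, 16, 5))))
  rec <- data.frame(video_id = c("A1", "A2"), ef = c(55.1234, 40.5678),
                    edv = c(100, 120), esv = c(44.8766, 71.31864),
                    fps = c(50, 50), n_frames = c(5L, 5L),
                    ed_frame = c(0L, 0L), es_frame = c(2L, 3L),
                    split = c("TRAIN", "TEST"), stringsAsFactors = FALSE)
  rec$esv <- rec$edv * (1 - rec$ef / 100)
  out <- tempfile()
  paths <- write_dataset(rec, vids, out)
  back <- read_dataset(out)
  expect_equal(nrow(back), 2)
  expect_equal(back$ef, rec$ef, tolerance = 1e-4)
  expect_equal(back[, c("ed_frame", "es_frame", "split")],
               rec[, c("ed_frame", "es_frame", "split")])
  v <- read_video(video_path(out, "A1"))
  expect_identical(v$pixels, vids[[1]]$pixels)
  # zero records -> valid empty manifest
  out2 <- tempfile()
  write_dataset(rec[0, ], list(), out2)
  expect_equal(nrow(read_dataset(out2)), 0)
  # length mismatch
  expect_error(write_dataset(rec, vids[1], tempfile()),
               class = "efnet_validation_error")
})
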