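test_that("multi-page TIFF round trip is lossless for every supported dtype", {
  set.seed(11)
  for (dt in c("uint8", "uint16", "float32")) {
    rng <- if (dt == "uint8") 255 else 65535
    pages <- lapply(1:5, function(i) {
      if (dt == "float32") matrix(runif(12 * 9) * 1e4, 12, 9)
      else matrix(sample(0:rng, 108, TRUE), 12, 9)
    })
    f <- withr::local_tempfile(fileext = ".tif")
    write_tiff(pages, f, dtype = dt)
    back <- read_tiff(f)
    expect_length(back, 5)
    if (dt == "float32") {
      # float32 storage: exact to single precision
      expect_equal(back, pages, tolerance = 1e-6)
    } else {
      expect_identical(lapply(back, as.integer), lapply(pages, as.integer))
    }
  }
})

test_that("TIFF files interoperate with an independent reader/writer", {
  f <- withr::local_tempfile(fileext = ".tif")
  pages <- lapply(1:3, function(i) matrix(seq_len(30) * i, 5, 6))
  write_tiff(pages, f, dtype = "uint16")
  script <- paste0(
    "import tifffile, sys\n",
    "a = tifffile.imread(sys.argv[1])\n",
    "print(a.shape[0], a.shape[1], a.shape[2], int(a.sum()))\n")
  out <- system2("python", c("-c", shQuote(script), shQuote(f)), stdout = TRUE)
  got <- as.numeric(strsplit(out, " ")[[1]])
  expect_equal(got, c(3, 5, 6, sum(unlist(pages))))

  # and read a file the independent writer produced
  f2 <- withr::local_tempfile(fileext = ".tif")
  script2 <- paste0(
    "import tifffile, numpy as np, sys\n",
    "a = (np.arange(60).reshape(2, 5, 6) * 7 % 1000).astype('uint16')\n",
    "tifffile.imwrite(sys.argv[1], a, photometric='minisblack')\n")
  system2("python", c("-c", shQuote(script2), shQuote(f2)))
  back <- read_tiff(f2)
  expect_length(back, 2)
  expect_equal(back[[1]][1, ], as.numeric((0:5) * 7 %% 1000))
  expect_equal(back[[2]][5, 6], (59 * 7) %% 1000)
})

test_that("read_stack honors declared channel layout and calibration", {
  set.seed(12)
  arrs <- list(f340 = array(sample(0:500, 8 * 7 * 4, TRUE), c(8, 7, 4)),
               f380 = array(sample(0:500, 8 * 7 * 4, TRUE), c(8, 7, 4)))
  rec <- TimeLapseRecording(arrs, dt = 0.5, pixel_size = 1.5)
  for (layout in c("interleaved", "blocks")) {
    f <- withr::local_tempfile(fileext = ".tif")
    md <- write_stack(rec, f, dtype = "uint16", layout = layout)
    back <- read_stack(f, md)
    expect_equal(back$channels$f340, arrs$f340)
    expect_equal(back$channels$f380, arrs$f380)
    expect_equal(back$dt, 0.5)
    expect_equal(back$pixel_size, 1.5)
  }
  # 10-page single channel
  f <- withr::local_tempfile(fileext = ".tif")
  write_tiff(lapply(1:10, function(i) matrix(i, 4, 4)), f, dtype = "uint8")
  rec1 <- read_stack(f, list(channels = "brightfield", dt = 1, pixel_size = 1))
  expect_equal(n_frames(rec1), 10)
  # page count not divisible by channel count
  expect_error(read_stack(f, list(channels = c("a", "b", "c"), dt = 1, pixel_size = 1)),
               "divisible")
  # bad calibration
  expect_error(TimeLapseRecording(list(brightfield = array(0, c(2, 2, 2))),
                                  dt = 0, pixel_size = 1), "dt")
  expect_error(read_stack("no/such/file.tif", list(channels = "a", dt = 1,
                                                   pixel_size = 1)))
})

test_that("recording invariants are enforced", {
  a <- array(1, c(4, 4, 3)); b <- array(1, c(4, 5, 3))
  expect_error(TimeLapseRecording(list(f340 = a, f380 = b), 1, 1), "identical")
  expect_error(TimeLapseRecording(list(f340 = a), 1, 1, t0_index = 4), "t0_index")
  rec <- TimeLapseRecording(list(f340 = a), 1, 1)
  expect_equal(frame_times(rec), c(0, 1, 2))
  expect_error(get_channel(rec, "gcamp"), "not present")
})

test_that("write_results emits deterministic CSV incl. header-only files", {
  dir <- withr::local_tempdir()
  fs <- flow_change(c(0, 1, 3), smoothing_window = 1L)
  tabs <- flow_to_df(fs)
  tabs$empty <- data.frame(roi = character(0), value = numeric(0))
  files <- write_results(tabs, dir)
  s <- read.csv(file.path(dir, "s.csv"))
  expect_equal(nrow(s), 3)
  expect_equal(names(s), c("frame", "time_s", "s", "s_smooth"))
  cc <- read.csv(file.path(dir, "c.csv"))
  expect_equal(nrow(cc), 2)
  expect_equal(cc$c, c(1, 2))
  e <- read.csv(file.path(dir, "empty.csv"))
  expect_equal(nrow(e), 0)
  expect_equal(names(e), c("roi", "value"))
  # round trip within float formatting
  tr <- SignalTrace(0:4, c(1, 2, 1.5, 1.25, 3), kind = "ratio", roi = "ROI 0")
  write_results(list(trace = trace_to_df(tr)), dir)
  back <- read.csv(file.path(dir, "trace.csv"))
  expect_equal(back$value, tr$values)
  expect_equal(back$time_s, tr$times)
})

test_that("config reading validates metadata and builds protocols", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    metadata = list(channels = c("f340", "f380"), dt = 1, pixel_size = 2),
    stimulus = list(onsets = c(30, 120), duration = 10, agent = "ATP",
                    concentration = 100)
  ), f, auto_unbox = TRUE)
  cfg <- read_config(f)
  expect_equal(cfg$metadata$channels, c("f340", "f380"))
  expect_s3_class(cfg$stimulus, "StimulusProtocol")
  expect_equal(cfg$stimulus$onsets, c(30, 120))
  expect_error(StimulusProtocol(c(10, 5), 10), "increasing")
  expect_error(StimulusProtocol(10, 0), "duration")
})
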