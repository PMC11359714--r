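make_rec <- function(data, fs = 250)
  new_recording(data, fs, paste0("ch", seq_len(nrow(data))))

test_that("artifact marking thresholds absolute amplitude", {
  rec <- make_rec(matrix(0, 2, 100))
  expect_false(any(mark_artifacts(rec, 100)))
  rec2 <- make_rec(rbind(c(rep(0, 99), 150), rep(0, 100)))
  mk <- mark_artifacts(rec2, 100)
  expect_true(mk[1, 100]); expect_equal(sum(mk), 1)
  ramp <- seq(-200, 200, length.out = 401)
  mk3 <- mark_artifacts(make_rec(matrix(ramp, 1)), 100)
  expect_equal(sum(mk3), sum(abs(ramp) > 100))
  expect_error(mark_artifacts(rec, -5), "positive")
})

test_that("zero-phase band-pass keeps the band, kills the stop band and DC", {
  fs <- 250; t <- seq(0, 4, by = 1 / fs)[-1]
  in_band <- sin(2 * pi * 20 * t)
  out <- bandpass(make_rec(matrix(in_band, 1), fs), 8, 30)
  mid <- 200:800
  expect_lt(abs(sd(out$data[1, mid]) / sd(in_band[mid]) - 1), 0.05)
  low <- sin(2 * pi * 2 * t)
  out2 <- bandpass(make_rec(matrix(low, 1), fs), 8, 30)
  expect_lt(sd(out2$data[1, mid]), 0.1 * sd(low[mid]))
  dc <- matrix(7, 1, 1000)
  out3 <- bandpass(make_rec(dc, fs), 8, 30)
  expect_lt(abs(mean(out3$data[1, 200:800])), 1e-6)
  expect_lt(max(abs(out3$data[1, 200:800])), 1e-4)
  expect_error(bandpass(make_rec(dc, fs), 30, 8), "band edges")
})

test_that("band-pass preserves shape and is linear", {
  fs <- 250
  set.seed(4)
  x <- matrix(rnorm(3 * 1000), 3)
  y <- matrix(rnorm(3 * 1000), 3)
  fx <- bandpass(make_rec(x, fs), 1, 45)$data
  fy <- bandpass(make_rec(y, fs), 1, 45)$data
  fxy <- bandpass(make_rec(2 * x - 3 * y, fs), 1, 45)$data
  expect_identical(dim(fx), dim(x))
  expect_equal(fxy, 2 * fx - 3 * fy, tolerance = 1e-8)
})

ramp_epochs <- function() {
  # 2 trials x 2 channels x 750 samples at 250 Hz, cue at sample 501
  arr <- array(0, c(2, 2, 750))
  arr[1, 1, ] <- 7
  arr[2, 1, ] <- seq_len(750)
  arr[, 2, ] <- rnorm(1500)
  new_epochs(arr, c("left_hand", "foot"), 250, cue_sample = 501,
             round_id = c(1, 2))
}

test_that("baseline correction subtracts the pre-cue window mean and is idempotent", {
  set.seed(8)
  ep <- ramp_epochs()
  bc <- baseline_correct(ep)
  # window [-200, 0] ms at 250 Hz = 50 samples just before the cue
  win <- 451:500
  expect_length(win, 50)
  expect_true(all(abs(apply(bc$data[, , win], c(1, 2), mean)) < 1e-10))
  expect_true(all(bc$data[1, 1, ] == 0))          # constant channel -> zero
  ref <- ep$data[2, 1, ] - mean(ep$data[2, 1, win])
  expect_equal(bc$data[2, 1, ], ref, tolerance = 1e-12)
  bc2 <- baseline_correct(bc)
  expect_equal(bc2$data, bc$data, tolerance = 1e-10)
  expect_error(baseline_correct(ep, c(-5000, 0)), "outside the epoch")
})

test_that("round-wise folds assign rounds 2k-1, 2k to test and partition trials", {
  set.seed(9)
  nt <- 400  # 40 trials per round
  arr <- array(rnorm(nt * 2 * 10), c(nt, 2, 10))
  ep <- new_epochs(arr, rep(mi_classes(), length.out = nt), 250, 5,
                   round_id = rep(1:10, each = 40))
  sp1 <- split_rounds(ep, 1)
  expect_setequal(unique(sp1$test$round_id), c(1, 2))
  expect_setequal(unique(sp1$train$round_id), 3:10)
  expect_equal(dim(sp1$train$data)[1], 320)
  expect_equal(dim(sp1$test$data)[1], 80)
  tested <- unlist(lapply(1:5, function(k)
    unique(split_rounds(ep, k)$test$round_id)))
  expect_setequal(tested, 1:10)
  expect_length(tested, 10)
  expect_error(split_rounds(ep, 6))
})

test_that("epoching cuts the documented trial layout", {
  fs <- 250
  rec <- new_recording(matrix(seq_len(2 * 5000), 2, byrow = TRUE), fs,
                       c("a", "b"))
  ep <- epoch_trials(rec, cue_samples = c(1000, 3000),
                     labels = c("left_hand", "tongue"), round_ids = c(1, 2))
  expect_equal(dim(ep$data), c(2, 2, 1500))
  expect_equal(ep$cue_sample, 501)
  # direct slicing oracle
  expect_equal(ep$data[2, 1, ], rec$data[1, 2500:3999], ignore_attr = TRUE)
  # near-degenerate single-sample epoch
  ep1 <- epoch_trials(rec, 500, pre_s = 0, post_s = 1 / fs,
                      labels = "foot", round_ids = 1)
  expect_equal(dim(ep1$data)[3], 1)
  expect_equal(drop(ep1$data[1, , 1]), unname(rec$data[, 500]))
  expect_error(epoch_trials(rec, 100, labels = "foot", round_ids = 1),
               "bounds")
})

test_that("recording and epoch CSV formats round-trip", {
  set.seed(11)
  rec <- new_recording(matrix(rnorm(12), 3), 250, c("C3", "Cz", "C4"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  rec2 <- read_recording_csv(path)
  expect_identical(rec2$channel_labels, rec$channel_labels)
  expect_equal(rec2$fs, 250)
  expect_equal(rec2$data, rec$data, tolerance = 1e-12, ignore_attr = TRUE)

  arr <- array(rnorm(2 * 3 * 8), c(2, 3, 8))
  ep <- new_epochs(arr, c("left_hand", "foot"), 250, 3, c(1, 2),
                   c("C3", "Cz", "C4"))
  dir <- withr::local_tempdir()
  write_epochs_dir(ep, dir)
  ep2 <- read_epochs_dir(dir)
  expect_equal(ep2$data, ep$data, tolerance = 1e-12)
  expect_identical(as.character(ep2$labels), as.character(ep$labels))
  expect_identical(ep2$round_id, ep$round_id)
})
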