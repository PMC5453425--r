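test_that("recording round-trips through the CSV/JSON container", {
  rec <- tiny_recording(ne = 3, n = 40)
  stem <- file.path(tempdir(), "rt_rec")
  write_recording(rec, stem)
  rec2 <- load_recording(stem)
  expect_equal(rec2$channels$V1, rec$channels$V1, ignore_attr = TRUE)
  expect_equal(rec2$channels$PFC, rec$channels$PFC, ignore_attr = TRUE)
  expect_equal(rec2$fs, rec$fs)
  expect_equal(rec2$condition, rec$condition)
  expect_equal(n_epochs(rec2), 3)
})

test_that("malformed containers raise format errors", {
  rec <- tiny_recording()
  stem <- file.path(tempdir(), "bad_rec")
  write_recording(rec, stem)
  meta <- jsonlite::read_json(paste0(stem, ".json"))
  meta$fs <- NULL
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE)
  expect_error(load_recording(stem), "fs")
  expect_error(load_recording(file.path(tempdir(), "nonexistent")),
               "not found")
  expect_error(recording(list(a = matrix(1:4, 2), b = matrix(1:6, 2)),
                         fs = 100), "identical")
})

test_that("segment_epochs drops the trailing remainder", {
  e <- segment_epochs(rnorm(10000), fs = 1000, epoch_len_s = 4.81)
  expect_equal(dim(e), c(2, 4810))
  expect_equal(dim(segment_epochs(rnorm(4810), 1000)), c(1, 4810))
  expect_error(segment_epochs(rnorm(4809), 1000), "shorter")
  # values preserved in order
  x <- 1:100
  expect_equal(as.vector(t(segment_epochs(x, 10, 3))), x[1:90])
})

test_that("znormalize gives zero mean unit SD and is idempotent", {
  z <- znormalize(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(znormalize(z), z)
  expect_error(znormalize(rep(2, 10)), "constant")
  m <- znormalize(matrix(rnorm(200, 5, 3), 4))
  expect_equal(unname(apply(m, 1, mean)), rep(0, 4))
  expect_equal(unname(apply(m, 1, sd)), rep(1, 4))
})

test_that("relative delta power separates slow from fast epochs", {
  fs <- 1000; tt <- (1:4810) / fs
  expect_gt(relative_delta_power(sin(2 * pi * 2 * tt), fs), 0.9)
  expect_lt(relative_delta_power(sin(2 * pi * 20 * tt), fs), 0.05)
  qc <- reject_by_delta(rbind(sin(2 * pi * 2 * tt), sin(2 * pi * 20 * tt)),
                        fs)
  expect_equal(qc$rejected, c(TRUE, FALSE))
  expect_equal(qc$reason, c("delta_power", ""))
  # rejection is strict: a fraction exactly at the threshold is kept
  rd <- qc$relative_delta[1]
  qc2 <- reject_by_delta(matrix(sin(2 * pi * 2 * tt), 1), fs,
                         threshold = rd)
  expect_false(qc2$rejected[1])
  # bounded in [0, 1] for arbitrary signals
  set.seed(1)
  for (i in 1:5) {
    v <- relative_delta_power(rnorm(1000), fs)
    expect_true(v >= 0 && v <= 1)
  }
})

test_that("band power concentrates where the signal lives", {
  fs <- 1000; tt <- (1:4810) / fs
  s <- sin(2 * pi * 10 * tt)
  expect_gt(band_power(s, fs, c(8, 12)),
            50 * band_power(s, fs, c(12, 30)))
  expect_equal(band_power(rep(0, 4810), fs, c(8, 12)), 0)
  # white noise: power approximately proportional to bandwidth
  set.seed(3)
  r <- mean(replicate(6, {
    wn <- rnorm(4810)
    band_power(wn, fs, c(100, 200)) / band_power(wn, fs, c(10, 20))
  }))
  expect_gt(r, 7); expect_lt(r, 13)
})

test_that("act matches the AR(1) closed form within one sample", {
  set.seed(4)
  expect_equal(act(rnorm(4810)), 1)
  for (phi in c(0.5, 0.7, 0.9)) {
    lag <- act(ar1(4810, phi))
    expect_lte(abs(lag - ceiling(-1 / log(phi))), 1)
  }
  expect_error(act(rep(1, 100)), "constant")
  expect_error(act(sin(2 * pi * (1:50) / 1e6), max_lag = 10), "decays")
  expect_true(is.na(act(sin(2 * pi * (1:50) / 1e6), max_lag = 10,
                        on_no_decay = "na")))
})

test_that("butterworth band-pass behaves as designed", {
  fs <- 1000; tt <- (1:4000) / fs
  # DC removal: the 0.1 Hz high-pass edge decays over tens of seconds,
  # so judge the offset on the tail of a 40-s signal
  tl <- (1:40000) / fs
  y <- butter_bandpass(5 + sin(2 * pi * 50 * tl), fs, 0.1, 300)
  expect_lt(abs(mean(y[30001:40000])), 0.05)
  # stop-band attenuation and pass-band preservation (steady state)
  amp <- function(f, lo, hi) {
    y <- butter_bandpass(sin(2 * pi * f * tt), fs, lo, hi)
    max(abs(y[2001:4000]))
  }
  expect_lt(amp(50, 12, 30), 0.1)
  expect_gt(amp(20, 12, 30), 0.9)
  expect_lt(abs(amp(19, 12, 30) - 1), 0.05)  # near geometric centre
  expect_error(butter_bandpass(rnorm(100), fs, 30, 12), "band edges")
  # epoch matrices filter row-wise
  m <- matrix(sin(2 * pi * 20 * tt), 2, 2000, byrow = TRUE)
  fm <- butter_bandpass(m, fs, 12, 30)
  expect_equal(dim(fm), dim(m))
  expect_equal(fm[1, ], fm[2, ])
})

test_that("amplitude QC flags only extreme epochs and alters nothing", {
  set.seed(6)
  ep <- matrix(rnorm(3 * 500), 3)
  ep[2, 100] <- 40
  qc <- reject_by_amplitude(ep, z_max = 8)
  expect_equal(qc$rejected, c(FALSE, TRUE, FALSE))
})

test_that("resample_signal decimates with anti-aliasing", {
  fs <- 1000; tt <- (1:4000) / fs
  x <- sin(2 * pi * 10 * tt)
  y <- resample_signal(x, fs, 500)
  expect_length(y, 2000)
  expect_gt(max(abs(y[1001:2000])), 0.9)
  expect_error(resample_signal(x, 1000, 300), "integer")
})
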