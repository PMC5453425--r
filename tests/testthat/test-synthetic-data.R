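test_that("synth_params validates its invariants", {
  expect_s3_class(synth_params(), "synth_params")
  expect_error(synth_params(coupling_delay = 0), "coupling_delay")
  expect_error(synth_params(epoch_len_s = 0.05, coupling_delay = 60),
               "coupling_delay")
  expect_error(synth_params(source_entropy_scale = 0), "source_entropy")
  expect_error(synth_params(source_entropy_scale = 1.2), "source_entropy")
  expect_error(synth_params(storage_gain = 1), "storage_gain")
})

test_that("generation is bit-identical under a fixed seed", {
  p <- synth_params(n_epochs = 3, epoch_len_s = 0.3, seed = 42)
  r1 <- generate_recording(p, "c1")
  r2 <- generate_recording(p, "c1")
  expect_identical(r1, r2)
  # different recording index -> different substream
  r3 <- generate_recording(p, "c1", rec_index = 2L)
  expect_false(identical(r1$channels$source, r3$channels$source))
})

test_that("recording structure matches the declared geometry", {
  p <- synth_params(n_epochs = 4, epoch_len_s = 0.25, fs = 800, seed = 1)
  r <- generate_recording(p, "cond")
  expect_equal(dim(r$channels$source), c(4, 200))
  expect_equal(dim(r$channels$target), c(4, 200))
  expect_equal(r$fs, 800)
})

test_that("uncoupled channels show no transfer beyond the surrogate null", {
  p <- synth_params(n_epochs = 12, epoch_len_s = 0.8, coupling_gain = 0,
                    seed = 7)
  r <- generate_recording(p, "c")
  est <- function(s, t) te_spo(s, t, u = 5, record = FALSE)
  te <- est(r$channels$source, r$channels$target)
  ns <- null_sd(r$channels$source, r$channels$target, est)
  expect_lt(abs(te), 3 * ns)
})

test_that("mean TE is non-decreasing in coupling gain", {
  # unsmoothed injection so the transfer is concentrated at one lag
  te <- vapply(c(0, 0.2, 0.5), function(g) {
    p <- synth_params(n_epochs = 12, epoch_len_s = 1, coupling_gain = g,
                      coupling_delay = 5, smooth_samples = 0, seed = 9)
    r <- generate_recording(p, "g")
    te_spo(r$channels$source, r$channels$target, u = 5, record = FALSE)
  }, numeric(1))
  p0 <- synth_params(n_epochs = 12, epoch_len_s = 1, coupling_gain = 0,
                     smooth_samples = 0, seed = 9)
  r0 <- generate_recording(p0, "g")
  tol <- null_sd(r0$channels$source, r0$channels$target,
                 function(s, t) te_spo(s, t, u = 5, record = FALSE))
  expect_true(all(diff(te) > -tol))
})

test_that("lower source_entropy_scale lowers estimated source entropy", {
  h <- vapply(c(1, 0.5), function(s) {
    p <- synth_params(n_epochs = 6, epoch_len_s = 1,
                      source_entropy_scale = s, seed = 11)
    r <- generate_recording(p, "c")
    kl_entropy(matrix(as.vector(r$channels$source), ncol = 1), k = 4)
  }, numeric(1))
  expect_gt(h[1], h[2])
})

test_that("condition sets are nested and validated", {
  base <- synth_params(n_recordings_per_condition = 2, n_epochs = 3,
                       epoch_len_s = 0.3, seed = 2)
  recs <- generate_condition_set(base, list(a = list(), b = list(
    source_entropy_scale = 0.5)))
  expect_length(recs, 4)
  expect_setequal(unique(vapply(recs, function(r) r$condition, "")),
                  c("a", "b"))
  expect_length(unique(vapply(recs, function(r) r$session_id, "")), 4)
  expect_error(generate_condition_set(base, list(a = list())), "2 conditions")
  expect_error(generate_condition_set(
    base, list(a = list(), b = list(n_recordings_per_condition = 1))),
    "2 recordings")
})

test_that("per-recording intercept jitter yields positive ICC", {
  base <- synth_params(n_recordings_per_condition = 4, n_epochs = 8,
                       epoch_len_s = 0.5, intercept_sd = 0.15, seed = 5)
  recs <- generate_condition_set(base, list(a = list(), b = list()))
  tab <- do.call(rbind, lapply(recs, function(r) {
    data.frame(value = apply(r$channels$source, 1, function(e)
      kl_entropy(matrix(e, ncol = 1))), session_id = r$session_id)
  }))
  expect_gt(icc(tab), 0)
})
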