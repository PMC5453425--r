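# shared fixture builders; everything generated in code, fixed seeds

ar1 <- function(n, phi, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  as.numeric(stats::filter(rnorm(n, 0, sd), phi, method = "recursive"))
}

# epoch matrices with a unidirectional delayed coupling (uniform noise,
# the design of the filtering study)
coupled_pair <- function(ne, n, gain, delay, seed = 1) {
  set.seed(seed)
  src <- matrix(runif(ne * n), ne)
  tgt <- matrix(runif(ne * n), ne)
  tgt[, (delay + 1):n] <- tgt[, (delay + 1):n] +
    gain * src[, 1:(n - delay), drop = FALSE]
  list(src = src, tgt = tgt)
}

tiny_recording <- function(ne = 3, n = 50, seed = 1) {
  set.seed(seed)
  recording(list(V1 = matrix(rnorm(ne * n), ne),
                 PFC = matrix(rnorm(ne * n), ne)),
            fs = 1000, condition = "iso_0.0", session_id = "s1")
}

# empirical SD of an estimator under epoch shuffling (surrogate null)
null_sd <- function(src, tgt, est, n = 8, seed = 99) {
  set.seed(seed)
  sd(replicate(n, est(src, tgt[sample.int(nrow(tgt)), , drop = FALSE])))
}
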