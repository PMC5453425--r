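test_that("discretize maps into n+2 ordered bins with overflow", {
  set.seed(1)
  x <- rnorm(5000)
  s <- discretize(x, n_inner_bins = 10)
  expect_true(all(s >= 1 & s <= 12))
  # monotone: value order preserved as bin order
  o <- order(x)
  expect_true(all(diff(s[o]) >= 0))
  # overflow bins
  m <- mean(x); sdv <- sd(x)
  expect_equal(unique(s[x > m + 3.5 * sdv]), 12L)
  expect_equal(unique(s[x < m - 3.5 * sdv]), 1L)
  # a value at the mean lands in one of the two central bins
  i <- which.min(abs(x - m))
  expect_true(s[i] %in% c(6L, 7L))
  expect_error(discretize(rep(1, 50)), "constant")
  expect_error(discretize(x, n_inner_bins = 1), "2 inner")
})

test_that("state words enumerate the embedded alphabet", {
  wc <- state_words(rep(1L, 50), d = 3, role = "target_state", n_bins = 12)
  expect_length(wc$counts, 1)
  # valid states per epoch: n - (lag + (d-1) tau) = 50 - 3
  expect_equal(wc$N, 47)
  # alternating 2-symbol stream, d=2: exactly 2 distinct words
  wc2 <- state_words(rep(c(1L, 2L), 30), d = 2, tau = 1,
                     role = "target_state", n_bins = 2)
  expect_length(wc2$counts, 2)
  # declared support is the word-space size
  expect_equal(state_words(rep(c(1L, 2L), 30), d = 14, role = "target_state",
                           n_bins = 12)$K, 12^14)
  expect_error(word_counts(c(5, 5), K = 1), "K must be")
})

test_that("NSB agrees with plug-in on well-sampled alphabets", {
  set.seed(3)
  sym <- sample(1:8, 10000, replace = TRUE)
  wc <- word_counts(as.integer(table(sym)), K = 1e12)
  expect_lt(abs(nsb_entropy(wc) - 3), 0.05)
  expect_lt(abs(nsb_entropy(wc) - plugin_entropy(wc)), 0.05)
  # near-deterministic distribution
  wc1 <- word_counts(c(500, 2), K = 1e6)
  expect_lt(nsb_entropy(wc1), 0.1)
  # no coincidences: estimator undefined
  expect_error(nsb_entropy(word_counts(rep(1L, 50), K = 1e12)),
               "coincidences")
})

test_that("NSB estimates are independent of the declared support", {
  set.seed(4)
  p <- (1:1000)^-1.5; p <- p / sum(p)
  sm <- sample(1:1000, 2000, replace = TRUE, prob = p)
  nn <- as.integer(table(sm))
  h6 <- nsb_entropy(word_counts(nn, K = 1e6))
  h12 <- nsb_entropy(word_counts(nn, K = 1e12))
  expect_lt(abs(h6 - h12), 0.02)
})

test_that("NSB entropy respects its bounds on random count vectors", {
  set.seed(5)
  for (i in 1:6) {
    nn <- as.integer(table(sample(1:20, 400, replace = TRUE,
                                  prob = runif(20)^2)))
    K <- 10^sample(3:12, 1)
    h <- nsb_entropy(word_counts(nn, K = K))
    expect_gte(h, 0)
    expect_lte(h, log2(K))
  }
})

test_that("decomposed TE matches an independent plug-in oracle", {
  # deterministic copy y_t = x_{t-2} on a small alphabet
  set.seed(6)
  x <- runif(3000)
  y <- c(runif(2), x[1:2998])
  d <- te_decomposed(x, y, dX = 1, dY = 1, u = 2, n_inner_bins = 4,
                     estimator = "plugin")
  # oracle: direct empirical conditional mutual information computed from
  # the joint contingency table, independent index arithmetic
  sx <- discretize(x, 4); sy <- discretize(y, 4)
  tt <- 3:3000
  tab <- table(pres = sy[tt], xs = sx[tt - 2], yp = sy[tt - 1])
  p <- tab / sum(tab)
  cmi <- 0
  for (yp in dimnames(tab)$yp) {
    pyp <- sum(p[, , yp])
    if (pyp == 0) next
    sub <- p[, , yp] / pyp
    px <- colSums(sub); pt <- rowSums(sub)
    nz <- sub > 0
    cmi <- cmi + pyp * sum(sub[nz] * log2(sub[nz] /
                                            outer(pt, px)[nz]))
  }
  expect_equal(d$value, cmi, tolerance = 1e-10)
  # a deterministic copy transfers (almost) the full present entropy
  h_pres <- plugin_entropy(state_words(sy[tt], d = 1, role = "present",
                                       n_bins = 6))
  expect_gt(d$value, 0.9 * h_pres)
  # NSB route agrees on this well-sampled case
  dn <- te_decomposed(x, y, dX = 1, dY = 1, u = 2, n_inner_bins = 4)
  expect_lt(abs(dn$value - d$value), 0.05)
})

test_that("decomposed TE of independent channels is near zero", {
  set.seed(7)
  d <- te_decomposed(runif(4000), runif(4000), dX = 1, dY = 1, u = 3,
                     n_inner_bins = 6)
  expect_lt(abs(d$value), 0.05)
})

test_that("decomposed AIS recovers storage of a period-2 signal", {
  set.seed(8)
  x <- rep(c(-1, 1), 300) + rnorm(600, 0, 1e-3)
  a <- ais_decomposed(x, d = 1, n_inner_bins = 4, estimator = "plugin")
  expect_equal(a$value, 1, tolerance = 1e-3)
  # i.i.d. noise stores nothing
  a0 <- ais_decomposed(rnorm(4000), d = 1, n_inner_bins = 6)
  expect_lt(abs(a0$value), 0.05)
})

test_that("subsample robustness flags stable and unstable estimates", {
  set.seed(4)
  big <- sample(1:8, 50000, replace = TRUE)
  stable <- subsample_robustness(function(f)
    word_counts(as.integer(table(big[1:round(f * 50000)])), K = 1e6))
  expect_true(stable$stable)
  expect_equal(nrow(stable$curve), 5)
  set.seed(6)
  p <- (1:2000)^-1.2; p <- p / sum(p)
  sm <- sample(1:2000, 250, replace = TRUE, prob = p)
  unstable <- subsample_robustness(function(f)
    word_counts(as.integer(table(sm[1:round(f * 250)])), K = 1e12))
  expect_false(unstable$stable)
  expect_error(subsample_robustness(function(f) NULL, fractions = c(1)),
               "3 fractions")
})
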