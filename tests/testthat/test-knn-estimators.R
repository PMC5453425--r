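# Closed-form oracles: H of N(0,1) = 0.5*ln(2*pi*e); MI of a bivariate
# Gaussian = -0.5*ln(1 - rho^2); AIS of a Gaussian AR(1) at d = 1
# = -0.5*ln(1 - phi^2).

test_that("KL entropy matches the Gaussian closed form and its identities", {
  set.seed(42)
  x <- matrix(rnorm(10000), ncol = 1)
  expect_lt(abs(kl_entropy(x, k = 4) - 0.5 * log(2 * pi * exp(1))), 0.02)
  # translation invariance (distances unchanged)
  expect_equal(kl_entropy(x + 100), kl_entropy(x), tolerance = 1e-10)
  # scaling identity H(a x) = H(x) + ln a
  expect_lt(abs(kl_entropy(3 * x) - kl_entropy(x) - log(3)), 0.01)
  # unit conversion
  expect_equal(kl_entropy(x, units = "bits"), kl_entropy(x) / log(2))
  expect_error(kl_entropy(matrix(rnorm(4), 4), k = 4), "N > k")
})

test_that("duplicate points are jittered deterministically or rejected", {
  x <- matrix(rep(c(1, 2, 3), each = 10) + 0.001 * (1:30), ncol = 1)
  x[5] <- x[4]  # exact duplicate
  expect_error(kl_entropy(x, jitter = 0), "duplicate")
  h1 <- kl_entropy(x)
  h2 <- kl_entropy(x)
  expect_identical(h1, h2)
})

test_that("KSG MI matches the Gaussian closed form", {
  set.seed(7)
  n <- 10000; rho <- 0.9
  a <- rnorm(n); b <- rho * a + sqrt(1 - rho^2) * rnorm(n)
  expect_lt(abs(ksg_mi(a, b, k = 4) + 0.5 * log(1 - rho^2)), 0.03)
  # independent pairs: MI within 3 surrogate SDs of zero
  set.seed(8)
  u <- runif(5000); v <- runif(5000)
  ns <- sd(replicate(8, ksg_mi(u, sample(v))))
  expect_lt(abs(ksg_mi(u, v)), 3 * ns)
  expect_error(ksg_mi(u, v[1:10]), "misaligned")
})

test_that("conditioning on an irrelevant variable leaves MI unchanged", {
  set.seed(9)
  n <- 8000; rho <- 0.8
  a <- rnorm(n); b <- rho * a + sqrt(1 - rho^2) * rnorm(n)
  cc <- rnorm(n)
  expect_lt(abs(ksg_cmi(a, b, cc) - ksg_mi(a, b)), 0.03)
})

test_that("estimators are invariant under additive channel shifts", {
  set.seed(10)
  pair <- coupled_pair(5, 200, gain = 0.4, delay = 3)
  t1 <- te_spo(pair$src, pair$tgt, u = 3, record = FALSE)
  t2 <- te_spo(pair$src + 50, pair$tgt - 20, u = 3, record = FALSE)
  # exact only up to float rounding of shifted coordinates, which can flip
  # boundary neighbours; absolute differences stay at noise level
  expect_lt(abs(t1 - t2), 1e-4)
  a1 <- ais(pair$tgt, d = 2, record = FALSE)
  a2 <- ais(pair$tgt + 7, d = 2, record = FALSE)
  expect_lt(abs(a1 - a2), 1e-4)
})

test_that("AIS reflects autoregressive predictability", {
  set.seed(11)
  expect_lt(abs(ais(rnorm(6000), d = 1, record = FALSE)), 0.01)
  strong <- ais(ar1(15000, 0.95), d = 1, record = FALSE)
  weak <- ais(ar1(15000, 0.2), d = 1, record = FALSE)
  expect_gt(strong, weak)
  # closed form at d = 1
  expect_lt(abs(strong + 0.5 * log(1 - 0.95^2)), 0.06)
  rec <- ais(ar1(2000, 0.5), d = 2, site = "V1")
  expect_s3_class(rec, "estimate_record")
  expect_equal(rec$measure, "AIS")
  expect_equal(rec$params$d, 2)
})

test_that("TE_SPO detects coupling only near the true delay", {
  set.seed(12)
  pair <- coupled_pair(10, 2000, gain = 0.2, delay = 10)
  est <- function(u) te_spo(pair$src, pair$tgt, u = u, record = FALSE)
  te10 <- est(10)
  ns <- null_sd(pair$src, pair$tgt,
                function(s, t) te_spo(s, t, u = 10, record = FALSE))
  expect_gt(te10, 3 * ns)
  # u far below the physical delay: information not yet arrived
  expect_lt(est(1), 0.5 * te10)
  # uncoupled channels: within the null
  set.seed(13)
  un <- list(src = matrix(runif(10 * 2000), 10),
             tgt = matrix(runif(10 * 2000), 10))
  expect_lt(abs(te_spo(un$src, un$tgt, u = 10, record = FALSE)), 3 * ns)
  expect_error(te_spo(pair$src, pair$tgt[1:5, ], u = 1), "mismatch")
  expect_error(te_spo(pair$src, pair$tgt, u = 0), "u must be")
})

test_that("delay scan reconstructs single and multiple couplings", {
  set.seed(14)
  n <- 20000
  x <- runif(n); y <- runif(n)
  y[11:n] <- y[11:n] + 0.2 * x[1:(n - 10)]
  sc <- scan_delay(x, y, u_grid = 1:20)
  expect_equal(sc$u_opt, 10)
  expect_true(10 %in% sc$peaks)
  # argmax invariant to grid order
  sc2 <- scan_delay(x, y, u_grid = c(15, 3, 10, 1, 20, 7))
  expect_equal(sc2$u_opt, 10)
  # two superposed couplings: both delays appear among the peaks
  set.seed(15)
  x2 <- runif(n); y2 <- runif(n)
  y2[6:n] <- y2[6:n] + 0.25 * x2[1:(n - 5)]
  y2[13:n] <- y2[13:n] + 0.25 * x2[1:(n - 12)]
  sc3 <- scan_delay(x2, y2, u_grid = 1:20)
  expect_true(all(c(5, 12) %in% sc3$peaks))
  expect_error(scan_delay(x, y, u_grid = integer(0)), "non-empty")
})

test_that("te_net is the normalized directed difference", {
  expect_equal(te_net(0.3, 0.1), 0.5)
  expect_equal(te_net(0.2, 0.2), 0)
  expect_error(te_net(0, 0), "undefined")
  # unidirectional coupling: positive toward the coupled direction with
  # per-direction optimized delays
  set.seed(16)
  pair <- coupled_pair(8, 2000, gain = 0.3, delay = 6)
  fwd <- scan_delay(pair$src, pair$tgt, u_grid = 1:10)
  rev <- scan_delay(pair$tgt, pair$src, u_grid = 1:10)
  expect_gt(te_net(max(fwd$te_values), max(rev$te_values)), 0)
})
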