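test_that("surrogate test detects coupling and is reproducible", {
  pair <- coupled_pair(50, 100, gain = 0.4, delay = 5, seed = 8)
  est <- function(s, t) te_spo(s, t, u = 5, record = FALSE)
  r <- surrogate_test(pair$src, pair$tgt, est, n_surrogates = 100, seed = 1)
  expect_lt(r$p, 0.05)
  expect_gt(r$observed, max(r$null_values))
  expect_identical(
    r$p, surrogate_test(pair$src, pair$tgt, est, 100, seed = 1)$p)
  # p-values carry the +1 correction: never zero, floor 1/(n+1)
  expect_gte(r$p, 1 / 101)
  expect_error(surrogate_test(pair$src[1, , drop = FALSE],
                              pair$tgt[1, , drop = FALSE], est), "2 epochs")
})

test_that("binomial aggregation follows the closed form", {
  expect_equal(binomial_aggregate(0, 5), 1)
  expect_equal(binomial_aggregate(5, 5, 0.05), 0.05^5)
  # 1 - P(0) - P(1) for n = 8, p0 = 0.05, frozen from the closed form
  expect_equal(binomial_aggregate(2, 8, 0.05), 0.05724465, tolerance = 1e-7)
  # monotone decreasing in the count
  ps <- vapply(0:8, binomial_aggregate, numeric(1), n_recordings = 8)
  expect_true(all(diff(ps) < 0))
  expect_error(binomial_aggregate(9, 8), "n_significant")
})

test_that("permutation ANOVA separates injected effects", {
  set.seed(21)
  A <- rep(c("a1", "a2", "a3"), each = 8)
  B <- rep(rep(c("b1", "b2"), each = 4), 3)
  # main effect of A only
  y <- rnorm(24) + 2 * (A == "a3") - 2 * (A == "a1")
  r <- perm_anova_2way(y, A, B, n_perm = 499, seed = 1)
  expect_lt(r$p_main_A, 0.01)
  expect_gt(r$p_main_B, 0.1)
  # crossed interaction: effect of A reverses across B
  y2 <- rnorm(24) + 3 * ifelse(B == "b1", A == "a1", A == "a3")
  r2 <- perm_anova_2way(y2, A, B, n_perm = 499, seed = 1)
  expect_lt(r2$p_interaction, 0.05)
  # empty / thin cells rejected
  expect_error(perm_anova_2way(rnorm(6), c("a", "a", "a", "b", "b", "b"),
                               c("x", "x", "y", "y", "x", "x")),
               "every cell")
  expect_gte(min(r$p_main_A, r$p_main_B, r$p_interaction), 1 / 500)
})

test_that("per-recording aggregation uses the median", {
  tab <- data.frame(value = c(1, 2, 100, 7),
                    session_id = c("r1", "r1", "r1", "r2"),
                    condition = "c1", measure = "TE_SPO",
                    direction_or_site = "V1->PFC")
  agg <- aggregate_by_recording(tab)
  expect_equal(nrow(agg), 2)
  expect_equal(agg$value[agg$session_id == "r1"], 2)
  expect_equal(agg$value[agg$session_id == "r2"], 7)
})

test_that("LMM comparison detects an injected direction effect", {
  set.seed(22)
  tab <- expand.grid(epoch = 1:15, session_id = paste0("r", 1:8),
                     direction = c("PFC->V1", "V1->PFC"),
                     condition = c("iso_0.0", "iso_0.5", "iso_1.0"))
  gam <- rnorm(8, 0, 0.5)[as.integer(factor(tab$session_id))]
  tab$value <- gam + 0.4 * (tab$direction == "PFC->V1") + rnorm(nrow(tab))
  cmp <- lmm_compare(tab)
  tt <- cmp$table
  dir_row <- tt[tt$effect == "direction", ]
  expect_lt(dir_row$p, 0.001)
  expect_lt(dir_row$BIC_big, dir_row$BIC_small)
  # no condition effect injected
  expect_gt(tt$p[tt$effect == "condition"], 0.05)
  expect_equal(tt$df[tt$effect == "condition"], 2)
  expect_named(cmp$models, c("fm_0", "fm_a", "fm_d", "fm_ab", "fm_axb"))
})

test_that("ICC matches the variance-ratio oracle", {
  set.seed(23)
  flat <- data.frame(value = rnorm(200),
                     session_id = rep(paste0("r", 1:10), each = 20))
  expect_lt(icc(flat), 0.05)
  disjoint <- data.frame(value = rep(1:10, each = 20) +
                           rnorm(200, 0, 1e-3),
                         session_id = rep(paste0("r", 1:10), each = 20))
  expect_gt(icc(disjoint), 0.99)
  # intercept SD equal to noise SD -> ICC about 0.5
  half <- data.frame(value = rep(rnorm(40), each = 25) + rnorm(1000),
                     session_id = rep(paste0("r", 1:40), each = 25))
  expect_lt(abs(icc(half) - 0.5), 0.15)
  expect_error(icc(data.frame(value = 1:3, session_id = c("a", "a", "b"))),
               "2 recordings")
})

test_that("restricted Spearman ignores between-recording confounds", {
  set.seed(24)
  ids <- rep(paste0("r", 1:5), each = 20)
  x <- rnorm(100)
  r1 <- spearman_restricted_perm(x, x, ids, n_perm = 199, seed = 1)
  expect_equal(r1$rho, 1)
  expect_equal(r1$p, 1 / 200)
  # correlation existing only between recordings: y constant within
  # recording, recording means tracking x's recording means
  xm <- rep(1:5, each = 20) + rnorm(100, 0, 0.2)
  yc <- rep(1:5, each = 20)
  r2 <- spearman_restricted_perm(xm, yc, ids, n_perm = 199, seed = 2)
  expect_gt(r2$rho, 0.9)     # pooled correlation looks strong
  expect_equal(r2$p, 1)      # but the restricted null reproduces it always
})

test_that("permutation t-test separates shifted samples", {
  set.seed(25)
  r <- perm_ttest(rnorm(40, 1), rnorm(40, 0), n_perm = 999, seed = 1)
  expect_lt(r$p, 0.01)
  r0 <- perm_ttest(rnorm(40), rnorm(40), n_perm = 999, seed = 1)
  expect_gt(r0$p, 0.05)
})
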