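#' @name inference_stats
#' @title Surrogate, permutation and mixed-model inference
#'
#' @description
#' Significance machinery for information-theoretic estimates: epoch-shuffle
#' surrogate tests with binomial aggregation over recordings, two-factor
#' permutation ANOVA with restricted permutation schemes, linear
#' mixed-model comparison for the nested epochs-within-recordings design,
#' and restricted-permutation Spearman correlations. All permutation
#' p-values use the `+1` correction `(1 + #exceedances) / (1 + n_perm)`,
#' so they are never exactly zero.
NULL

#' Epoch-shuffle surrogate test
#'
#' Builds the null distribution of an estimator by permuting whole epochs
#' of the target time series while leaving the source epoch order
#' untouched: within-epoch structure (and hence estimator bias) is
#' preserved, source-target coupling is destroyed.
#'
#' @param source_epochs,target_epochs epoch x sample matrices.
#' @param estimator `function(source, target) -> numeric`, deterministic
#'   given the data (e.g. a pooled [te_spo()] with fixed parameters).
#' @param n_surrogates number of surrogate data sets.
#' @param seed RNG seed for the permutations.
#' @return List of class `surrogate_result`: `observed`, `null_values`,
#'   `p`, `n_surrogates`.
#' @export
surrogate_test <- function(source_epochs, target_epochs, estimator,
                           n_surrogates = 500, seed = 1L) {
  .assert(is.matrix(source_epochs) && is.matrix(target_epochs) &&
            all(dim(source_epochs) == dim(target_epochs)),
          "source and target must be matching epoch matrices")
  ne <- nrow(target_epochs)
  .assert(ne >= 2, "need at least 2 epochs to permute")
  observed <- estimator(source_epochs, target_epochs)
  null_values <- .with_seed(seed, {
    vapply(seq_len(n_surrogates), function(s) {
      estimator(source_epochs, target_epochs[sample.int(ne), , drop = FALSE])
    }, numeric(1))
  })
  p <- (1 + sum(null_values >= observed)) / (1 + n_surrogates)
  structure(list(observed = observed, null_values = null_values, p = p,
                 n_surrogates = n_surrogates),
            class = "surrogate_result")
}

#' Binomial aggregation of per-recording significances
#'
#' One-sided binomial test of the number of significant recordings under
#' the null that each recording is significant with probability `p0`.
#'
#' @param n_significant significant recordings.
#' @param n_recordings recordings tested.
#' @param p0 per-recording false-positive rate under the null.
#' @return Upper-tail probability `P(L >= n_significant)`.
#' @export
binomial_aggregate <- function(n_significant, n_recordings, p0 = 0.05) {
  .assert(n_significant >= 0 && n_significant <= n_recordings,
          "n_significant must lie in [0, n_recordings]")
  if (n_significant == 0) return(1)
  pbinom(n_significant - 1, n_recordings, p0, lower.tail = FALSE)
}

#' Two-factor permutation ANOVA
#'
#' F-ratios from classical (Type II) sums of squares on possibly
#' unbalanced cells, with the residual mean square taken from the full
#' interaction model. Main effects are tested by permuting observations
#' only *within* the levels of the other factor (preserving that factor's
#' effect exactly); the interaction is tested by unrestricted permutation,
#' which destroys the mains as well and therefore yields an approximative
#' test.
#'
#' @param values numeric response vector.
#' @param factor_A_levels,factor_B_levels factor level per observation.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return List of class `anova_result` with F-ratios, permutation
#'   p-values and the scheme used per effect.
#' @export
perm_anova_2way <- function(values, factor_A_levels, factor_B_levels,
                            n_perm = 10000, seed = 1L) {
  A <- factor(factor_A_levels); B <- factor(factor_B_levels)
  y <- as.numeric(values)
  n <- length(y)
  .assert(length(A) == n && length(B) == n, "factor length mismatch")
  .assert(nlevels(A) >= 2 && nlevels(B) >= 2, "need >= 2 levels per factor")
  cells <- table(A, B)
  .assert(all(cells >= 2), "need >= 2 observations in every cell")
  dfA <- nlevels(A) - 1; dfB <- nlevels(B) - 1
  dfI <- dfA * dfB; dfe <- n - nlevels(A) * nlevels(B)
  .assert(dfe > 0, "no residual degrees of freedom")
  rss_of <- function(form) {
    X <- model.matrix(form)
    q <- qr.Q(qr(X))
    function(yy) sum(yy^2) - sum(crossprod(q, yy)^2)
  }
  rss_a <- rss_of(~A); rss_b <- rss_of(~B)
  rss_ab <- rss_of(~A + B); rss_axb <- rss_of(~A * B)
  fstats <- function(yy) {
    r_ab <- rss_ab(yy); r_axb <- rss_axb(yy)
    mse <- r_axb / dfe
    c(FA = ((rss_b(yy) - r_ab) / dfA) / mse,
      FB = ((rss_a(yy) - r_ab) / dfB) / mse,
      FI = ((r_ab - r_axb) / dfI) / mse)
  }
  f_obs <- fstats(y)
  perm_within <- function(strata) {
    idx <- seq_len(n)
    for (lv in unique(strata)) {
      sel <- which(strata == lv)
      idx[sel] <- sel[sample.int(length(sel))]
    }
    # restricted scheme must leave the stratifying factor untouched
    stopifnot(identical(strata[idx], strata))
    idx
  }
  exc <- c(FA = 0, FB = 0, FI = 0)
  .with_seed(seed, {
    for (i in seq_len(n_perm)) {
      fa <- fstats(y[perm_within(B)])["FA"]
      fb <- fstats(y[perm_within(A)])["FB"]
      fi <- fstats(y[sample.int(n)])["FI"]
      exc <- exc + (c(fa, fb, fi) >= f_obs)
    }
  })
  p <- (1 + exc) / (1 + n_perm)
  structure(list(F_main_A = unname(f_obs["FA"]),
                 F_main_B = unname(f_obs["FB"]),
                 F_interaction = unname(f_obs["FI"]),
                 p_main_A = unname(p["FA"]), p_main_B = unname(p["FB"]),
                 p_interaction = unname(p["FI"]), n_perm = n_perm,
                 df = c(A = dfA, B = dfB, interaction = dfI, error = dfe),
                 scheme = c(A = "within-B", B = "within-A",
                            interaction = "unrestricted")),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<pANOVA (%d perms): F_A=%.3f p=%.4f | F_B=%.3f p=%.4f | F_AxB=%.3f p=%.4f>\n",
              x$n_perm, x$F_main_A, x$p_main_A, x$F_main_B, x$p_main_B,
              x$F_interaction, x$p_interaction))
  invisible(x)
}

#' Aggregate per-epoch estimates to per-recording medians
#'
#' Epoch-level estimates within one recording are dependent, so group
#' statistics use one number per recording: the median over epochs (the
#' distributions over epochs are skewed).
#'
#' @param tab data frame with a `value` column and grouping columns
#'   (subset of `measure`, `session_id`, `condition`, `direction_or_site`).
#' @return Data frame with one median `value` per group.
#' @export
aggregate_by_recording <- function(tab) {
  .assert(is.data.frame(tab) && "value" %in% names(tab),
          "tab must be a data frame with a 'value' column")
  keys <- intersect(c("measure", "condition", "direction_or_site",
                      "session_id"), names(tab))
  .assert("session_id" %in% keys, "tab must have a 'session_id' column")
  aggregate(tab["value"], by = tab[keys], FUN = median)
}

#' Linear mixed-model comparison for nested per-epoch estimates
#'
#' Fits, by maximum likelihood, the model
#' `y_ij = b0 + g_j + b1 D_i + b2 A_i(lvl2) + b3 A_i(lvl3) + e_ij`
#' with a per-recording random intercept `g_j`, direction coded +1/-1 and
#' condition coded as treatment contrasts against the first (reference)
#' level, together with its nested submodels: null (random intercept
#' only), condition only, direction only, additive, and interaction.
#' Effects are assessed by likelihood-ratio tests (mains against the null
#' model, interaction against the additive model) and BIC.
#'
#' @param tab data frame with columns `value`, `direction` (2 levels; the
#'   first level is coded +1), `condition` (first level = reference), and
#'   `session_id`.
#' @return List with the fitted models (`fm_0`, `fm_a`, `fm_d`, `fm_ab`,
#'   `fm_axb`) and a comparison `table` (BIC, deviance, chisq, df, p).
#' @export
lmm_compare <- function(tab) {
  .assert(all(c("value", "direction", "condition", "session_id") %in%
                names(tab)), "tab needs value/direction/condition/session_id")
  dat <- data.frame(value = tab$value,
                    direction = factor(tab$direction),
                    condition = factor(tab$condition),
                    session_id = factor(tab$session_id))
  .assert(nlevels(dat$direction) == 2, "direction must have 2 levels")
  dat$D <- ifelse(dat$direction == levels(dat$direction)[1], 1, -1)
  fits <- list(
    fm_0   = lme4::lmer(value ~ 1 + (1 | session_id), dat, REML = FALSE),
    fm_a   = lme4::lmer(value ~ condition + (1 | session_id), dat, REML = FALSE),
    fm_d   = lme4::lmer(value ~ D + (1 | session_id), dat, REML = FALSE),
    fm_ab  = lme4::lmer(value ~ condition + D + (1 | session_id), dat,
                        REML = FALSE),
    fm_axb = lme4::lmer(value ~ condition * D + (1 | session_id), dat,
                        REML = FALSE))
  cmp <- function(effect, small, big) {
    d0 <- -2 * as.numeric(logLik(fits[[small]]))
    d1 <- -2 * as.numeric(logLik(fits[[big]]))
    df <- attr(logLik(fits[[big]]), "df") - attr(logLik(fits[[small]]), "df")
    chisq <- d0 - d1
    data.frame(effect = effect, model = big, against = small,
               BIC_small = stats::BIC(fits[[small]]),
               BIC_big = stats::BIC(fits[[big]]),
               deviance = d1, chisq = chisq, df = df,
               p = pchisq(chisq, df, lower.tail = FALSE))
  }
  table <- rbind(cmp("condition", "fm_0", "fm_a"),
                 cmp("direction", "fm_0", "fm_d"),
                 cmp("interaction", "fm_ab", "fm_axb"))
  list(models = fits, table = table)
}

#' Intraclass correlation coefficient of per-epoch estimates
#'
#' One-way random-effects ICC: the share of total variance attributable to
#' the per-recording random intercept, from the ML fit of the
#' intercept-only mixed model.
#'
#' @param tab data frame with `value` and `session_id` columns; needs >= 2
#'   recordings with >= 2 epochs each.
#' @export
icc <- function(tab) {
  .assert(all(c("value", "session_id") %in% names(tab)),
          "tab needs value and session_id columns")
  cnt <- table(tab$session_id)
  .assert(sum(cnt >= 2) >= 2, "need >= 2 recordings with >= 2 epochs")
  fm <- lme4::lmer(value ~ 1 + (1 | session_id), tab, REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fm))
  v_rec <- vc$vcov[vc$grp == "session_id"]
  v_res <- vc$vcov[vc$grp == "Residual"]
  v_rec / (v_rec + v_res)
}

#' Spearman correlation with a within-recording permutation test
#'
#' Rank correlation on the pooled data; the null distribution permutes `y`
#' only within recordings, so between-recording (confounded) structure is
#' kept under the null and cannot drive significance.
#'
#' @param x,y aligned numeric vectors.
#' @param recording_ids recording label per observation (>= 2 distinct).
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return List with `rho` and two-sided permutation `p`.
#' @export
spearman_restricted_perm <- function(x, y, recording_ids, n_perm = 1000,
                                     seed = 1L) {
  .assert(length(x) == length(y) && length(x) == length(recording_ids),
          "x, y and recording_ids must be aligned")
  .assert(length(unique(recording_ids)) >= 2, "need >= 2 recordings")
  rho <- cor(x, y, method = "spearman")
  ids <- as.character(recording_ids)
  n <- length(y)
  null_rho <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- seq_len(n)
      for (lv in unique(ids)) {
        sel <- which(ids == lv)
        idx[sel] <- sel[sample.int(length(sel))]
      }
      cor(x, y[idx], method = "spearman")
    }, numeric(1))
  })
  p <- (1 + sum(abs(null_rho) >= abs(rho))) / (1 + n_perm)
  list(rho = rho, p = p, n_perm = n_perm)
}

#' Permutation independent-samples t-test
#'
#' Two-sided permutation test on the Welch t statistic, used by the
#' source-entropy simulation to compare per-epoch transfer entropies.
#'
#' @param x,y numeric samples.
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @export
perm_ttest <- function(x, y, n_perm = 10000, seed = 1L) {
  tstat <- function(a, b) {
    (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
  }
  obs <- tstat(x, y)
  pooled <- c(x, y); nx <- length(x)
  null_t <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled))
      tstat(pooled[idx[1:nx]], pooled[idx[-(1:nx)]])
    }, numeric(1))
  })
  list(statistic = obs,
       p = (1 + sum(abs(null_t) >= abs(obs))) / (1 + n_perm),
       n_perm = n_perm)
}
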