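#' @name bayes_estimators
#' @title Bayesian (NSB) entropy estimation for discretized signals
#'
#' @description
#' Signals are discretized into `n_inner_bins` equal-width bins spanning
#' +/- 3 SD around the mean plus two overflow bins (alphabet size
#' `N_bins = n_inner_bins + 2`). Delay-embedded state "words" over this
#' alphabet are counted, and entropies of word distributions are estimated
#' with the Nemenman-Shafee-Bialek (NSB) estimator: a mixture of symmetric
#' Dirichlet priors whose mixing density is flat in the prior expected
#' entropy, integrated numerically over the concentration parameter.
#' Transfer entropy decomposes into four such entropies and active
#' information storage into three. Values are in bits.
NULL

#' Discretize an epoch into voltage bins
#'
#' Values within +/- 3 SD of the mean are mapped to `n_inner_bins`
#' equal-width bins (half-open, right edge exclusive); values below /
#' above that range go to the bottom / top overflow bin. A value exactly
#' at the mean falls in the right one of the two central bins (half-open
#' convention). Bin order preserves value order.
#'
#' @param epoch numeric vector or matrix; when a matrix, the bin edges are
#'   computed from all values pooled so epochs share one alphabet.
#' @param n_inner_bins number of inner bins (alphabet size minus 2).
#' @return Integer symbols in `1..(n_inner_bins + 2)`, same shape as input.
#' @export
discretize <- function(epoch, n_inner_bins = 10) {
  .assert(n_inner_bins >= 2, "need at least 2 inner bins")
  v <- as.vector(epoch)
  m <- mean(v); s <- sd(v)
  .assert(is.finite(s) && s > 0, "degenerate signal: constant input")
  edges <- seq(m - 3 * s, m + 3 * s, length.out = n_inner_bins + 1)
  sym <- findInterval(v, edges, left.open = FALSE) + 1L
  if (is.matrix(epoch)) matrix(sym, nrow(epoch), ncol(epoch)) else sym
}

#' Character words for one embedding role over a symbol stream
#' @noRd
.word_block <- function(symbols, d, tau, lag, t_from) {
  blk <- .embed_block(symbols, d, tau, lag, t_from)
  apply(blk$states, 1, paste, collapse = ".")
}

#' Word-count histogram with declared support
#'
#' @param counts integer vector of observed word frequencies.
#' @param K declared support size (>= number of distinct observed words).
#' @param word_len symbols per word.
#' @param n_bins alphabet size per symbol.
#' @export
word_counts <- function(counts, K, word_len = NA, n_bins = NA) {
  counts <- as.integer(counts[counts > 0])
  .assert(K >= length(counts), "K must be at least the number of observed words")
  structure(list(counts = counts, K = K, word_len = word_len,
                 n_bins = n_bins, N = sum(counts)),
            class = "word_counts")
}

#' Build state-word counts from a discretized signal
#'
#' Delay-embeds the symbol stream in the given role and counts the
#' resulting words over all epochs pooled. Roles: `target_state` embeds
#' the past at lag 1, `source_state` at lag `u`, `present` takes the
#' current symbol.
#'
#' @param symbols integer vector or epoch x sample matrix from
#'   [discretize()].
#' @param d,tau embedding dimension and delay.
#' @param u assumed transfer delay (used by role `source_state`).
#' @param role one of `"target_state"`, `"source_state"`, `"present"`.
#' @param n_bins alphabet size (inferred from the symbols if missing).
#' @param K declared support; defaults to `n_bins ^ word_length`.
#' @export
state_words <- function(symbols, d, tau = 1, u = 1,
                        role = c("target_state", "source_state", "present"),
                        n_bins = max(symbols), K = NULL) {
  role <- match.arg(role)
  if (role == "present") { d <- 1L; lag <- 0L } else
    lag <- if (role == "source_state") as.integer(u) else 1L
  words <- .word_block(symbols, d, tau, lag,
                       t_from = 1 + lag + (d - 1) * tau)
  tab <- table(words)
  if (is.null(K)) K <- as.double(n_bins)^d
  word_counts(as.integer(tab), K = K, word_len = d, n_bins = n_bins)
}

#' Plug-in (maximum likelihood) entropy of a word distribution, in bits
#'
#' @param wc a [word_counts()] object.
#' @export
plugin_entropy <- function(wc) {
  p <- wc$counts / wc$N
  -sum(p * log2(p))
}

# Gauss-Legendre nodes/weights on [a, b] (Golub-Welsch)
.gauss_legendre <- function(n, a, b) {
  i <- 1:(n - 1)
  bet <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- bet
  J[cbind(i + 1, i)] <- bet
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = (b - a) / 2 * e$values[ord] + (a + b) / 2,
       w = (b - a) / 2 * 2 * e$vectors[1, ord]^2)
}

# prior expected entropy (nats) under symmetric Dirichlet(beta), support K
.nsb_xi <- function(beta, K) digamma(K * beta + 1) - digamma(beta + 1)

.nsb_beta_of_xi <- function(xi, K) {
  f <- function(lb) .nsb_xi(exp(lb), K) - xi
  exp(uniroot(f, c(-200, 200), tol = 1e-12)$root)
}

# lgamma(kappa) - lgamma(N + kappa), stable for huge kappa where the
# direct difference cancels catastrophically
.lgamma_drop <- function(kappa, N) {
  if (kappa > N * 1e9)
    -N * log(kappa) - N * (N - 1) / (2 * kappa)
  else
    lgamma(kappa) - lgamma(N + kappa)
}

# sum_i [lgamma(n_i + beta) - lgamma(beta)], stable for large beta via the
# exact product form sum_j #(n_i > j) * log(beta + j)
.lgamma_counts <- function(nn, beta) {
  if (beta < 1e5) return(sum(lgamma(nn + beta)) - length(nn) * lgamma(beta))
  js <- 0:(max(nn) - 1)
  m <- vapply(js, function(j) sum(nn > j), numeric(1))
  sum(m * log(beta + js))
}

# log evidence of the counts under Dirichlet(beta)
.nsb_logL <- function(beta, nn, K) {
  N <- sum(nn)
  .lgamma_drop(K * beta, N) + .lgamma_counts(nn, beta)
}

# posterior mean entropy (nats) given beta
.nsb_post_H <- function(beta, nn, K) {
  N <- sum(nn); K1 <- length(nn); kappa <- K * beta
  digamma(N + kappa + 1) -
    (sum((nn + beta) * digamma(nn + beta + 1)) +
       (K - K1) * beta * digamma(beta + 1)) / (N + kappa)
}

#' Nemenman-Shafee-Bialek entropy estimate
#'
#' Posterior-mean entropy under the NSB prior: the evidence-weighted
#' average of Dirichlet posterior-mean entropies, integrated over a grid
#' uniform in the prior expected entropy (which is what makes the prior
#' nearly flat in entropy). Requires at least two coincidences among the
#' observations; without coincidences the evidence carries no information
#' about the entropy.
#'
#' @param wc a [word_counts()] object.
#' @param K support size used in the prior (defaults to the declared
#'   support of `wc`); a working support smaller than the combinatorial
#'   maximum is legitimate for sparse distributions.
#' @param n_quad quadrature nodes for the final integral.
#' @return Entropy estimate in bits.
#' @export
nsb_entropy <- function(wc, K = wc$K, n_quad = 64) {
  .assert(inherits(wc, "word_counts"), "wc must be word_counts")
  nn <- wc$counts
  N <- sum(nn)
  .assert(N - length(nn) >= 2,
          "NSB undefined: need at least 2 coincidences among observations")
  logK <- log(K)
  # locate the evidence mass on a coarse xi grid, then integrate
  xs <- seq(logK * 1e-6, logK * (1 - 1e-9), length.out = 200)
  ll <- vapply(xs, function(xi) .nsb_logL(.nsb_beta_of_xi(xi, K), nn, K),
               numeric(1))
  mx <- max(ll)
  keep <- which(ll > mx - 35)
  a <- xs[max(1, min(keep) - 1)]
  b <- xs[min(length(xs), max(keep) + 1)]
  gl <- .gauss_legendre(n_quad, a, b)
  betas <- vapply(gl$x, .nsb_beta_of_xi, numeric(1), K = K)
  lw <- vapply(betas, .nsb_logL, numeric(1), nn = nn, K = K)
  w <- gl$w * exp(lw - max(lw))
  h <- vapply(betas, .nsb_post_H, numeric(1), nn = nn, K = K)
  sum(w * h) / sum(w) / log(2)
}

#' Aligned word tables for the TE decomposition roles
#' @noRd
.te_words <- function(src_sym, tgt_sym, dX, dY, tau_x, tau_y, u) {
  t_from <- .align_t_from(list(list(d = dX, tau = tau_x, lag = u),
                               list(d = dY, tau = tau_y, lag = 1),
                               list(d = 1, tau = 1, lag = 0)))
  list(pres  = .word_block(tgt_sym, 1L, 1L, 0L, t_from),
       ypast = .word_block(tgt_sym, dY, tau_y, 1L, t_from),
       xstate = .word_block(src_sym, dX, tau_x, as.integer(u), t_from))
}

.count_words <- function(words, K) {
  word_counts(as.integer(table(words)), K = K)
}

#' Transfer entropy from discretized data via entropy decomposition
#'
#' `TE = H(Y_past, X_state) + H(Y_t, Y_past) - H(Y_past)
#'  - H(Y_t, Y_past, X_state)`, each term estimated individually (NSB by
#' default, plug-in as the exact-oracle route). The support for each term
#' is `min(N_bins^word_length, K_max)`: a working support below the
#' combinatorial maximum keeps the NSB integral well-conditioned and is
#' valid for sparse word distributions.
#'
#' @param source,target numeric epoch x sample matrices (continuous).
#' @param dX,dY,tau,u embedding parameters as in [te_spo()]; `tau` length
#'   1 or 2 `(source, target)`.
#' @param n_inner_bins inner voltage bins (alphabet is this plus 2).
#' @param K_max working support ceiling (default `1e12`).
#' @param estimator `"nsb"` or `"plugin"`.
#' @return List with `value` (bits), the four `terms`, and the settings.
#' @export
te_decomposed <- function(source, target, dX = 1, dY = 1, tau = 1, u = 1,
                          n_inner_bins = 10, K_max = 1e12,
                          estimator = c("nsb", "plugin")) {
  estimator <- match.arg(estimator)
  if (is.vector(source)) source <- matrix(source, nrow = 1)
  if (is.vector(target)) target <- matrix(target, nrow = 1)
  .assert(all(dim(source) == dim(target)), "epoch mismatch between channels")
  tau_x <- tau[1]; tau_y <- tau[length(tau)]
  nb <- n_inner_bins + 2
  src_sym <- discretize(source, n_inner_bins)
  tgt_sym <- discretize(target, n_inner_bins)
  wds <- .te_words(src_sym, tgt_sym, dX, dY, tau_x, tau_y, u)
  kf <- function(len) min(as.double(nb)^len, K_max)
  est <- function(words, len) {
    wc <- .count_words(words, kf(len))
    if (estimator == "nsb") nsb_entropy(wc) else plugin_entropy(wc)
  }
  h_yp_x  <- est(paste(wds$ypast, wds$xstate, sep = "|"), dY + dX)
  h_t_yp  <- est(paste(wds$pres, wds$ypast, sep = "|"), 1 + dY)
  h_yp    <- est(wds$ypast, dY)
  h_all   <- est(paste(wds$pres, wds$ypast, wds$xstate, sep = "|"),
                 1 + dY + dX)
  list(value = h_yp_x + h_t_yp - h_yp - h_all,
       terms = c(H_ypast_xstate = h_yp_x, H_present_ypast = h_t_yp,
                 H_ypast = h_yp, H_present_ypast_xstate = h_all),
       n_bins = nb, estimator = estimator,
       params = list(dX = dX, dY = dY, tau = c(tau_x, tau_y), u = u))
}

#' Active information storage from discretized data
#'
#' `AIS = H(Y_t) + H(Y_past) - H(Y_t, Y_past)`, each term NSB- or
#' plug-in-estimated.
#'
#' @param epochs numeric vector or epoch x sample matrix.
#' @inheritParams te_decomposed
#' @param d,tau embedding of the past state.
#' @export
ais_decomposed <- function(epochs, d = 1, tau = 1, n_inner_bins = 10,
                           K_max = 1e12, estimator = c("nsb", "plugin")) {
  estimator <- match.arg(estimator)
  if (is.vector(epochs)) epochs <- matrix(epochs, nrow = 1)
  sym <- discretize(epochs, n_inner_bins)
  nb <- n_inner_bins + 2
  t_from <- .align_t_from(list(list(d = d, tau = tau, lag = 1),
                               list(d = 1, tau = 1, lag = 0)))
  pres <- .word_block(sym, 1L, 1L, 0L, t_from)
  past <- .word_block(sym, d, tau, 1L, t_from)
  kf <- function(len) min(as.double(nb)^len, K_max)
  est <- function(words, len) {
    wc <- .count_words(words, kf(len))
    if (estimator == "nsb") nsb_entropy(wc) else plugin_entropy(wc)
  }
  h_t <- est(pres, 1)
  h_p <- est(past, d)
  h_j <- est(paste(pres, past, sep = "|"), 1 + d)
  list(value = h_t + h_p - h_j,
       terms = c(H_present = h_t, H_past = h_p, H_joint = h_j),
       n_bins = nb, estimator = estimator, params = list(d = d, tau = tau))
}

#' Subsample-robustness check of an entropy estimate
#'
#' Re-estimates the entropy on nested subsamples of the data and flags the
#' estimate as stable when, over the top half of the curve, the relative
#' deviation from the full-sample estimate stays below `tol`. Recordings
#' whose estimates fail this check cannot be verified and should be
#' excluded.
#'
#' @param builder function taking a fraction in (0, 1] and returning a
#'   [word_counts()] for that nested subsample.
#' @param fractions increasing fractions (at least 3, last one 1).
#' @param tol relative-deviation tolerance over the top half of the curve.
#' @return List with `curve` (data frame fraction / N / H) and `stable`.
#' @export
subsample_robustness <- function(builder,
                                 fractions = c(0.1, 0.25, 0.5, 0.75, 1),
                                 tol = 0.05) {
  .assert(length(fractions) >= 3, "need at least 3 fractions")
  fractions <- sort(fractions)
  h <- numeric(length(fractions)); nn <- integer(length(fractions))
  for (i in seq_along(fractions)) {
    wc <- builder(fractions[i])
    nn[i] <- wc$N
    h[i] <- nsb_entropy(wc)
  }
  top <- seq(ceiling(length(fractions) / 2), length(fractions))
  ref <- h[length(h)]
  stable <- is.finite(ref) && ref > 0 &&
    max(abs(h[top] - ref)) / ref < tol
  list(curve = data.frame(fraction = fractions, N = nn, H = h),
       stable = stable)
}
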