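#' Delay-embedding specification
#'
#' Defines past-state construction for one signal: the past state at time
#' `t` is the vector `(y[t-l], y[t-l-tau], ..., y[t-l-(d-1)tau])` where the
#' base lag `l` is 1 for a target's own past and the assumed transfer delay
#' `u >= 1` for a source state.
#'
#' @param d embedding dimension (number of past samples), >= 1.
#' @param tau embedding delay in samples, >= 1.
#' @param u assumed information-transfer delay in samples (source
#'   embeddings only), >= 1 or `NULL` for a target-past embedding.
#' @return An object of class `embedding_spec`.
#' @export
embedding_spec <- function(d, tau = 1, u = NULL) {
  .assert(d >= 1 && d == round(d), "d must be a positive integer")
  .assert(tau >= 1 && tau == round(tau), "tau must be a positive integer")
  if (!is.null(u))
    .assert(u >= 1 && u == round(u), "u must be a positive integer (delta >= 1)")
  structure(list(d = as.integer(d), tau = as.integer(tau),
                 u = if (is.null(u)) NULL else as.integer(u)),
            class = "embedding_spec")
}

#' Stack delay-embedded states of all epochs, rows ordered (epoch, time).
#' `lag` is the base lag of the newest embedded sample; `t_from` the first
#' present-time index (1-based) to produce a state for.
#' @noRd
.embed_block <- function(epochs, d, tau, lag, t_from = NULL) {
  if (is.vector(epochs)) epochs <- matrix(epochs, nrow = 1)
  n <- ncol(epochs)
  need <- 1 + lag + (d - 1) * tau
  if (d == 1 && lag == 0) need <- 1
  if (is.null(t_from)) t_from <- need
  .assert(t_from <= n, "epoch too short for this embedding spec")
  ts <- t_from:n
  states <- matrix(0, nrow(epochs) * length(ts), d)
  for (j in seq_len(d)) {
    cols <- ts - lag - (j - 1) * tau
    states[, j] <- as.vector(t(epochs[, cols, drop = FALSE]))
  }
  list(states = states,
       time_index = rep(ts, times = nrow(epochs)),
       epoch_index = rep(seq_len(nrow(epochs)), each = length(ts)))
}

#' Delay-embed epoched data into a state matrix
#'
#' Constructs past states (or present samples) for every valid time point
#' of every epoch; states never span epoch boundaries. With
#' `align = "past_of_t"` the state attributed to time `t` is
#' `(y[t-1], y[t-1-tau], ...)` for a target-past spec, and additionally
#' lagged by the transfer delay `u` for a source spec. With
#' `align = "present_t"` the "state" is the present sample itself.
#'
#' @param epochs numeric vector (one epoch) or epoch x sample matrix.
#' @param spec an [embedding_spec()].
#' @param align `"past_of_t"` or `"present_t"`.
#' @return A list of class `state_matrix` with `states` (point x dim),
#'   `time_index`, `epoch_index`.
#' @export
delay_embed <- function(epochs, spec, align = c("past_of_t", "present_t")) {
  align <- match.arg(align)
  .assert(inherits(spec, "embedding_spec"), "spec must be an embedding_spec")
  if (align == "present_t") {
    out <- .embed_block(epochs, 1L, 1L, 0L)
  } else {
    lag <- if (is.null(spec$u)) 1L else spec$u
    out <- .embed_block(epochs, spec$d, spec$tau, lag)
  }
  out$d <- if (align == "present_t") 1L else spec$d
  out$tau <- spec$tau
  class(out) <- "state_matrix"
  out
}

#' Common aligned time range for several (d, tau, lag) roles
#' @noRd
.align_t_from <- function(roles) {
  1 + max(vapply(roles, function(r) r$lag + (r$d - 1) * r$tau, 0))
}

#' Optimize embedding parameters by the Ragwitz local-predictor criterion
#'
#' For each candidate `(d, tau)`, every point's next sample is predicted as
#' the mean of the next samples of its `k` nearest neighbours in the
#' delay-embedded state space (max norm; one-sample prediction horizon);
#' the candidate minimizing the mean squared prediction error wins. Ties
#' are broken toward smaller `d`, then smaller `tau`. Epochs are pooled for
#' the neighbour search but embeddings never cross epoch boundaries.
#'
#' @param epochs numeric vector or epoch x sample matrix.
#' @param d_candidates integer vector of candidate dimensions.
#' @param tau_candidates integer vector of candidate delays; if `NULL`,
#'   derived from the mean epoch autocorrelation decay time via
#'   `tau_act_fractions`.
#' @param tau_act_fractions fractions of the ACT used to build the tau grid
#'   when `tau_candidates` is `NULL`.
#' @param k neighbours for the local predictor.
#' @return List with `d`, `tau`, and `mse_table` (one row per candidate).
#' @export
ragwitz_optimize <- function(epochs, d_candidates = 1:5,
                             tau_candidates = NULL,
                             tau_act_fractions = c(0.2, 0.4, 0.6, 0.8, 1.0),
                             k = 4) {
  if (is.vector(epochs)) epochs <- matrix(epochs, nrow = 1)
  .assert(sd(as.vector(epochs)) > 0, "degenerate signal: constant input")
  if (is.null(tau_candidates)) {
    acts <- apply(epochs, 1, act, on_no_decay = "na")
    base <- mean(acts, na.rm = TRUE)
    if (!is.finite(base)) base <- 1
    tau_candidates <- sort(unique(pmax(1L, round(tau_act_fractions * base))))
  }
  grid <- expand.grid(tau = sort(unique(as.integer(tau_candidates))),
                      d = sort(unique(as.integer(d_candidates))))
  grid <- grid[order(grid$d, grid$tau), c("d", "tau")]
  .assert(nrow(grid) >= 2, "need at least 2 candidate (d, tau) pairs")
  mse <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    d <- grid$d[i]; tau <- grid$tau[i]
    emb <- .embed_block(epochs, d, tau, lag = 1L)
    y_next <- as.vector(t(epochs))[(emb$epoch_index - 1) * ncol(epochs) +
                                     emb$time_index]
    .assert(nrow(emb$states) > k, "too few samples for this candidate grid")
    nn <- .cpp_knn(emb$states, k)
    pred <- rowMeans(matrix(y_next[nn$idx], nrow = nrow(nn$idx)))
    mse[i] <- mean((pred - y_next)^2)
  }
  best <- which.min(mse)  # grid ordered by (d, tau): ties go to smaller
  list(d = grid$d[best], tau = grid$tau[best],
       mse_table = cbind(grid, mse = mse))
}

#' Common embedding dimension across conditions and directions
#'
#' The estimator bias depends on the embedding dimension, so estimates are
#' made comparable by embedding every epoch with the maximum optimized `d`
#' across all conditions and directions; `tau` stays per-epoch.
#'
#' @param specs list of [embedding_spec()] objects (or lists with a `d`).
#' @return The maximum `d`.
#' @export
common_dimension <- function(specs) {
  .assert(length(specs) >= 1, "empty spec list")
  max(vapply(specs, function(s) as.integer(s$d), integer(1)))
}
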