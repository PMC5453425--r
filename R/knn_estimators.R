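#' @name knn_estimators
#' @title Nearest-neighbour estimators for entropy, storage and transfer
#'
#' @description
#' Continuous-data estimation of differential entropy (Kozachenko-Leonenko),
#' mutual information and conditional mutual information
#' (Kraskov-Stoegbauer-Grassberger, KSG), and on top of these active
#' information storage (AIS) and self-prediction-optimal transfer entropy
#' (TE_SPO) with an explicit assumed transfer delay `u`. All neighbour
#' searches use the maximum norm. Values are in nats unless converted.
#'
#' The mutual-information form is the KSG "algorithm 2" expression
#' `psi(k) - 1/k + psi(N) - <psi(n_x) + psi(n_y)>` (marginal radii from the
#' k-th joint neighbour, counts inclusive); the conditional form is the
#' "algorithm 1" expression
#' `psi(k) + <psi(n_c + 1) - psi(n_ac + 1) - psi(n_bc + 1)>` (joint radius,
#' strict counts). The two conventions carry slightly different biases;
#' comparative statistics are unaffected.
NULL

.as_states <- function(x) {
  if (inherits(x, "state_matrix")) x$states
  else if (is.matrix(x)) x
  else matrix(x, ncol = 1)
}

#' Deterministically break exact duplicates before neighbour searches.
#' Duplicate points (typical after discretization) make k-th neighbour
#' distances zero and the KSG counts ill-defined; a tiny seeded jitter
#' (amplitude `jitter` x column SD) restores uniqueness without moving the
#' estimate at working precision.
#' @noRd
.maybe_jitter <- function(X, jitter = 1e-10, jitter_seed = 0L) {
  if (!anyDuplicated(X)) return(X)
  if (jitter <= 0)
    stop("duplicate points in state space; enable jitter or de-duplicate",
         call. = FALSE)
  scales <- apply(X, 2, sd)
  scales[scales == 0] <- 1
  .with_seed(jitter_seed, {
    X + matrix(rnorm(length(X)), nrow(X)) *
      rep(jitter * scales, each = nrow(X))
  })
}

.to_units <- function(nats, units) {
  if (units == "bits") nats / log(2) else nats
}

#' Kozachenko-Leonenko differential entropy
#'
#' `H = -psi(k) + psi(N) + (d/N) * sum_i log(eps_i)` with `eps_i` twice the
#' max-norm distance from point `i` to its k-th nearest neighbour.
#'
#' @param states point x dimension matrix (or `state_matrix`, or vector).
#' @param k number of neighbours.
#' @param units `"nats"` or `"bits"`.
#' @param jitter relative amplitude of the deterministic duplicate-breaking
#'   jitter; 0 turns it off (duplicates then raise an error).
#' @param jitter_seed seed of the jitter stream.
#' @return Differential entropy estimate.
#' @export
kl_entropy <- function(states, k = 4, units = c("nats", "bits"),
                       jitter = 1e-10, jitter_seed = 0L) {
  units <- match.arg(units)
  X <- .as_states(states)
  n <- nrow(X); d <- ncol(X)
  .assert(n > k, "need more points than neighbours (N > k)")
  X <- .maybe_jitter(X, jitter, jitter_seed)
  kd <- .cpp_knn(X, k)$dist
  .assert(all(kd > 0), "zero k-th neighbour distance; increase jitter")
  h <- -digamma(k) + digamma(n) + (d / n) * sum(log(2 * kd))
  .to_units(h, units)
}

#' KSG mutual information (algorithm 2)
#'
#' @param a,b aligned point x dimension matrices (same number of rows).
#' @inheritParams kl_entropy
#' @export
ksg_mi <- function(a, b, k = 4, units = c("nats", "bits"),
                   jitter = 1e-10, jitter_seed = 0L) {
  units <- match.arg(units)
  A <- .as_states(a); B <- .as_states(b)
  .assert(nrow(A) == nrow(B), "misaligned state matrices")
  n <- nrow(A)
  .assert(n > k, "need more points than neighbours (N > k)")
  J <- .maybe_jitter(cbind(A, B), jitter, jitter_seed)
  da <- ncol(A); db <- ncol(B)
  nn <- .cpp_knn(J, k)
  blocks <- rbind(c(1L, da), c(da + 1L, da + db))
  rad <- .cpp_marginal_radii(J, nn$idx, blocks)
  n_x <- .cpp_count_within(J[, 1:da, drop = FALSE], rad[, 1], strict = FALSE)
  n_y <- .cpp_count_within(J[, (da + 1):(da + db), drop = FALSE], rad[, 2],
                           strict = FALSE)
  mi <- digamma(k) - 1 / k + digamma(n) - mean(digamma(n_x) + digamma(n_y))
  .to_units(mi, units)
}

#' KSG conditional mutual information (algorithm 1)
#'
#' `I(A; B | C)` with the search radius set per point by the k-th
#' neighbour in the full joint space and strict neighbour counts in the
#' subspaces `(C)`, `(A, C)` and `(B, C)`.
#'
#' @param a,b,cond aligned point x dimension matrices.
#' @inheritParams kl_entropy
#' @export
ksg_cmi <- function(a, b, cond, k = 4, units = c("nats", "bits"),
                    jitter = 1e-10, jitter_seed = 0L) {
  units <- match.arg(units)
  A <- .as_states(a); B <- .as_states(b); C <- .as_states(cond)
  .assert(nrow(A) == nrow(B) && nrow(A) == nrow(C),
          "misaligned state matrices")
  n <- nrow(A)
  .assert(n > k, "need more points than neighbours (N > k)")
  J <- .maybe_jitter(cbind(A, B, C), jitter, jitter_seed)
  da <- ncol(A); db <- ncol(B); dc <- ncol(C)
  Ac <- J[, 1:da, drop = FALSE]
  Bc <- J[, (da + 1):(da + db), drop = FALSE]
  Cc <- J[, (da + db + 1):(da + db + dc), drop = FALSE]
  eps <- .cpp_knn(J, k)$dist
  n_c  <- .cpp_count_within(Cc, eps, strict = TRUE)
  n_ac <- .cpp_count_within(cbind(Ac, Cc), eps, strict = TRUE)
  n_bc <- .cpp_count_within(cbind(Bc, Cc), eps, strict = TRUE)
  cmi <- digamma(k) +
    mean(digamma(n_c + 1) - digamma(n_ac + 1) - digamma(n_bc + 1))
  .to_units(cmi, units)
}

#' One information-theoretic estimate with its provenance
#' @noRd
.estimate_record <- function(measure, value, units, direction_or_site,
                             condition = "none", session_id = "session1",
                             epoch_index = "pooled", params = list()) {
  structure(list(measure = measure, value = value, unit = units,
                 direction_or_site = direction_or_site,
                 condition = condition, session_id = session_id,
                 epoch_index = epoch_index, params = params),
            class = "estimate_record")
}

#' @export
print.estimate_record <- function(x, ...) {
  cat(sprintf("<%s = %.4f %s | %s | %s | epoch %s>\n", x$measure, x$value,
              x$unit, x$direction_or_site, x$condition,
              paste(x$epoch_index, collapse = ",")))
  invisible(x)
}

#' @export
as.data.frame.estimate_record <- function(x, ...) {
  data.frame(measure = x$measure, value = x$value, unit = x$unit,
             direction_or_site = x$direction_or_site,
             condition = x$condition, session_id = x$session_id,
             epoch_index = paste(x$epoch_index, collapse = ","),
             k = if (is.null(x$params$k)) NA else x$params$k,
             d = if (is.null(x$params$d)) NA else paste(x$params$d, collapse = "/"),
             tau = if (is.null(x$params$tau)) NA else paste(x$params$tau, collapse = "/"),
             u = if (is.null(x$params$u)) NA else x$params$u,
             stringsAsFactors = FALSE)
}

#' Active information storage
#'
#' Mutual information between the present sample and the signal's own
#' delay-embedded past state, estimated with the KSG estimator over all
#' epochs pooled.
#'
#' @param epochs numeric vector or epoch x sample matrix.
#' @param d,tau embedding dimension and delay of the past state.
#' @inheritParams kl_entropy
#' @param site site label recorded in the result.
#' @param record if `TRUE` return an `estimate_record`, else the bare value.
#' @export
ais <- function(epochs, d, tau = 1, k = 4, units = c("nats", "bits"),
                site = "site", record = TRUE, jitter = 1e-10) {
  units <- match.arg(units)
  if (is.vector(epochs)) epochs <- matrix(epochs, nrow = 1)
  t_from <- .align_t_from(list(list(d = d, tau = tau, lag = 1),
                               list(d = 1, tau = 1, lag = 0)))
  past <- .embed_block(epochs, d, tau, lag = 1L, t_from = t_from)
  pres <- .embed_block(epochs, 1L, 1L, lag = 0L, t_from = t_from)
  v <- ksg_mi(pres$states, past$states, k = k, units = units, jitter = jitter)
  if (!record) return(v)
  .estimate_record("AIS", v, units, direction_or_site = site,
                   params = list(k = k, d = d, tau = tau))
}

#' Self-prediction-optimal transfer entropy
#'
#' `TE_SPO(X -> Y, u) = I(Y_t ; X_{t-u}^{dX} | Y_{t-1}^{dY})`: the
#' conditional mutual information between the target's present sample and
#' the source's past state lagged by the assumed transfer delay `u`, given
#' the target's own past state. Estimated with the KSG conditional
#' estimator over all epochs pooled.
#'
#' @param source,target numeric vectors or epoch x sample matrices with
#'   matching epoch structure.
#' @param dX,dY source and target embedding dimensions.
#' @param tau embedding delay(s); length 1 (shared) or 2 `(source, target)`.
#' @param u assumed transfer delay in samples, >= 1.
#' @inheritParams kl_entropy
#' @param direction direction label recorded in the result.
#' @param record if `TRUE` return an `estimate_record`, else the bare value.
#' @export
te_spo <- function(source, target, dX = 1, dY = 1, tau = 1, u = 1, k = 4,
                   units = c("nats", "bits"), direction = "source->target",
                   record = TRUE, jitter = 1e-10) {
  units <- match.arg(units)
  .assert(u >= 1, "u must be >= 1 (physical delay delta >= 1)")
  if (is.vector(source)) source <- matrix(source, nrow = 1)
  if (is.vector(target)) target <- matrix(target, nrow = 1)
  .assert(all(dim(source) == dim(target)),
          "epoch mismatch between source and target channels")
  tau_x <- tau[1]; tau_y <- tau[length(tau)]
  t_from <- .align_t_from(list(list(d = dX, tau = tau_x, lag = u),
                               list(d = dY, tau = tau_y, lag = 1),
                               list(d = 1, tau = 1, lag = 0)))
  .assert(t_from <= ncol(target), "epoch too short for this (d, tau, u)")
  pres <- .embed_block(target, 1L, 1L, lag = 0L, t_from = t_from)
  past_y <- .embed_block(target, dY, tau_y, lag = 1L, t_from = t_from)
  src_st <- .embed_block(source, dX, tau_x, lag = as.integer(u),
                         t_from = t_from)
  v <- ksg_cmi(pres$states, src_st$states, past_y$states, k = k,
               units = units, jitter = jitter)
  if (!record) return(v)
  .estimate_record("TE_SPO", v, units, direction_or_site = direction,
                   params = list(k = k, d = c(dX, dY),
                                 tau = c(tau_x, tau_y), u = u))
}

#' Scan assumed transfer delays and reconstruct the coupling delay
#'
#' Estimates `TE_SPO` for every `u` in the grid and reconstructs the
#' information-transfer delay as the `u` maximizing it (ties toward the
#' smallest `u`). All local maxima of the TE-vs-u curve are reported as
#' well: multiple peaks are diagnostically meaningful (multiple transfer
#' channels, feedback loops, or filtering artifacts).
#'
#' @inheritParams te_spo
#' @param u_grid integer vector of assumed delays (all >= 1).
#' @return List of class `delay_scan`: `u_grid`, `te_values`, `u_opt`,
#'   `peaks`.
#' @export
scan_delay <- function(source, target, dX = 1, dY = 1, tau = 1,
                       u_grid = 1:20, k = 4, jitter = 1e-10) {
  .assert(length(u_grid) >= 1 && all(u_grid >= 1),
          "u grid must be non-empty with all u >= 1")
  u_grid <- sort(unique(as.integer(u_grid)))
  te <- vapply(u_grid, function(u)
    te_spo(source, target, dX, dY, tau, u, k, record = FALSE,
           jitter = jitter), numeric(1))
  u_opt <- u_grid[which.max(te)]  # which.max returns first => smallest u
  lo <- c(-Inf, te[-length(te)]); hi <- c(te[-1], -Inf)
  peaks <- u_grid[te > lo & te >= hi]
  structure(list(u_grid = u_grid, te_values = te, u_opt = u_opt,
                 peaks = peaks),
            class = "delay_scan")
}

#' @export
print.delay_scan <- function(x, ...) {
  cat(sprintf("<delay_scan: u_opt = %d | peaks at %s | grid %d..%d>\n",
              x$u_opt, paste(x$peaks, collapse = ","),
              min(x$u_grid), max(x$u_grid)))
  invisible(x)
}

#' Net transfer entropy
#'
#' Normalized difference `(TE_fwd - TE_rev) / (TE_fwd + TE_rev)` of the two
#' directed transfer entropies; lies in `[-1, 1]` for nonnegative inputs.
#' Only meaningful when each direction uses its own optimized delay.
#'
#' @param te_xy,te_yx directed `TE_SPO` values (forward, reverse).
#' @export
te_net <- function(te_xy, te_yx) {
  s <- te_xy + te_yx
  .assert(is.finite(s) && s != 0, "te_net undefined: TE_fwd + TE_rev == 0")
  (te_xy - te_yx) / s
}

#' Z-normalize a vector of estimates across conditions (reporting mode)
#'
#' @param values numeric vector of estimates pooled across conditions.
#' @export
znorm_across <- function(values) (values - mean(values)) / sd(values)
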