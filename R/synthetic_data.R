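#' Parameters for the synthetic two-site LFP generator
#'
#' Describes a generative world emulating the statistical structure of
#' epoched two-site local field potential recordings: a source channel with
#' tunable entropy (overall variance scale), predictability (autoregressive
#' weight) and oscillatory components, and a target channel receiving a
#' scaled, Gaussian-smoothed and delayed copy of the source at a fixed
#' sample delay. Epochs are independent realizations; embeddings downstream
#' never cross epoch boundaries, and neither does the generator.
#'
#' Defaults mirror the recording setup the analysis assumes: 4.81-s epochs
#' at 1000 Hz, several hundred epochs per recording, a handful of
#' recordings per condition, a coupling delay of a few milliseconds and a
#' coupling gain of 0.2 (the gain used in the in-package simulation
#' studies). Oscillatory defaults (theta 4 Hz and alpha 10 Hz components)
#' are a documented free choice, not a measured spectrum.
#'
#' @param n_recordings_per_condition recordings ("sessions") per condition.
#' @param n_epochs epochs per recording.
#' @param epoch_len_s epoch length in seconds.
#' @param fs sampling rate in Hz.
#' @param coupling_gain gain of the source-to-target coupling (>= 0).
#' @param coupling_delay coupling delay in samples (>= 1, < epoch length).
#' @param source_entropy_scale multiplier in (0, 1] on the source standard
#'   deviation; 1 corresponds to the awake-like, high-entropy regime.
#' @param storage_gain AR(1) coefficient in `[0, 1)` of both channels' own
#'   dynamics; larger values mean more predictable (higher-storage) signals.
#' @param osc_components list of `c(freq_hz, amplitude)` oscillations added
#'   to the source. Oscillations are narrowband stochastic resonators
#'   (AR(2) with pole radius 0.99), not deterministic sinusoids: real LFP
#'   rhythms have finite bandwidth and phase diffusion, and a deterministic
#'   sine carries no innovation, which would make storage and transfer
#'   degenerate.
#' @param noise_sd innovation standard deviation (signal units).
#' @param smooth_samples SD, in samples, of the Gaussian kernel applied to
#'   the source before injection into the target.
#' @param intercept_sd SD of the per-recording log-normal jitter applied to
#'   `source_entropy_scale` and `storage_gain`, giving recordings distinct
#'   "intercepts" so the intraclass correlation of downstream estimates is
#'   positive.
#' @param seed master seed; per-recording substreams are derived
#'   deterministically from it.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(n_recordings_per_condition = 5,
                         n_epochs = 400,
                         epoch_len_s = 4.81,
                         fs = 1000,
                         coupling_gain = 0.2,
                         coupling_delay = 5,
                         source_entropy_scale = 1,
                         storage_gain = 0.5,
                         osc_components = list(c(4, 0.5), c(10, 1)),
                         noise_sd = 1,
                         smooth_samples = 10,
                         intercept_sd = 0.05,
                         seed = 1L) {
  p <- list(n_recordings_per_condition = n_recordings_per_condition,
            n_epochs = n_epochs, epoch_len_s = epoch_len_s, fs = fs,
            coupling_gain = coupling_gain, coupling_delay = coupling_delay,
            source_entropy_scale = source_entropy_scale,
            storage_gain = storage_gain, osc_components = osc_components,
            noise_sd = noise_sd, smooth_samples = smooth_samples,
            intercept_sd = intercept_sd, seed = as.integer(seed))
  validate_synth_params(p)
  class(p) <- "synth_params"
  p
}

#' @noRd
validate_synth_params <- function(p) {
  n_samp <- round(p$epoch_len_s * p$fs)
  .assert(p$fs > 0, "fs must be positive")
  .assert(p$n_epochs >= 1, "need at least one epoch")
  .assert(p$coupling_gain >= 0, "coupling_gain must be >= 0")
  .assert(p$coupling_delay >= 1 && p$coupling_delay < n_samp,
          "coupling_delay must be >= 1 sample and smaller than the epoch")
  .assert(p$source_entropy_scale > 0 && p$source_entropy_scale <= 1,
          "source_entropy_scale must lie in (0, 1]")
  .assert(p$storage_gain >= 0 && p$storage_gain < 1,
          "storage_gain must lie in [0, 1) for stationarity")
  .assert(p$noise_sd > 0, "noise_sd must be positive")
  invisible(p)
}

#' Narrowband stochastic oscillation: AR(2) resonator at frequency f with
#' pole radius r, innovation variance scaled for unit stationary variance.
#' @noRd
.resonator <- function(n, freq, fs, r = 0.99) {
  theta <- 2 * pi * freq / fs
  a1 <- 2 * r * cos(theta); a2 <- -r^2
  # stationary variance of AR(2): gamma0 = s2e (1+r^2) /
  #   ((1-r^2)((1+r^2)^2 - 4 r^2 cos^2(theta)))
  g0 <- (1 + r^2) / ((1 - r^2) * ((1 + r^2)^2 - 4 * r^2 * cos(theta)^2))
  e <- rnorm(n, 0, sqrt(1 / g0))
  as.numeric(stats::filter(e, c(a1, a2), method = "recursive"))
}

#' Gaussian smoothing of each epoch row (kernel SD in samples)
#' @noRd
.gauss_smooth <- function(x, sd_samples) {
  if (sd_samples <= 0) return(x)
  half <- max(1L, ceiling(4 * sd_samples))
  kern <- exp(-0.5 * ((-half:half) / sd_samples)^2)
  kern <- kern / sum(kern)
  sm <- function(v) {
    padded <- c(rep(v[1], half), v, rep(v[length(v)], half))
    as.numeric(stats::filter(padded, kern, sides = 2))[(half + 1):(half + length(v))]
  }
  if (is.matrix(x)) t(apply(x, 1, sm)) else sm(x)
}

#' Generate one synthetic two-site recording
#'
#' Source channel: AR(1) own dynamics plus oscillatory components plus
#' white noise, with the final signal scaled by `source_entropy_scale`.
#' Target channel: AR(1) own dynamics plus `coupling_gain` times a
#' Gaussian-smoothed copy of the source delayed by `coupling_delay`
#' samples. Epochs are generated independently.
#'
#' @param params a [synth_params()] object.
#' @param condition condition label attached to the recording.
#' @param session_id session identifier (defaults to a label derived from
#'   the condition and recording index).
#' @param rec_index recording index within the condition; selects the
#'   deterministic random substream and the per-recording jitter.
#' @return A [recording()] with channels `source` and `target`.
#' @export
generate_recording <- function(params, condition = "cond1",
                               session_id = NULL, rec_index = 1L) {
  validate_synth_params(params)
  n <- round(params$epoch_len_s * params$fs)
  ne <- params$n_epochs
  seed <- .substream(params$seed, match(condition, condition, 0L),
                     sum(utf8ToInt(condition)), rec_index)
  if (is.null(session_id))
    session_id <- sprintf("%s_rec%02d", condition, rec_index)
  .with_seed(seed, {
    # per-recording intercept jitter (log-normal, multiplicative)
    jit <- exp(rnorm(2, 0, params$intercept_sd))
    ses <- min(1, params$source_entropy_scale * jit[1])
    phi <- min(0.99, params$storage_gain * jit[2])
    src <- matrix(0, ne, n)
    tgt <- matrix(0, ne, n)
    for (e in seq_len(ne)) {
      x <- as.numeric(stats::filter(rnorm(n, 0, params$noise_sd),
                                    phi, method = "recursive"))
      for (oc in params$osc_components)
        x <- x + oc[2] * .resonator(n, oc[1], params$fs)
      x <- ses * x
      y_own <- as.numeric(stats::filter(rnorm(n, 0, params$noise_sd),
                                        phi, method = "recursive"))
      coupled <- rep(0, n)
      if (params$coupling_gain > 0) {
        xs <- .gauss_smooth(x, params$smooth_samples)
        d <- params$coupling_delay
        coupled[(d + 1):n] <- params$coupling_gain * xs[1:(n - d)]
      }
      src[e, ] <- x
      tgt[e, ] <- y_own + coupled
    }
    recording(list(source = src, target = tgt), fs = params$fs,
              condition = condition, session_id = session_id)
  })
}

#' Generate a nested condition set of synthetic recordings
#'
#' Applies per-condition overrides to a base parameter set and generates
#' `n_recordings_per_condition` recordings per condition, each from its own
#' deterministic substream. The result is the nested structure (epochs
#' within recordings within conditions) that the permutation-ANOVA and
#' mixed-model stages require.
#'
#' @param base a [synth_params()] object.
#' @param condition_map named list; each element is a list of parameter
#'   overrides for that condition (e.g.
#'   `list(iso_1.0 = list(source_entropy_scale = 0.5))`).
#' @return A list of [recording()] objects.
#' @export
generate_condition_set <- function(base, condition_map) {
  .assert(length(condition_map) >= 2, "need at least 2 conditions")
  .assert(!is.null(names(condition_map)) && all(nzchar(names(condition_map))),
          "condition_map must be a named list")
  out <- list()
  for (cond in names(condition_map)) {
    p <- modifyList(unclass(base), condition_map[[cond]])
    class(p) <- "synth_params"
    validate_synth_params(p)
    .assert(p$n_recordings_per_condition >= 2,
            "need >= 2 recordings per condition for the statistics stages")
    for (r in seq_len(p$n_recordings_per_condition))
      out[[length(out) + 1]] <- generate_recording(p, condition = cond,
                                                   rec_index = r)
  }
  out
}
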