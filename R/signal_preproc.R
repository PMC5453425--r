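#' Epoched two-channel recording container
#'
#' Holds the epoch-by-sample matrices of two simultaneously recorded
#' channels (e.g. sites V1 and PFC) together with the sampling rate and
#' experiment metadata. Both channels must have identical epoch count and
#' epoch length; embeddings and estimators never cross epoch boundaries.
#'
#' @param channels named list of exactly two numeric matrices
#'   (epoch x sample); names are the site labels.
#' @param fs sampling rate in Hz.
#' @param condition condition label (e.g. `"iso_0.0"`).
#' @param session_id recording-session identifier.
#' @return An object of class `recording`.
#' @export
recording <- function(channels, fs, condition = "none",
                      session_id = "session1") {
  .assert(is.list(channels) && length(channels) == 2,
          "channels must be a named list of exactly two matrices")
  .assert(!is.null(names(channels)) && all(nzchar(names(channels))),
          "channels must be named by site")
  channels <- lapply(channels, function(ch) {
    if (is.vector(ch)) ch <- matrix(ch, nrow = 1)
    .assert(is.matrix(ch) && is.numeric(ch), "each channel must be numeric")
    ch
  })
  d1 <- dim(channels[[1]]); d2 <- dim(channels[[2]])
  .assert(all(d1 == d2), "channels must have identical epoch count and length")
  .assert(is.numeric(fs) && fs > 0, "fs must be a positive number")
  structure(list(channels = channels, fs = fs, condition = condition,
                 session_id = session_id),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<recording %s | condition %s | sites %s | %d epochs x %d samples @ %g Hz>\n",
              x$session_id, x$condition,
              paste(names(x$channels), collapse = "/"), d[1], d[2], x$fs))
  invisible(x)
}

#' @rdname recording
#' @param x a `recording`.
#' @export
n_epochs <- function(x) nrow(x$channels[[1]])

#' @rdname recording
#' @export
sites <- function(x) names(x$channels)

#' Write / load a recording (CSV + JSON sidecar)
#'
#' Plain-text container: `<path>.csv` holds the long-format samples
#' (columns `channel`, `epoch`, `sample`, `value`), `<path>.json` the
#' metadata (`fs`, `sites`, `condition`, `session_id`, `n_epochs`,
#' `epoch_len`). Write-then-load reproduces values to float precision.
#'
#' @param rec a [recording()].
#' @param path file stem (without extension).
#' @return `load_recording` returns a [recording()].
#' @export
write_recording <- function(rec, path) {
  .assert(inherits(rec, "recording"), "rec must be a recording")
  d <- dim(rec$channels[[1]])
  rows <- do.call(rbind, lapply(names(rec$channels), function(ch) {
    m <- rec$channels[[ch]]
    data.frame(channel = ch,
               epoch = rep(seq_len(d[1]), each = d[2]),
               sample = rep(seq_len(d[2]), times = d[1]),
               value = as.vector(t(m)))
  }))
  utils::write.csv(rows, paste0(path, ".csv"), row.names = FALSE)
  meta <- list(fs = rec$fs, sites = names(rec$channels),
               condition = rec$condition, session_id = rec$session_id,
               n_epochs = d[1], epoch_len = d[2])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
load_recording <- function(path) {
  csv <- paste0(path, ".csv"); js <- paste0(path, ".json")
  .assert(file.exists(csv) && file.exists(js),
          sprintf("recording files not found at stem '%s'", path))
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  for (f in c("fs", "sites", "n_epochs", "epoch_len"))
    .assert(!is.null(meta[[f]]), sprintf("format error: missing '%s' metadata", f))
  tab <- utils::read.csv(csv)
  .assert(all(c("channel", "epoch", "sample", "value") %in% names(tab)),
          "format error: csv must have channel/epoch/sample/value columns")
  channels <- lapply(meta$sites, function(ch) {
    sub <- tab[tab$channel == ch, ]
    .assert(nrow(sub) == meta$n_epochs * meta$epoch_len,
            sprintf("format error: ragged or missing data for channel '%s'", ch))
    m <- matrix(NA_real_, meta$n_epochs, meta$epoch_len)
    m[cbind(sub$epoch, sub$sample)] <- sub$value
    .assert(!anyNA(m), "format error: incomplete epoch grid")
    m
  })
  names(channels) <- meta$sites
  recording(channels, fs = meta$fs,
            condition = if (is.null(meta$condition)) "none" else meta$condition,
            session_id = if (is.null(meta$session_id)) "session1" else meta$session_id)
}

#' Cut a continuous signal into fixed-length epochs
#'
#' @param signal numeric vector.
#' @param fs sampling rate in Hz.
#' @param epoch_len_s epoch length in seconds (default 4.81 s).
#' @return Matrix (epoch x sample); the trailing remainder shorter than one
#'   epoch is dropped.
#' @export
segment_epochs <- function(signal, fs, epoch_len_s = 4.81) {
  n_ep_samp <- round(epoch_len_s * fs)
  n <- length(signal)
  .assert(n >= n_ep_samp, "signal shorter than one epoch")
  ne <- floor(n / n_ep_samp)
  matrix(signal[seq_len(ne * n_ep_samp)], nrow = ne, ncol = n_ep_samp,
         byrow = TRUE)
}

#' Z-normalize epochs to zero mean and unit variance
#'
#' Operates per epoch (per row of a matrix). Idempotent.
#'
#' @param epoch numeric vector (one epoch) or matrix (epoch x sample).
#' @export
znormalize <- function(epoch) {
  if (is.matrix(epoch)) return(t(apply(epoch, 1, znormalize)))
  s <- sd(epoch)
  .assert(is.finite(s) && s > 0, "degenerate signal: constant epoch")
  (epoch - mean(epoch)) / s
}

#' @rdname znormalize
#' @param rec a [recording()]; every epoch of every channel is normalized.
#' @export
znormalize_recording <- function(rec) {
  rec$channels <- lapply(rec$channels, znormalize)
  rec
}

# ---- multitaper spectral estimation -------------------------------------

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed as the top eigenvectors of the canonical symmetric tridiagonal
#' matrix (LAPACK bisection + inverse iteration). Tapers are unit-energy;
#' polarity fixed so the mean (or for antisymmetric tapers the largest
#' element) is positive. Results are cached per (n, half-bandwidth) pair.
#'
#' @param n taper length in samples.
#' @param w normalized half-bandwidth in cycles/sample (W/fs).
#' @param k number of tapers.
#' @return n x k matrix of tapers.
#' @export
dpss_tapers <- function(n, w, k) {
  key <- sprintf("dpss_%d_%.8f_%d", n, w, k)
  if (!is.null(.infodyn_env[[key]])) return(.infodyn_env[[key]])
  vec <- .cpp_dpss_eigvec(n, w, k)
  for (j in seq_len(ncol(vec))) {
    v <- vec[, j] / sqrt(sum(vec[, j]^2))
    s <- sum(v)
    if (abs(s) < 1e-8) s <- v[which.max(abs(v))[1]]
    vec[, j] <- if (s < 0) -v else v
  }
  .infodyn_env[[key]] <- vec
  vec
}

#' Multitaper power spectral density of one epoch
#'
#' Slepian multitaper PSD with the given spectral smoothing; the taper
#' count follows the standard rule `K = max(1, floor(2 T W - 1))` with
#' `T` the epoch duration and `W` the smoothing half-bandwidth.
#'
#' @param epoch numeric vector.
#' @param fs sampling rate in Hz.
#' @param smoothing_hz spectral smoothing (half-bandwidth) in Hz.
#' @return List with `freq` (Hz) and `psd` (power per Hz, one-sided).
#' @export
multitaper_psd <- function(epoch, fs, smoothing_hz = 1) {
  n <- length(epoch)
  tw <- (n / fs) * smoothing_hz
  k <- max(1L, floor(2 * tw - 1))
  tap <- dpss_tapers(n, smoothing_hz / fs, k)
  nf <- floor(n / 2) + 1
  acc <- numeric(nf)
  for (j in seq_len(k)) {
    sp <- fft(tap[, j] * epoch)[seq_len(nf)]
    acc <- acc + (Mod(sp)^2) / fs
  }
  psd <- acc / k
  # one-sided: double interior bins
  if (n %% 2 == 0) psd[2:(nf - 1)] <- 2 * psd[2:(nf - 1)]
  else psd[2:nf] <- 2 * psd[2:nf]
  list(freq = (seq_len(nf) - 1) * fs / n, psd = psd)
}

#' Band power of an epoch
#'
#' Integrated multitaper PSD over a frequency band. Conventional bands:
#' delta 0.5-4, theta 4-8, alpha 8-12, beta 12-30, gamma 30-40 Hz.
#'
#' @param epoch numeric vector.
#' @param fs sampling rate in Hz.
#' @param band numeric `c(lo, hi)` in Hz.
#' @param smoothing_hz multitaper smoothing in Hz.
#' @export
band_power <- function(epoch, fs, band, smoothing_hz = 1) {
  .assert(length(band) == 2 && band[1] < band[2] && band[2] <= fs / 2,
          "band must lie within (0, fs/2]")
  sp <- multitaper_psd(epoch, fs, smoothing_hz)
  sel <- sp$freq >= band[1] & sp$freq <= band[2]
  df <- fs / length(epoch)
  sum(sp$psd[sel]) * df
}

#' Relative delta power of an epoch
#'
#' Fraction of total 0.5-50 Hz power that lies in the delta band
#' (0.5-4 Hz); used for epoch rejection in the awake condition.
#'
#' @inheritParams band_power
#' @export
relative_delta_power <- function(epoch, fs, smoothing_hz = 1) {
  .assert(fs >= 100, "fs must be at least 100 Hz")
  delta <- band_power(epoch, fs, c(0.5, 4), smoothing_hz)
  total <- band_power(epoch, fs, c(0.5, 50), smoothing_hz)
  if (total <= 0) return(0)
  min(1, delta / total)
}

#' Epoch rejection by relative delta power
#'
#' Flags epochs whose relative delta power exceeds the threshold (strictly
#' more than; a fraction exactly at the threshold is kept). Flags only;
#' sample values are never altered.
#'
#' @param epochs epoch x sample matrix.
#' @param fs sampling rate in Hz.
#' @param threshold rejection threshold on the delta fraction.
#' @return Data frame with `epoch_index`, `rejected`, `reason`,
#'   `relative_delta`.
#' @export
reject_by_delta <- function(epochs, fs, threshold = 0.30) {
  if (is.vector(epochs)) epochs <- matrix(epochs, nrow = 1)
  rd <- apply(epochs, 1, relative_delta_power, fs = fs)
  data.frame(epoch_index = seq_len(nrow(epochs)),
             rejected = rd > threshold,
             reason = ifelse(rd > threshold, "delta_power", ""),
             relative_delta = rd)
}

#' Epoch rejection by extreme amplitudes
#'
#' Artifact rejection hook standing in for manual inspection: an epoch is
#' flagged when any absolute z-scored sample exceeds `z_max`. The default
#' of 8 SD is a deliberately permissive, documented choice.
#'
#' @param epochs epoch x sample matrix.
#' @param z_max rejection threshold in epoch-level SD units.
#' @export
reject_by_amplitude <- function(epochs, z_max = 8) {
  if (is.vector(epochs)) epochs <- matrix(epochs, nrow = 1)
  z <- apply(epochs, 1, function(e) max(abs(e - mean(e)) / sd(e)))
  data.frame(epoch_index = seq_len(nrow(epochs)),
             rejected = z > z_max,
             reason = ifelse(z > z_max, "artifact", ""),
             max_abs_z = z)
}

#' Autocorrelation decay time (ACT)
#'
#' Smallest positive lag at which the autocorrelation coefficient of the
#' (z-normalized) epoch drops below `exp(-1)`.
#'
#' @param epoch numeric vector, non-constant.
#' @param max_lag largest lag searched (defaults to epoch length - 1).
#' @param on_no_decay `"error"` or `"na"` if the autocorrelation never
#'   decays below `exp(-1)` within `max_lag`.
#' @return Lag in samples.
#' @export
act <- function(epoch, max_lag = length(epoch) - 1,
                on_no_decay = c("error", "na")) {
  on_no_decay <- match.arg(on_no_decay)
  .assert(sd(epoch) > 0, "degenerate signal: constant epoch")
  ac <- acf(epoch, lag.max = max_lag, plot = FALSE)$acf[-1]
  hit <- which(ac < exp(-1))
  if (!length(hit)) {
    if (on_no_decay == "error")
      stop("autocorrelation never decays below exp(-1) within the epoch",
           call. = FALSE)
    return(NA_integer_)
  }
  hit[1]
}

# ---- Butterworth filtering ----------------------------------------------

#' Butterworth filter design (second-order sections)
#'
#' Bilinear-transform design of an analog Butterworth prototype; returns
#' the cascade of biquads used by [butter_bandpass()]. Verified against
#' reference implementations during development.
#'
#' @param order filter order of the analog prototype.
#' @param fs sampling rate in Hz.
#' @param lo,hi band edges in Hz (`lo = NULL` gives a low-pass at `hi`).
#' @return Matrix of second-order sections (rows: b0 b1 b2 a0 a1 a2).
#' @export
butter_design <- function(order, fs, lo, hi) {
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  proto <- exp(1i * pi * (2 * seq_len(order) + order - 1) / (2 * order))
  if (is.null(lo)) {            # low-pass
    wc <- warp(hi)
    poles <- proto * wc
    zeros <- complex(0)
    k <- wc^order
  } else {                       # band-pass
    w1 <- warp(lo); w2 <- warp(hi)
    w0 <- sqrt(w1 * w2); bw <- w2 - w1
    poles <- c(vapply(proto, function(p) {
      disc <- sqrt((p * bw)^2 - 4 * w0^2 + 0i)
      (p * bw + disc) / 2
    }, complex(1)), vapply(proto, function(p) {
      disc <- sqrt((p * bw)^2 - 4 * w0^2 + 0i)
      (p * bw - disc) / 2
    }, complex(1)))
    zeros <- rep(0 + 0i, order)
    k <- bw^order
  }
  # bilinear transform
  fs2 <- 2 * fs
  zd_p <- (fs2 + poles) / (fs2 - poles)
  zd_z <- (fs2 + zeros) / (fs2 - zeros)
  k_d <- k * Re(prod(fs2 - zeros) / prod(fs2 - poles))
  # remaining zeros at z = -1
  zd_z <- c(zd_z, rep(-1 + 0i, length(poles) - length(zeros)))
  # pair conjugate poles/zeros into biquads; order poles by radius
  pp <- zd_p[order(Mod(zd_p))]
  pp <- pp[Im(pp) >= 0]
  zz <- zd_z[Im(zd_z) >= 0 & abs(Im(zd_z)) > 1e-12]
  zz_real <- Re(zd_z[abs(Im(zd_z)) <= 1e-12])
  sos <- matrix(0, length(pp), 6)
  for (i in seq_along(pp)) {
    p <- pp[i]
    a <- if (abs(Im(p)) > 1e-12) c(1, -2 * Re(p), Mod(p)^2)
         else c(1, -Re(p), 0)
    if (length(zz) >= 1) {
      z <- zz[1]; zz <- zz[-1]
      b <- c(1, -2 * Re(z), Mod(z)^2)
    } else if (length(zz_real) >= 2) {
      z1 <- zz_real[1]; z2 <- zz_real[2]; zz_real <- zz_real[-(1:2)]
      b <- c(1, -(z1 + z2), z1 * z2)
    } else if (length(zz_real) == 1) {
      z1 <- zz_real[1]; zz_real <- numeric(0)
      b <- c(1, -z1, 0)
    } else b <- c(1, 0, 0)
    sos[i, ] <- c(b, a)
  }
  sos[1, 1:3] <- sos[1, 1:3] * k_d
  sos
}

#' Causal Butterworth band-pass filter
#'
#' One-pass (causal) filtering with a fourth-order Butterworth band-pass,
#' the preprocessing filter studied in the filtering simulation. Matrices
#' are filtered per epoch row.
#'
#' @param x numeric vector or epoch x sample matrix.
#' @param fs sampling rate in Hz.
#' @param lo,hi band edges in Hz, `0 < lo < hi < fs/2`.
#' @param order filter order (default 4).
#' @export
butter_bandpass <- function(x, fs, lo, hi, order = 4) {
  .assert(lo > 0 && lo < hi && hi < fs / 2,
          "band edges must satisfy 0 < lo < hi < fs/2")
  sos <- butter_design(order, fs, lo, hi)
  if (is.matrix(x)) t(apply(x, 1, .cpp_sosfilt, sos = sos))
  else .cpp_sosfilt(x, sos)
}

#' Resample a signal by an integer decimation factor
#'
#' Helper for sampling-rate sensitivity checks: low-pass filters at 80% of
#' the new Nyquist frequency (8th-order Butterworth) and keeps every m-th
#' sample. Only integer factors are supported.
#'
#' @param x numeric vector.
#' @param fs_from,fs_to old and new sampling rates; `fs_from / fs_to` must
#'   be a whole number.
#' @export
resample_signal <- function(x, fs_from, fs_to) {
  m <- fs_from / fs_to
  .assert(abs(m - round(m)) < 1e-9 && m >= 1, "only integer decimation")
  m <- round(m)
  if (m == 1) return(x)
  sos <- butter_design(8, fs_from, NULL, 0.8 * fs_to / 2)
  xf <- .cpp_sosfilt(x, sos)
  xf[seq(1, length(xf), by = m)]
}
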