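# Band-power features from windowed recordings: common-average
# re-referencing, Hamming-window periodogram band means, square-root
# high-gamma raw features, baseline compensation against session gain drift,
# channel-stability filtering and cross-repetition consistency maps.

#' Standard analysis bands
#'
#' Frequency bands in Hz: alpha 8-13, beta 13-30, low gamma 30-80, high
#' gamma 80-150.  Band edges are inclusive on both ends when averaging
#' periodogram bins; the DC bin is never included.
#'
#' @param name One of `"alpha"`, `"beta"`, `"low_gamma"`, `"high_gamma"`.
#' @return List with `name`, `lo`, `hi`.
#' @export
band_definition <- function(name = c("high_gamma", "alpha", "beta", "low_gamma")) {
  name <- match.arg(name)
  edges <- list(alpha = c(8, 13), beta = c(13, 30),
                low_gamma = c(30, 80), high_gamma = c(80, 150))[[name]]
  list(name = name, lo = edges[1], hi = edges[2])
}

#' Common-average re-referencing
#'
#' Subtracts, at every sample, the mean over a chosen subset of noise-free
#' channels from all retained channels.
#'
#' @param samples Channels x time numeric matrix (microvolts).
#' @param channel_subset Indices of the channels whose average is the
#'   reference (default: all).
#' @return Matrix of the same shape, re-referenced.
#' @export
rereference_common_average <- function(samples, channel_subset = seq_len(nrow(samples))) {
  if (length(channel_subset) == 0) stop_invalid("invalid argument: empty channel subset")
  ref <- colMeans(samples[channel_subset, , drop = FALSE])
  sweep(samples, 2, ref)
}

hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

# One-sided Hamming-window periodogram, density normalization (power/Hz).
periodogram_psd <- function(x, fs) {
  n <- length(x)
  w <- hamming_window(n)
  X <- stats::fft(x * w)
  n_half <- floor(n / 2) + 1
  psd <- (Mod(X[seq_len(n_half)])^2) / (fs * sum(w^2))
  scale <- rep(2, n_half)
  scale[1] <- 1
  if (n %% 2 == 0) scale[n_half] <- 1   # Nyquist bin not duplicated
  psd <- psd * scale
  freq <- (seq_len(n_half) - 1) * fs / n
  list(freq = freq, psd = psd)
}

#' Mean power spectral density within a band
#'
#' Hamming-windowed FFT periodogram of one 1-s single-channel window,
#' density-normalized (microvolts squared per Hz), averaged over the FFT
#' bins whose frequency lies inside the band (both edges inclusive, DC bin
#' excluded).  One periodogram per window; no segment averaging.
#'
#' @param window Numeric vector, one second of signal (`length = round(fs)`).
#' @param fs Sampling rate in Hz.
#' @param band A [band_definition()] (or list with `lo`, `hi`).
#' @return Mean PSD within the band.
#' @export
band_psd_mean <- function(window, fs, band = band_definition("high_gamma")) {
  if (band$hi >= fs / 2) stop_invalid("invalid config: band exceeds Nyquist frequency")
  if (band$lo <= 0) stop_invalid("invalid config: band must start above 0 Hz")
  pg <- periodogram_psd(window, fs)
  sel <- pg$freq >= band$lo & pg$freq <= band$hi & pg$freq > 0
  if (!any(sel)) stop_invalid("invalid config: no FFT bins inside band")
  mean(pg$psd[sel])
}

#' Raw high-gamma feature of one window
#'
#' Square root of the band-mean PSD in the high-gamma band; units
#' microvolts per root-Hz.
#'
#' @inheritParams band_psd_mean
#' @export
raw_feature <- function(window, fs, band = band_definition("high_gamma")) {
  sqrt(band_psd_mean(window, fs, band))
}

#' Compensation factor: resting baseline (ratio of sums)
#'
#' `comp = sum_i feature_i(baseline) / sum_i feature_i(baseline0)`, where
#' the baseline windows come from the current session's 30-s rest and
#' baseline0 from the rest recorded before the first training video.
#' Compensated features are `raw / comp`.  Inputs may be vectors (one
#' channel) or windows x channels matrices (per-channel factors returned).
#'
#' @param baseline,baseline0 Raw baseline features.
#' @return Compensation factor (scalar or per-channel vector).
#' @export
comp_resting <- function(baseline, baseline0) {
  baseline <- as.matrix(baseline); baseline0 <- as.matrix(baseline0)
  if (nrow(baseline) == 0 || nrow(baseline0) == 0)
    stop_invalid("baseline feature lists must be nonempty")
  denom <- colSums(baseline0)
  if (any(denom <= 0)) stop_invalid("degenerate baseline: zero baseline0 sum")
  drop(colSums(baseline) / denom)
}

#' Compensation factor: image-matched baseline (mean of ratios)
#'
#' `comp = mean_i(feature_i(baseline) / feature_i(baseline0))` over matched
#' image presentations (60 in the study protocol).
#'
#' @param baseline,baseline0 Raw baseline features, matched row-by-row by
#'   image (vectors or images x channels matrices).
#' @return Compensation factor (scalar or per-channel vector).
#' @export
comp_images <- function(baseline, baseline0) {
  baseline <- as.matrix(baseline); baseline0 <- as.matrix(baseline0)
  if (!all(dim(baseline) == dim(baseline0)))
    stop_invalid("baseline pairs must be matched by image")
  bad <- which(baseline0 <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_invalid("degenerate baseline: zero baseline0 feature at image %d", bad[1, 1])
  drop(colMeans(baseline / baseline0))
}

#' Apply a compensation factor to raw features
#'
#' @param features Windows x channels raw features.
#' @param comp Per-channel factors (or scalar).
#' @return Compensated features of the same shape.
#' @export
compensate_features <- function(features, comp) {
  if (any(comp <= 0)) stop_invalid("compensation factors must be > 0")
  sweep(as.matrix(features), 2, comp, `/`)
}

#' Channel stability filter
#'
#' A channel is discarded when the sample standard deviation of its
#' per-image baseline ratios `feature_i(baseline) / feature_i(baseline0)`
#' exceeds 0.5 in at least one video.
#'
#' @param ratio_list List with one element per video, each an
#'   images x channels matrix of baseline ratios.
#' @param threshold SD threshold (default 0.5).
#' @return Logical vector: `TRUE` for retained channels.
#' @export
channel_stability_filter <- function(ratio_list, threshold = 0.5) {
  if (!is.list(ratio_list)) ratio_list <- list(ratio_list)
  sds <- sapply(ratio_list, function(m) apply(as.matrix(m), 2, stats::sd))
  sds <- matrix(sds, ncol = length(ratio_list))
  apply(sds, 1, function(s) all(s <= threshold))
}

#' Fisher z-transform with clipping
#'
#' `atanh(r)` after clipping `|r|` at `1 - 1e-7` so that identical sequences
#' give a large finite value instead of infinity.
#'
#' @param r Correlation(s) in `[-1, 1]`.
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop_invalid("invalid argument: |r| > 1")
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' Inverse Fisher transform
#' @param z Numeric.
#' @return `tanh(z)`.
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Cross-repetition consistency map
#'
#' For each channel, the Pearson correlation of band powers over the
#' windows of every pair of stimulus repetitions, Fisher z-transformed and
#' averaged across all pairs.  A zero-variance repetition contributes z = 0
#' to its pairs (with a warning).
#'
#' @param powers 3-d array: repetitions x windows x channels.
#' @return Per-channel mean z (length = channels).
#' @export
consistency_map <- function(powers) {
  d <- dim(powers)
  if (is.null(d) || length(d) != 3) stop_invalid("powers must be reps x windows x channels")
  if (d[1] < 2) stop_invalid("need >= 2 repetitions")
  pairs <- utils::combn(d[1], 2)
  vapply(seq_len(d[3]), function(ch) {
    zs <- apply(pairs, 2, function(p) {
      a <- powers[p[1], , ch]; b <- powers[p[2], , ch]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        warning("zero-variance repetition: pair contributes z = 0")
        return(0)
      }
      fisher_z(stats::cor(a, b))
    })
    mean(zs)
  }, numeric(1))
}

#' Extract per-event compensated features from a recording
#'
#' Cuts a 1000-ms window around each event (by default centered on the
#' onset, i.e. -500 to +500 ms; `window_offset` shifts the window start
#' relative to the onset in seconds, e.g. 0, 0.5 or 1.0 for the imagery-task
#' windows), computes the raw high-gamma feature per channel and divides by
#' the per-channel compensation factor.
#'
#' @param samples Channels x time matrix.
#' @param fs Sampling rate (Hz).
#' @param onsets Event onset samples (1-based).
#' @param comp Per-channel compensation factors (default 1 = raw).
#' @param window_offset Start of the window relative to the onset in
#'   seconds; default -0.5 (centered window).
#' @param band Band definition (default high gamma).
#' @return Events x channels feature matrix.
#' @export
extract_scene_features <- function(samples, fs, onsets, comp = 1,
                                   window_offset = -0.5,
                                   band = band_definition("high_gamma")) {
  n_win <- round(fs)
  starts <- onsets + round(window_offset * fs)
  bad <- which(starts < 1 | starts + n_win - 1 > ncol(samples))
  if (length(bad) > 0)
    stop_invalid("event %d too close to the record edge", bad[1])
  feats <- t(vapply(starts, function(s0) {
    seg <- samples[, s0:(s0 + n_win - 1), drop = FALSE]
    apply(seg, 1, raw_feature, fs = fs, band = band)
  }, numeric(nrow(samples))))
  compensate_features(feats, rep(comp, length.out = nrow(samples)))
}

#' Simplified STFT spectrogram in dB relative to a baseline interval
#'
#' Plain short-time Fourier transform (Hamming window, fixed step), power
#' converted to dB relative to the mean power per frequency over a stated
#' baseline interval.  This is a simplified stand-in for wavelet-style
#' time-frequency decompositions; the dB-difference logic between
#' conditions is what the imagery analysis relies on.
#'
#' @param signal Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param window Window length in samples.
#' @param step Step in samples (> 0).
#' @param baseline Indices (in frames) of the baseline interval; default all
#'   frames.
#' @return List: `time` (frame centers, s), `freq` (Hz), `db`
#'   (frames x freq matrix).
#' @export
stft_spectrogram <- function(signal, fs, window = 256, step = 64,
                             baseline = NULL) {
  if (step <= 0) stop_invalid("invalid config: step must be > 0")
  if (window > length(signal)) stop_invalid("invalid config: window longer than signal")
  starts <- seq(1, length(signal) - window + 1, by = step)
  w <- hamming_window(window)
  n_half <- floor(window / 2) + 1
  pow <- t(vapply(starts, function(s0) {
    X <- stats::fft(signal[s0:(s0 + window - 1)] * w)
    Mod(X[seq_len(n_half)])^2
  }, numeric(n_half)))
  if (is.null(baseline)) baseline <- seq_len(nrow(pow))
  ref <- colMeans(pow[baseline, , drop = FALSE])
  ref[ref <= 0] <- .Machine$double.eps
  db <- 10 * log10(sweep(pow + .Machine$double.eps, 2, ref, `/`))
  list(time = (starts + window / 2 - 1) / fs,
       freq = (seq_len(n_half) - 1) * fs / window,
       db = db)
}
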