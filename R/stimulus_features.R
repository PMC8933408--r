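# Low-level stimulus features: spatiotemporal Gabor motion energy from
# 1-s luminance clips and modulation-transfer auditory features from 1-s
# audio, both at configurable scale.  Synthetic drifting gratings and
# AM tones are provided so the filters can be exercised without codecs.

#' Spatiotemporal Gabor filter bank for motion energy
#'
#' Quadrature Gabor pairs differing in motion direction, spatial frequency
#' and temporal frequency, positioned on a square grid spaced in units of
#' the spatial envelope SD.  The envelope SD is tied to the spatial
#' frequency (a fixed number of carrier cycles per SD), so the channel
#' count is a pure function of the configuration; zero-spatial-frequency
#' filters get a single direction and grid position (direction is undefined
#' at DC).  Spatial filters with nonzero frequency are made exactly
#' zero-mean so uniform frames produce zero energy.
#'
#' @param frame_size Square frame side in pixels (default 32).
#' @param fps Frames per second (default 15).
#' @param directions Motion directions in degrees (default 0, 45, ..., 315).
#' @param spatial_freqs Cycles per image (default 0, 1.5, 3, 6, 12, 24).
#' @param temporal_freqs Hz (default 0, 2, 4).
#' @param grid_spacing_sd Grid spacing in envelope SDs (default 4).
#' @param cycles_per_sd Carrier cycles per envelope SD (default 1).
#' @return Object of class `motion_energy_bank` with the channel table and
#'   precomputed spatial filter maps.
#' @export
motion_energy_bank <- function(frame_size = 32, fps = 15,
                               directions = seq(0, 315, by = 45),
                               spatial_freqs = c(0, 1.5, 3, 6, 12, 24),
                               temporal_freqs = c(0, 2, 4),
                               grid_spacing_sd = 4, cycles_per_sd = 1) {
  px <- (seq_len(frame_size) - 0.5) / frame_size
  coords <- expand.grid(x = px, y = px)
  spatial <- list()
  channels <- NULL
  for (sf in spatial_freqs) {
    if (sf == 0) {
      sd_frac <- 0.3
      pos <- data.frame(px = 0.5, py = 0.5)
      dirs <- 0
    } else {
      sd_frac <- cycles_per_sd / sf
      spacing <- grid_spacing_sd * sd_frac
      n_axis <- max(1L, as.integer(round(1 / spacing)))
      centers <- (seq_len(n_axis) - 0.5) / n_axis
      pos <- expand.grid(px = centers, py = centers)
      dirs <- directions
    }
    for (p in seq_len(nrow(pos))) {
      env <- exp(-((coords$x - pos$px[p])^2 + (coords$y - pos$py[p])^2) /
                   (2 * sd_frac^2))
      for (th in dirs) {
        rad <- th * pi / 180
        u <- cos(rad) * (coords$x - pos$px[p]) + sin(rad) * (coords$y - pos$py[p])
        if (sf == 0) {
          ev <- env; od <- rep(0, length(env))
        } else {
          ev <- env * cos(2 * pi * sf * u)
          od <- env * sin(2 * pi * sf * u)
          ev <- ev - mean(ev)
          od <- od - mean(od)
        }
        nrm <- sqrt(sum(ev^2) + sum(od^2))
        key <- length(spatial) + 1
        spatial[[key]] <- list(even = ev / nrm, odd = od / nrm)
        for (tf in temporal_freqs) {
          channels <- rbind(channels, data.frame(
            spatial_index = key, direction = th, spatial_freq = sf,
            temporal_freq = tf, px = pos$px[p], py = pos$py[p]))
        }
      }
    }
  }
  structure(list(frame_size = frame_size, fps = fps, channels = channels,
                 spatial = spatial, epsilon = 1e-8,
                 config = list(directions = directions,
                               spatial_freqs = spatial_freqs,
                               temporal_freqs = temporal_freqs,
                               grid_spacing_sd = grid_spacing_sd,
                               cycles_per_sd = cycles_per_sd)),
            class = "motion_energy_bank")
}

#' @export
print.motion_energy_bank <- function(x, ...) {
  cat(sprintf("Motion-energy bank: %d channels (%dx%d px, %g fps)\n",
              nrow(x$channels), x$frame_size, x$frame_size, x$fps))
  invisible(x)
}

#' Motion-energy features of a 1-s luminance clip
#'
#' Each frame is projected onto the even/odd spatial filter maps; the
#' resulting complex time series is demodulated at the channel's temporal
#' frequency and the squared magnitude of the coherent sum is the channel's
#' motion energy.  Energies are log-transformed (`log(x + 1e-8)`) and the
#' construction time-averages within the window by design.
#'
#' @param frames 3-d array `time x height x width` of luminance values, at
#'   the bank's frame size and rate.
#' @param bank A [motion_energy_bank()].
#' @return Numeric vector, one value per bank channel.
#' @export
motion_energy_features <- function(frames, bank) {
  d <- dim(frames)
  if (length(d) != 3 || d[2] != bank$frame_size || d[3] != bank$frame_size)
    stop_invalid("shape error: frames must be time x %d x %d",
                 bank$frame_size, bank$frame_size)
  n_t <- d[1]
  # flatten frames to T x pixels; pixel order must match the bank's maps
  # (expand.grid over x then y == column-major over a [x, y] grid)
  F_mat <- matrix(frames, n_t, d[2] * d[3])
  even_mat <- vapply(bank$spatial, `[[`, numeric(d[2] * d[3]), "even")
  odd_mat <- vapply(bank$spatial, `[[`, numeric(d[2] * d[3]), "odd")
  A_even <- F_mat %*% even_mat    # T x n_spatial
  A_odd <- F_mat %*% odd_mat
  t_sec <- (seq_len(n_t) - 1) / bank$fps
  vapply(seq_len(nrow(bank$channels)), function(ci) {
    ch <- bank$channels[ci, ]
    Fc <- complex(real = A_even[, ch$spatial_index],
                  imaginary = A_odd[, ch$spatial_index])
    demod <- exp(-2i * pi * ch$temporal_freq * t_sec)
    e <- Mod(sum(Fc * demod) / n_t)^2
    log(e + bank$epsilon)
  }, numeric(1))
}

#' Synthetic drifting grating clip
#'
#' @param bank A [motion_energy_bank()] (defines size and rate).
#' @param direction Degrees of motion.
#' @param spatial_freq Cycles per image.
#' @param temporal_freq Hz.
#' @param n_frames Number of frames (default one second).
#' @param contrast Peak amplitude around the 0.5 mean level.
#' @return `time x height x width` luminance array.
#' @export
make_drifting_grating <- function(bank, direction, spatial_freq, temporal_freq,
                                  n_frames = bank$fps, contrast = 0.5) {
  px <- (seq_len(bank$frame_size) - 0.5) / bank$frame_size
  coords <- expand.grid(x = px, y = px)
  rad <- direction * pi / 180
  u <- cos(rad) * coords$x + sin(rad) * coords$y
  out <- array(0, c(n_frames, bank$frame_size, bank$frame_size))
  for (t in seq_len(n_frames)) {
    ph <- 2 * pi * temporal_freq * (t - 1) / bank$fps
    out[t, , ] <- matrix(0.5 + contrast * cos(2 * pi * spatial_freq * u - ph),
                         bank$frame_size, bank$frame_size)
  }
  out
}

#' Auditory modulation-transfer filter bank
#'
#' A 128-band spectrogram (25-ms window, 10-ms step, bands log-spaced from
#' 20 Hz to 10 kHz) is filtered by 100 modulation-selective filters (10
#' spectral scales x 10 temporal rates, complex Gabors along the
#' log-frequency and time axes); log modulation energies are averaged over
#' time and pooled into 20 log-spaced output bands, giving exactly
#' 100 x 20 = 2000 features.
#'
#' @param n_bands Spectrogram bands (default 128).
#' @param win_s,step_s Spectrogram window and step in seconds
#'   (defaults 0.025 and 0.010).
#' @param f_lo,f_hi Band range in Hz (defaults 20 and 10000).
#' @param scales Spectral modulation scales in cycles/octave (default 10
#'   log-spaced in 0.25-8).
#' @param rates Temporal modulation rates in Hz (default 10 log-spaced in
#'   1-32).
#' @param n_out_bands Pooled output bands (default 20).
#' @return Object of class `auditory_mtf_bank`.
#' @export
auditory_mtf_bank <- function(n_bands = 128, win_s = 0.025, step_s = 0.010,
                              f_lo = 20, f_hi = 10000,
                              scales = exp(seq(log(0.25), log(8), length.out = 10)),
                              rates = exp(seq(log(1), log(32), length.out = 10)),
                              n_out_bands = 20) {
  structure(list(n_bands = n_bands, win_s = win_s, step_s = step_s,
                 f_lo = f_lo, f_hi = f_hi, scales = scales, rates = rates,
                 n_out_bands = n_out_bands, epsilon = 1e-8),
            class = "auditory_mtf_bank")
}

#' @export
print.auditory_mtf_bank <- function(x, ...) {
  cat(sprintf("Auditory MTF bank: %d bands, %d scales x %d rates -> %d features\n",
              x$n_bands, length(x$scales), length(x$rates),
              length(x$scales) * length(x$rates) * x$n_out_bands))
  invisible(x)
}

# Band spectrogram: bands x frames matrix of band powers.
band_spectrogram <- function(audio, fs, bank) {
  win <- round(bank$win_s * fs)
  step <- round(bank$step_s * fs)
  starts <- seq(1, length(audio) - win + 1, by = step)
  w <- hamming_window(win)
  n_half <- floor(win / 2) + 1
  freq <- (seq_len(n_half) - 1) * fs / win
  P <- vapply(starts, function(s0) {
    Mod(stats::fft(audio[s0:(s0 + win - 1)] * w)[seq_len(n_half)])^2
  }, numeric(n_half))           # bins x frames
  edges <- exp(seq(log(bank$f_lo), log(bank$f_hi), length.out = bank$n_bands + 1))
  S <- matrix(0, bank$n_bands, ncol(P))
  for (b in seq_len(bank$n_bands)) {
    sel <- which(freq >= edges[b] & freq < edges[b + 1])
    if (length(sel) == 0) sel <- which.min(abs(freq - sqrt(edges[b] * edges[b + 1])))
    S[b, ] <- colMeans(P[sel, , drop = FALSE])
  }
  S
}

# Toeplitz convolution matrix for a complex kernel centered at lag 0.
# Kernels are made zero-mean (band-pass): a modulation filter must not
# respond to the stationary mean of the spectrogram.
conv_matrix <- function(kernel_fun, n, sigma) {
  half <- min(n - 1, ceiling(3 * sigma))
  lags <- -half:half
  k <- kernel_fun(lags)
  k <- k - mean(k)
  M <- matrix(0 + 0i, n, n)
  for (i in seq_len(n)) {
    j <- i + lags
    ok <- j >= 1 & j <= n
    M[i, j[ok]] <- k[ok]
  }
  M
}

#' Auditory modulation-transfer features of a 1-s waveform
#'
#' @param audio Mono waveform.
#' @param fs Sampling rate; must be at least twice the bank's upper band
#'   edge.
#' @param bank An [auditory_mtf_bank()].
#' @return Numeric vector of length `scales x rates x n_out_bands`
#'   (2000 at defaults), ordered band-fastest within rate within scale.
#' @export
auditory_mtf_features <- function(audio, fs, bank = auditory_mtf_bank()) {
  if (fs < 2 * bank$f_hi)
    stop_invalid("invalid config: fs must be >= %g Hz", 2 * bank$f_hi)
  S <- band_spectrogram(audio, fs, bank)
  # modulation filters measure fluctuation about the stationary band level;
  # remove each band's temporal mean so truncated kernels at the window
  # edges cannot respond to it
  S <- S - rowMeans(S)
  n_ch <- nrow(S); n_fr <- ncol(S)
  oct_per_ch <- log2(bank$f_hi / bank$f_lo) / bank$n_bands
  dt <- bank$step_s
  pool <- split(seq_len(n_ch),
                ceiling(seq_len(n_ch) / (n_ch / bank$n_out_bands)))
  out <- numeric(0)
  for (sc in bank$scales) {
    sigma_s <- 1 / (sc * oct_per_ch)
    Ks <- conv_matrix(function(l) exp(-l^2 / (2 * sigma_s^2)) *
                        exp(2i * pi * sc * l * oct_per_ch), n_ch, sigma_s)
    SK <- Ks %*% S
    for (rt in bank$rates) {
      sigma_t <- 1 / (rt * dt)
      Kt <- conv_matrix(function(l) exp(-l^2 / (2 * sigma_t^2)) *
                          exp(2i * pi * rt * l * dt), n_fr, sigma_t)
      E <- Mod(SK %*% t(Kt))^2
      logE <- log(E + bank$epsilon)
      band_means <- vapply(pool, function(ix) mean(logE[ix, ]), numeric(1))
      out <- c(out, band_means)
    }
  }
  unname(out)
}

#' Synthetic amplitude-modulated tone
#'
#' @param fs Sampling rate (Hz).
#' @param carrier Carrier frequency (Hz).
#' @param rate Modulation rate (Hz).
#' @param dur Duration in seconds (default 1).
#' @param depth Modulation depth in `[0, 1]`.
#' @return Waveform vector.
#' @export
make_am_tone <- function(fs, carrier, rate, dur = 1, depth = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  (1 + depth * sin(2 * pi * rate * t)) * sin(2 * pi * carrier * t)
}

#' Luminance (CIE L*) from sRGB frames
#'
#' Standard sRGB linearization followed by the CIE L* transform (D65 white
#' point).  Out-of-range inputs are clipped to `[0, 1]` with a warning.
#'
#' @param frames Array with the last dimension of size 3 (RGB in `[0, 1]`),
#'   or an `n x 3` matrix.
#' @return Array of L* values in `[0, 100]` with the RGB dimension dropped.
#' @export
rgb_to_lab_luminance <- function(frames) {
  d <- dim(frames) %||% c(length(frames) / 3, 3)
  if (d[length(d)] != 3) stop_invalid("last dimension must be RGB")
  v <- as.numeric(frames)
  if (any(v < 0 | v > 1)) {
    warning("RGB values outside [0, 1] clipped")
    v <- pmin(pmax(v, 0), 1)
  }
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  m <- matrix(lin, ncol = 3)
  Y <- m %*% c(0.2126729, 0.7151522, 0.0721750)   # sRGB D65 luminance row
  fy <- ifelse(Y > (6 / 29)^3, Y^(1 / 3), Y / (3 * (6 / 29)^2) + 4 / 29)
  L <- 116 * fy - 16
  if (length(d) > 2) array(L, d[-length(d)]) else drop(L)
}
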