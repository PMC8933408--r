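# Band-power features: re-referencing, periodogram band means, raw
# features, compensation factors, stability filter, consistency map,
# event-window extraction and the STFT spectrogram.

# independent periodogram oracle: explicit DFT loops, no fft()
direct_dft_psd <- function(x, fs) {
  n <- length(x)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  xw <- x * w
  n_half <- floor(n / 2) + 1
  psd <- numeric(n_half)
  for (k in seq_len(n_half)) {
    re <- sum(xw * cos(-2 * pi * (k - 1) * (0:(n - 1)) / n))
    im <- sum(xw * sin(-2 * pi * (k - 1) * (0:(n - 1)) / n))
    psd[k] <- (re^2 + im^2) / (fs * sum(w^2))
  }
  scale <- rep(2, n_half); scale[1] <- 1
  if (n %% 2 == 0) scale[n_half] <- 1
  list(freq = (seq_len(n_half) - 1) * fs / n, psd = psd * scale)
}

test_that("common-average re-referencing zeroes the reference subset mean", {
  one <- matrix(rnorm(100), 1)
  expect_equal(rereference_common_average(one, 1), one * 0)
  two <- rbind(a = rnorm(50), b = 0)
  two[2, ] <- two[1, ]
  expect_equal(rereference_common_average(two, 1:2), two * 0)
  five <- matrix(rnorm(5 * 200), 5)
  rr <- rereference_common_average(five, c(1, 3, 5))
  expect_lt(max(abs(colMeans(rr[c(1, 3, 5), ]))), 1e-10)
  expect_error(rereference_common_average(five, integer(0)), "empty")
})

test_that("band PSD mean matches a direct-DFT oracle and scales quadratically", {
  fs <- 1000
  t <- (0:999) / fs
  x <- sin(2 * pi * 100 * t)
  hg <- band_psd_mean(x, fs, band_definition("high_gamma"))
  al <- band_psd_mean(x, fs, band_definition("alpha"))
  expect_gt(hg / al, 1e3)
  # oracle comparison on a composite signal
  set.seed(3)
  y <- sin(2 * pi * 90 * t) + 0.3 * rnorm(1000)
  or <- direct_dft_psd(y, fs)
  for (b in c("alpha", "high_gamma")) {
    bd <- band_definition(b)
    sel <- or$freq >= bd$lo & or$freq <= bd$hi & or$freq > 0
    expect_equal(band_psd_mean(y, fs, bd), mean(or$psd[sel]), tolerance = 1e-8)
  }
  expect_equal(band_psd_mean(rep(0, 1000), fs), 0)
  expect_equal(band_psd_mean(3 * y, fs), 9 * band_psd_mean(y, fs),
               tolerance = 1e-10)
  expect_error(band_psd_mean(y, fs, list(lo = 80, hi = 600)), "Nyquist")
})

test_that("one-sided PSD satisfies the Parseval-style normalization", {
  set.seed(4)
  fs <- 500
  x <- rnorm(500)
  pg <- semdecode:::periodogram_psd(x, fs)
  w <- semdecode:::hamming_window(500)
  df <- fs / 500
  expect_equal(sum(pg$psd) * df, sum((w * x)^2) / sum(w^2), tolerance = 1e-6)
})

test_that("raw feature is the square root of the band mean and matches the flat-spectrum value", {
  fs <- 1000
  set.seed(5)
  x <- rnorm(1000)
  expect_equal(raw_feature(x, fs), sqrt(band_psd_mean(x, fs)))
  expect_equal(raw_feature(rep(0, 1000), fs), 0)
  expect_equal(raw_feature(-2 * x, fs), 2 * raw_feature(x, fs), tolerance = 1e-10)
  # white noise, unit variance: one-sided density 2 sigma^2 / fs
  feats <- replicate(1000, raw_feature(rnorm(1000), fs))
  analytic <- sqrt(2 / fs)
  se <- sd(feats) / sqrt(length(feats))
  expect_lt(abs(mean(feats) - analytic), 3 * se + 1e-4)
})

test_that("compensation factors match their defining formulas", {
  expect_equal(comp_resting(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(comp_resting(2 * c(1, 2, 3), c(1, 2, 3)), 2)
  expect_equal(comp_resting(c(1, 2, 3), c(2, 2, 2)), 1)    # 6/6
  expect_error(comp_resting(c(1, 2), c(0, 0)), "degenerate")
  expect_equal(comp_images(c(1, 1), c(1, 1)), 1)
  expect_equal(comp_images(c(1, 3), c(1, 1)), 2)            # mean of 1 and 3
  set.seed(6)
  a <- matrix(runif(60 * 3, 0.5, 2), 60); b <- matrix(runif(60 * 3, 0.5, 2), 60)
  oracle <- sapply(1:3, function(e) {
    acc <- 0
    for (i in 1:60) acc <- acc + a[i, e] / b[i, e]
    acc / 60
  })
  expect_equal(unname(comp_images(a, b)), oracle, tolerance = 1e-12)
  expect_error(comp_images(c(1, 2), c(1, 0)), "image 2")
})

test_that("stability filter discards channels with ratio SD > 0.5 in any video", {
  const <- matrix(1, 60, 1)
  expect_true(channel_stability_filter(list(const)))
  alt <- matrix(rep(c(0, 2), 30), ncol = 1)
  expect_equal(sd(alt), sqrt(60 / 59), tolerance = 1e-6)   # ~1.008 by hand
  expect_false(channel_stability_filter(list(alt)))
  # stable in video 1, SD 0.6 in video 2: discarded
  v2 <- matrix(rnorm(60, 1, 0.6), ncol = 1)
  v2 <- (v2 - mean(v2)) / sd(v2) * 0.6 + 1
  expect_false(channel_stability_filter(list(const, v2)))
  expect_true(channel_stability_filter(list(const, const)))
})

test_that("consistency map averages Fisher-z over all repetition pairs", {
  set.seed(7)
  reps <- 4; wins <- 150
  arr <- array(rnorm(reps * wins * 2), c(reps, wins, 2))
  cm <- consistency_map(arr)
  # oracle: explicit C(4,2) = 6 pair loop
  oracle <- sapply(1:2, function(ch) {
    zs <- c()
    for (i in 1:3) for (j in (i + 1):4)
      zs <- c(zs, atanh(min(max(cor(arr[i, , ch], arr[j, , ch]),
                                -(1 - 1e-7)), 1 - 1e-7)))
    mean(zs)
  })
  expect_equal(cm, oracle, tolerance = 1e-12)
  # symmetric in repetition order
  expect_equal(consistency_map(arr[4:1, , , drop = FALSE]), cm)
  # identical repetitions: clipped finite maximum
  same <- array(rep(rnorm(wins), each = reps), c(reps, wins, 1))
  expect_equal(consistency_map(same), atanh(1 - 1e-7))
  # independent noise: per-channel z near 0
  big <- array(rnorm(4 * 150 * 100), c(4, 150, 100))
  expect_lt(mean(abs(consistency_map(big))), 0.2)
})

test_that("event-window extraction finds a high-gamma burst and honors offsets", {
  fs <- 500
  n <- 6 * fs
  set.seed(8)
  sig <- matrix(rnorm(2 * n, sd = 0.1), 2)
  onsets <- c(1 * fs, 3 * fs, 5 * fs) + 1
  # 120-Hz burst around the second event on channel 2
  tt <- (0:(fs - 1)) / fs
  burst_idx <- (onsets[2] - fs / 2):(onsets[2] + fs / 2 - 1)
  sig[2, burst_idx] <- sig[2, burst_idx] + 5 * sin(2 * pi * 120 * tt)
  f <- extract_scene_features(sig, fs, onsets)
  expect_equal(which.max(f[, 2]), 2L)
  # comp = 1 leaves raw features untouched
  expect_equal(f, extract_scene_features(sig, fs, onsets, comp = c(1, 1)))
  expect_equal(extract_scene_features(sig, fs, onsets, comp = c(2, 4)),
               sweep(f, 2, c(2, 4), `/`), tolerance = 1e-12)
  # offset windows: burst placed 1-2 s after an event is seen at offset 1.0
  sig2 <- matrix(rnorm(n, sd = 0.1), 1)
  ev <- fs + 1
  idx2 <- (ev + fs):(ev + 2 * fs - 1)
  sig2[1, idx2] <- sig2[1, idx2] + 5 * sin(2 * pi * 120 * tt)
  f0 <- extract_scene_features(sig2, fs, ev, window_offset = 0)
  f1 <- extract_scene_features(sig2, fs, ev, window_offset = 1)
  expect_gt(f1[1, 1] / f0[1, 1], 5)
  expect_error(extract_scene_features(sig, fs, 10), "edge")
})

test_that("STFT spectrogram shows stationary ridges and monotone chirp tracks", {
  fs <- 1000
  t <- (0:(4 * fs - 1)) / fs
  set.seed(9)
  tone <- c(rnorm(fs, sd = 1e-3), sin(2 * pi * 50 * t) + rnorm(length(t), sd = 1e-3))
  sp <- stft_spectrogram(tone, fs, window = 256, step = 128,
                         baseline = which((seq(1, length(tone) - 255, 128) + 128) / fs < 0.9))
  on_frames <- sp$time > 1.3
  ridge <- sp$freq[apply(sp$db[on_frames, ], 1, which.max)]
  expect_true(all(abs(ridge - 50) < fs / 256 + 1e-9))
  # silence: uniform floor (zero dB everywhere relative to itself)
  spz <- stft_spectrogram(rep(0, 2000), fs, window = 256, step = 128)
  expect_equal(max(abs(spz$db)), 0)
  # linear chirp: ridge frequency nondecreasing, near instantaneous frequency
  f0 <- 20; k <- 50
  chirp <- sin(2 * pi * (f0 * t + k * t^2 / 2))
  spc <- stft_spectrogram(chirp, fs, window = 256, step = 128)
  ridge_c <- spc$freq[apply(spc$db, 1, which.max)]
  inst <- f0 + k * spc$time
  expect_true(all(diff(ridge_c) > -2 * fs / 256))
  expect_lt(mean(abs(ridge_c - inst)), 2 * fs / 256)
  expect_error(stft_spectrogram(tone, fs, window = 256, step = 0), "step")
})
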