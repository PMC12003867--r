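test_that("amplitude masking uses strict +/-1500 uV bounds", {
  x <- c(-1501, -1500, -10, 0, 1499, 1500, 1501)
  y <- mask_amplitude(x)
  expect_identical(is.na(y), c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                               TRUE))
  expect_identical(y[!is.na(y)], x[c(2:6)])
  z <- matrix(0, 10, 10)
  expect_identical(mask_amplitude(z), z)
})

test_that("raising the mask bound never increases the NaN count", {
  set.seed(1)
  x <- rnorm(2000, sd = 900)
  counts <- vapply(seq(500, 3000, by = 250),
                   function(b) sum(is.na(mask_amplitude(x, b))), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("band-pass preserves in-band amplitude and removes DC", {
  t <- seq_len(3000) / 10
  x <- 100 * sin(2 * pi * 15 / 60 * t)
  y <- bandlimit_filter(x, 10)
  expect_lt(abs(max(abs(y[1000:2000])) / 100 - 1), 0.05)
  dc <- bandlimit_filter(rep(500, 3000), 10)
  expect_lt(max(abs(dc[1000:2000])), 5)          # < 1% of the 500 uV offset
  expect_equal(bandlimit_filter(rep(0, 3000), 10), rep(0, 3000))
  # NaN positions preserved
  x[100:110] <- NA
  expect_identical(is.na(bandlimit_filter(x, 10)), is.na(x))
})

test_that("dominant frequency recovers pure tones within a bin", {
  for (f in c(4, 11, 15, 27)) {
    x <- sin(2 * pi * f / 60 * seq_len(3000) / 10)
    sp <- compute_dominant_frequency(x, 10)
    expect_lt(abs(sp$DF - f), 0.3)
  }
  expect_true(is.na(compute_dominant_frequency(rep(1, 3000), 10)$DF))
  expect_true(is.na(compute_dominant_frequency(rep(NA_real_, 100), 10)$DF))
})

test_that("white-noise DF equals the periodogram argmax", {
  set.seed(42)
  x <- rnorm(3000)
  sp <- compute_dominant_frequency(x, 10)
  inband <- sp$freq_cpm >= 1 & sp$freq_cpm <= 60
  brute <- sp$freq_cpm[inband][which.max(sp$power[inband])]
  expect_lt(abs(sp$DF - brute), 0.3)   # within the interpolation refinement
})

test_that("DF channel filter applies the tissue thresholds", {
  dfs <- c(3.99, 4, 10.99, 11, 25, NA)
  expect_identical(filter_channels_by_df(dfs, 2L),
                   c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE))  # intestine
  expect_identical(filter_channels_by_df(dfs, 1L),
                   c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE))    # stomach
  expect_identical(filter_channels_by_df(dfs, 3L),
                   filter_channels_by_df(dfs, 4L))
})

test_that("stability is the band-power ratio", {
  f <- seq(0, 60, by = 0.1)
  # all power within [DF-1, DF+1]
  p <- as.numeric(abs(f - 15) <= 1)
  expect_equal(channel_stability(p, f, 15), 1)
  # uniform power over [2, 40]: ratio of band widths
  pu <- as.numeric(f >= 2 & f <= 40)
  expect_equal(channel_stability(pu, f, 15), 21 / 381, tolerance = 0.01)
  # brute-force oracle on random spectra
  set.seed(9)
  for (i in 1:5) {
    pr <- runif(length(f))
    df <- runif(1, 5, 30)
    num <- 0; den <- 0
    for (j in seq_along(f)) {
      if (f[j] >= df - 1 && f[j] <= df + 1) num <- num + pr[j]
      if (f[j] >= 2 && f[j] <= 40) den <- den + pr[j]
    }
    expect_equal(channel_stability(pr, f, df), num / den)
  }
  expect_equal(channel_stability(rep(0, length(f)), f, 15), 0)
})

test_that("reference amplitudes recover sinusoid extrema", {
  t <- seq_len(3000) / 10
  A <- 120
  x <- A * sin(2 * pi * 12 / 60 * t)
  base <- rbind(x, x, x)
  ref <- compute_reference_amplitudes(base, 10, rep(12, 3), c(3, 2, 1),
                                      rep(TRUE, 3))
  expect_equal(ref$avg_peak, A, tolerance = 0.02)
  expect_equal(ref$avg_trough, -A, tolerance = 0.02)
  expect_identical(ref$source_channels, c(1L, 2L, 3L))
  # three identical channels equal one channel
  expect_warning(
    ref1 <- compute_reference_amplitudes(rbind(x), 10, 12, 1, TRUE),
    "fewer than 3")
  expect_equal(ref$avg_peak, ref1$avg_peak)
  expect_error(compute_reference_amplitudes(base, 10, rep(12, 3),
                                            rep(1, 3), rep(FALSE, 3)))
})

test_that("stability ranking picks the three most stable channels", {
  t <- seq_len(2000) / 10
  x <- sin(2 * pi * 12 / 60 * t)
  base <- do.call(rbind, rep(list(x), 6))
  stab <- c(0.2, 0.9, 0.5, 0.9, 0.1, 0.7)
  ref <- compute_reference_amplitudes(base, 10, rep(12, 6), stab,
                                      rep(TRUE, 6))
  ord <- order(-stab, seq_along(stab))[1:3]    # brute-force sort, ties by index
  expect_identical(ref$source_channels, as.integer(ord))
})

test_that("normalization maps the 110% reference endpoints to 0 and 1", {
  ref <- list(avg_peak = 200, avg_trough = -100)
  expect_equal(normalize_signal(200 * 1.1, ref), 1)
  expect_equal(normalize_signal(-100 * 1.1, ref), 0)
  expect_equal(normalize_signal((200 * 1.1 + -100 * 1.1) / 2, ref), 0.5)
  expect_true(is.na(normalize_signal(NA_real_, ref)))
  expect_error(normalize_signal(0, list(avg_peak = 1, avg_trough = 1)))
})

test_that("augmentation averages passing 4-neighbours", {
  layout <- array_layout()
  sig <- matrix(rnorm(60 * 50), 60, 50)
  # channel at (2,2) has neighbours (1,2), (3,2), (2,1), (2,3)
  target <- layout$channel[layout$row == 2 & layout$col == 2]
  nbs <- layout$channel[(layout$row == 1 & layout$col == 2) |
                        (layout$row == 3 & layout$col == 2) |
                        (layout$row == 2 & layout$col == 1) |
                        (layout$row == 2 & layout$col == 3)]
  # identical neighbours: replacement equals their shared trace
  sig[nbs, ] <- rep(sig[nbs[1], ], each = length(nbs))
  pass <- rep(TRUE, 60); pass[target] <- FALSE
  aug <- augment_channels(sig, pass, layout)
  expect_equal(aug$signal[target, ], sig[nbs[1], ])
  expect_identical(aug$augmented, target)
  # two passing neighbours: brute-force mean
  pass2 <- pass; pass2[nbs[1:2]] <- FALSE
  sig2 <- matrix(rnorm(60 * 50), 60, 50)
  aug2 <- augment_channels(sig2, pass2, layout)
  good <- setdiff(nbs, nbs[1:2])
  expect_equal(aug2$signal[target, ], colMeans(sig2[good, ]))
  # no failed channels: unchanged, empty set
  aug3 <- augment_channels(sig2, rep(TRUE, 60), layout)
  expect_identical(aug3$signal, sig2)
  expect_length(aug3$augmented, 0)
})

test_that("decimation keeps length, DC and slow-wave amplitude", {
  x <- 100 * sin(2 * pi * 15 / 60 * seq_len(720000) / 1000)
  y <- downsample(x, 100)
  expect_length(y, 7200)
  expect_lt(abs(max(abs(y[2000:5000])) / 100 - 1), 0.02)
  expect_equal(downsample(rep(3.5, 500), 100), rep(3.5, 5))
  # NaN support propagation
  m <- rep(FALSE, 1000); m[150:260] <- TRUE
  md <- decimate_nan_mask(m, 100)
  expect_identical(md, c(FALSE, TRUE, TRUE, rep(FALSE, 7)))
})

test_that("window extraction matches brute-force slicing", {
  sf <- 10
  sig <- matrix(rnorm(60 * 7200), 60, 7200)
  b <- extract_window(sig, sf, c(50, 250))
  expect_equal(dim(b), c(2000, 60))
  expect_identical(b, t(sig[, 501:2500]))
  # signal equal to its own time index: first baseline row is t = 50 s
  tsig <- matrix(rep((0:7199) / sf, each = 60), 60, 7200, byrow = FALSE)
  tb <- extract_window(tsig, sf, c(50, 250))
  expect_equal(unique(tb[1, ]), 50)
  expect_error(extract_window(sig, sf, c(700, 721)), "too short")
})

test_that("interference is the elementwise sum", {
  B <- matrix(rnorm(200), 20, 10)
  P <- matrix(rnorm(200), 20, 10)
  I <- make_interference(B, P)
  expect_equal(unclass(I), B + P, ignore_attr = TRUE)
  expect_equal(as.numeric(make_interference(B, -B)), rep(0, 200))
  z <- matrix(0, 20, 10)
  expect_equal(as.numeric(make_interference(z, z)), rep(0, 200))
  expect_error(make_interference(B, matrix(0, 5, 5)), "dimension")
})

test_that("missing-value exclusion is strict at 1.6%", {
  expect_true(retain_dataset(0.016, 0.016))
  expect_false(retain_dataset(0.0161, 0.001))
  expect_false(retain_dataset(0.001, 0.02))
  expect_true(retain_dataset(0, 0))
})

test_that("preprocessing yields 2000 x 60 matrices with conservation", {
  m <- fx_matched()$matched
  expect_equal(dim(m$baseline), c(2000, 60))
  expect_equal(dim(m$postdrug), c(2000, 60))
  expect_equal(dim(m$interference), c(2000, 60))
  expect_equal(unclass(m$interference), m$baseline + m$postdrug,
               ignore_attr = TRUE)
  expect_equal(mean(is.na(m$baseline)), m$nan_frac_baseline)
  expect_equal(mean(is.na(m$postdrug)), m$nan_frac_postdrug)
})

test_that("time-shifted windows are offset by exactly +/-10 s", {
  p <- preprocess_params()
  expect_equal(p$windows$forward - p$windows$postdrug, c(-10, -10))
  expect_equal(p$windows$backward - p$windows$postdrug, c(10, 10))
  # a shifted interference differs from the unshifted one on real signal
  m <- fx_matched()$matched
  expect_gt(mean(unclass(m$forward) != unclass(m$interference),
                 na.rm = TRUE), 0.5)
  expect_gt(mean(unclass(m$backward) != unclass(m$interference),
                 na.rm = TRUE), 0.5)
})

test_that("preprocessing is deterministic", {
  fx <- fx_matched()
  m2 <- preprocess_recording(fx$rec)
  expect_identical(fx$matched$baseline, m2$baseline)
  expect_identical(fx$matched$interference, m2$interference)
})

test_that("clean synthetic channels pass the DF filter, dead ones fail", {
  fx <- fx_clean_rec()
  m <- preprocess_recording(fx$rec)
  expect_true(all(m$report$pass))
  expect_equal(m$nan_frac_baseline, 0)
  expect_true(m$retained)
})
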