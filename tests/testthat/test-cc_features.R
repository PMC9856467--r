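test_that("the zero-phase band-pass keeps in-band amplitude and timing", {
  fs <- 1000
  t <- (0:(4 * fs - 1)) / fs
  band <- c(100, 200)
  fc <- sqrt(band[1] * band[2])                 # geometric center
  x <- sin(2 * pi * fc * t)
  y <- bandpass_zero_phase(x, fs, band)
  mid <- 1000:3000                              # avoid end transients
  expect_lt(abs(max(abs(y[mid])) / 1 - 1), 0.05)
  v <- max_cc(x[mid][1:400], y[mid][1:400], 50)
  expect_equal(attr(v, "lag"), 0L)

  x2 <- sin(2 * pi * 2 * band[2] * t)           # stopband at 2*f_hi
  y2 <- bandpass_zero_phase(x2, fs, band)
  expect_lt(max(abs(y2[mid])), 0.1)

  pulse <- exp(-((0:1000) - 500)^2 / 50)        # symmetric pulse, odd length
  yp <- bandpass_zero_phase(pulse, fs, band)
  expect_equal(yp, rev(yp), tolerance = 1e-6)
  expect_error(bandpass_zero_phase(x, fs, c(200, 100)), "band")
})

test_that("max_cc matches identities and the brute-force oracle", {
  set.seed(20)
  x <- rnorm(400)
  expect_equal(as.numeric(max_cc(x, x, 50)), 1, tolerance = 1e-12)
  expect_equal(as.numeric(max_cc(x, 3 * x, 50)), 1, tolerance = 1e-12)
  expect_equal(as.numeric(max_cc(rep(0, 100), rnorm(100), 10)), 0)

  # known shift: maximum at lag 5 with the (N-5)/N zero-padding ratio
  y <- c(rep(0, 5), x[1:395])
  v <- max_cc(x, y, 50)
  expect_equal(attr(v, "lag"), 5L)

  for (k in 1:200) {
    n <- sample(20:60, 1)
    L <- sample(0:(n - 1), 1)
    a <- rnorm(n); b <- rnorm(n)
    got <- max_cc(a, b, L)
    ora <- oracle_max_cc(a, b, L)
    expect_equal(as.numeric(got), as.numeric(ora), tolerance = 1e-9)
    expect_equal(attr(got, "lag"), as.integer(attr(ora, "lag")))
  }
})

test_that("cc_curves shares the MSC grid and matches per-window max_cc", {
  set.seed(21)
  rec <- recording(matrix(rnorm(3 * 3000), ncol = 3), 1000)
  feats <- cc_curves(rec, rbind(c(1, 2), c(1, 3)))
  m <- build_msc_map(rec$data[, 1], rec$data[, 2], 1000)
  expect_equal(ncol(feats$per_pair_cc), ncol(m$values))
  expect_equal(feats$times, m$times)
  expect_true(all(abs(feats$per_pair_cc) <= 1 + 1e-9))
  # consistency with the scalar operation (no band: raw channels)
  for (k in c(1, 7, 14)) {
    i0 <- 1 + (k - 1) * 200
    ref <- max_cc(rec$data[i0:(i0 + 399), 1], rec$data[i0:(i0 + 399), 2], 50)
    expect_equal(unname(feats$per_pair_cc[1, k]), as.numeric(ref),
                 tolerance = 1e-9)
  }
  expect_lt(mean(feats$per_pair_cc), 0.3)       # independent channels
})

test_that("identical channels give cc curves pinned at 1", {
  x <- rnorm(2000)
  rec <- recording(cbind(x, x), 1000, channel_labels = c("a", "b"))
  feats <- cc_curves(rec, rbind(c(1, 2)))
  expect_equal(as.numeric(feats$per_pair_cc), rep(1, ncol(feats$per_pair_cc)),
               tolerance = 1e-9)
})

test_that("avg and std aggregate selected and background pairs", {
  sel <- rbind(c(1, 2), c(1, 3))
  bg <- rbind(c(2, 4), c(3, 4))
  per <- matrix(c(1, 1, 0, 0), nrow = 4, ncol = 6,
                dimnames = list(c("1-2", "1-3", "2-4", "3-4"), NULL))
  feats <- structure(list(times = 0.2 * (1:6), per_pair_cc = per,
                          pairs = mscdetect:::as_pair_matrix(rbind(sel, bg)),
                          duration_s = 1.4, avg = NULL, std = NULL),
                     class = "cc_features")
  out <- avg_std(feats, sel, bg)
  expect_equal(out$avg, rep(1, 6), ignore_attr = TRUE)
  expect_equal(out$std, rep(0.5, 6), ignore_attr = TRUE)  # pop sd of 1,1,0,0

  # permutation invariance
  out2 <- avg_std(feats, sel[2:1, ], bg[2:1, ])
  expect_equal(out2$avg, out$avg)
  expect_equal(out2$std, out$std)

  per2 <- per; per2[] <- 0.42
  feats$per_pair_cc <- per2
  out3 <- avg_std(feats, sel, bg)
  expect_equal(out3$avg, rep(0.42, 6), ignore_attr = TRUE)
  expect_equal(out3$std, rep(0, 6), ignore_attr = TRUE)
  expect_error(avg_std(feats, sel[0, , drop = FALSE], bg), "empty")
  expect_error(avg_std(feats, rbind(c(1, 9)), bg), "lacks rows")
})

test_that("the biased cross-correlation and cross-spectrum are a DFT pair", {
  set.seed(22)
  for (k in 1:10) {
    N <- 400
    x <- rnorm(N); y <- rnorm(N)
    # full biased cross-correlation sequence on the circular FFT grid
    nfft <- 1024
    lags_pos <- 0:(N - 1)
    r <- vapply(lags_pos, function(n) sum(x[1:(N - n)] * y[(1 + n):N]) / N,
                numeric(1))
    r_neg <- vapply(1:(N - 1), function(n) sum(x[(1 + n):N] * y[1:(N - n)]) / N,
                    numeric(1))
    seq_full <- c(r, rep(0, nfft - (2 * N - 1)), rev(r_neg))
    lhs <- stats::fft(seq_full)
    X <- stats::fft(c(x, rep(0, nfft - N)))
    Y <- stats::fft(c(y, rep(0, nfft - N)))
    rhs <- Conj(X) * Y / N
    expect_equal(lhs, rhs, tolerance = 1e-6)
  }
})

test_that("feature curves round-trip through CSV", {
  set.seed(23)
  rec <- recording(matrix(rnorm(4 * 2000), ncol = 4), 1000)
  feats <- avg_std(cc_curves(rec, rbind(c(1, 2), c(3, 4))),
                   rbind(c(1, 2)), rbind(c(3, 4)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(feats, path)
  back <- read_features(path)
  expect_equal(back$times, feats$times)
  expect_equal(back$avg, feats$avg, ignore_attr = TRUE)
  expect_equal(back$std, feats$std, ignore_attr = TRUE)
  expect_equal(unname(back$per_pair_cc), unname(feats$per_pair_cc))
})
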