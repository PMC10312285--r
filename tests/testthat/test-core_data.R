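test_that("connectome reading enforces symmetry, zero diagonal and 0.2 max", {
  set.seed(1)
  M <- matrix(runif(25, 0, 5), 5, 5)  # asymmetric, nonzero diagonal
  f <- tempfile(fileext = ".txt")
  write.table(M, f, row.names = FALSE, col.names = FALSE)
  b <- read_connectome(f, normalize = TRUE)
  expect_identical(b$C, t(b$C))
  expect_identical(unname(diag(b$C)), rep(0, 5))
  expect_identical(max(b$C), 0.2)
  # symmetrisation is the transpose average, then rescaled
  S <- (M + t(M)) / 2; diag(S) <- 0; S <- S * 0.2 / max(S)
  expect_equal(unname(b$C), S, tolerance = 1e-12)
  unlink(f)
})

test_that("degenerate and malformed connectomes are rejected", {
  expect_error(connectome_bundle(matrix(0, 3, 3)), "no nonzero")
  expect_error(connectome_bundle(matrix(1, 3, 2)), "square")
  expect_error(connectome_bundle(matrix(c(0, -1, -1, 0), 2, 2)), "negative")
})

test_that("connectome and coordinate files round-trip", {
  b <- small_bundle(n = 8)
  f <- tempfile(); fc <- tempfile()
  write_connectome(b, f, coords_path = fc)
  b2 <- read_connectome(f, coords_path = fc, normalize = FALSE)
  expect_equal(b2$C, b$C, tolerance = 1e-12)
  expect_equal(b2$coords, b$coords, tolerance = 1e-12)
  expect_identical(b2$labels, b$labels)
  unlink(c(f, fc))
})

test_that("map and BOLD files round-trip and validate lengths", {
  m <- heterogeneity_map(c(0.7, 1.1, 1.9), "t1t2")
  f <- tempfile()
  write_map(m, f)
  m2 <- read_map(f, n_regions = 3, source_tag = "t1t2")
  expect_equal(m2$beta, m$beta, tolerance = 1e-12)
  expect_error(read_map(f, n_regions = 5), "5 regions expected")
  unlink(f)

  set.seed(2)
  bold <- bold_dataset(list(matrix(rnorm(400), 4, 100)), tr = 0.72)
  d <- tempfile()
  paths <- write_bold(bold, d)
  b2 <- read_bold(paths, tr = 0.72)
  expect_identical(dim(b2$subjects[[1]]), c(4L, 100L))
  expect_equal(b2$subjects[[1]], bold$subjects[[1]], tolerance = 1e-12,
               ignore_attr = TRUE)
  unlink(d, recursive = TRUE)
})

test_that("band-pass filter passes in-band tones and rejects out-of-band", {
  tr <- 0.72
  x <- tone_matrix(c(0.04, 0.5), tr = tr, n_samples = 1000)
  y <- bandpass_filter(x, tr)
  # FFT oracle: amplitude at each row's own frequency before/after
  amp_at <- function(v, f) {
    n <- length(v)
    fr <- seq(0, n - 1) / (n * tr)
    k <- which.min(abs(fr - f))
    2 * Mod(fft(v))[k] / n
  }
  mid <- 200:800  # away from filtfilt edge transients
  expect_gt(amp_at(y[1, mid], 0.04) / amp_at(x[1, mid], 0.04), 0.95)
  # 0.5 Hz aliases onto the sampled grid; compare total power instead
  p_in <- sum(y[2, ]^2) / sum(x[2, ]^2)
  expect_lt(10 * log10(p_in), -20)
  # constant rows are demeaned to ~0
  z <- bandpass_filter(matrix(5, 1, 400), tr)
  expect_lt(max(abs(z)), 1e-8)
})

test_that("infeasible bands are rejected", {
  expect_error(bandpass_filter(matrix(rnorm(100), 1), tr = 10,
                               low = 0.008, high = 0.08), "infeasible")
  expect_error(bandpass_filter(matrix(rnorm(100), 1), tr = 0.72,
                               low = 0.08, high = 0.008), "infeasible")
})

test_that("analytic signal recovers phase velocity and amplitude", {
  tr <- 0.72; f0 <- 0.05; A <- 2.3
  x <- tone_matrix(f0, tr = tr, n_samples = 2000, amp = A)
  pan <- analytic_signal(x)
  expect_s3_class(pan, "analytic_panel")
  mid <- 200:1800
  # linear-phase regression oracle: unwrapped phase slope = 2 pi f0 per second
  ph <- pan$phase[1, mid]
  un <- cumsum(c(ph[1], ((diff(ph) + pi) %% (2 * pi)) - pi))
  t_mid <- (mid - 1) * tr
  slope <- coef(lm(un ~ t_mid))[2]
  expect_equal(unname(slope), 2 * pi * f0, tolerance = 0.01 * 2 * pi * f0)
  expect_equal(mean(pan$amplitude[1, mid]), A, tolerance = 0.02 * A)
  expect_true(all(pan$phase > -pi & pan$phase <= pi))
  # zero row convention
  pan0 <- analytic_signal(matrix(0, 1, 50))
  expect_identical(unname(pan0$amplitude[1, ]), rep(0, 50))
  expect_identical(unname(pan0$phase[1, ]), rep(0, 50))
})

test_that("filter plus analytic signal recover the in-band tone of a two-tone mix", {
  tr <- 0.72; n <- 1500
  t <- (seq_len(n) - 1) * tr
  x <- matrix(cos(2 * pi * 0.03 * t) + 0.8 * cos(2 * pi * 0.3 * t), 1)
  y <- bandpass_filter(x, tr)
  pan <- analytic_signal(y)
  mid <- 200:1300
  ph <- pan$phase[1, mid]
  un <- cumsum(c(ph[1], ((diff(ph) + pi) %% (2 * pi)) - pi))
  f_est <- unname(coef(lm(un ~ t[mid]))[2]) / (2 * pi)
  # FFT oracle frequency grid step
  expect_lt(abs(f_est - 0.03), 1 / (n * tr))
})
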