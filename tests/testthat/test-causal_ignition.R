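test_that("Gaussian entropies match closed forms and independence limits", {
  set.seed(11)
  x <- rnorm(5000)
  # univariate unit-variance Gaussian with T = 1: H = 1/2 log 2 pi e for the
  # past block (sample covariance within tolerance)
  h <- gaussian_entropies(x, rnorm(5000), T = 1)
  expect_equal(h$H_kop_past, 0.5 * log(2 * pi * exp(1)), tolerance = 0.01)
  # independent amplitude stream adds no predictive information
  h10 <- gaussian_entropies(x, rnorm(5000), T = 10)
  expect_lt(abs(h10$H_future_given_past - h10$H_future_given_both), 0.01)
  # duplicated conditioning variable takes the ridge path but stays finite
  hdup <- gaussian_entropies(x, x, T = 10)
  expect_true(hdup$ridged)
  expect_true(all(is.finite(unlist(hdup[1:5]))))
})

test_that("transfer entropy matches the analytic value of a linear causal system", {
  set.seed(12)
  L <- 10000; cc <- 0.6; bA <- 0.4; sn <- 0.5
  A <- as.numeric(arima.sim(list(ar = 0.8), L))
  K <- numeric(L)
  for (t in 1:(L - 1)) K[t + 1] <- cc * K[t] + bA * A[t] + sn * rnorm(1)
  i_n <- conditional_mi(K, A, T = 10)
  # independent regression oracle: residual variances of the restricted and
  # full linear predictors (Granger form 1/2 log(var_r / var_f))
  d <- embed(cbind(K, A), 12)
  Kf <- d[, 1]; Kp <- d[, seq(3, 23, 2)]; Ap <- d[, seq(4, 24, 2)]
  te_or <- 0.5 * log(var(resid(lm(Kf ~ Kp))) /
                     var(resid(lm(Kf ~ Kp + Ap))))
  expect_equal(i_n, te_or, tolerance = 0.1 * te_or)
  # invariance to affine rescaling of the amplitude
  expect_equal(conditional_mi(K, 3.7 * A + 2, T = 10), i_n,
               tolerance = 1e-10)
  # independent streams: I near zero and nonnegative
  i0 <- conditional_mi(K, as.numeric(arima.sim(list(ar = 0.8), L)), T = 10)
  expect_gte(i0, 0)
  expect_lt(i0, 0.01)
})

test_that("CI normalization clips to the unit interval and flags a zero denominator", {
  expect_identical(normalize_ci(0.4, 0.4), 1)
  expect_identical(normalize_ci(0, 0.4), 0)
  expect_warning(z <- normalize_ci(0.1, 0), "non-positive")
  expect_identical(z, 0)
  expect_message(o <- normalize_ci(0.5, 0.4), "clipped")
  expect_identical(o, 1)
})

test_that("circular-shift surrogates preserve the sample multiset and detect coupling", {
  set.seed(13)
  L <- 600
  A <- as.numeric(arima.sim(list(ar = 0.8), L))
  K <- 0.5 * c(0, A[-L]) + 0.3 * rnorm(L)
  sp <- surrogate_pvalue(K, A, T = 10, n_surrogates = 99, seed = 5)
  expect_equal(sp$p, 1 / 100, tolerance = 1e-12)  # coupled: p at floor
  # a shifted series is a permutation of the original
  s <- 37
  As <- c(A[(s + 1):L], A[1:s])
  expect_identical(sort(As), sort(A))
  expect_error(surrogate_pvalue(K[1:30], A[1:30], T = 10), "shorter")
  expect_error(surrogate_pvalue(K, A, T = 10, n_surrogates = 5), "19")
})

test_that("Stouffer aggregation matches the normal-CDF oracle", {
  expect_equal(aggregate_stouffer(c(0.5, 0.5, 0.5)), 0.5, tolerance = 1e-12)
  p2 <- aggregate_stouffer(c(0.0228, 0.0228))
  z <- qnorm(1 - 0.0228)
  expect_equal(p2, 1 - pnorm(sqrt(2) * z), tolerance = 1e-10)
  expect_equal(aggregate_stouffer(0.123), 0.123, tolerance = 1e-10)
  expect_error(aggregate_stouffer(numeric(0)), "empty")
})

test_that("the FDR mask reproduces hand-computed step-up decisions monotonically", {
  expect_identical(fdr_mask(rep(1, 6)), rep(0L, 6))
  expect_identical(fdr_mask(c(0.001, 0.02, 0.9), q = 0.05), c(1L, 1L, 0L))
  set.seed(14)
  p <- runif(40)^2
  m1 <- fdr_mask(p, q = 0.01)
  m2 <- fdr_mask(p, q = 0.05)
  expect_true(all(m1 <= m2))  # lowering q never adds regions
})

test_that("masked CI fit validates its inputs", {
  v <- runif(10)
  expect_equal(ci_fit(v, v, rep(1, 10)), 1)
  expect_error(ci_fit(v, v, rep(0, 10)), "fewer than 3")
  expect_error(ci_fit(v, v[1:5], rep(1, 10)), "equal length")
  set.seed(15)
  r <- replicate(200, ci_fit(rnorm(20), rnorm(20), rep(1, 20)))
  expect_lt(abs(median(r)), 0.1)  # random vectors: fit centred on zero
})

test_that("the proxy CI equals the lagged correlation and handles degeneracy", {
  set.seed(16)
  spec <- small_spec(n = 5, seed = 23, subjects = 1, duration = 300)
  b <- make_connectome(spec)
  bold <- make_ground_truth_bold(b, spec, "hopf",
                                 params = hopf_params(5, G = 0.3,
                                                      duration = 300))
  pan <- group_observables(bold)
  p <- proxy_ci(pan)
  kop <- pan$kop_series[[1]]
  Ts <- length(kop)
  manual <- cor(pan$amplitudes[[1]][2, 1:(Ts - 1)], kop[2:Ts])
  expect_equal(p[2], manual, tolerance = 1e-12)
  expect_true(all(abs(p) <= 1))
})

test_that("full CI analysis produces calibrated structures per subject", {
  spec <- small_spec(n = 6, seed = 29, subjects = 2, duration = 300)
  b <- make_connectome(spec)
  bold <- make_ground_truth_bold(b, spec, "hopf",
                                 params = hopf_params(6, G = 0.3,
                                                      duration = 300))
  res <- ci_analysis(bold, T = 5, n_surrogates = 19, seed = 3)
  expect_s3_class(res, "ci_result")
  expect_identical(dim(res$ci), c(2L, 6L))
  expect_true(all(res$ci >= 0 & res$ci <= 1))
  expect_true(all(res$pvals > 0 & res$pvals <= 1))
  expect_identical(length(res$mask), 6L)
  expect_identical(res$group_ci, colMeans(res$ci))
  expect_identical(length(res$group_proxy), 6L)
})
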