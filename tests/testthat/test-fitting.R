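# Small end-to-end fixtures: a 10-region network with short recordings keeps
# each grid point cheap while preserving the pipeline's structure.
fit_fixture <- function() {
  spec <- synthetic_spec(n_regions = 10, seed = 61, subjects = 3,
                         duration = 300)
  bundle <- make_connectome(spec)
  map <- make_heterogeneity_map(bundle$coords, 20, seed = 62)
  emp <- make_ground_truth_bold(bundle, spec, "hopf",
                                params = hopf_params(10, G = 0.4,
                                                     duration = 300))
  list(spec = spec, bundle = bundle, map = map, emp = emp)
}

test_that("iso-error curve extraction matches constructed minima and tie rules", {
  bias <- c(-0.5, 0, 0.5)
  scale <- c(0, 1, 2)
  g <- matrix(1, 3, 3)
  g[2, 1] <- 0.1; g[1, 2] <- 0.2; g[3, 3] <- 0.3   # known column minima
  curve <- iso_errkop_curve(g, bias, scale)
  expect_equal(curve$bias, c(0, -0.5, 0.5))
  expect_equal(curve$scale, scale)
  # constant column: tie broken toward |bias| = 0
  gc <- matrix(1, 3, 3)
  cc <- iso_errkop_curve(gc, bias, scale)
  expect_true(all(cc$bias == 0))
  # all-missing column is skipped
  gm <- g; gm[, 2] <- NA
  cm <- iso_errkop_curve(gm, bias, scale)
  expect_identical(nrow(cm), 2L)
  # single-scale grid collapses to one pair
  c1 <- iso_errkop_curve(g[, 1, drop = FALSE], bias, scale[1])
  expect_identical(nrow(c1), 1L)
  expect_equal(c1$bias, 0)
})

test_that("the heterogeneous optimum maximises CI fit on the curve with scale ties", {
  bias <- c(-0.5, 0, 0.5); scale <- c(0, 1, 2)
  g <- matrix(1, 3, 3); g[2, 1] <- 0.1; g[1, 2] <- 0.1; g[3, 3] <- 0.1
  curve <- iso_errkop_curve(g, bias, scale)
  cifit <- matrix(0, 3, 3)
  cifit[1, 2] <- 0.9                      # unique maximum on the curve
  opt <- select_heterogeneous_optimum(curve, cifit, bias, scale)
  expect_equal(opt$bias, -0.5)
  expect_equal(opt$scale, 1)
  expect_equal(opt$cifit, 0.9)
  # monotone CI fit along the curve: endpoint selected
  ci2 <- matrix(0, 3, 3)
  ci2[2, 1] <- 0.1; ci2[1, 2] <- 0.5; ci2[3, 3] <- 0.8
  expect_equal(select_heterogeneous_optimum(curve, ci2, bias, scale)$scale, 2)
  # ties: smaller scale wins
  ci3 <- matrix(0.5, 3, 3)
  expect_equal(select_heterogeneous_optimum(curve, ci3, bias, scale)$scale, 0)
  # single-pair curve: identity
  c1 <- curve[2, , drop = FALSE]
  expect_equal(select_heterogeneous_optimum(c1, ci2, bias, scale)$scale, 1)
})

test_that("the homogeneous sweep returns its grid, optimum and S3 surface", {
  fx <- fit_fixture()
  fit <- fit_homogeneous(fx$bundle, fx$emp, "hopf",
                         G_values = c(0.1, 0.4, 0.9), seed = 5)
  expect_s3_class(fit, "wb_fit")
  expect_identical(nrow(fit$grid), 3L)
  expect_true(all(is.finite(fit$grid$errkop)))
  expect_identical(fit$optimum$errkop, min(fit$grid$errkop))
  expect_named(coef(fit), "G")
  expect_output(print(fit), "homogeneous")
  # single-point grid returns that point
  f1 <- fit_homogeneous(fx$bundle, fx$emp, "hopf", G_values = 0.4, seed = 5)
  expect_identical(f1$optimum$G, 0.4)
  expect_error(fit_homogeneous(fx$bundle, fx$emp, "hopf",
                               G_values = numeric(0)), "nonempty")
})

test_that("the bias-scale exploration fills its grids and honours the homogeneous corner", {
  fx <- fit_fixture()
  emp_ci <- ci_analysis(group_observables(fx$emp), T = 5,
                        n_surrogates = 19, seed = 7)
  emp_ci$mask <- rep(1L, 10)  # full mask keeps the smoke test deterministic
  ex <- explore_bias_scale(fx$bundle, fx$map, fx$emp, "hopf", G_opt = 0.4,
                           bias_values = c(-0.3, 0, 0.3),
                           scale_values = c(0, 0.5), emp_ci = emp_ci,
                           T = 5, seed = 9, ci_method = "proxy")
  expect_s3_class(ex, "wb_fit")
  expect_false(anyNA(ex$errkop))
  expect_false(anyNA(ex$cifit))
  expect_identical(dim(ex$errkop), c(3L, 2L))
  expect_true(all(ex$iso_curve$scale == c(0, 0.5)))
  expect_true(nrow(ex$optimum) == 1)
  # (0, 0) reproduces the homogeneous model within sampling noise: compare
  # against a direct homogeneous simulation at the same seed scheme
  expect_lt(ex$errkop[2, 1], 0.2)
})

test_that("model comparison refuses degenerate repeat counts and reports tests", {
  fx <- fit_fixture()
  sur <- generate_surrogates(fx$map, fx$bundle$coords, 3, seed = 4)
  expect_error(
    compare_models(fx$bundle, fx$map, fx$emp, "hopf", G_opt = 0.4,
                   optimum = data.frame(bias = 0, scale = 0),
                   surrogates = sur, n_repeats = 1, seed = 3),
    "fewer than 5")
  emp_ci <- ci_analysis(group_observables(fx$emp), T = 5,
                        n_surrogates = 19, seed = 7)
  emp_ci$mask <- rep(1L, 10)
  cmp <- compare_models(fx$bundle, fx$map, fx$emp, "hopf", G_opt = 0.4,
                        optimum = data.frame(bias = 0, scale = 0),
                        surrogates = sur, n_repeats = 5, emp_ci = emp_ci,
                        T = 5, seed = 3, ci_method = "proxy")
  expect_s3_class(cmp, "wb_comparison")
  expect_identical(nrow(cmp$distributions), 15L)
  expect_identical(nrow(cmp$tests), 9L)  # 3 metrics x 3 pairs
  expect_true(all(cmp$tests$p_bonferroni >= cmp$tests$p_raw - 1e-15))
  # identical configurations (optimum 0,0 makes het == hom generative
  # process): corrected p should not be significant
  p_hh <- cmp$tests$p_bonferroni[cmp$tests$model_a == "heterogeneous" &
                                 cmp$tests$model_b == "homogeneous"]
  expect_true(all(p_hh > 0.05))
})

test_that("the full pipeline is reproducible from its base seed", {
  fx <- fit_fixture()
  f1 <- fit_homogeneous(fx$bundle, fx$emp, "hopf", G_values = c(0.2, 0.6),
                        seed = 11)
  f2 <- fit_homogeneous(fx$bundle, fx$emp, "hopf", G_values = c(0.2, 0.6),
                        seed = 11)
  expect_identical(f1$grid, f2$grid)
})
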