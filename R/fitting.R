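#' @name fitting_pipeline
#' @title Whole-brain model fitting pipeline
#' @description
#' Grid-search fitting of the Stuart-Landau and exact mean-field whole-brain
#' models to (empirical or synthetic) BOLD data: a homogeneous sweep over the
#' global coupling (and, for the mean-field model, the inhibitory half-width),
#' a bias x scale exploration of the heterogeneity modulation, extraction of
#' the iso-error curve of the Kuramoto fitting error, selection of the
#' heterogeneous optimum by maximal causal-ignition fit along that curve, and
#' a repeated-run comparison of heterogeneous, homogeneous and spatial-null
#' models with Wilcoxon rank-sum tests.
NULL

# Simulate one batch of model trials and return a filtered BOLD dataset.
# `model` is "hopf" or "meanfield"; `params` is fully specified (a / d_e,d_i
# and G already set).
simulate_trials <- function(bundle, model, params, n_trials, seed, tr) {
  subjects <- lapply(seq_len(n_trials), function(k) {
    if (model == "hopf")
      simulate_hopf(params, bundle, seed = seed + k, tr = tr)
    else
      simulate_meanfield_bold(params, bundle, seed = seed + k, tr = tr)
  })
  filter_bold(bold_dataset(subjects, tr = tr))
}

# Fit metrics of one simulated dataset against an empirical panel.
# ci_method "full" correlates the transfer-entropy CI vectors (Eq.-21 style);
# "proxy" correlates the one-lag amplitude-to-KoP proxy vectors, the variant
# used when trial counts or sampling make the full estimator too noisy. Both
# are masked by the empirical significance mask.
trial_metrics <- function(mod_bold, emp_panel, emp_ci = NULL, T = 10,
                          edge_trim = 10, ci_method = c("full", "proxy")) {
  ci_method <- match.arg(ci_method)
  pan <- group_observables(mod_bold, edge_trim)
  out <- list(errkop = abs(emp_panel$kop_mean - pan$kop_mean),
              fcfit = fc_fit(emp_panel$fc, pan$fc),
              gbcfit = gbc_fit(emp_panel$gbc, pan$gbc))
  if (!is.null(emp_ci)) {
    if (ci_method == "full") {
      mod_ci <- ci_analysis(pan, T = T, n_surrogates = 0)
      out$cifit <- ci_fit(emp_ci$group_ci, mod_ci$group_ci, emp_ci$mask)
    } else {
      out$cifit <- ci_fit(emp_ci$group_proxy, proxy_ci(pan), emp_ci$mask)
    }
  }
  out
}

#' Fit the homogeneous whole-brain model
#'
#' Sweeps the global coupling `G` (Stuart-Landau model) or the
#' `(G, d_i)` plane (mean-field model) with the regional parameters held
#' equal across regions, simulating `n_trials` trials per grid point and
#' computing the Kuramoto fitting error and the FC fit against the empirical
#' data. The optimum is the grid point minimising the Kuramoto error. For the
#' Stuart-Landau model the intrinsic frequencies are estimated per region
#' from the empirical spectra.
#'
#' @param bundle a [connectome_bundle()].
#' @param emp empirical [bold_dataset()].
#' @param model `"hopf"` or `"meanfield"`.
#' @param G_values sorted vector of coupling values.
#' @param d_i_values sorted vector of inhibitory half-widths (mean-field
#'   model only; default keeps the template's value).
#' @param params optional [hopf_params()] or [fre_params()] template; built
#'   with defaults (duration matching the empirical recording) when `NULL`.
#' @param n_trials trials per grid point; defaults to the number of empirical
#'   subjects.
#' @param seed base seed; every grid point and trial derives its own seed.
#' @param edge_trim samples dropped at each series end after the Hilbert
#'   transform.
#' @return An object of class `wb_fit` with the per-point `errkop`/`fcfit`
#'   values and the selected `optimum`.
#' @export
fit_homogeneous <- function(bundle, emp, model = c("hopf", "meanfield"),
                            G_values, d_i_values = NULL, params = NULL,
                            n_trials = NULL, seed = 1L, edge_trim = 10) {
  model <- match.arg(model)
  stopifnot(inherits(bundle, "connectome_bundle"),
            inherits(emp, "bold_dataset"))
  if (is.unsorted(G_values) || length(G_values) == 0)
    stop("G_values must be a nonempty sorted vector")
  if (is.null(n_trials)) n_trials <- emp$n_subjects
  emp_panel <- group_observables(emp, edge_trim)
  duration <- (min(vapply(emp$subjects, ncol, 1L)) - 1) * emp$tr
  if (model == "hopf") {
    if (is.null(params))
      params <- hopf_params(bundle$n_regions, duration = duration)
    params$omega <- estimate_intrinsic_frequencies(
      if (isTRUE(emp$filtered)) emp else filter_bold(emp))
    grid <- data.frame(G = G_values)
  } else {
    if (is.null(params))
      params <- fre_params(bundle$n_regions, duration = duration)
    if (is.null(d_i_values)) d_i_values <- params$d_i[1]
    grid <- expand.grid(G = G_values, d_i = d_i_values)
  }
  res <- lapply(seq_len(nrow(grid)), function(g) {
    p <- params
    p$G <- grid$G[g]
    if (model == "meanfield")
      p$d_i <- rep(grid$d_i[g], bundle$n_regions)
    tryCatch({
      bold <- simulate_trials(bundle, model, p, n_trials,
                              seed = seed + 7919L * g, tr = emp$tr)
      trial_metrics(bold, emp_panel, edge_trim = edge_trim)
    }, error = function(e) {
      warning("grid point ", g, " failed: ", conditionMessage(e))
      list(errkop = NA_real_, fcfit = NA_real_, gbcfit = NA_real_)
    })
  })
  grid$errkop <- vapply(res, `[[`, numeric(1), "errkop")
  grid$fcfit <- vapply(res, `[[`, numeric(1), "fcfit")
  opt <- which.min(grid$errkop)
  structure(list(model = model, kind = "homogeneous", grid = grid,
                 optimum = grid[opt, , drop = FALSE],
                 emp_kop = emp_panel$kop_mean, params = params,
                 n_trials = n_trials, seed = seed),
            class = "wb_fit")
}

#' Explore the bias x scale heterogeneity plane
#'
#' At a fixed coupling (the homogeneous optimum), modulates the regional
#' parameters by every (bias, scale) pair via [heterogeneous_a()] /
#' [heterogeneous_d()] and computes four fit statistics per point: Kuramoto
#' error, FC fit, GBC fit and causal-ignition fit (masked by the empirical
#' significance mask). A failing grid point is recorded as missing and the
#' exploration continues.
#'
#' @inheritParams fit_homogeneous
#' @param map a [heterogeneity_map()].
#' @param G_opt coupling at which the plane is explored.
#' @param bias_values,scale_values sorted grids of the modulation parameters.
#' @param emp_ci optional precomputed `ci_result` of the empirical data (with
#'   surrogate mask); computed here when `NULL`.
#' @param ci_method `"full"` correlates the transfer-entropy CI vectors;
#'   `"proxy"` correlates the one-lag amplitude-to-synchronization proxy
#'   vectors (the low-sampling variant), both restricted to the empirical
#'   significance mask.
#' @param T causal-ignition past-window length.
#' @param n_surrogates surrogates for the empirical significance mask.
#' @param q FDR level of the mask.
#' @return A `wb_fit` with matrices `errkop`, `fcfit`, `gbcfit`, `cifit`
#'   (rows = bias, columns = scale), the `iso_curve`, and the selected
#'   `optimum` on it.
#' @export
explore_bias_scale <- function(bundle, map, emp, model = c("hopf",
                                                           "meanfield"),
                               G_opt, bias_values, scale_values,
                               params = NULL, n_trials = NULL, seed = 1L,
                               emp_ci = NULL, T = 10, n_surrogates = 100,
                               q = 0.05, edge_trim = 10,
                               ci_method = c("full", "proxy")) {
  model <- match.arg(model)
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(map, "heterogeneity_map"))
  if (is.unsorted(bias_values) || is.unsorted(scale_values))
    stop("bias_values and scale_values must be sorted")
  if (is.null(n_trials)) n_trials <- emp$n_subjects
  emp_panel <- group_observables(emp, edge_trim)
  if (is.null(emp_ci))
    emp_ci <- ci_analysis(emp_panel, T = T, n_surrogates = n_surrogates,
                          q = q, seed = seed)
  duration <- (min(vapply(emp$subjects, ncol, 1L)) - 1) * emp$tr
  if (model == "hopf") {
    if (is.null(params))
      params <- hopf_params(bundle$n_regions, duration = duration)
    params$omega <- estimate_intrinsic_frequencies(
      if (isTRUE(emp$filtered)) emp else filter_bold(emp))
  } else if (is.null(params)) {
    params <- fre_params(bundle$n_regions, duration = duration)
  }
  params$G <- G_opt
  nb <- length(bias_values); ns <- length(scale_values)
  mk <- function() matrix(NA_real_, nb, ns,
                          dimnames = list(bias = format(bias_values),
                                          scale = format(scale_values)))
  errkop <- fcfit <- gbcfit <- cifit <- mk()
  idx <- 0
  for (js in seq_len(ns)) {
    for (jb in seq_len(nb)) {
      idx <- idx + 1
      p <- params
      if (model == "hopf") {
        p$a <- heterogeneous_a(p$a0, bias_values[jb], scale_values[js], map)
      } else {
        d <- heterogeneous_d(p$d_e[1], p$d_i[1], bias_values[jb],
                             scale_values[js], map)
        p$d_e <- d$d_e
        p$d_i <- d$d_i
      }
      m <- tryCatch({
        bold <- simulate_trials(bundle, model, p, n_trials,
                                seed = seed + 7919L * idx, tr = emp$tr)
        trial_metrics(bold, emp_panel, emp_ci, T, edge_trim, ci_method)
      }, error = function(e) {
        warning("grid point (bias=", bias_values[jb], ", scale=",
                scale_values[js], ") failed: ", conditionMessage(e))
        NULL
      })
      if (!is.null(m)) {
        errkop[jb, js] <- m$errkop
        fcfit[jb, js] <- m$fcfit
        gbcfit[jb, js] <- m$gbcfit
        cifit[jb, js] <- m$cifit
      }
    }
  }
  curve <- iso_errkop_curve(errkop, bias_values, scale_values)
  opt <- select_heterogeneous_optimum(curve, cifit, bias_values,
                                      scale_values)
  structure(list(model = model, kind = "heterogeneous", G = G_opt,
                 bias_values = bias_values, scale_values = scale_values,
                 errkop = errkop, fcfit = fcfit, gbcfit = gbcfit,
                 cifit = cifit, iso_curve = curve, optimum = opt,
                 emp_ci = emp_ci, params = params, n_trials = n_trials,
                 seed = seed),
            class = "wb_fit")
}

#' Iso-error curve of the Kuramoto fitting error
#'
#' For each scale value (column), the bias value minimising the Kuramoto
#' error. Ties are broken toward the smaller `|bias|`; a column with no
#' finite value is skipped.
#'
#' @param errkop_grid bias x scale matrix of Kuramoto errors.
#' @param bias_values,scale_values the grid axes.
#' @return Data frame with columns `scale`, `bias`, `i_bias`, `i_scale` and
#'   `errkop`, one row per retained scale.
#' @export
iso_errkop_curve <- function(errkop_grid, bias_values, scale_values) {
  rows <- lapply(seq_along(scale_values), function(js) {
    col <- errkop_grid[, js]
    if (all(!is.finite(col))) return(NULL)
    best <- which(col == min(col, na.rm = TRUE))
    jb <- best[which.min(abs(bias_values[best]))]
    data.frame(scale = scale_values[js], bias = bias_values[jb],
               i_bias = jb, i_scale = js, errkop = col[jb])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("iso-error curve is empty (all grid points missing)")
  out
}

#' Select the heterogeneous optimum on the iso-error curve
#'
#' The (bias, scale) pair on the curve maximising the causal-ignition fit;
#' ties are broken toward the smaller scale.
#'
#' @param curve output of [iso_errkop_curve()].
#' @param cifit_grid bias x scale matrix of CI fits.
#' @param bias_values,scale_values the grid axes.
#' @return One-row data frame with `bias`, `scale` and `cifit`.
#' @export
select_heterogeneous_optimum <- function(curve, cifit_grid, bias_values,
                                         scale_values) {
  if (is.null(curve) || nrow(curve) == 0) stop("empty iso-error curve")
  vals <- mapply(function(jb, js) cifit_grid[jb, js],
                 curve$i_bias, curve$i_scale)
  if (all(!is.finite(vals))) stop("no finite CI fit on the curve")
  best <- which(vals == max(vals, na.rm = TRUE))
  k <- best[which.min(curve$scale[best])]
  data.frame(bias = curve$bias[k], scale = curve$scale[k], cifit = vals[k])
}

#' Repeated-run comparison of heterogeneous, homogeneous and null models
#'
#' Re-simulates each model `n_repeats` times with fresh seeds and collects
#' the distributions of the causal-ignition, GBC and FC fit statistics. The
#' spatial-null model replaces the heterogeneity map by an
#' autocorrelation-preserving surrogate (cycling through the supplied set
#' across repeats). Pairwise two-sided Wilcoxon rank-sum tests between the
#' three models are Bonferroni-corrected over the three pairs per metric.
#'
#' @inheritParams explore_bias_scale
#' @param optimum one-row data frame (or list) with the heterogeneous `bias`
#'   and `scale`.
#' @param surrogates a `surrogate_set` from [generate_surrogates()].
#' @param n_repeats repeated runs per model (at least 5).
#' @param alt_map optional fourth model: an alternative heterogeneity map
#'   evaluated at the same optimum.
#' @return An object of class `wb_comparison`: `distributions` (long data
#'   frame of metric values), `tests` (pairwise corrected p-values) and
#'   `medians`.
#' @export
compare_models <- function(bundle, map, emp, model = c("hopf", "meanfield"),
                           G_opt, optimum, surrogates, n_repeats = 50,
                           n_trials = NULL, params = NULL, seed = 1L,
                           emp_ci = NULL, T = 10, n_surrogates = 100,
                           q = 0.05, edge_trim = 10, alt_map = NULL,
                           ci_method = c("full", "proxy")) {
  model <- match.arg(model)
  ci_method <- match.arg(ci_method)
  if (n_repeats < 5) stop("statistics refused for fewer than 5 repeats")
  stopifnot(inherits(surrogates, "surrogate_set"))
  if (is.null(n_trials)) n_trials <- emp$n_subjects
  emp_panel <- group_observables(emp, edge_trim)
  if (is.null(emp_ci))
    emp_ci <- ci_analysis(emp_panel, T = T, n_surrogates = n_surrogates,
                          q = q, seed = seed)
  duration <- (min(vapply(emp$subjects, ncol, 1L)) - 1) * emp$tr
  if (model == "hopf") {
    if (is.null(params))
      params <- hopf_params(bundle$n_regions, duration = duration)
    params$omega <- estimate_intrinsic_frequencies(
      if (isTRUE(emp$filtered)) emp else filter_bold(emp))
  } else if (is.null(params)) {
    params <- fre_params(bundle$n_regions, duration = duration)
  }
  params$G <- G_opt
  bias <- optimum$bias[1]
  scale <- optimum$scale[1]
  models <- list(heterogeneous = function(r) map,
                 homogeneous = function(r) NULL,
                 spatial_null = function(r)
                   surrogates$maps[[(r - 1) %% length(surrogates$maps) + 1]])
  if (!is.null(alt_map)) models$alternative <- function(r) alt_map
  rows <- list()
  for (mname in names(models)) {
    for (r in seq_len(n_repeats)) {
      m <- models[[mname]](r)
      p <- params
      if (model == "hopf") {
        p$a <- if (is.null(m)) rep(p$a0, bundle$n_regions)
               else heterogeneous_a(p$a0, bias, scale, m)
      } else {
        if (is.null(m)) {
          p$d_e <- rep(p$d_e[1], bundle$n_regions)
          p$d_i <- rep(p$d_i[1], bundle$n_regions)
        } else {
          d <- heterogeneous_d(p$d_e[1], p$d_i[1], bias, scale, m)
          p$d_e <- d$d_e
          p$d_i <- d$d_i
        }
      }
      bold <- simulate_trials(bundle, model, p, n_trials,
                              seed = seed + 104729L * r, tr = emp$tr)
      met <- trial_metrics(bold, emp_panel, emp_ci, T, edge_trim, ci_method)
      rows[[length(rows) + 1]] <-
        data.frame(model = mname, repeat_id = r, cifit = met$cifit,
                   gbcfit = met$gbcfit, fcfit = met$fcfit)
    }
  }
  dist <- do.call(rbind, rows)
  metrics <- c("cifit", "gbcfit", "fcfit")
  pairs <- utils::combn(names(models), 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(metrics, function(met) {
    do.call(rbind, lapply(pairs, function(pr) {
      x <- dist[dist$model == pr[1], met]
      y <- dist[dist$model == pr[2], met]
      p <- suppressWarnings(wilcox.test(x, y)$p.value)
      data.frame(metric = met, model_a = pr[1], model_b = pr[2],
                 p_raw = p)
    }))
  }))
  tests$p_bonferroni <- NA_real_
  for (met in metrics) {
    k <- tests$metric == met
    tests$p_bonferroni[k] <- p.adjust(tests$p_raw[k], method = "bonferroni")
  }
  med <- aggregate(dist[, metrics], by = list(model = dist$model), median)
  structure(list(distributions = dist, tests = tests, medians = med,
                 optimum = data.frame(bias = bias, scale = scale),
                 G = G_opt, n_repeats = n_repeats, model = model,
                 seed = seed),
            class = "wb_comparison")
}

# ---- S3 methods -----------------------------------------------------------

#' @export
print.wb_fit <- function(x, ...) {
  cat("Whole-brain model fit (", x$model, ", ", x$kind, ")\n", sep = "")
  if (x$kind == "homogeneous") {
    cat("  grid:", nrow(x$grid), "point(s);",
        x$n_trials, "trial(s) per point\n")
    cat("  optimum:", paste(names(x$optimum)[1:(ncol(x$optimum) - 2)],
                            "=", unlist(x$optimum[1:(ncol(x$optimum) - 2)]),
                            collapse = ", "),
        " ErrKoP =", format(round(x$optimum$errkop, 4)), "\n")
  } else {
    cat("  grid:", length(x$bias_values), "bias x",
        length(x$scale_values), "scale;", x$n_trials,
        "trial(s) per point at G =", x$G, "\n")
    cat("  optimum: bias =", x$optimum$bias, ", scale =", x$optimum$scale,
        " (CIfit =", format(round(x$optimum$cifit, 4)), ")\n")
  }
  invisible(x)
}

#' @export
summary.wb_fit <- function(object, ...) {
  print(object)
  if (object$kind == "homogeneous") {
    cat("\nGrid values:\n")
    print(object$grid, row.names = FALSE)
  } else {
    cat("\nIso-error curve (bias minimising ErrKoP per scale):\n")
    print(object$iso_curve[, c("scale", "bias", "errkop")],
          row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.wb_fit <- function(object, ...) {
  op <- object$optimum
  if (object$kind == "homogeneous") {
    out <- unlist(op[setdiff(names(op), c("errkop", "fcfit"))])
  } else {
    out <- c(G = object$G, bias = op$bias, scale = op$scale)
  }
  out
}

#' @export
plot.wb_fit <- function(x, ...) {
  if (x$kind == "homogeneous") {
    grid <- x$grid
    graphics::par(mar = c(4, 4, 2, 4))
    plot(grid$G, grid$errkop, type = "b", pch = 16, col = "darkorange",
         xlab = "G", ylab = "ErrKoP", ...)
    graphics::par(new = TRUE)
    plot(grid$G, grid$fcfit, type = "b", pch = 17, col = "steelblue",
         axes = FALSE, xlab = "", ylab = "")
    graphics::axis(4)
    graphics::mtext("FCfit", side = 4, line = 2.5)
    graphics::abline(v = x$optimum$G, lty = 2)
  } else {
    graphics::image(x$bias_values, x$scale_values, x$errkop,
                    xlab = "bias", ylab = "scale", main = "ErrKoP", ...)
    graphics::points(x$iso_curve$bias, x$iso_curve$scale, pch = 8,
                     col = "red")
    graphics::points(x$optimum$bias, x$optimum$scale, pch = 19,
                     col = "purple", cex = 1.4)
  }
  invisible(x)
}

#' @export
print.wb_comparison <- function(x, ...) {
  cat("Model comparison (", x$model, "): ", x$n_repeats,
      " repeats at G = ", x$G, ", (bias, scale) = (",
      x$optimum$bias, ", ", x$optimum$scale, ")\n", sep = "")
  cat("\nMedians:\n")
  print(x$medians, row.names = FALSE)
  cat("\nPairwise Wilcoxon rank-sum tests (Bonferroni-corrected):\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' @export
summary.wb_comparison <- function(object, ...) print(object, ...)

#' @export
plot.wb_comparison <- function(x, metric = "cifit", ...) {
  graphics::boxplot(stats::as.formula(paste(metric, "~ model")),
                    data = x$distributions, ylab = metric, ...)
  invisible(x)
}
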