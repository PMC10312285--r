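#' @name causal_ignition
#' @title Causal ignition: region-to-synchronization transfer entropy
#' @description
#' The causal-ignition (CI) statistic quantifies, for each region, the extra
#' knowledge that the past of the region's oscillation amplitude contributes
#' to predicting the next-step global synchronization level (the Kuramoto
#' order parameter), beyond what the synchronization's own past provides:
#' a conditional mutual information, i.e. a transfer entropy, evaluated under
#' a Gaussian (second-order, covariance-based) approximation. Past windows of
#' length `T` samples are used (default 10), advanced one sample at a time.
#' The statistic is normalized by the total information that amplitude and
#' synchronization pasts jointly carry about the future synchronization,
#' yielding values in `[0, 1]`.
NULL

# log-determinant of a covariance matrix via Cholesky; adds a ridge
# proportional to trace/dim when the matrix is numerically singular.
logdet_cov <- function(S, ridge = 1e-8) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    lam <- ridge * sum(diag(S)) / nrow(S)
    ch <- chol(S + diag(lam, nrow(S)))
    attr(ch, "ridged") <- TRUE
  }
  structure(2 * sum(log(diag(ch))), ridged = isTRUE(attr(ch, "ridged")))
}

# Differential entropy of a Gaussian with covariance S (nats).
gaussian_entropy_cov <- function(S, ridge = 1e-8) {
  S <- as.matrix(S)
  ld <- logdet_cov(S, ridge)
  structure(nrow(S) / 2 * log(2 * pi * exp(1)) + as.numeric(ld) / 2,
            ridged = isTRUE(attr(ld, "ridged")))
}

# Embedding blocks for the CI statistic: for window positions i = T..(L-1),
# Xf = s[i+1] (future), Xp = s[i..i-T+1] (own past), Ap = a[i..i-T+1]
# (amplitude past). Built with stats::embed.
ci_embed <- function(kop, A, T) {
  L <- length(kop)
  if (length(A) != L) stop("series lengths differ")
  if (T < 1) stop("T must be at least 1")
  if (L - T < 5 * (2 * T + 1))
    stop("series too short: need at least ", 5 * (2 * T + 1) + T,
         " samples for T = ", T)
  Ek <- stats::embed(kop, T + 1)       # [s_t, s_{t-1}, ..., s_{t-T}]
  Ea <- stats::embed(A, T + 1)
  list(Xf = Ek[, 1],
       Xp = Ek[, -1, drop = FALSE],
       Ap = Ea[, -1, drop = FALSE])
}

#' Gaussian entropy terms of the causal-ignition embedding
#'
#' Computes the four (conditional) differential entropies entering the
#' transfer-entropy statistic under the Gaussian approximation, each as
#' `dim/2 * log(2 pi e) + 1/2 * log det Sigma` with covariances estimated
#' over all window positions and conditioning done by entropy differences
#' (equivalently, Schur complements).
#'
#' @param kop numeric synchronization series.
#' @param A numeric amplitude series of one region (same length).
#' @param T past-window length in samples.
#' @param ridge relative ridge added to numerically singular covariances.
#' @return List with entries `H_kop_past` = H(KoP past), `H_future_given_past`
#'   = H(KoP_{i+1} | KoP past), `H_amp_given_past` = H(A past | KoP past) and
#'   `H_future_given_both` = H(KoP_{i+1} | KoP past, A past), in nats, plus
#'   `ridged` (logical: any ridge applied).
#' @export
gaussian_entropies <- function(kop, A, T = 10, ridge = 1e-8) {
  e <- ci_embed(kop, A, T)
  M <- cbind(e$Xf, e$Xp, e$Ap)
  S <- stats::cov(M)
  i_f <- 1
  i_p <- 1 + seq_len(T)
  i_a <- 1 + T + seq_len(T)
  H <- function(idx) gaussian_entropy_cov(S[idx, idx, drop = FALSE], ridge)
  h_p <- H(i_p)
  h_fp <- H(c(i_f, i_p))
  h_pa <- H(c(i_p, i_a))
  h_all <- H(c(i_f, i_p, i_a))
  ridged <- any(vapply(list(h_p, h_fp, h_pa, h_all),
                       function(x) isTRUE(attr(x, "ridged")), logical(1)))
  list(H_kop_past = as.numeric(h_p),
       H_future_given_past = as.numeric(h_fp) - as.numeric(h_p),
       H_amp_given_past = as.numeric(h_pa) - as.numeric(h_p),
       H_future_given_both = as.numeric(h_all) - as.numeric(h_pa),
       H_future = as.numeric(gaussian_entropy_cov(S[i_f, i_f, drop = FALSE],
                                                  ridge)),
       ridged = ridged)
}

#' Conditional mutual information (Gaussian transfer entropy)
#'
#' `I_n = H(KoP_{i+1} | KoP past) - H(KoP_{i+1} | A past, KoP past)`:
#' the reduction in uncertainty about the next synchronization value gained
#' from the region's amplitude past. Nonnegative up to numerical error;
#' negative values within `-1e-10` are clipped to 0.
#'
#' @inheritParams gaussian_entropies
#' @return Scalar transfer entropy in nats.
#' @export
conditional_mi <- function(kop, A, T = 10, ridge = 1e-8) {
  h <- gaussian_entropies(kop, A, T, ridge)
  max(h$H_future_given_past - h$H_future_given_both, 0)
}

#' Normalize a causal-ignition value
#'
#' `CI = I_n / total`, where `total` is the mutual information that the
#' amplitude and synchronization pasts jointly carry about the future
#' synchronization. Clipped to `[0, 1]`; a non-positive `total` yields 0 with
#' a warning.
#'
#' @param i_n transfer entropy of one region.
#' @param total joint mutual information (denominator).
#' @param eps threshold below which `total` counts as zero.
#' @return Scalar in `[0, 1]`.
#' @export
normalize_ci <- function(i_n, total, eps = 1e-12) {
  if (!is.finite(total) || total <= eps) {
    warning("total mutual information non-positive; CI set to 0")
    return(0)
  }
  ci <- i_n / total
  if (ci < 0 || ci > 1) {
    message("CI value ", format(ci), " clipped to [0, 1]")
    ci <- min(max(ci, 0), 1)
  }
  ci
}

# CI of one region from precomputed entropies.
ci_one <- function(kop, A, T, ridge = 1e-8) {
  h <- gaussian_entropies(kop, A, T, ridge)
  i_n <- max(h$H_future_given_past - h$H_future_given_both, 0)
  total <- h$H_future - h$H_future_given_both
  suppressMessages(suppressWarnings(normalize_ci(i_n, total)))
}

#' Causal-ignition vector of all regions
#'
#' @param kop synchronization series (length T_s).
#' @param A_mat N x T_s matrix of region amplitudes.
#' @param T past-window length.
#' @param ridge covariance ridge.
#' @return Length-N vector of normalized CI values.
#' @export
ci_vector <- function(kop, A_mat, T = 10, ridge = 1e-8) {
  A_mat <- as.matrix(A_mat)
  vapply(seq_len(nrow(A_mat)), function(n) ci_one(kop, A_mat[n, ], T, ridge),
         numeric(1))
}

#' Circular-shift surrogate p-value for one region's CI
#'
#' The amplitude series is circularly shifted by offsets drawn uniformly from
#' `[T + 1, L - T - 1]` (excluding near-zero shifts), destroying the temporal
#' alignment with the synchronization series while preserving the amplitude's
#' sample multiset and autocorrelation. The p-value uses the standard
#' add-one permutation estimate `p = (1 + #{surrogate >= observed}) /
#' (1 + n_surrogates)`.
#'
#' @inheritParams gaussian_entropies
#' @param n_surrogates number of surrogates (at least 19).
#' @param seed seed for the shift offsets.
#' @return List with `p`, `observed` CI and the vector of surrogate CIs.
#' @export
surrogate_pvalue <- function(kop, A, T = 10, n_surrogates = 100, seed = 1L,
                             ridge = 1e-8) {
  if (n_surrogates < 19) stop("need at least 19 surrogates")
  L <- length(A)
  if (L < 4 * T) stop("series shorter than 4 * T")
  obs <- ci_one(kop, A, T, ridge)
  set.seed(seed)
  shifts <- sample(seq(T + 1, L - T - 1), n_surrogates, replace = TRUE)
  sur <- vapply(shifts, function(s) {
    As <- c(A[(s + 1):L], A[1:s])
    ci_one(kop, As, T, ridge)
  }, numeric(1))
  list(p = (1 + sum(sur >= obs)) / (1 + n_surrogates),
       observed = obs, surrogates = sur)
}

#' Stouffer aggregation of p-values across subjects
#'
#' Sums the inverse-normal transformed p-values:
#' `z = sum Phi^{-1}(1 - p_s) / sqrt(S)`, group p = `1 - Phi(z)`. Inputs are
#' floored/ceilinged at machine-safe bounds.
#'
#' @param pvals numeric vector of per-subject p-values in (0, 1).
#' @return Scalar group p-value.
#' @export
aggregate_stouffer <- function(pvals) {
  if (length(pvals) == 0) stop("empty p-value list")
  p <- pmin(pmax(pvals, 1e-15), 1 - 1e-15)
  z <- sum(qnorm(1 - p)) / sqrt(length(p))
  1 - pnorm(z)
}

#' Benjamini-Hochberg significance mask
#'
#' Standard step-up false-discovery-rate control over regions.
#'
#' @param pvals group p-values, one per region.
#' @param q FDR level.
#' @return Integer 0/1 vector: 1 where the region is significant.
#' @export
fdr_mask <- function(pvals, q = 0.05) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  as.integer(p.adjust(pvals, method = "BH") <= q)
}

#' CI fit: masked correlation of group CI vectors
#'
#' Pearson correlation between group-averaged empirical and modeled CI
#' vectors restricted to the regions marked significant in the empirical
#' mask.
#'
#' @param emp,mod length-N group CI vectors.
#' @param mask 0/1 vector derived from the empirical data.
#' @return Scalar correlation.
#' @export
ci_fit <- function(emp, mod, mask) {
  if (length(emp) != length(mod) || length(emp) != length(mask))
    stop("CI vectors and mask must have equal length")
  keep <- which(mask == 1)
  if (length(keep) < 3)
    stop("fewer than 3 regions survive the mask")
  cor(emp[keep], mod[keep])
}

#' Low-sampling proxy of causal ignition
#'
#' Per region, the Pearson correlation between the region's amplitude at time
#' t and the global synchronization at t + 1 -- a one-step substitute for the
#' full transfer-entropy statistic when the repetition time is coarse. A
#' constant amplitude yields 0 with a message.
#'
#' @param bold a [bold_dataset()], or an `observable_panel` from
#'   [group_observables()].
#' @param edge_trim samples dropped at each end after the Hilbert transform
#'   (when `bold` is a dataset).
#' @return Length-N vector: the subject-averaged proxy CI.
#' @export
proxy_ci <- function(bold, edge_trim = 10) {
  pan <- if (inherits(bold, "observable_panel")) bold
         else group_observables(bold, edge_trim)
  n <- nrow(pan$fc)
  per_subj <- vapply(seq_along(pan$kop_series), function(k) {
    kop <- pan$kop_series[[k]]
    A <- pan$amplitudes[[k]]
    Ts <- length(kop)
    if (Ts < 3) stop("need at least 3 samples")
    vapply(seq_len(n), function(i) {
      a <- A[i, 1:(Ts - 1)]
      if (sd(a) == 0) {
        message("region ", i, ": constant amplitude, proxy CI set to 0")
        return(0)
      }
      cor(a, kop[2:Ts])
    }, numeric(1))
  }, numeric(n))
  rowMeans(as.matrix(per_subj))
}

#' Full causal-ignition analysis of a BOLD dataset
#'
#' Per subject: synchronization series and amplitudes from the filtered
#' phases, per-region CI and circular-shift surrogate p-values. Across
#' subjects: Stouffer aggregation, Benjamini-Hochberg mask, and the
#' group-averaged CI vector.
#'
#' @param bold a [bold_dataset()] or `observable_panel`.
#' @param T past-window length (samples).
#' @param n_surrogates surrogates per subject-region test; 0 skips the
#'   significance stage (no p-values/mask; used for model trials).
#' @param q FDR level for the mask.
#' @param seed base seed for the surrogate offsets.
#' @param edge_trim samples dropped at each end after the Hilbert transform.
#' @return An object of class `ci_result`: list with `ci` (subjects x N
#'   matrix), `group_ci`, `group_proxy` (the subject-averaged one-lag proxy
#'   CI, see [proxy_ci()]), and when surrogates are used `pvals` (subjects x
#'   N), `group_pvals`, `mask`.
#' @export
ci_analysis <- function(bold, T = 10, n_surrogates = 100, q = 0.05,
                        seed = 1L, edge_trim = 10) {
  pan <- if (inherits(bold, "observable_panel")) bold
         else group_observables(bold, edge_trim)
  n <- nrow(pan$fc)
  S <- length(pan$kop_series)
  ci <- matrix(NA_real_, S, n)
  pv <- if (n_surrogates > 0) matrix(NA_real_, S, n) else NULL
  for (s in seq_len(S)) {
    kop <- pan$kop_series[[s]]
    A <- pan$amplitudes[[s]]
    for (i in seq_len(n)) {
      if (n_surrogates > 0) {
        sp <- surrogate_pvalue(kop, A[i, ], T, n_surrogates,
                               seed = seed + 1000L * s + i)
        ci[s, i] <- sp$observed
        pv[s, i] <- sp$p
      } else {
        ci[s, i] <- ci_one(kop, A[i, ], T)
      }
    }
  }
  out <- list(ci = ci, group_ci = colMeans(ci), T = T,
              group_proxy = proxy_ci(pan))
  if (n_surrogates > 0) {
    out$pvals <- pv
    out$group_pvals <- apply(pv, 2, aggregate_stouffer)
    out$mask <- fdr_mask(out$group_pvals, q)
  }
  structure(out, class = "ci_result")
}

#' @export
print.ci_result <- function(x, ...) {
  cat("Causal ignition:", ncol(x$ci), "regions,", nrow(x$ci),
      "subject(s), T =", x$T, "\n")
  cat("  group CI range: [", format(round(min(x$group_ci), 4)), ", ",
      format(round(max(x$group_ci), 4)), "]\n", sep = "")
  if (!is.null(x$mask))
    cat("  significant regions:", sum(x$mask), "/", length(x$mask), "\n")
  invisible(x)
}
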