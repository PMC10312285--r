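#' Functional connectivity matrix
#'
#' Pearson correlation between all region pairs over the full series. A
#' zero-variance region gets zero correlations (and unit self-correlation),
#' with a message.
#'
#' @param bold region x sample matrix.
#' @return N x N symmetric correlation matrix with unit diagonal.
#' @export
compute_fc <- function(bold) {
  bold <- as.matrix(bold)
  if (ncol(bold) < 3) stop("need at least 3 samples for FC")
  sds <- apply(bold, 1, sd)
  fc <- suppressWarnings(cor(t(bold)))
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    message(length(bad), " zero-variance region(s); correlations set to 0")
    fc[bad, ] <- 0
    fc[, bad] <- 0
  }
  diag(fc) <- 1
  fc
}

#' FC fit: correlation of upper-triangular elements
#'
#' Pearson correlation between the strict upper triangles of two (typically
#' group-averaged) functional connectivity matrices.
#'
#' @param emp,mod N x N matrices with matching N (N >= 3).
#' @return Scalar correlation.
#' @export
fc_fit <- function(emp, mod) {
  emp <- as.matrix(emp); mod <- as.matrix(mod)
  if (!all(dim(emp) == dim(mod))) stop("FC matrices must have equal size")
  if (nrow(emp) < 3) stop("need at least 3 regions")
  ut <- upper.tri(emp)
  cor(emp[ut], mod[ut])
}

#' Global brain connectivity
#'
#' Per-region mean of its FC row, diagonal included:
#' `GBC_i = sum_j FC_ij / N`. (Excluding the diagonal would only shift every
#' entry by 1/N and cannot change the fit correlation.)
#'
#' @param fc N x N functional connectivity matrix.
#' @return Length-N vector.
#' @export
compute_gbc <- function(fc) {
  fc <- as.matrix(fc)
  rowSums(fc) / nrow(fc)
}

#' GBC fit: correlation of group-averaged GBC vectors
#'
#' @param emp,mod length-N numeric vectors.
#' @return Scalar correlation.
#' @export
gbc_fit <- function(emp, mod) {
  if (length(emp) != length(mod)) stop("GBC vectors must have equal length")
  cor(emp, mod)
}

#' Kuramoto order parameter
#'
#' `KoP(t) = |sum_p exp(i phi_p(t))| / N`: the modulus of the population-mean
#' unit phase vector at each time point, plus its temporal mean. 1 means all
#' phases equal (full synchronisation); uniformly spread phases give values
#' near 0.
#'
#' @param phases N x T matrix of instantaneous phases (radians), or an
#'   `analytic_panel` from [analytic_signal()].
#' @return List with `series` (length T) and `mean` (scalar in `[0, 1]`).
#' @export
compute_kop <- function(phases) {
  if (inherits(phases, "analytic_panel")) phases <- phases$phase
  phases <- as.matrix(phases)
  series <- Mod(colMeans(exp(1i * phases)))
  list(series = series, mean = mean(series))
}

#' Kuramoto-level fitting error
#'
#' Absolute difference between the subject-averaged empirical and
#' trial-averaged modeled mean Kuramoto order parameters. Both datasets are
#' band-pass filtered identically (their own `band`/`tr`) before phase
#' extraction; `edge_trim` samples are discarded at each end after the
#' Hilbert transform.
#'
#' @param emp,mod [bold_dataset()] objects (unfiltered; filtering is applied
#'   here), or scalars interpreted as already-computed mean KoP values.
#' @param edge_trim samples dropped at each series end after the transform.
#' @return Scalar error `|KoP_emp - KoP_mod|`.
#' @export
err_kop <- function(emp, mod, edge_trim = 10) {
  k_emp <- if (is.numeric(emp)) emp else mean_kop(emp, edge_trim)
  k_mod <- if (is.numeric(mod)) mod else mean_kop(mod, edge_trim)
  abs(k_emp - k_mod)
}

#' Subject-averaged mean Kuramoto order parameter of a dataset
#'
#' @param bold a [bold_dataset()].
#' @param edge_trim samples dropped at each end after the Hilbert transform.
#' @return Scalar mean KoP.
#' @export
mean_kop <- function(bold, edge_trim = 10) {
  stopifnot(inherits(bold, "bold_dataset"))
  filt <- if (isTRUE(bold$filtered)) bold else filter_bold(bold)
  mean(vapply(filt$subjects, function(s) {
    pan <- analytic_signal(s)
    ph <- trim_edges(pan$phase, edge_trim)
    compute_kop(ph)$mean
  }, numeric(1)))
}

# Drop `k` columns from each end (no-op when the series is too short).
trim_edges <- function(m, k) {
  if (k <= 0 || ncol(m) <= 2 * k + 2) return(m)
  m[, (k + 1):(ncol(m) - k), drop = FALSE]
}

#' Group observables of a BOLD dataset
#'
#' Filters each subject, extracts phases and amplitudes, and returns the
#' group-averaged functional connectivity, the global brain connectivity of
#' the group FC, the subject-averaged mean Kuramoto order parameter, and the
#' per-subject panels needed by downstream statistics.
#'
#' @param bold a [bold_dataset()].
#' @param edge_trim samples dropped at each end after the Hilbert transform.
#' @return An object of class `observable_panel`: list with `fc` (group
#'   averaged), `gbc`, `kop_mean`, and per-subject lists `fc_subj`,
#'   `kop_series`, `phases`, `amplitudes`.
#' @export
group_observables <- function(bold, edge_trim = 10) {
  stopifnot(inherits(bold, "bold_dataset"))
  filt <- if (isTRUE(bold$filtered)) bold else filter_bold(bold)
  fc_subj <- list()
  kop_series <- list()
  phases <- list()
  amplitudes <- list()
  kop_means <- numeric(0)
  for (k in seq_along(filt$subjects)) {
    s <- filt$subjects[[k]]
    pan <- analytic_signal(s)
    ph <- trim_edges(pan$phase, edge_trim)
    am <- trim_edges(pan$amplitude, edge_trim)
    kop <- compute_kop(ph)
    fc_subj[[k]] <- compute_fc(s)
    kop_series[[k]] <- kop$series
    phases[[k]] <- ph
    amplitudes[[k]] <- am
    kop_means[k] <- kop$mean
  }
  fc <- Reduce(`+`, fc_subj) / length(fc_subj)
  structure(list(fc = fc, gbc = compute_gbc(fc), kop_mean = mean(kop_means),
                 kop_means = kop_means, fc_subj = fc_subj,
                 kop_series = kop_series, phases = phases,
                 amplitudes = amplitudes),
            class = "observable_panel")
}

#' @export
print.observable_panel <- function(x, ...) {
  cat("Observable panel:", nrow(x$fc), "regions,", length(x$fc_subj),
      "subject(s)\n")
  cat("  mean KoP:", format(round(x$kop_mean, 4)),
      " mean |FC|:", format(round(mean(abs(x$fc[upper.tri(x$fc)])), 4)), "\n")
  invisible(x)
}
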