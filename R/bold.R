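#' Multi-subject BOLD dataset
#'
#' A list of per-subject region x sample matrices sharing the same parcellation
#' and repetition time, together with the analysis frequency band.
#'
#' @param subjects list of numeric matrices, regions in rows, samples in
#'   columns; all subjects must share the number of regions.
#' @param tr repetition time in seconds.
#' @param band length-2 numeric, band-pass edges in Hz.
#' @return An object of class `bold_dataset` with elements `subjects`, `tr`,
#'   `band`, `n_regions` and `n_subjects`.
#' @export
bold_dataset <- function(subjects, tr, band = c(0.008, 0.08)) {
  if (!is.list(subjects)) subjects <- list(subjects)
  subjects <- lapply(subjects, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  if (length(subjects) == 0)
    stop("at least one subject required")
  n <- nrow(subjects[[1]])
  if (!all(vapply(subjects, nrow, 1L) == n))
    stop("all subjects must have the same number of regions")
  if (any(vapply(subjects, ncol, 1L) < 2))
    stop("each subject needs at least 2 samples")
  if (!is.numeric(tr) || length(tr) != 1 || tr <= 0)
    stop("tr must be a positive scalar (seconds)")
  band <- as.numeric(band)
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1])
    stop("band must be (low, high) with 0 < low < high")
  structure(list(subjects = subjects, tr = tr, band = band,
                 n_regions = n, n_subjects = length(subjects)),
            class = "bold_dataset")
}

#' @export
print.bold_dataset <- function(x, ...) {
  ts <- vapply(x$subjects, ncol, 1L)
  cat("BOLD dataset:", x$n_subjects, "subject(s),", x$n_regions,
      "regions, TR =", x$tr, "s\n")
  cat("  samples per subject:", paste(range(ts), collapse = "-"),
      " band:", paste(x$band, collapse = "-"), "Hz\n")
  invisible(x)
}

#' Read or write BOLD data as one TSV per subject
#'
#' Each file holds one subject: regions in rows, samples in columns, no header.
#'
#' @param paths character vector of file paths, one per subject.
#' @param tr repetition time in seconds.
#' @param band band-pass edges in Hz.
#' @param n_regions optional expected region count; mismatch is an error.
#' @return [read_bold()] returns a [bold_dataset()].
#' @export
read_bold <- function(paths, tr, band = c(0.008, 0.08), n_regions = NULL) {
  subjects <- lapply(paths, function(p)
    as.matrix(read.table(p, header = FALSE, sep = "\t")))
  if (!is.null(n_regions) && nrow(subjects[[1]]) != n_regions)
    stop("BOLD has ", nrow(subjects[[1]]), " regions but ", n_regions,
         " expected")
  bold_dataset(subjects, tr = tr, band = band)
}

#' @param bold a [bold_dataset()].
#' @param dir output directory (created if absent).
#' @param prefix file name prefix; files are `<prefix><k>.tsv`.
#' @return [write_bold()] returns the vector of written paths, invisibly.
#' @rdname read_bold
#' @export
write_bold <- function(bold, dir, prefix = "subject_") {
  stopifnot(inherits(bold, "bold_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(seq_along(bold$subjects), function(k) {
    p <- file.path(dir, sprintf("%s%03d.tsv", prefix, k))
    write.table(format(bold$subjects[[k]], digits = 17, trim = TRUE,
                       scientific = TRUE),
                p, row.names = FALSE, col.names = FALSE, quote = FALSE,
                sep = "\t")
    p
  }, character(1))
  invisible(paths)
}

#' Zero-phase band-pass filter for BOLD signals
#'
#' Removes each row's mean, then applies a second-order Butterworth band-pass
#' forward and backward (zero phase) row by row.
#'
#' @param signals region x sample numeric matrix.
#' @param tr sampling interval in seconds.
#' @param low,high band edges in Hz; must satisfy `0 < low < high < 1/(2 tr)`.
#' @param order Butterworth order (applied twice by the forward-backward pass).
#' @return Filtered matrix of the same shape.
#' @export
bandpass_filter <- function(signals, tr, low = 0.008, high = 0.08,
                            order = 2) {
  signals <- as.matrix(signals)
  nyq <- 1 / (2 * tr)
  if (!(low > 0 && low < high && high < nyq))
    stop("infeasible band [", low, ", ", high, "] Hz for TR = ", tr,
         " s (Nyquist = ", format(nyq), " Hz)")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  out <- t(apply(signals, 1, function(row) {
    row <- row - mean(row)
    as.numeric(signal::filtfilt(bf, row))
  }))
  dimnames(out) <- dimnames(signals)
  out
}

#' Band-pass filter every subject of a BOLD dataset
#'
#' @param bold a [bold_dataset()]; its `band` element supplies the edges.
#' @param order Butterworth order.
#' @return A new `bold_dataset` with filtered signals.
#' @export
filter_bold <- function(bold, order = 2) {
  stopifnot(inherits(bold, "bold_dataset"))
  out <- bold
  out$subjects <- lapply(bold$subjects, bandpass_filter, tr = bold$tr,
                         low = bold$band[1], high = bold$band[2],
                         order = order)
  out$filtered <- TRUE
  out
}

# Analytic signal of one demeaned row via the frequency-domain Hilbert
# transform: doubles positive frequencies, zeroes negative ones.
hilbert_analytic <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase and amplitude via the Hilbert transform
#'
#' Computes per-row analytic signals of band-limited, demeaned data. Phases
#' are wrapped to (-pi, pi]; amplitudes are the modulus. An all-zero row gets
#' amplitude 0 and phase 0 by convention.
#'
#' @param filtered region x sample matrix of band-limited signals.
#' @return An object of class `analytic_panel`: list with matrices `phase`
#'   and `amplitude` of the input shape.
#' @export
analytic_signal <- function(filtered) {
  filtered <- as.matrix(filtered)
  ph <- am <- matrix(0, nrow(filtered), ncol(filtered),
                     dimnames = dimnames(filtered))
  for (i in seq_len(nrow(filtered))) {
    row <- filtered[i, ]
    if (all(row == 0)) next
    z <- hilbert_analytic(row)
    ph[i, ] <- Arg(z)
    am[i, ] <- Mod(z)
  }
  structure(list(phase = ph, amplitude = am), class = "analytic_panel")
}
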