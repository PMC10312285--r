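#' Structural connectome bundle
#'
#' Bundles a structural coupling matrix with region labels and 3-D centroid
#' coordinates. The matrix is symmetrised by averaging with its transpose, the
#' diagonal is zeroed, and (optionally) the weights are rescaled so that the
#' maximum entry equals `max_weight`, the convention used throughout the
#' package (0.2 by default, matching common dMRI-derived connectome scaling).
#'
#' @param C square nonnegative numeric matrix of coupling weights.
#' @param labels character vector of region names (defaults to `"R1"..."RN"`).
#' @param coords optional N x 3 numeric matrix of region centroids (mm).
#' @param normalize logical; rescale so `max(C) == max_weight`.
#' @param max_weight target maximum weight after normalisation.
#' @return An object of class `connectome_bundle` with elements `C`, `labels`,
#'   `coords` and `n_regions`.
#' @export
connectome_bundle <- function(C, labels = NULL, coords = NULL,
                              normalize = FALSE, max_weight = 0.2) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C))
    stop("connectome matrix must be square, got ", nrow(C), " x ", ncol(C))
  if (nrow(C) < 2)
    stop("connectome must have at least 2 regions")
  storage.mode(C) <- "double"
  if (anyNA(C) || any(!is.finite(C)))
    stop("connectome contains non-finite entries")
  if (any(C < 0))
    stop("connectome contains negative weights")
  C <- (C + t(C)) / 2
  diag(C) <- 0
  if (all(C == 0))
    stop("connectome has no nonzero off-diagonal weights")
  if (normalize) {
    C <- C * (max_weight / max(C))
    # rescaling in floating point can miss the target in the last ulp;
    # pin the maximal entries so max(C) == max_weight exactly
    C[C >= max(C)] <- max_weight
  }
  n <- nrow(C)
  if (is.null(labels))
    labels <- paste0("R", seq_len(n))
  if (length(labels) != n)
    stop("length(labels) must equal the number of regions")
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 3)
      stop("coords must be an N x 3 matrix")
    storage.mode(coords) <- "double"
    dimnames(coords) <- list(labels, c("x", "y", "z"))
  }
  dimnames(C) <- list(labels, labels)
  structure(list(C = C, labels = labels, coords = coords, n_regions = n),
            class = "connectome_bundle")
}

#' @export
print.connectome_bundle <- function(x, ...) {
  cat("Structural connectome:", x$n_regions, "regions\n")
  cat("  max weight:", format(max(x$C)), " density:",
      format(round(mean(x$C[upper.tri(x$C)] > 0), 3)), "\n")
  cat("  coordinates:", if (is.null(x$coords)) "absent" else "present", "\n")
  invisible(x)
}

#' Read a structural connectome from delimited text
#'
#' Reads a square whitespace- or comma-delimited numeric matrix, enforces
#' symmetry (average with transpose), zeroes the diagonal and, by default,
#' rescales the weights to a maximum of 0.2. Optionally reads a companion
#' coordinate table (TSV with columns `label`, `x`, `y`, `z`).
#'
#' @param path path to the matrix file.
#' @param coords_path optional path to the coordinate table.
#' @param normalize logical; rescale so the maximum weight is `max_weight`.
#' @param max_weight target maximum weight.
#' @return A [connectome_bundle()].
#' @export
read_connectome <- function(path, coords_path = NULL, normalize = TRUE,
                            max_weight = 0.2) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  C <- as.matrix(read.table(path, header = FALSE, sep = sep))
  labels <- NULL
  coords <- NULL
  if (!is.null(coords_path)) {
    tab <- read.table(coords_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    need <- c("label", "x", "y", "z")
    if (!all(need %in% names(tab)))
      stop("coordinate table must have columns label, x, y, z")
    if (nrow(tab) != nrow(C))
      stop("coordinate table has ", nrow(tab), " rows but connectome has ",
           nrow(C), " regions")
    labels <- as.character(tab$label)
    coords <- as.matrix(tab[, c("x", "y", "z")])
  }
  connectome_bundle(C, labels = labels, coords = coords,
                    normalize = normalize, max_weight = max_weight)
}

#' Write a connectome bundle to delimited text
#'
#' Inverse of [read_connectome()]: writes the coupling matrix as
#' whitespace-delimited text and, if coordinates are present, a TSV coordinate
#' table with columns `label`, `x`, `y`, `z`.
#'
#' @param bundle a [connectome_bundle()].
#' @param path output path for the matrix.
#' @param coords_path optional output path for the coordinate table.
#' @return `bundle`, invisibly.
#' @export
write_connectome <- function(bundle, path, coords_path = NULL) {
  stopifnot(inherits(bundle, "connectome_bundle"))
  write.table(format(bundle$C, digits = 17, trim = TRUE, scientific = TRUE),
              path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  if (!is.null(coords_path)) {
    if (is.null(bundle$coords))
      stop("bundle has no coordinates to write")
    tab <- data.frame(label = bundle$labels,
                      x = bundle$coords[, 1],
                      y = bundle$coords[, 2],
                      z = bundle$coords[, 3])
    write.table(tab, coords_path, row.names = FALSE, sep = "\t", quote = FALSE)
  }
  invisible(bundle)
}
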