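#' Regional heterogeneity map
#'
#' One scalar per region modulating the local dynamical parameters (the
#' bifurcation parameter of the Stuart-Landau model, or the Lorentzian
#' half-widths of the mean-field model). Empirically this is a T1w/T2w ratio
#' map or a node-level global-brain-connectivity map; synthetic and surrogate
#' maps carry the corresponding tag.
#'
#' @param beta numeric vector, one finite value per region.
#' @param source_tag one of `"t1t2"`, `"gbc"`, `"synthetic"`, `"surrogate"`.
#' @return An object of class `heterogeneity_map` with elements `beta` and
#'   `source_tag`.
#' @export
heterogeneity_map <- function(beta, source_tag = c("synthetic", "t1t2",
                                                   "gbc", "surrogate")) {
  source_tag <- match.arg(source_tag)
  beta <- as.numeric(beta)
  if (length(beta) < 1 || anyNA(beta) || any(!is.finite(beta)))
    stop("heterogeneity map must be a finite numeric vector")
  structure(list(beta = beta, source_tag = source_tag),
            class = "heterogeneity_map")
}

#' @export
print.heterogeneity_map <- function(x, ...) {
  cat("Heterogeneity map (", x$source_tag, "): ", length(x$beta),
      " regions, range [", format(min(x$beta)), ", ", format(max(x$beta)),
      "]\n", sep = "")
  invisible(x)
}

#' Read or write a heterogeneity map (one value per line)
#'
#' @param path file path.
#' @param n_regions optional expected length; mismatch is an error.
#' @param source_tag tag recorded on the map.
#' @return [read_map()] returns a [heterogeneity_map()]; [write_map()] returns
#'   the map invisibly.
#' @export
read_map <- function(path, n_regions = NULL, source_tag = "synthetic") {
  beta <- scan(path, what = double(), quiet = TRUE)
  if (!is.null(n_regions) && length(beta) != n_regions)
    stop("map has ", length(beta), " values but ", n_regions,
         " regions expected")
  heterogeneity_map(beta, source_tag)
}

#' @param map a [heterogeneity_map()].
#' @rdname read_map
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "heterogeneity_map"))
  writeLines(format(map$beta, digits = 17, trim = TRUE, scientific = TRUE),
             path)
  invisible(map)
}
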