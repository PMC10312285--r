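#' Specification of a synthetic study
#'
#' Holds the knobs of the synthetic-data generator: a spatially embedded
#' connectome built from an exponential distance rule, a spatially
#' autocorrelated positive heterogeneity map, and ground-truth BOLD from a
#' known model. Defaults emulate a resting-state acquisition: 68 cortical
#' regions, ~15 minutes at TR = 0.72 s, with "subjects" as independent noise
#' realisations of one ground-truth parameterisation.
#'
#' @param n_regions number of regions (>= 2).
#' @param seed base seed of the generator.
#' @param edr_lambda exponential-distance-rule decay rate (1/mm).
#' @param map_smoothness spatial kernel width of the heterogeneity map (mm).
#' @param subjects number of independent noise realisations.
#' @param duration recording duration (s).
#' @param tr repetition time (s).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_regions = 68, seed = 1L, edr_lambda = 0.023,
                           map_smoothness = 20, subjects = 10,
                           duration = 900, tr = 0.72) {
  if (n_regions < 2) stop("n_regions must be at least 2")
  if (duration / tr < 200)
    stop("duration/tr must give at least 200 samples (got ",
         floor(duration / tr), ")")
  if (edr_lambda < 0 || map_smoothness < 0)
    stop("edr_lambda and map_smoothness must be nonnegative")
  structure(list(n_regions = as.integer(n_regions), seed = as.integer(seed),
                 edr_lambda = edr_lambda, map_smoothness = map_smoothness,
                 subjects = as.integer(subjects), duration = duration,
                 tr = tr),
            class = "synthetic_spec")
}

#' Synthetic spatially embedded connectome
#'
#' Places regions approximately uniformly on a sphere of 70 mm radius and
#' draws weights from an exponential distance rule,
#' `w_ij = exp(-lambda d_ij) * lognormal noise`, then symmetrises, zeroes the
#' diagonal and rescales to a maximum weight of 0.2.
#'
#' @param spec a [synthetic_spec()].
#' @param radius sphere radius (mm).
#' @param noise_sdlog log-s.d. of the multiplicative lognormal edge noise.
#' @return A [connectome_bundle()] with coordinates attached.
#' @export
make_connectome <- function(spec, radius = 70, noise_sdlog = 0.5) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_regions
  set.seed(spec$seed)
  xyz <- matrix(rnorm(3 * n), n, 3)
  xyz <- xyz / sqrt(rowSums(xyz^2)) * radius
  D <- as.matrix(dist(xyz))
  W <- exp(-spec$edr_lambda * D) *
    matrix(exp(rnorm(n * n, sd = noise_sdlog)), n, n)
  diag(W) <- 0
  connectome_bundle(W, coords = xyz, normalize = TRUE)
}

#' Synthetic spatially autocorrelated heterogeneity map
#'
#' White noise per region smoothed by a Gaussian kernel over inter-node
#' distances, then affinely mapped to a positive range. Zero smoothness gives
#' rescaled white noise (no spatial autocorrelation); large smoothness gives
#' a near-constant map.
#'
#' @param coords N x 3 coordinate matrix (mm).
#' @param smoothness Gaussian kernel width (mm); must be nonnegative.
#' @param seed integer seed.
#' @param range target `c(min, max)` of the map.
#' @return A [heterogeneity_map()] tagged `synthetic`.
#' @export
make_heterogeneity_map <- function(coords, smoothness = 20, seed = 1L,
                                   range = c(0.5, 2.0)) {
  if (smoothness < 0) stop("smoothness must be nonnegative")
  coords <- as.matrix(coords)
  n <- nrow(coords)
  set.seed(seed)
  z <- rnorm(n)
  lo <- min(z); hi <- max(z)
  D <- as.matrix(dist(coords))
  zs <- kernel_smooth(z, D, smoothness)
  # the affine map is anchored to the pre-smoothing field, so zero smoothness
  # gives rescaled white noise spanning the range while a very wide kernel
  # collapses toward the range midpoint (smoothing is a convex average, so
  # the smoothed field cannot leave [lo, hi])
  if (hi > lo) {
    u <- (zs - lo) / (hi - lo)
  } else {
    u <- rep(0.5, n)
  }
  heterogeneity_map(range[1] + u * (range[2] - range[1]), "synthetic")
}

#' Ground-truth BOLD from a known whole-brain model
#'
#' Runs the chosen simulator with a known (bias, scale) heterogeneity ground
#' truth, one independent noise realisation per "subject", and returns
#' band-limited BOLD at the spec's repetition time. The Stuart-Landau model's
#' x variable is used directly as the fMRI-like signal; the mean-field model
#' passes excitatory rates through the hemodynamic transform.
#'
#' @param bundle a [connectome_bundle()].
#' @param spec a [synthetic_spec()] (subjects, duration, tr).
#' @param model `"hopf"` or `"meanfield"`.
#' @param params a [hopf_params()] or [fre_params()]; its `a` (or
#'   `d_e`/`d_i`) fields are overridden by the heterogeneity modulation when
#'   `map` is given.
#' @param map optional [heterogeneity_map()]; with `bias`/`scale` it defines
#'   the ground-truth modulation. `NULL` keeps the homogeneous parameters.
#' @param bias,scale ground-truth modulation parameters.
#' @param filter logical; band-pass filter the returned BOLD (default TRUE).
#' @return A [bold_dataset()]; attributes `ground_truth` records the
#'   generating parameters.
#' @export
make_ground_truth_bold <- function(bundle, spec, model = c("hopf",
                                                           "meanfield"),
                                   params = NULL, map = NULL, bias = 0,
                                   scale = 0, filter = TRUE) {
  model <- match.arg(model)
  stopifnot(inherits(bundle, "connectome_bundle"),
            inherits(spec, "synthetic_spec"))
  if (spec$duration <= 0) stop("duration must be positive")
  n <- bundle$n_regions
  if (model == "hopf") {
    if (is.null(params))
      params <- hopf_params(n, duration = spec$duration)
    params$duration <- spec$duration
    if (!is.null(map))
      params$a <- heterogeneous_a(params$a0, bias, scale, map)
    subjects <- lapply(seq_len(spec$subjects), function(k)
      simulate_hopf(params, bundle, seed = spec$seed + 100L * k,
                    tr = spec$tr))
  } else {
    if (is.null(params))
      params <- fre_params(n, duration = spec$duration)
    params$duration <- spec$duration
    if (!is.null(map)) {
      d <- heterogeneous_d(params$d_e[1], params$d_i[1], bias, scale, map)
      params$d_e <- d$d_e
      params$d_i <- d$d_i
    }
    subjects <- lapply(seq_len(spec$subjects), function(k)
      simulate_meanfield_bold(params, bundle, seed = spec$seed + 100L * k,
                              tr = spec$tr))
  }
  bold <- bold_dataset(subjects, tr = spec$tr)
  if (filter) bold <- filter_bold(bold)
  attr(bold, "ground_truth") <- list(model = model, bias = bias,
                                     scale = scale, G = params$G,
                                     seed = spec$seed)
  bold
}
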