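#' Parameters of the Stuart-Landau whole-brain model
#'
#' The local dynamics of each region follow the normal form of a supercritical
#' Hopf bifurcation with bifurcation parameter `a` (subcritical `a < 0`: noisy
#' damped focus; supercritical `a > 0`: limit cycle of radius `sqrt(a)`) and
#' intrinsic angular frequency `omega`. Regions are coupled diffusively
#' through the connectome with global gain `G`, and both Cartesian components
#' receive independent additive Gaussian noise of standard deviation `nu`.
#'
#' @param n_regions number of regions N.
#' @param a0 homogeneous bifurcation parameter baseline (default -0.02).
#' @param a optional length-N vector of regional bifurcation parameters; when
#'   `NULL`, all regions use `a0`.
#' @param omega intrinsic angular frequencies (rad/s), scalar or length N.
#'   Default corresponds to 0.05 Hz oscillations.
#' @param G global coupling gain (nonnegative).
#' @param nu noise standard deviation.
#' @param dt Euler-Maruyama step (s). Must resolve the fastest oscillation.
#' @param duration simulated time kept after the transient (s).
#' @param transient initial model time discarded (s).
#' @return An object of class `hopf_params`.
#' @export
hopf_params <- function(n_regions, a0 = -0.02, a = NULL,
                        omega = 2 * pi * 0.05, G = 0, nu = 0.02,
                        dt = 0.1, duration = 900, transient = 20) {
  if (is.null(a)) a <- rep(a0, n_regions)
  if (length(a) == 1) a <- rep(a, n_regions)
  if (length(omega) == 1) omega <- rep(omega, n_regions)
  if (length(a) != n_regions || length(omega) != n_regions)
    stop("a and omega must have length n_regions")
  if (G < 0 || nu < 0 || dt <= 0 || duration <= 0)
    stop("G and nu must be nonnegative; dt and duration positive")
  if (dt >= 2 * pi / max(omega) / 20)
    stop("dt too coarse for the fastest oscillator: need dt < ",
         format(2 * pi / max(omega) / 20), " s")
  structure(list(n_regions = n_regions, a0 = a0, a = a, omega = omega,
                 G = G, nu = nu, dt = dt, duration = duration,
                 transient = transient),
            class = "hopf_params")
}

#' Heterogeneity-modulated bifurcation parameters
#'
#' Maps a regional heterogeneity map onto per-region bifurcation parameters
#' through a bias and a scale. In the default multiplicative mode
#' `a_n = a0 * (1 + bias + scale * beta_n)`, so `(bias, scale) = (0, 0)`
#' recovers the homogeneous model exactly. The additive mode
#' `a_n = a0 + bias + scale * beta_n` is available for comparison.
#'
#' @param a0 homogeneous baseline.
#' @param bias additive modulation term (delta_1).
#' @param scale multiplier of the heterogeneity map (delta_2).
#' @param map a [heterogeneity_map()].
#' @param mode `"multiplicative"` (default) or `"additive"`.
#' @return Numeric vector of per-region bifurcation parameters.
#' @export
heterogeneous_a <- function(a0, bias, scale, map,
                            mode = c("multiplicative", "additive")) {
  mode <- match.arg(mode)
  stopifnot(inherits(map, "heterogeneity_map"))
  if (anyNA(map$beta)) stop("heterogeneity map contains NA")
  switch(mode,
         multiplicative = a0 * (1 + bias + scale * map$beta),
         additive = a0 + bias + scale * map$beta)
}

#' Simulate the coupled Stuart-Landau network
#'
#' Euler-Maruyama integration of the Cartesian-coordinate network equations
#' from small random initial conditions. The diffusive coupling term is
#' `G * sum_j C_ij (x_j - x_i)` (and likewise for y). The transient is
#' discarded and the x component is returned subsampled at `tr`.
#'
#' @param params a [hopf_params()].
#' @param bundle a [connectome_bundle()].
#' @param seed integer seed; fixed seeds give bit-reproducible trajectories.
#' @param tr output sampling interval (s); must be a multiple of `dt` (it is
#'   rounded to the nearest step).
#' @return Region x sample matrix of the x variable.
#' @export
simulate_hopf <- function(params, bundle, seed = 1L, tr = 0.72) {
  stopifnot(inherits(params, "hopf_params"),
            inherits(bundle, "connectome_bundle"))
  if (bundle$n_regions != params$n_regions)
    stop("params built for ", params$n_regions, " regions but connectome has ",
         bundle$n_regions)
  # snap the step so that an integer number of steps lands exactly on tr
  stride <- max(1L, as.integer(ceiling(tr / params$dt)))
  dt <- tr / stride
  n_tr <- as.integer(round(params$transient / dt))
  n_steps <- n_tr + as.integer(round(params$duration / dt))
  set.seed(seed)
  x0 <- rnorm(params$n_regions, sd = 0.01)
  y0 <- rnorm(params$n_regions, sd = 0.01)
  out <- cpp_simulate_hopf(params$a, params$omega, bundle$C, params$G,
                           params$nu, dt, n_steps, n_tr, stride,
                           x0, y0)
  rownames(out) <- bundle$labels
  out
}

#' Estimate intrinsic frequencies from BOLD data
#'
#' For each region, the peak frequency of the group-averaged periodogram
#' within the analysis band, returned as angular frequency (rad/s). A region
#' whose in-band spectrum is flat (peak indistinct from the in-band mean)
#' falls back to the band midpoint, with a message.
#'
#' @param bold a band-pass filtered [bold_dataset()].
#' @param flat_tol relative tolerance used to declare a spectrum flat.
#' @return Numeric vector of angular frequencies, one per region.
#' @export
estimate_intrinsic_frequencies <- function(bold, flat_tol = 0.01) {
  stopifnot(inherits(bold, "bold_dataset"))
  n <- bold$n_regions
  ts_min <- min(vapply(bold$subjects, ncol, 1L))
  freqs <- seq(0, floor(ts_min / 2)) / (ts_min * bold$tr)
  in_band <- freqs >= bold$band[1] & freqs <= bold$band[2]
  if (!any(in_band))
    stop("no Fourier frequency falls inside the band; series too short")
  pow <- matrix(0, n, sum(in_band))
  for (s in bold$subjects) {
    for (i in seq_len(n)) {
      x <- s[i, seq_len(ts_min)]
      px <- Mod(fft(x - mean(x)))^2
      pow[i, ] <- pow[i, ] + px[seq_along(freqs)][in_band]
    }
  }
  band_freqs <- freqs[in_band]
  midpoint <- mean(bold$band)
  omega <- vapply(seq_len(n), function(i) {
    p <- pow[i, ]
    if (max(p) <= (1 + flat_tol) * mean(p)) {
      message("region ", i, ": flat in-band spectrum, using band midpoint")
      return(2 * pi * midpoint)
    }
    2 * pi * band_freqs[which.max(p)]
  }, numeric(1))
  omega
}

#' Locate the Hopf bifurcation of an uncoupled Stuart-Landau node
#'
#' Sweeps the bifurcation parameter with bisection on the long-time amplitude
#' of the noise-free node. The modulus of the node obeys the radial equation
#' `dr/dt = a r - r^3` (exact polar reduction of the normal form), integrated
#' with an adaptive-step RK4 from `r0` for a horizon scaled as `20/|a|`; the
#' node is classified oscillatory when the final amplitude exceeds
#' `sqrt(|a|)/2` (half the limit-cycle radius).
#'
#' @param lower,upper bracketing interval for the bifurcation parameter; the
#'   lower end must be classified quiescent and the upper end oscillatory.
#' @param tol bisection tolerance on the located parameter.
#' @param r0 initial amplitude.
#' @return The located critical bifurcation parameter.
#' @export
locate_sl_bifurcation <- function(lower = -0.2, upper = 0.25, tol = 1e-6,
                                  r0 = 0.1) {
  oscillates <- function(a) {
    if (a == 0) return(FALSE)
    t_end <- 20 / abs(a)
    r <- r0
    t <- 0
    f <- function(r) r * (a - r^2)
    while (t < t_end) {
      dt <- 0.02 / (abs(a) + 3 * r^2 + 1e-12)
      dt <- min(dt, t_end - t)
      k1 <- f(r)
      k2 <- f(r + dt / 2 * k1)
      k3 <- f(r + dt / 2 * k2)
      k4 <- f(r + dt * k3)
      r <- r + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (r < 0) r <- 0
      t <- t + dt
    }
    r > sqrt(abs(a)) / 2
  }
  if (oscillates(lower) || !oscillates(upper))
    stop("bracket does not straddle the bifurcation")
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (oscillates(mid)) upper <- mid else lower <- mid
  }
  (lower + upper) / 2
}
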