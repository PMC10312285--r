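#' Parameters of the exact mean-field whole-brain model
#'
#' Each region holds an excitatory and an inhibitory population of quadratic
#' integrate-and-fire neurons, reduced exactly to firing-rate equations (mean
#' rate and mean membrane potential per population) in the thermodynamic
#' limit. The model is integrated in its nondimensional form, in which the
#' unit of time is `tau_m / sqrt(eta_ref)` seconds, where `eta_ref` is the
#' dimensional reference drive of the inhibitory population used in the
#' rescaling (see [nondimensionalize_fre()]).
#'
#' `d_e` and `d_i` are the rescaled Lorentzian half-widths of the excitatory
#' and inhibitory drive distributions; they act as bifurcation parameters: a
#' Hopf bifurcation curve in the (d_e, d_i) plane separates damped from
#' self-sustained rate oscillations (see [locate_hopf_curve()]). The default
#' couplings place the homogeneous node near that curve (critical
#' `d_i* ~ 0.85` at `d_e = 1`), with the default `d_i = 1` slightly on the
#' damped side. The rate equations are noise-free in the exact reduction;
#' additive Gaussian noise of standard deviation `noise_v` on the voltage
#' equations is an extension that produces fluctuating activity below the
#' bifurcation.
#'
#' @param n_regions number of regions N.
#' @param d_e,d_i rescaled Lorentzian half-widths, scalar or length-N vectors.
#' @param eta rescaled excitatory drive.
#' @param j_ee,j_ei,j_ie,j_ii rescaled synaptic strengths (E-to-E, I-to-E,
#'   E-to-I, I-to-I); `j_ei` and `j_ii` are negative.
#' @param G global coupling gain; inter-regional coupling enters only the
#'   excitatory voltage equation as `G * j_ee * sum_p C_np r_e^p`.
#' @param tau_m membrane time constant (s).
#' @param eta_ref dimensional reference drive used by the rescaling.
#' @param noise_v noise s.d. on the voltage equations (0 = exact reduction).
#' @param dt integration step in nondimensional time.
#' @param duration simulated time kept after the transient (s, real time).
#' @param transient initial real time discarded (s).
#' @return An object of class `fre_params`.
#' @export
fre_params <- function(n_regions, d_e = 1, d_i = 1, eta = 4.03,
                       j_ee = 5.04, j_ei = -10.2, j_ie = 10.2,
                       j_ii = -2.04, G = 0, tau_m = 0.010, eta_ref = 1,
                       noise_v = 0.02, dt = 1e-3, duration = 60,
                       transient = 2) {
  if (length(d_e) == 1) d_e <- rep(d_e, n_regions)
  if (length(d_i) == 1) d_i <- rep(d_i, n_regions)
  if (length(d_e) != n_regions || length(d_i) != n_regions)
    stop("d_e and d_i must be scalars or length n_regions")
  if (any(d_e <= 0) || any(d_i <= 0))
    stop("d_e and d_i must be positive")
  if (tau_m <= 0 || eta_ref <= 0)
    stop("tau_m and eta_ref must be positive")
  if (G < 0 || noise_v < 0 || dt <= 0 || duration <= 0)
    stop("G and noise_v must be nonnegative; dt and duration positive")
  structure(list(n_regions = n_regions, d_e = d_e, d_i = d_i, eta = eta,
                 j_ee = j_ee, j_ei = j_ei, j_ie = j_ie, j_ii = j_ii,
                 G = G, tau_m = tau_m, eta_ref = eta_ref,
                 noise_v = noise_v, dt = dt, duration = duration,
                 transient = transient),
            class = "fre_params")
}

# Seconds of real time per nondimensional time unit.
fre_time_unit <- function(params) params$tau_m / sqrt(params$eta_ref)

#' Heterogeneity-modulated Lorentzian half-widths
#'
#' Applies the same bias/scale modulation as [heterogeneous_a()] to the
#' excitatory and inhibitory half-widths simultaneously. Values driven to or
#' below zero are clipped to `floor` with a warning (half-widths must stay
#' positive).
#'
#' @param d0_e,d0_i homogeneous half-widths.
#' @param bias,scale modulation parameters; `(0, 0)` recovers the homogeneous
#'   values.
#' @param map a [heterogeneity_map()].
#' @param mode `"multiplicative"` or `"additive"` (see [heterogeneous_a()]).
#' @param floor positive lower clip for the modulated half-widths.
#' @return List with vectors `d_e` and `d_i`.
#' @export
heterogeneous_d <- function(d0_e, d0_i, bias, scale, map,
                            mode = c("multiplicative", "additive"),
                            floor = 1e-3) {
  mode <- match.arg(mode)
  stopifnot(inherits(map, "heterogeneity_map"))
  mod <- switch(mode,
                multiplicative = 1 + bias + scale * map$beta,
                additive = NULL)
  if (mode == "multiplicative") {
    d_e <- d0_e * mod
    d_i <- d0_i * mod
  } else {
    d_e <- d0_e + bias + scale * map$beta
    d_i <- d0_i + bias + scale * map$beta
  }
  n_clip <- sum(d_e < floor) + sum(d_i < floor)
  if (n_clip > 0) {
    warning(n_clip, " modulated half-width value(s) clipped to ", floor)
    d_e <- pmax(d_e, floor)
    d_i <- pmax(d_i, floor)
  }
  list(d_e = d_e, d_i = d_i)
}

#' Fixed point of one uncoupled excitatory-inhibitory node
#'
#' Solves the quiescent fixed point of the nondimensional rate equations for
#' one region (no inter-regional coupling): `0 = d/pi + 2 r v` for both
#' populations together with the two voltage equations, by minimising the
#' squared residual over (log r_e, log r_i) from several starting points.
#'
#' @param d_e,d_i half-widths (scalars).
#' @param params an [fre_params()] supplying `eta` and the couplings.
#' @return List with elements `r_e`, `v_e`, `r_i`, `v_i` and `residual`.
#' @export
fre_fixed_point <- function(d_e, d_i, params) {
  eta <- params$eta
  j_ee <- params$j_ee; j_ei <- params$j_ei
  j_ie <- params$j_ie; j_ii <- params$j_ii
  resid <- function(p) {
    re <- exp(p[1]); ri <- exp(p[2])
    ve <- -d_e / (2 * pi * re); vi <- -d_i / (2 * pi * ri)
    c(ve^2 + eta - (pi * re)^2 + j_ee * re + j_ei * ri,
      vi^2 + 1 - (pi * ri)^2 + j_ii * ri + j_ie * re)
  }
  best <- NULL
  for (s in list(c(-1, -1), c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(-2, -2))) {
    o <- tryCatch(optim(s, function(p) sum(resid(p)^2), method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-16)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best) || best$value > 1e-10)
    stop("fixed-point search did not converge (residual ",
         format(if (is.null(best)) NA else best$value), ")")
  r_e <- exp(best$par[1]); r_i <- exp(best$par[2])
  list(r_e = r_e, v_e = -d_e / (2 * pi * r_e),
       r_i = r_i, v_i = -d_i / (2 * pi * r_i),
       residual = best$value)
}

# Jacobian of the 4-D uncoupled node at a fixed point, state order
# (r_e, v_e, r_i, v_i).
fre_node_jacobian <- function(fp, params) {
  with(fp, rbind(
    c(2 * v_e, 2 * r_e, 0, 0),
    c(-2 * pi^2 * r_e + params$j_ee, 2 * v_e, params$j_ei, 0),
    c(0, 0, 2 * v_i, 2 * r_i),
    c(params$j_ie, 0, -2 * pi^2 * r_i + params$j_ii, 2 * v_i)))
}

# Largest real part of the node Jacobian eigenvalues at (d_e, d_i).
fre_max_eigen_real <- function(d_e, d_i, params) {
  fp <- fre_fixed_point(d_e, d_i, params)
  max(Re(eigen(fre_node_jacobian(fp, params), only.values = TRUE)$values))
}

#' Locate the Hopf bifurcation curve in the (d_e, d_i) plane
#'
#' For each requested excitatory half-width, bisects on the inhibitory
#' half-width for the sign change of the largest real part of the Jacobian
#' eigenvalues of the uncoupled node's fixed point. A `d_e` for which no sign
#' change exists inside `d_i_range` is flagged with `NA`.
#'
#' @param d_e_values vector of excitatory half-widths to scan.
#' @param params an [fre_params()] supplying drive and couplings.
#' @param d_i_range search interval for the inhibitory half-width.
#' @param tol root tolerance on the eigenvalue real part crossing.
#' @param n_scan coarse-grid size used to bracket the sign change.
#' @return Data frame with columns `d_e`, `d_i` (critical value or `NA`) and
#'   `max_re` (eigenvalue real part at the returned point).
#' @export
locate_hopf_curve <- function(d_e_values, params = fre_params(1),
                              d_i_range = c(0.05, 5), tol = 1e-8,
                              n_scan = 25) {
  rows <- lapply(d_e_values, function(de) {
    g <- function(di) fre_max_eigen_real(de, di, params)
    grid <- seq(d_i_range[1], d_i_range[2], length.out = n_scan)
    vals <- vapply(grid, function(di) tryCatch(g(di), error = function(e) NA_real_),
                   numeric(1))
    ok <- which(!is.na(vals))
    w <- ok[which(diff(sign(vals[ok])) != 0)]
    if (length(w) == 0)
      return(data.frame(d_e = de, d_i = NA_real_, max_re = NA_real_))
    i <- w[1]
    j <- ok[which(ok > i)][1]
    root <- uniroot(g, c(grid[i], grid[j]), tol = tol)$root
    data.frame(d_e = de, d_i = root, max_re = g(root))
  })
  do.call(rbind, rows)
}

#' Simulate the exact mean-field whole-brain network
#'
#' Euler(-Maruyama) integration of the nondimensional rate equations for all
#' regions, coupled through the connectome at the excitatory-to-excitatory
#' level. Initial conditions sit at the uncoupled homogeneous fixed point
#' plus small seeded perturbations. The transient is discarded.
#'
#' @param params an [fre_params()].
#' @param bundle a [connectome_bundle()].
#' @param seed integer seed.
#' @param out_dt output sampling interval in seconds (rates are kept every
#'   `round(out_dt / (dt * time_unit))` steps); defaults to 10 ms.
#' @return Region x sample matrix of excitatory rates (nondimensional), with
#'   attribute `dt_s` giving the output sampling interval in seconds.
#' @export
simulate_fre_network <- function(params, bundle, seed = 1L, out_dt = 0.01) {
  stopifnot(inherits(params, "fre_params"),
            inherits(bundle, "connectome_bundle"))
  if (bundle$n_regions != params$n_regions)
    stop("params built for ", params$n_regions, " regions but connectome has ",
         bundle$n_regions)
  tu <- fre_time_unit(params)
  stride <- max(1L, as.integer(round(out_dt / (params$dt * tu))))
  n_tr <- as.integer(round(params$transient / (params$dt * tu)))
  n_steps <- n_tr + as.integer(round(params$duration / (params$dt * tu)))
  fp <- fre_fixed_point(mean(params$d_e), mean(params$d_i), params)
  set.seed(seed)
  n <- params$n_regions
  re0 <- pmax(fp$r_e + rnorm(n, sd = 0.01 * fp$r_e), 1e-4)
  ri0 <- pmax(fp$r_i + rnorm(n, sd = 0.01 * fp$r_i), 1e-4)
  ve0 <- fp$v_e + rnorm(n, sd = 0.01)
  vi0 <- fp$v_i + rnorm(n, sd = 0.01)
  out <- cpp_simulate_fre(params$d_e, params$d_i, params$eta, params$j_ee,
                          params$j_ei, params$j_ie, params$j_ii, params$G,
                          bundle$C, params$noise_v, params$dt, n_steps,
                          n_tr, stride, re0, ve0, ri0, vi0)
  rownames(out) <- bundle$labels
  attr(out, "dt_s") <- stride * params$dt * tu
  out
}

#' Nondimensionalize (and re-dimensionalize) mean-field quantities
#'
#' Maps dimensional firing-rate-equation quantities onto their rescaled
#' counterparts: \eqn{r = \tau_m R/\sqrt{\eta_{ref}}},
#' \eqn{v = V/\sqrt{\eta_{ref}}}, \eqn{\tilde t = \sqrt{\eta_{ref}}\, t/\tau_m},
#' \eqn{j = J/\sqrt{\eta_{ref}}}, \eqn{d = \Delta/\eta_{ref}},
#' \eqn{\eta = \bar\eta/\eta_{ref}}. The square roots are
#' required for the dimensional rate equations to map exactly onto the
#' rescaled ones (verified by the package's dual-integration test); the
#' half-widths and drives rescale linearly. [dimensionalize_fre()] is the
#' exact inverse.
#'
#' @param x named list holding any subset of the dimensional fields `R`, `V`,
#'   `t`, `J`, `Delta`, `eta_bar` (vectors allowed).
#' @param eta_ref positive dimensional reference drive.
#' @param tau_m membrane time constant (s).
#' @return Named list with the corresponding rescaled fields `r`, `v`,
#'   `t_tilde`, `j`, `d`, `eta`.
#' @export
nondimensionalize_fre <- function(x, eta_ref, tau_m = 0.010) {
  if (eta_ref <= 0) stop("eta_ref must be positive")
  s <- sqrt(eta_ref)
  out <- list()
  if (!is.null(x$R)) out$r <- tau_m * x$R / s
  if (!is.null(x$V)) out$v <- x$V / s
  if (!is.null(x$t)) out$t_tilde <- s * x$t / tau_m
  if (!is.null(x$J)) out$j <- x$J / s
  if (!is.null(x$Delta)) out$d <- x$Delta / eta_ref
  if (!is.null(x$eta_bar)) out$eta <- x$eta_bar / eta_ref
  out
}

#' @param y named list holding any subset of the rescaled fields `r`, `v`,
#'   `t_tilde`, `j`, `d`, `eta`.
#' @rdname nondimensionalize_fre
#' @export
dimensionalize_fre <- function(y, eta_ref, tau_m = 0.010) {
  if (eta_ref <= 0) stop("eta_ref must be positive")
  s <- sqrt(eta_ref)
  out <- list()
  if (!is.null(y$r)) out$R <- s * y$r / tau_m
  if (!is.null(y$v)) out$V <- s * y$v
  if (!is.null(y$t_tilde)) out$t <- tau_m * y$t_tilde / s
  if (!is.null(y$j)) out$J <- s * y$j
  if (!is.null(y$d)) out$Delta <- eta_ref * y$d
  if (!is.null(y$eta)) out$eta_bar <- eta_ref * y$eta
  out
}

#' Integrate one population's rate equations (dimensional or rescaled)
#'
#' Deterministic RK4 integrators for a single all-to-all population, used for
#' cross-checking the network integrator, the nondimensionalization and the
#' microscopic QIF simulation. The dimensional form is
#' `tau_m dR/dt = Delta/(pi tau_m) + 2 R V`,
#' `tau_m dV/dt = V^2 + eta_bar - (pi tau_m R)^2 + J tau_m R`; the rescaled
#' form is `r' = d/pi + 2 r v`, `v' = v^2 + eta + j r - (pi r)^2`.
#'
#' @param state0 numeric `c(R, V)` (or `c(r, v)`) initial state.
#' @param times increasing vector of output times (s, or nondimensional).
#' @param Delta,eta_bar,J,tau_m dimensional parameters.
#' @return Matrix with columns `time`, `R`, `V` (or `t_tilde`, `r`, `v`).
#' @export
integrate_fre_dimensional <- function(state0, times, Delta, eta_bar, J,
                                      tau_m = 0.010) {
  f <- function(s) {
    R <- s[1]; V <- s[2]
    c((Delta / (pi * tau_m) + 2 * R * V) / tau_m,
      (V^2 + eta_bar - (pi * tau_m * R)^2 + J * tau_m * R) / tau_m)
  }
  rk4_path(state0, times, f, c("R", "V"))
}

#' @param d,eta,j rescaled parameters.
#' @rdname integrate_fre_dimensional
#' @export
integrate_fre_rescaled <- function(state0, times, d, eta, j) {
  f <- function(s) {
    r <- s[1]; v <- s[2]
    c(d / pi + 2 * r * v,
      v^2 + eta - (pi * r)^2 + j * r)
  }
  rk4_path(state0, times, f, c("r", "v"))
}

# Fixed-step RK4 along `times`, refining each interval into steps of at most
# `h_max` (relative to the interval length).
rk4_path <- function(state0, times, f, names, n_sub = 20L) {
  out <- matrix(NA_real_, length(times), 1 + length(state0))
  colnames(out) <- c("time", names)
  s <- as.numeric(state0)
  out[1, ] <- c(times[1], s)
  for (k in seq_len(length(times) - 1)) {
    h <- (times[k + 1] - times[k]) / n_sub
    for (m in seq_len(n_sub)) {
      k1 <- f(s)
      k2 <- f(s + h / 2 * k1)
      k3 <- f(s + h / 2 * k2)
      k4 <- f(s + h * k3)
      s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[k + 1, ] <- c(times[k + 1], s)
  }
  out
}

#' Parameters of a microscopic QIF population
#'
#' A finite population of quadratic integrate-and-fire neurons with
#' heterogeneous drives on a deterministic Lorentzian quantile grid,
#' `eta_k = eta_center + delta * tan(pi/2 * (2k - n - 1)/(n + 1))`, recurrent
#' coupling `J` mediated by the instantaneous population rate, and a finite
#' spike/reset proxy `v_reset = -v_threshold` for the infinite threshold of
#' the exact reduction.
#'
#' @param n_neurons population size (at least 100).
#' @param eta_center,delta centre and half-width of the Lorentzian drive.
#' @param J recurrent coupling strength.
#' @param tau_m membrane time constant (s).
#' @param v_threshold spike threshold (reset at `-v_threshold`).
#' @return An object of class `qif_params`.
#' @export
qif_params <- function(n_neurons = 10000, eta_center = 1, delta = 1, J = 0,
                       tau_m = 0.010, v_threshold = 100) {
  if (n_neurons < 100) stop("n_neurons must be at least 100")
  if (delta < 0 || tau_m <= 0 || v_threshold <= 0)
    stop("delta nonnegative; tau_m and v_threshold positive")
  structure(list(n_neurons = as.integer(n_neurons), eta_center = eta_center,
                 delta = delta, J = J, tau_m = tau_m,
                 v_threshold = v_threshold),
            class = "qif_params")
}

#' Simulate a microscopic QIF population
#'
#' Euler integration with spike-and-reset. The population rate is the spike
#' count per step divided by `n dt`; a smoothed rate is additionally returned
#' from a centred sliding window.
#'
#' @param qif a [qif_params()].
#' @param duration simulated time (s).
#' @param dt integration step (s).
#' @param seed seed for the initial membrane potentials.
#' @param rate_window width (s) of the sliding window for the smoothed rate;
#'   must be at least `dt`.
#' @return List with `time`, `rate` (instantaneous), `rate_smooth`, `v_mean`
#'   and the drive grid `eta`.
#' @export
simulate_qif_population <- function(qif, duration = 2, dt = 2e-5, seed = 1L,
                                    rate_window = 0.05) {
  stopifnot(inherits(qif, "qif_params"))
  if (rate_window < dt) stop("rate_window shorter than dt")
  n <- qif$n_neurons
  k <- seq_len(n)
  eta <- qif$eta_center +
    qif$delta * tan(pi / 2 * (2 * k - n - 1) / (n + 1))
  set.seed(seed)
  v0 <- runif(n, -2, 2)
  n_steps <- as.integer(round(duration / dt))
  sim <- cpp_simulate_qif(eta, qif$J, qif$tau_m, qif$v_threshold, dt,
                          n_steps, v0)
  w <- max(1L, as.integer(round(rate_window / dt)))
  kern <- rep(1 / w, w)
  smooth <- stats::filter(sim$rate, kern, sides = 2)
  list(time = seq_len(n_steps) * dt, rate = sim$rate,
       rate_smooth = as.numeric(smooth), v_mean = sim$v_mean, eta = eta)
}

#' Balloon-Windkessel hemodynamic constants
#'
#' Standard literature values: signal decay `kappa` (1/s), autoregulation
#' `gamma` (1/s), transit time `tau` (s), Grubb exponent `alpha`, resting
#' oxygen extraction `rho`, resting venous volume fraction `V0`.
#'
#' @param kappa,gamma,tau,alpha,rho,V0 positive constants.
#' @return An object of class `hemodynamic_params`.
#' @export
hemodynamic_params <- function(kappa = 0.65, gamma = 0.41, tau = 0.98,
                               alpha = 0.32, rho = 0.34, V0 = 0.02) {
  vals <- c(kappa, gamma, tau, alpha, rho, V0)
  if (any(vals <= 0)) stop("all hemodynamic constants must be positive")
  structure(list(kappa = kappa, gamma = gamma, tau = tau, alpha = alpha,
                 rho = rho, V0 = V0), class = "hemodynamic_params")
}

#' Transform firing rates into BOLD-like signals
#'
#' Drives the standard four-state hemodynamic model (vasodilatory signal,
#' inflow, venous volume, deoxyhemoglobin) with the z-scored rate of each
#' region and applies the nonlinear BOLD readout, then downsamples to the
#' repetition time. A constant (zero-variance) rate drives the model with
#' zeros and yields a constant BOLD level.
#'
#' @param rates region x sample matrix of rates sampled at `dt`.
#' @param dt sampling interval of `rates` (s).
#' @param tr output repetition time (s).
#' @param hemo a [hemodynamic_params()].
#' @return Region x sample BOLD matrix sampled at `tr`.
#' @export
balloon_windkessel <- function(rates, dt, tr, hemo = hemodynamic_params()) {
  stopifnot(inherits(hemo, "hemodynamic_params"))
  rates <- as.matrix(rates)
  z <- t(apply(rates, 1, function(r) {
    s <- sd(r)
    if (s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  bold <- cpp_balloon_windkessel(z, dt, hemo$kappa, hemo$gamma, hemo$tau,
                                 hemo$alpha, hemo$rho, hemo$V0)
  stride <- max(1L, as.integer(round(tr / dt)))
  keep <- seq(1L, ncol(bold), by = stride)
  out <- bold[, keep, drop = FALSE]
  rownames(out) <- rownames(rates)
  out
}

#' Simulate mean-field BOLD for one trial
#'
#' Convenience chain: [simulate_fre_network()] then [balloon_windkessel()].
#'
#' @inheritParams simulate_fre_network
#' @param tr repetition time of the output BOLD (s).
#' @param hemo a [hemodynamic_params()].
#' @return Region x sample BOLD matrix at `tr`.
#' @export
simulate_meanfield_bold <- function(params, bundle, seed = 1L, tr = 0.72,
                                    hemo = hemodynamic_params()) {
  rates <- simulate_fre_network(params, bundle, seed = seed)
  balloon_windkessel(rates, attr(rates, "dt_s"), tr, hemo)
}
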