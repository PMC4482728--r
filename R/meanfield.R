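# Siegert transfer function and the coupled k-population rate equations.

#' LIF neuron parameters
#'
#' Membrane and synapse constants of the leaky integrate-and-fire model.
#' Internally all computations use mV and ms; rates are reported in Hz.  The
#' derived threshold rate \code{nu_thr = theta / (J * tau)} (in 1/ms) is the
#' external Poisson rate at which the mean drive alone reaches threshold;
#' stimuli \code{s} are expressed in units of \code{nu_thr}, so \code{s = 1}
#' marks the boundary between sub- and supra-threshold external drive.
#'
#' Defaults are the cortical parameter set of the classic sparse-network
#' literature: \code{tau = 20} ms, \code{tau_ref = 2} ms, \code{theta = 20}
#' mV, \code{v_reset = 10} mV, \code{J = 0.1} mV.
#'
#' @param tau membrane time constant (ms).
#' @param tau_ref absolute refractory period (ms).
#' @param theta firing threshold (mV).
#' @param v_reset reset potential (mV).
#' @param J postsynaptic potential amplitude per spike (mV).
#' @return An object of class \code{"neuron_params"}.
#' @export
neuron_params <- function(tau = 20, tau_ref = 2, theta = 20, v_reset = 10,
                          J = 0.1) {
  if (tau <= 0 || tau_ref <= 0 || J <= 0)
    stop("'tau', 'tau_ref' and 'J' must be positive")
  if (theta <= v_reset) stop("'theta' must exceed 'v_reset'")
  structure(list(tau = tau, tau_ref = tau_ref, theta = theta,
                 v_reset = v_reset, J = J, nu_thr = theta / (J * tau)),
            class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf(
    "LIF parameters: tau=%g ms, tau_ref=%g ms, theta=%g mV, v_reset=%g mV, J=%g mV\n",
    x$tau, x$tau_ref, x$theta, x$v_reset, x$J))
  cat(sprintf("  nu_thr = theta/(J tau) = %g /ms (%g kHz)\n", x$nu_thr, x$nu_thr))
  invisible(x)
}

#' Siegert transfer function
#'
#' Stationary firing rate of an LIF neuron receiving Gaussian white current
#' with mean \code{mu} and noise SD \code{sigma} (both mV):
#' \deqn{r = \left[\tau_{ref} + \tau\sqrt{\pi}
#'   \int_{(V_r-\mu)/\sigma}^{(\Theta-\mu)/\sigma}
#'   e^{x^2}(1+\mathrm{erf}(x))\,dx\right]^{-1}.}
#' The integrand is evaluated through the scaled complementary error function
#' and the Dawson integral so that large \eqn{|x|} neither overflows nor loses
#' precision.  At \code{sigma = 0} the noiseless limit is returned: 0 below
#' threshold, \eqn{[\tau_{ref} + \tau\ln((\mu-V_r)/(\mu-\Theta))]^{-1}} above.
#'
#' @param mu input mean (mV); recycled against \code{sigma}.
#' @param sigma input noise SD (mV), must be >= 0.
#' @param params a \code{"neuron_params"} object.
#' @return firing rate(s) in Hz.
#' @examples
#' p <- neuron_params()
#' siegert_rate(24, sqrt(0.1 * 24), p)  # supra-threshold drive
#' @export
siegert_rate <- function(mu, sigma, params = neuron_params()) {
  stopifnot(inherits(params, "neuron_params"))
  if (any(sigma < 0)) stop("'sigma' must be >= 0")
  n <- max(length(mu), length(sigma))
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  1000 * siegert_rate_cpp(mu, sigma, params$tau, params$tau_ref,
                          params$theta, params$v_reset)
}

#' Input moments of the k-populations
#'
#' Mean and variance of the Gaussian-approximated synaptic input of each
#' in-degree class: \eqn{\mu_k = J\tau(\nu_{thr} s + \sum_{k'} N_{kk'}
#' \hat r_{k'})} and \eqn{\sigma_k^2 = J \mu_k} (delta-pulse synapses of
#' uniform amplitude \code{J}).
#'
#' @param kernel a \code{"connection_kernel"}.
#' @param rates_hz per-class firing rates (Hz), aligned with
#'   \code{kernel$degrees}.
#' @param s stimulus in units of \code{nu_thr}.
#' @param params a \code{"neuron_params"}.
#' @return list with \code{mu} (mV) and \code{sigma_sq} (mV^2) per class.
#' @export
input_moments <- function(kernel, rates_hz, s, params = neuron_params()) {
  stopifnot(inherits(kernel, "connection_kernel"))
  if (length(rates_hz) != length(kernel$degrees))
    stop("'rates_hz' must align with the kernel degree support")
  if (any(rates_hz < 0)) stop("negative rates")
  r <- rates_hz / 1000  # 1/ms
  mu <- params$J * params$tau *
    (params$nu_thr * s + unname(drop(kernel$N %*% r)))
  list(mu = mu, sigma_sq = params$J * mu)
}

#' Solve the coupled self-consistent rate equations
#'
#' Relaxes \eqn{\tau_x \, d\hat r_k/dt = -\hat r_k + \phi_k(\hat r, s)} by
#' explicit Euler steps (\code{dt = tau_x / 3}) until the fixed-point residual
#' \eqn{\max_k |\phi_k(\hat r) - \hat r_k|} drops below \code{tol}.  The
#' stationary rates satisfy the self-consistency condition of the k-population
#' mean-field model.  Initialization at high rates (default 80 % of the
#' refractory bound) selects the stable upper branch wherever the system is
#' bistable.
#'
#' @param kernel a \code{"connection_kernel"}.
#' @param s stimulus in units of \code{nu_thr}.
#' @param params a \code{"neuron_params"}.
#' @param init initial rates in Hz (scalar or per class).
#' @param tau_x relaxation time constant (ms).
#' @param tol convergence tolerance on the residual (Hz).
#' @param t_max maximum relaxation time (ms).
#' @return An object of class \code{"population_rates"}: list with
#'   \code{degrees}, \code{rates} (Hz), \code{s}, \code{converged},
#'   \code{steps}, \code{residual} (Hz).
#' @export
solve_selfconsistent <- function(kernel, s, params = neuron_params(),
                                 init = 0.8 * 1000 / params$tau_ref,
                                 tau_x = 3, tol = 1e-6, t_max = 2000 * tau_x) {
  stopifnot(inherits(kernel, "connection_kernel"))
  if (tau_x <= 0) stop("'tau_x' must be positive")
  m <- length(kernel$degrees)
  init <- rep_len(init, m)
  if (any(init < 0) || any(init > 1000 / params$tau_ref))
    stop("'init' must lie within [0, 1000/tau_ref] Hz")
  dt <- tau_x / 3
  res <- relax_rates_cpp(kernel$N, params$nu_thr * s, init / 1000, params$J,
                         params$tau, params$tau_ref, params$theta,
                         params$v_reset, tau_x, dt, tol / 1000,
                         as.integer(ceiling(t_max / dt)))
  if (!res$converged)
    warning(sprintf("no fixed point within t_max = %g ms (residual %.3g Hz)",
                    t_max, res$residual * 1000))
  structure(list(degrees = kernel$degrees, rates = res$rates * 1000, s = s,
                 converged = res$converged, steps = res$steps,
                 residual = res$residual * 1000),
            class = "population_rates")
}

#' @export
print.population_rates <- function(x, ...) {
  cat(sprintf("Stationary k-population rates at s = %g (%d classes)\n",
              x$s, length(x$degrees)))
  cat(sprintf("  range [%.3f, %.3f] Hz, residual %.2g Hz (%s)\n",
              min(x$rates), max(x$rates), x$residual,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' One-dimensional uncorrelated-network solver
#'
#' For networks whose in- and out-degrees are drawn independently, the coupled
#' equations collapse to a single self-consistent equation for the mean rate:
#' \eqn{\hat r = \sum_k P(k) \phi_k(\hat r)} with
#' \eqn{\mu_k = J\tau(\nu_{thr} s + k \hat r)}.  Solved by the same relaxation
#' scheme as the coupled system.
#'
#' @inheritParams solve_selfconsistent
#' @param dist a \code{"degree_dist"}.
#' @return list with \code{rate} (mean rate, Hz), \code{rates} (per class,
#'   Hz), \code{converged}.
#' @export
solve_scalar_uncorrelated <- function(dist, s, params = neuron_params(),
                                      init = 0.8 * 1000 / params$tau_ref,
                                      tau_x = 3, tol = 1e-6,
                                      t_max = 2000 * tau_x) {
  stopifnot(inherits(dist, "degree_dist"))
  r <- init / 1000  # 1/ms
  dt <- tau_x / 3
  Jt <- params$J * params$tau
  converged <- FALSE
  for (i in seq_len(ceiling(t_max / dt))) {
    mu <- Jt * (params$nu_thr * s + dist$k * r)
    phi <- siegert_rate_cpp(mu, sqrt(params$J * mu), params$tau,
                            params$tau_ref, params$theta, params$v_reset)
    rbar <- sum(dist$pmf * phi)
    if (abs(rbar - r) < tol / 1000) {
      converged <- TRUE
      r <- rbar
      break
    }
    r <- r + (dt / tau_x) * (rbar - r)
  }
  if (!converged) warning("scalar solver did not converge within t_max")
  mu <- Jt * (params$nu_thr * s + dist$k * r)
  phi <- siegert_rate_cpp(mu, sqrt(params$J * mu), params$tau, params$tau_ref,
                          params$theta, params$v_reset)
  list(rate = 1000 * sum(dist$pmf * phi), rates = 1000 * phi,
       converged = converged)
}

#' Stimulus-response curve by continuation
#'
#' Sweeps the stimulus grid and solves the coupled rate equations at each
#' point, initializing from the neighboring solution.  The default downward
#' sweep starts at the largest \code{s} from a high-rate state, which tracks
#' the stable upper branch of the bistable system; an upward sweep from a
#' quiescent state tracks the lower branch.  Returns the population mean rate
#' \eqn{\hat r(s) = \sum_k P(k) \hat r_k} and the population rate SD
#' \eqn{\sigma(s) = \sqrt{\sum_k P(k) (\hat r_k - \hat r)^2}}.
#'
#' @inheritParams solve_selfconsistent
#' @param s_grid sorted stimulus grid (units of \code{nu_thr}).
#' @param weights class weights \eqn{P(k)}; defaults to the kernel's own
#'   weights (empirical class proportions for sampled kernels, the pmf for
#'   analytic kernels).
#' @param direction \code{"down"} (default, upper branch) or \code{"up"}.
#' @param init_high,init_low initial rates (Hz) for the first solve of a
#'   downward / upward sweep.
#' @param keep_rates if \code{TRUE} (default) the per-class rate matrix is
#'   stored in the result.
#' @return An object of class \code{"response_curve"}: list with \code{s},
#'   \code{r_mean} (Hz), \code{sigma} (Hz), \code{branch}, \code{converged},
#'   \code{degrees}, \code{weights} and optionally \code{rates}
#'   (classes x stimuli matrix, Hz).
#' @export
response_curve <- function(kernel, s_grid = seq(0, 1.2, by = 0.02),
                           params = neuron_params(), weights = NULL,
                           direction = c("down", "up"),
                           init_high = 0.8 * 1000 / params$tau_ref,
                           init_low = 0, tau_x = 3, tol = 1e-6,
                           t_max = 2000 * tau_x, keep_rates = TRUE) {
  stopifnot(inherits(kernel, "connection_kernel"))
  direction <- match.arg(direction)
  if (is.unsorted(s_grid)) stop("'s_grid' must be sorted increasing")
  if (is.null(weights)) weights <- kernel$weights
  if (is.null(weights)) stop("no class weights available; supply 'weights'")
  weights <- weights / sum(weights)
  m <- length(kernel$degrees)
  ord <- if (direction == "down") rev(seq_along(s_grid)) else seq_along(s_grid)
  init <- rep_len(if (direction == "down") init_high else init_low, m)
  rates <- matrix(NA_real_, m, length(s_grid))
  conv <- logical(length(s_grid))
  for (i in ord) {
    sol <- solve_selfconsistent(kernel, s_grid[i], params, init = init,
                                tau_x = tau_x, tol = tol, t_max = t_max)
    rates[, i] <- sol$rates
    conv[i] <- sol$converged
    init <- sol$rates
  }
  r_mean <- drop(weights %*% rates)
  sigma <- sqrt(pmax(0, drop(weights %*% rates^2) - r_mean^2))
  out <- list(s = s_grid, r_mean = r_mean, sigma = sigma,
              branch = if (direction == "down") "upper" else "lower",
              converged = conv, degrees = kernel$degrees, weights = weights)
  if (keep_rates) out$rates <- rates
  structure(out, class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf("Response curve (%s branch): s in [%g, %g], %d points\n",
              x$branch, min(x$s), max(x$s), length(x$s)))
  cat(sprintf("  r_mean in [%.3f, %.3f] Hz; sigma up to %.3f Hz\n",
              min(x$r_mean), max(x$r_mean), max(x$sigma)))
  invisible(x)
}

#' Stimulus threshold of sustained activity
#'
#' Locates the extinction point of recurrent activity on a downward
#' continuation curve: the largest grid stimulus at which the mean rate is
#' below \code{epsilon} while it exceeds \code{epsilon} at the next grid
#' point.  Reported as the midpoint of the bracketing interval; the grid step
#' is the uncertainty.
#'
#' @param curve a \code{"response_curve"} (upper branch).
#' @param epsilon dead-network rate threshold (Hz).
#' @return list with \code{s_star} and \code{uncertainty} (the grid step).
#' @export
stimulus_threshold <- function(curve, epsilon = 0.1) {
  stopifnot(inherits(curve, "response_curve"))
  dead <- curve$r_mean < epsilon
  idx <- which(dead[-length(dead)] & !dead[-1L])
  if (!length(idx))
    stop("no extinction crossing on the stimulus grid")
  i <- max(idx)
  list(s_star = (curve$s[i] + curve$s[i + 1L]) / 2,
       uncertainty = curve$s[i + 1L] - curve$s[i])
}

#' Firing-rate distribution across the network
#'
#' Approximates the distribution of single-neuron firing rates by assuming
#' all neurons of a k-population fire at the population rate, so rate
#' \eqn{\hat r_k} carries probability mass \eqn{P(k)}; the masses are binned
#' and normalized to unit total.
#'
#' @param rates per-class rates (Hz).
#' @param weights class probabilities \eqn{P(k)} (normalized internally).
#' @param breaks bin edges (Hz) covering the rate range, or a single bin
#'   count.
#' @return data frame with \code{lower}, \code{upper}, \code{mass},
#'   \code{density}.
#' @export
firing_rate_distribution <- function(rates, weights, breaks = 30) {
  if (length(rates) != length(weights))
    stop("'rates' and 'weights' must have equal length")
  weights <- weights / sum(weights)
  if (length(breaks) == 1L) {
    if (breaks < 1) stop("need at least one bin")
    rng <- range(rates)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1L], rng[2L], length.out = breaks + 1L)
  }
  if (length(breaks) < 2L) stop("'breaks' must define at least one bin")
  bin <- cut(rates, breaks, include.lowest = TRUE)
  mass <- as.numeric(tapply(weights, bin, sum, default = 0))
  data.frame(lower = head(breaks, -1L), upper = tail(breaks, -1L),
             mass = mass, density = mass / diff(breaks))
}
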