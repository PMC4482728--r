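# Direct simulation of the LIF network (verification oracle) and readout.

#' Simulation configuration
#'
#' @param s stimulus in units of \code{nu_thr}.
#' @param dt integration step (ms).
#' @param t_measure measurement duration (ms); spikes are counted over this
#'   window.
#' @param burn_in discarded initial duration (ms) to reach stationarity.
#' @param seed optional integer seed.
#' @return An object of class \code{"sim_config"}.
#' @export
sim_config <- function(s, dt = 0.01, t_measure = 1000, burn_in = 200,
                       seed = NULL) {
  if (dt <= 0 || t_measure <= 0 || burn_in < 0)
    stop("'dt' and 't_measure' must be positive, 'burn_in' nonnegative")
  structure(list(s = s, dt = dt, t_measure = t_measure, burn_in = burn_in,
                 seed = seed), class = "sim_config")
}

#' Simulate the LIF network
#'
#' Forward-Euler integration of the delayed pulse-coupled LIF network at
#' resolution \code{config$dt}.  Every neuron receives an independent Poisson
#' spike train of rate \code{s * nu_thr}, each event depolarizing the membrane
#' by \code{J}; recurrent spikes arrive as \code{J}-pulses after their
#' per-edge synaptic delay (rounded to the integration grid, minimum one
#' step).  A threshold crossing emits a spike, resets the membrane to
#' \code{v_reset} and clamps it there for \code{tau_ref}, during which all
#' input is discarded.  Initial voltages are uniform on
#' \code{[v_reset, theta)}.
#'
#' @param network a \code{"lif_network"} (delays populated).
#' @param params a \code{"neuron_params"}.
#' @param config a \code{"sim_config"}.
#' @return An object of class \code{"spike_record"}: list with per-neuron
#'   \code{counts}, \code{rates_hz}, and the \code{t_measure} used.
#' @export
simulate_lif <- function(network, params = neuron_params(),
                         config = sim_config(s = 1.2)) {
  stopifnot(inherits(network, "lif_network"),
            inherits(params, "neuron_params"),
            inherits(config, "sim_config"))
  if (config$dt > params$tau_ref)
    stop("'dt' must not exceed the refractory period")
  if (any(network$delay_ms < config$dt))
    warning("delays below dt are rounded up to one integration step")
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- simulate_lif_cpp(network$from - 1L, network$to - 1L, network$delay_ms,
                          network$n, config$s, params$nu_thr, params$J,
                          params$tau, params$tau_ref, params$theta,
                          params$v_reset, config$dt, config$t_measure,
                          config$burn_in)
  structure(list(counts = res$counts, rates_hz = res$rates_hz,
                 t_measure = config$t_measure, s = config$s),
            class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("Spike record: %d neurons over %g ms, mean rate %.3f Hz\n",
              length(x$counts), x$t_measure, mean(x$rates_hz)))
  invisible(x)
}

#' Per-class population rates from a spike record
#'
#' Groups neurons by realized in-degree and averages their firing rates; this
#' is the simulation estimate of the k-population rates \eqn{\hat r_k}.
#'
#' @param record a \code{"spike_record"}.
#' @param network the simulated \code{"lif_network"}.
#' @return data frame with \code{degree}, \code{rate} (Hz) and
#'   \code{n_neurons}.
#' @export
population_rates_from_record <- function(record, network) {
  stopifnot(inherits(record, "spike_record"), inherits(network, "lif_network"))
  if (length(record$counts) != network$n)
    stop("record and network are inconsistent")
  deg <- network$in_degree
  degrees <- sort(unique(deg))
  grp <- factor(deg, levels = degrees)
  data.frame(degree = degrees,
             rate = as.numeric(tapply(record$rates_hz, grp, mean)),
             n_neurons = as.integer(table(grp)))
}

#' Population readout samples
#'
#' The network response \eqn{r} is the average firing rate of \code{n} neurons
#' sampled without replacement; repeated draws yield the readout noise
#' distribution, which for large \code{n} is approximately Gaussian with mean
#' \eqn{\hat r} and variance \eqn{\sigma^2 / n}.
#'
#' @param record a \code{"spike_record"}.
#' @param n readout size (number of neurons per draw).
#' @param n_draws number of independent draws.
#' @param seed optional integer seed.
#' @return numeric vector of \code{n_draws} readout rates (Hz).
#' @export
readout_sample <- function(record, n, n_draws = 1000, seed = NULL) {
  stopifnot(inherits(record, "spike_record"))
  N <- length(record$rates_hz)
  if (n > N) stop("'n' exceeds the network size")
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n_draws),
         function(i) mean(record$rates_hz[sample.int(N, n)]), 0)
}
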