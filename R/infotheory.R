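# Input/output mutual information of the stimulus -> population-rate channel.

#' Stimulus-response channel model
#'
#' Combines a mean-field response curve with the Gaussian readout-noise model:
#' conditioned on a stimulus \code{s}, the readout (mean rate of \code{n}
#' sampled neurons) is Gaussian with mean \eqn{\hat r(s)} and variance
#' \eqn{\sigma^2(s)/n}.  Stimuli are distributed uniformly on
#' \code{s_range} (the sub-threshold interval (0, 1) by default).
#'
#' @param curve a \code{"response_curve"}.
#' @param n readout size (neurons).
#' @param s_range support of the uniform stimulus prior.
#' @return An object of class \code{"channel_model"} holding the curve points
#'   that fall inside \code{s_range}.
#' @export
channel_model <- function(curve, n = 5000, s_range = c(0, 1)) {
  stopifnot(inherits(curve, "response_curve"))
  if (n < 1) stop("'n' must be >= 1")
  keep <- curve$s >= s_range[1L] & curve$s <= s_range[2L]
  if (sum(keep) < 3L) stop("fewer than 3 curve points inside 's_range'")
  structure(list(s = curve$s[keep], r = curve$r_mean[keep],
                 sigma = curve$sigma[keep], n = n, s_range = s_range,
                 branch = curve$branch),
            class = "channel_model")
}

#' @export
print.channel_model <- function(x, ...) {
  cat(sprintf("Stimulus channel: %d grid points on (%g, %g), readout n = %d\n",
              length(x$s), x$s_range[1L], x$s_range[2L], x$n))
  invisible(x)
}

#' Conditional readout distribution
#'
#' @param channel a \code{"channel_model"}.
#' @param s stimulus value inside the channel support (linearly interpolated
#'   on the curve grid).
#' @return list with \code{mean}, \code{sd} (\eqn{\sigma(s)/\sqrt{n}}) and a
#'   density function \code{pdf(r)}; for \code{sd = 0} the conditional is the
#'   degenerate (delta) distribution and \code{pdf} is \code{NA}-valued.
#' @export
conditional_response_pdf <- function(channel, s) {
  stopifnot(inherits(channel, "channel_model"))
  if (s < min(channel$s) || s > max(channel$s))
    stop("'s' outside the channel support")
  m <- approx(channel$s, channel$r, xout = s)$y
  sd <- approx(channel$s, channel$sigma, xout = s)$y / sqrt(channel$n)
  pdf <- if (sd > 0) function(r) dnorm(r, m, sd) else function(r) {
    ifelse(r == m, Inf, 0)
  }
  list(mean = m, sd = sd, degenerate = sd == 0, pdf = pdf)
}

# Trapezoid quadrature weights for possibly irregular grids.
trapezoid_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  dx <- diff(x)
  w[1L] <- dx[1L] / 2
  w[n] <- dx[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (dx[-1L] + dx[-(n - 1L)]) / 2
  w
}

# Split channel grid points into the dead atom (rate below dead_eps, mapped to
# the zero-response symbol) and the live continuum.  Returns per-point prior
# masses under the uniform stimulus prior.
channel_partition <- function(channel, dead_eps) {
  w <- trapezoid_weights(channel$s)
  w <- w / sum(w)
  dead <- channel$r < dead_eps
  sd <- channel$sigma / sqrt(channel$n)
  list(w = w, dead = dead, w_dead = sum(w[dead]), sd = sd)
}

new_mi_result <- function(I, H, H_noise, method, w_dead, n) {
  structure(list(I = I, H = H, H_noise = H_noise, method = method,
                 w_dead = w_dead, n = n),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf("Mutual information (%s): I = %.4f bits (H = %.4f, H_noise = %.4f)\n",
              x$method, x$I, x$H, x$H_noise))
  if (x$w_dead > 0)
    cat(sprintf("  quiescent-network atom mass: %.3f\n", x$w_dead))
  invisible(x)
}

#' Small-noise mutual information
#'
#' Expansion of the stimulus/response mutual information in
#' powers of the readout noise: \eqn{I = H - H_{noise}}, where
#' \eqn{H = -\int P(\hat r)\log_2 P(\hat r)\,d\hat r} is the response entropy
#' of the noiseless rate distribution obtained from the response curve by the
#' change of variables \eqn{P(\hat r) = P(s) / (d\hat r/ds)}, and
#' \eqn{H_{noise} = \frac{1}{2}\int P(\hat r)\log_2[2\pi e\,\sigma^2(\hat r)/n]
#' \,d\hat r}.
#'
#' Stimuli for which the network is quiescent (rate below \code{dead_eps})
#' form an atom: their probability mass \eqn{w} maps to the single symbol
#' \eqn{r = 0}.  The entropy of the mixed response distribution is then
#' \deqn{H = \int_{live} P(s)\log_2\!\frac{d\hat r/ds}{(1-w)\,...}\;ds
#'       - w \log_2 w,}
#' i.e. the differential entropy of the continuous part (sub-density of mass
#' \eqn{1-w}) minus the atom term, and the atom contributes zero noise
#' entropy.  The derivative is estimated by central differences on the
#' stimulus grid.
#'
#' @param channel a \code{"channel_model"}.
#' @param dead_eps quiescence threshold (Hz).
#' @param deriv_eps derivative magnitude below which a live segment counts as
#'   flat; an everywhere-flat live curve is an error (the expansion does not
#'   apply).
#' @return An \code{"mi_result"} with entries in bits.  A negative \code{I}
#'   is possible on pathological inputs and is returned with a warning, never
#'   clipped.
#' @export
mutual_information_small_noise <- function(channel, dead_eps = 0.1,
                                           deriv_eps = 1e-8) {
  stopifnot(inherits(channel, "channel_model"))
  part <- channel_partition(channel, dead_eps)
  live <- !part$dead
  if (!any(live)) return(new_mi_result(0, 0, 0, "small_noise", 1, channel$n))
  s <- channel$s; r <- channel$r
  drds <- numeric(length(s))
  drds[1L] <- (r[2L] - r[1L]) / (s[2L] - s[1L])
  nl <- length(s)
  drds[nl] <- (r[nl] - r[nl - 1L]) / (s[nl] - s[nl - 1L])
  if (nl > 2L)
    drds[2:(nl - 1L)] <- (r[-(1:2)] - r[1:(nl - 2L)]) / (s[-(1:2)] - s[1:(nl - 2L)])
  flat <- live & abs(drds) < deriv_eps
  if (all(!live | flat))
    stop("response curve is flat everywhere; small-noise expansion inapplicable")
  # flat live segments join the discrete part: group them into atoms by rate
  atom_mass <- numeric(0)
  w_dead <- part$w_dead
  if (w_dead > 0) atom_mass <- w_dead
  if (any(flat)) {
    grp <- cumsum(c(TRUE, diff(which(flat)) > 1L))
    for (gi in split(which(flat), grp)) atom_mass <- c(atom_mass, sum(part$w[gi]))
  }
  cont <- live & !flat
  wc <- part$w[cont]
  # H: differential part of the mixed entropy + atom part
  H_cont <- sum(wc * log2(abs(drds[cont])))  # P(s) uniform = 1 on (0,1)
  H_atoms <- if (length(atom_mass)) -sum(atom_mass * log2(atom_mass)) else 0
  H <- H_cont + H_atoms
  sdc <- part$sd[cont]
  if (any(sdc <= 0)) {
    warning("zero response noise on live points; flooring sigma at 1e-9 Hz")
    sdc <- pmax(sdc, 1e-9)
  }
  H_noise <- sum(wc * 0.5 * log2(2 * pi * exp(1) * sdc^2))
  I <- H - H_noise
  if (I < 0) warning("negative small-noise mutual information (expansion breakdown)")
  new_mi_result(I, H, H_noise, "small_noise", w_dead, channel$n)
}

#' Mutual information by direct quadrature
#'
#' Evaluates \eqn{I = \int ds \int dr\, P(s) P(r|s) \log_2[P(r|s)/P(r)]}
#' numerically, with the conditional \eqn{P(r|s)} Gaussian (mean
#' \eqn{\hat r(s)}, variance \eqn{\sigma^2(s)/n}) and the marginal
#' \eqn{P(r)} obtained by quadrature over the stimulus prior.  Quiescent
#' stimuli (rate below \code{dead_eps}) respond with the exact symbol
#' \eqn{r = 0}; they form an atom of mass \eqn{w} in the response marginal
#' and contribute \eqn{w \log_2(1/w)} to \eqn{I}.  This treatment is robust
#' where the small-noise expansion is not (flat or atomic regions of the
#' response curve).
#'
#' The inner integral for each live stimulus runs over a local grid of
#' \code{± 6} conditional SDs around \eqn{\hat r(s)} with \code{n_quad}
#' points; the reported \code{H} is \code{I + H_noise} with the Gaussian
#' conditional (noise) entropy.
#'
#' @param channel a \code{"channel_model"}.
#' @param dead_eps quiescence threshold (Hz).
#' @param n_quad points of the per-stimulus response quadrature grid.
#' @param sigma_floor SD floor (Hz) applied to live points with zero modeled
#'   noise.
#' @return An \code{"mi_result"} with entries in bits; \code{I >= 0} up to
#'   quadrature error.
#' @export
mutual_information_direct <- function(channel, dead_eps = 0.1, n_quad = 201,
                                      sigma_floor = 1e-9) {
  stopifnot(inherits(channel, "channel_model"))
  part <- channel_partition(channel, dead_eps)
  live <- which(!part$dead)
  w_dead <- part$w_dead
  I <- if (w_dead > 0 && w_dead < 1) w_dead * log2(1 / w_dead) else 0
  H_noise <- 0
  if (length(live)) {
    wl <- part$w[live]
    ml <- channel$r[live]
    sdl <- pmax(part$sd[live], sigma_floor)
    H_noise <- sum(wl * 0.5 * log2(2 * pi * exp(1) * sdl^2))
    for (j in seq_along(live)) {
      rg <- seq(ml[j] - 6 * sdl[j], ml[j] + 6 * sdl[j], length.out = n_quad)
      qw <- trapezoid_weights(rg)
      cond <- dnorm(rg, ml[j], sdl[j])
      marg <- rep(0, length(rg))
      for (j2 in seq_along(live))  # continuous part of P(r)
        marg <- marg + wl[j2] * dnorm(rg, ml[j2], sdl[j2])
      ok <- cond > 0 & marg > 0
      I <- I + wl[j] * sum(qw[ok] * cond[ok] * (log2(cond[ok]) - log2(marg[ok])))
    }
  }
  new_mi_result(I, I + H_noise, H_noise, "direct_quadrature", w_dead,
                channel$n)
}

#' Assortativity sweep of mutual information
#'
#' End-to-end pipeline behind the information-vs-assortativity profiles:
#' build a configuration-model network from \code{dist}, rewire it through a
#' grid of Pearson in-degree correlation levels, and at each level sample the
#' joint degree distribution, compute the upper-branch response curve by
#' downward continuation, and evaluate the stimulus/response mutual
#' information for a uniform sub-threshold stimulus prior.
#'
#' Levels are visited in increasing order, continuing the rewiring of the same
#' network (each level's graph is the previous one with additional
#' assortativity-increasing swaps).  Unreachable targets are reported with the
#' achieved Pearson value.
#'
#' @param dist a \code{"degree_dist"}.
#' @param p_levels increasing grid of target Pearson coefficients.
#' @param n readout size (neurons).
#' @param params a \code{"neuron_params"}.
#' @param n_nodes network size.
#' @param s_grid stimulus grid for the response curves (must extend above 1
#'   so the downward continuation starts supra-threshold).
#' @param method \code{"direct"} (default) or \code{"smallnoise"}.
#' @param seed optional integer seed.
#' @return data frame with one row per level: \code{p_target},
#'   \code{p_achieved}, \code{I}, \code{H}, \code{H_noise} (bits) and
#'   \code{r_max} (Hz, response at the top of the grid).
#' @export
assortativity_sweep <- function(dist, p_levels = seq(0, 0.9, by = 0.1),
                                n = 5000, params = neuron_params(),
                                n_nodes = 10000,
                                s_grid = seq(0, 1.2, by = 0.02),
                                method = c("direct", "smallnoise"),
                                seed = NULL) {
  stopifnot(inherits(dist, "degree_dist"))
  method <- match.arg(method)
  if (is.unsorted(p_levels)) stop("'p_levels' must be increasing")
  if (!is.null(seed)) set.seed(seed)
  net <- configuration_model(sample_degree_sequence(dist, n_nodes))
  out <- data.frame(p_target = p_levels, p_achieved = NA_real_, I = NA_real_,
                    H = NA_real_, H_noise = NA_real_, r_max = NA_real_)
  for (i in seq_along(p_levels)) {
    p_now <- pearson_in_degree_correlation(net)$p
    if (abs(p_levels[i] - p_now) > 0.01) {
      rw <- rewire_to_assortativity(net, p_levels[i])
      net <- rw$network
      p_now <- rw$p_achieved
    }
    kern <- sample_joint_degree(net)
    curve <- response_curve(kern, s_grid, params, keep_rates = FALSE)
    ch <- channel_model(curve, n = n)
    mi <- if (method == "direct") mutual_information_direct(ch)
          else mutual_information_small_noise(ch)
    out$p_achieved[i] <- p_now
    out$I[i] <- mi$I
    out$H[i] <- mi$H
    out$H_noise[i] <- mi$H_noise
    out$r_max[i] <- curve$r_mean[length(curve$s)]
  }
  attr(out, "method") <- method
  attr(out, "n") <- n
  out
}
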