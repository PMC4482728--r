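# Truncated power-law in-degree distributions and degree sampling.

#' Truncated power-law degree distribution
#'
#' Discrete probability mass function \eqn{P(k) = Z k^{\alpha}} on the integer
#' support \eqn{k_{min} \le k \le k_{max}}, with
#' \eqn{Z = (\sum_{k} k^{\alpha})^{-1}} taken over the same support.  This is
#' the canonical in-degree law of strongly heterogeneous neuronal networks;
#' heavier tails (larger \code{alpha}, e.g. -1.7 instead of -2.3) raise both
#' the mean and the variance of the connectivity.
#'
#' @param alpha power-law exponent (dimensionless); the distribution is
#'   proportional to \code{k^alpha}, so heterogeneous networks use negative
#'   values such as -2.
#' @param k_min,k_max integer degree bounds, \code{1 <= k_min <= k_max}.
#' @return An object of class \code{"degree_dist"}: a list with elements
#'   \code{alpha}, \code{k_min}, \code{k_max}, \code{k} (support),
#'   \code{pmf} and the normalization constant \code{Z}.
#' @examples
#' d <- truncated_powerlaw(-2, 10, 500)
#' degree_moments(d)
#' @export
truncated_powerlaw <- function(alpha, k_min, k_max) {
  if (length(alpha) != 1L || !is.finite(alpha))
    stop("'alpha' must be a single finite number")
  if (k_min < 1) stop("'k_min' must be >= 1")
  if (k_max < k_min) stop("'k_max' must be >= 'k_min'")
  if (k_min != round(k_min) || k_max != round(k_max))
    stop("'k_min' and 'k_max' must be integers")
  k <- as.integer(k_min):as.integer(k_max)
  w <- k^alpha
  Z <- 1 / sum(w)
  structure(list(alpha = alpha, k_min = as.integer(k_min),
                 k_max = as.integer(k_max), k = k, pmf = w * Z, Z = Z),
            class = "degree_dist")
}

#' @export
print.degree_dist <- function(x, ...) {
  m <- degree_moments(x)
  cat(sprintf("Truncated power-law degree distribution P(k) ~ k^%g on [%d, %d]\n",
              x$alpha, x$k_min, x$k_max))
  cat(sprintf("  mean %.2f, variance %.2f\n", m[["mean"]], m[["variance"]]))
  invisible(x)
}

#' Mean and variance of a degree distribution
#'
#' Exact discrete moments \eqn{\langle k \rangle = \sum_k k P(k)} and
#' \eqn{\sigma_P^2 = \sum_k k^2 P(k) - \langle k \rangle^2}.
#'
#' @param dist a \code{"degree_dist"} object.
#' @return Named numeric vector with elements \code{mean} and \code{variance}.
#' @export
degree_moments <- function(dist) {
  stopifnot(inherits(dist, "degree_dist"))
  m <- sum(dist$k * dist$pmf)
  v <- sum(dist$k^2 * dist$pmf) - m^2
  c(mean = m, variance = v)
}

#' Sample a degree sequence
#'
#' Draws \code{n} i.i.d. in-degrees from \code{dist}.  By default the network
#' convention is equal in- and out-degree per neuron (as observed, e.g., in
#' the C. elegans wiring diagram), so the same sequence serves as both the
#' in- and out-degree sequence.  With \code{equal_inout = FALSE} a second,
#' independent out-degree sequence is drawn and then minimally adjusted (unit
#' steps at randomly chosen nodes, within the support bounds) so that the stub
#' totals match; this variant exists to study networks whose in- and
#' out-degrees are independent.
#'
#' @param dist a \code{"degree_dist"} object.
#' @param n number of nodes (>= 1).
#' @param seed optional integer seed (sets the R RNG).
#' @param equal_inout if \code{TRUE} (default) out-degree equals in-degree per
#'   node and a single integer vector is returned; otherwise a list with
#'   elements \code{in_degree} and \code{out_degree}.
#' @export
sample_degree_sequence <- function(dist, n, seed = NULL, equal_inout = TRUE) {
  stopifnot(inherits(dist, "degree_dist"))
  if (n < 1) stop("'n' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  kin <- sample(dist$k, n, replace = TRUE, prob = dist$pmf)
  if (equal_inout) return(kin)
  kout <- sample(dist$k, n, replace = TRUE, prob = dist$pmf)
  diff <- sum(kin) - sum(kout)
  while (diff != 0) {
    i <- sample.int(n, 1L)
    step <- sign(diff)
    cand <- kout[i] + step
    if (cand >= dist$k_min && cand <= dist$k_max) {
      kout[i] <- cand
      diff <- diff - step
    }
  }
  list(in_degree = kin, out_degree = kout)
}
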