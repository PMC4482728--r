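# Independent oracles used across the suite.  These deliberately avoid the
# package's own numerical paths (C++ quadrature, relaxation solver).

erf_r <- function(x) 2 * pnorm(x * sqrt(2)) - 1

erfcx_r <- function(x) {  # x >= 0
  if (x <= 5) return(exp(x^2) * (1 - erf_r(x)))
  ix2 <- 1 / (2 * x^2)
  s <- 1; term <- 1
  for (k in 1:14) { term <- term * -(2 * k - 1) * ix2; s <- s + term }
  s / (x * sqrt(pi))
}

# Siegert rate via R's adaptive quadrature (Hz).  Valid while the upper
# integration limit stays below ~20 noise SDs (exp overflow guard).
ref_siegert <- function(mu, sigma, params) {
  a <- (params$v_reset - mu) / sigma
  b <- (params$theta - mu) / sigma
  stopifnot(b <= 20)
  f <- function(x) vapply(x, function(v)
    if (v < 0) erfcx_r(-v) else exp(v^2) * (1 + erf_r(v)), 0)
  val <- 0
  if (a < 0)
    val <- val + integrate(f, a, min(b, 0), rel.tol = 1e-12,
                           stop.on.error = FALSE)$value
  if (b > 0) {
    L <- max(a, 0)
    fpos <- function(t) exp(t^2 - 2 * b * t) * (1 + erf_r(b - t))
    val <- val + exp(b^2) * integrate(fpos, 0, b - L, rel.tol = 1e-12,
                                      stop.on.error = FALSE)$value
  }
  1000 / (params$tau_ref + params$tau * sqrt(pi) * val)
}

# Brute-force evaluation of the excess-distribution Pearson coefficient by
# explicit summation over the link-end joint table and the node degree table.
ref_pearson <- function(net) {
  indeg <- net$in_degree
  e_num <- table(k = indeg[net$to], kp = indeg[net$from])
  e <- e_num / sum(e_num)
  kk <- 0
  for (i in rownames(e)) for (j in colnames(e))
    kk <- kk + as.numeric(i) * as.numeric(j) * e[i, j]
  ptab <- table(indeg) / net$n
  kv <- as.numeric(names(ptab)); pk <- as.numeric(ptab)
  denom <- sum(kv * pk)
  # Q_k = (k+1) P(k+1) / sum k P(k): mass (k)P(k)/denom sits at degree k - 1
  mq <- sum((kv - 1) * kv * pk) / denom
  vq <- sum((kv - 1)^2 * kv * pk) / denom - mq^2
  (kk - mq^2) / vq
}

# Scalar fixed-point solve of r = phi(mu(r)) for a single decoupled degree
# class (delta kernel, N_kk = k), via root bracketing on the upper branch.
ref_scalar_delta <- function(k, s, params) {
  g <- function(r_hz) {  # r - phi(r) in Hz
    mu <- params$J * params$tau * (params$nu_thr * s + k * r_hz / 1000)
    r_hz - ref_siegert(mu, sqrt(params$J * mu), params)
  }
  # upper branch: descend from the refractory bound until the residual
  # changes sign, bracketing the upper-most fixed point
  upper <- 1000 / params$tau_ref
  lower <- upper / 2
  while (g(lower) > 0) {
    upper <- lower
    lower <- lower / 2
    if (lower < 1e-6) break
  }
  uniroot(g, c(lower, upper), tol = 1e-10)$root
}

default_params <- neuron_params()

# bare kernel constructor for hand-built N_kk' matrices in tests
new_connection_kernel_for_test <- function(degrees, N, weights = NULL)
  lifnet:::new_connection_kernel(degrees, N, weights = weights)

# Memoised desk-scale networks shared by the acceptance criteria (built once).
acceptance_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    set.seed(20150626)
    dist <- truncated_powerlaw(-2, 10, 500)
    net <- configuration_model(sample_degree_sequence(dist, 10000))
    assort <- rewire_to_plateau(net, "assortative", p_tol = 2e-4,
                                block_attempts = 50 * length(net$from))
    disassort <- rewire_to_plateau(net, "disassortative", p_tol = 2e-4)
    cache <<- list(dist = dist, uncorrelated = net,
                   assortative = assort$network,
                   disassortative = disassort$network)
    cache
  }
})
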