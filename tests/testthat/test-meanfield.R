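test_that("Siegert rate matches adaptive-quadrature reference values", {
  p <- default_params
  for (mu in c(5, 12, 15, 18, 19.9, 20.5, 24, 40)) {
    for (sg in c(0.8, 1.4, 3)) {
      if ((p$theta - mu) / sg > 20) next
      expect_equal(siegert_rate(mu, sg, p), ref_siegert(mu, sg, p),
                   tolerance = 1e-6,
                   label = sprintf("siegert(mu=%g, sigma=%g)", mu, sg))
    }
  }
})

test_that("Siegert limits: refractory bound, noiseless forms, monotone drive", {
  p <- default_params
  # mu -> Inf: rate -> 1/tau_ref = 500 Hz
  expect_equal(siegert_rate(1e7, 1, p), 1000 / p$tau_ref, tolerance = 1e-3)
  # sigma -> 0, mu < theta: silent
  expect_equal(siegert_rate(19.99, 0, p), 0)
  expect_lt(siegert_rate(19.5, 0.05, p), 1e-10)
  # sigma -> 0, mu > theta: noiseless ODE traversal time between reset and
  # threshold, tau * log((mu - vr)/(mu - theta))
  for (mu in c(21, 24, 40)) {
    closed <- 1000 / (p$tau_ref + p$tau * log((mu - p$v_reset) / (mu - p$theta)))
    expect_equal(siegert_rate(mu, 0, p), closed, tolerance = 1e-12)
    expect_equal(siegert_rate(mu, 1e-4, p), closed, tolerance = 1e-3)
  }
  # strictly increasing in mu at fixed sigma, bounded by the refractory limit
  mus <- seq(10, 30, by = 0.5)
  r <- siegert_rate(mus, rep(1.5, length(mus)), p)
  expect_true(all(diff(r) > 0))
  expect_true(all(r <= 1000 / p$tau_ref))
  expect_error(siegert_rate(20, -1, p), "sigma")
})

test_that("input moments follow the drive and the shot-noise identity", {
  p <- default_params
  d <- truncated_powerlaw(-2, 10, 50)
  kern <- analytic_kernel(d, "uncorrelated_equal_inout")
  z <- input_moments(kern, rep(0, length(d$k)), s = 0.7, p)
  # zero rates: mu_k = theta * s for every class
  expect_equal(z$mu, rep(p$theta * 0.7, length(d$k)), tolerance = 1e-12)
  r <- runif(length(d$k), 0, 100)
  m <- input_moments(kern, r, s = 1.1, p)
  expect_equal(m$sigma_sq, p$J * m$mu, tolerance = 1e-12)
  # two-class arithmetic oracle
  k2 <- new_connection_kernel_for_test(c(2L, 4L),
                                       matrix(c(1.5, 0.5, 1, 3), 2, byrow = TRUE))
  mm <- input_moments(k2, c(1000, 2000), s = 0.5, p)
  # mu_k = J tau (nu_thr s + N %*% r)   with r in 1/ms
  expect_equal(mm$mu, p$J * p$tau * (p$nu_thr * 0.5 +
                                       c(1.5 * 1 + 0.5 * 2, 1 * 1 + 3 * 2)),
               tolerance = 1e-12)
  expect_error(input_moments(k2, c(-1, 1), 1, p), "negative")
})

test_that("zero coupling reduces the coupled solve to the bare transfer function", {
  p <- default_params
  d <- truncated_powerlaw(-2, 10, 30)
  kern <- new_connection_kernel_for_test(d$k, matrix(0, length(d$k), length(d$k)),
                                         weights = d$pmf)
  s <- 1.3
  sol <- solve_selfconsistent(kern, s, p)
  expect_true(sol$converged)
  bare <- siegert_rate(p$theta * s, sqrt(p$J * p$theta * s), p)
  expect_equal(sol$rates, rep(bare, length(d$k)), tolerance = 1e-4)
})

test_that("delta-kernel populations decouple into scalar solves", {
  p <- default_params
  d <- truncated_powerlaw(-2, 20, 400)
  # a few spot degrees solved independently by root bracketing
  kern <- analytic_kernel(d, "assortative_delta")
  sol <- solve_selfconsistent(kern, 1.05, p, tol = 1e-8)
  expect_true(sol$converged)
  for (k in c(20, 50, 150, 400)) {
    ref <- ref_scalar_delta(k, 1.05, p)
    expect_equal(sol$rates[match(k, kern$degrees)], ref, tolerance = 1e-4,
                 label = sprintf("decoupled class k=%d", k))
  }
})

test_that("one-dimensional reduction agrees with the coupled independent-in/out solve", {
  p <- default_params
  d <- truncated_powerlaw(-2, 5, 80)
  s <- 1.2
  scalar <- solve_scalar_uncorrelated(d, s, p)
  coupled <- solve_selfconsistent(analytic_kernel(d, "independent_inout"), s, p)
  expect_true(scalar$converged && coupled$converged)
  expect_equal(scalar$rate, sum(d$pmf * coupled$rates), tolerance = 1e-3)
  expect_equal(scalar$rates, coupled$rates, tolerance = 1e-3)
  # supra-threshold drive fires; response is monotone in s
  expect_gt(scalar$rate, 0)
  r2 <- solve_scalar_uncorrelated(d, 1.4, p)
  expect_gt(r2$rate, scalar$rate)
})

test_that("response curves are monotone on the upper branch with sigma >= 0", {
  p <- default_params
  d <- truncated_powerlaw(-2, 5, 60)
  kern <- analytic_kernel(d, "uncorrelated_equal_inout")
  curve <- response_curve(kern, seq(0, 1.2, by = 0.05), p)
  expect_s3_class(curve, "response_curve")
  expect_identical(curve$branch, "upper")
  expect_true(all(diff(curve$r_mean) >= -1e-6))
  expect_true(all(curve$sigma >= 0))
  expect_true(all(curve$converged))
  # mean consistency with the stored per-class rates
  expect_equal(curve$r_mean, drop(curve$weights %*% curve$rates),
               tolerance = 1e-12)
})

test_that("threshold detection reports the bracketing midpoint or errors", {
  p <- default_params
  d <- truncated_powerlaw(-2, 5, 60)
  kern <- analytic_kernel(d, "uncorrelated_equal_inout")
  curve <- response_curve(kern, seq(0, 1.2, by = 0.05), p)
  th <- stimulus_threshold(curve, epsilon = 0.1)
  expect_equal(th$uncertainty, 0.05, tolerance = 1e-12)
  i <- match(th$s_star - 0.025, curve$s)
  expect_lt(curve$r_mean[i], 0.1)
  expect_gt(curve$r_mean[i + 1L], 0.1)
  # an always-active curve has no crossing
  alive <- curve
  alive$r_mean <- alive$r_mean + 5
  expect_error(stimulus_threshold(alive), "no extinction")
})

test_that("firing-rate distribution is a unit-mass histogram consistent with sigma", {
  w <- c(0.5, 0.3, 0.2)
  r <- c(10, 20, 40)
  h <- firing_rate_distribution(r, w, breaks = c(0, 15, 30, 50))
  expect_equal(sum(h$mass), 1, tolerance = 1e-12)
  expect_equal(h$mass, c(0.5, 0.3, 0.2))
  # point mass
  h1 <- firing_rate_distribution(rep(7, 4), rep(1, 4), breaks = 5)
  expect_equal(sum(h1$mass), 1)
  expect_equal(max(h1$mass), 1)
  # binned variance approximates the weighted population variance
  set.seed(30)
  r <- runif(200, 0, 100)
  w <- runif(200); w <- w / sum(w)
  h <- firing_rate_distribution(r, w, breaks = 400)
  mid <- (h$lower + h$upper) / 2
  vb <- sum(h$mass * mid^2) - sum(h$mass * mid)^2
  vp <- sum(w * r^2) - sum(w * r)^2
  expect_equal(vb, vp, tolerance = 0.01)
  expect_error(firing_rate_distribution(r, w[-1]), "equal length")
})
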