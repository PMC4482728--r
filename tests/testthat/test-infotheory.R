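# Synthetic response curves with known information content.
linear_channel <- function(a, b, sigma, n, ds = 0.01) {
  s <- seq(0, 1.2, by = ds)
  curve <- structure(list(s = s, r_mean = a + b * s,
                          sigma = rep(sigma, length(s)), branch = "upper",
                          converged = rep(TRUE, length(s)),
                          degrees = 1L, weights = 1),
                     class = "response_curve")
  channel_model(curve, n = n)
}

test_that("conditional readout density follows the Gaussian noise model", {
  ch <- linear_channel(a = 5, b = 40, sigma = 8, n = 100)
  c1 <- conditional_response_pdf(ch, 0.5)
  expect_equal(c1$mean, 25, tolerance = 1e-9)
  expect_equal(c1$sd, 8 / sqrt(100), tolerance = 1e-9)
  expect_equal(c1$pdf(25), dnorm(25, 25, 0.8))
  # doubling n halves the variance
  c2 <- conditional_response_pdf(linear_channel(5, 40, 8, 200), 0.5)
  expect_equal(c2$sd^2, c1$sd^2 / 2, tolerance = 1e-9)
  expect_error(conditional_response_pdf(ch, 2), "outside")
})

test_that("both estimators reproduce the linear-Gaussian closed form", {
  a <- 5; b <- 40; sigma <- 6; n <- 400
  ch <- linear_channel(a, b, sigma, n)
  sd_n <- sigma / sqrt(n)
  I_exact <- log2(b) - 0.5 * log2(2 * pi * exp(1) * sd_n^2)
  sn <- mutual_information_small_noise(ch, dead_eps = 1e-9)
  expect_equal(sn$H, log2(b), tolerance = 1e-3)
  expect_equal(sn$H_noise, 0.5 * log2(2 * pi * exp(1) * sd_n^2),
               tolerance = 1e-9)
  expect_equal(sn$I, I_exact, tolerance = 1e-3)
  expect_equal(sn$I, sn$H - sn$H_noise, tolerance = 1e-12)
  dq <- mutual_information_direct(ch, dead_eps = 1e-9)
  # edge effects of the exact channel (Gaussian mass outside the response
  # range) make the direct estimate slightly conservative
  expect_equal(dq$I, I_exact, tolerance = 0.02)
  expect_gte(dq$I, 0)
})

test_that("a constant response carries no information", {
  s <- seq(0, 1.2, by = 0.02)
  curve <- structure(list(s = s, r_mean = rep(30, length(s)),
                          sigma = rep(5, length(s)), branch = "upper",
                          converged = rep(TRUE, length(s)), degrees = 1L,
                          weights = 1), class = "response_curve")
  ch <- channel_model(curve, n = 100)
  expect_lt(abs(mutual_information_direct(ch)$I), 1e-6)
  expect_error(mutual_information_small_noise(ch), "flat")
})

test_that("information decreases with noise and increases with readout size", {
  ch_narrow <- linear_channel(5, 40, 2, 100)
  ch_wide <- linear_channel(5, 40, 20, 100)
  expect_gt(mutual_information_small_noise(ch_narrow, dead_eps = 1e-9)$I,
            mutual_information_small_noise(ch_wide, dead_eps = 1e-9)$I)
  for (f in list(mutual_information_direct,
                 function(x, ...) mutual_information_small_noise(x, 1e-9))) {
    i_small <- f(linear_channel(5, 40, 8, 50))$I
    i_big <- f(linear_channel(5, 40, 8, 5000))$I
    expect_gt(i_big, i_small)
  }
})

test_that("methods agree on a smooth strictly increasing curve at large n", {
  s <- seq(0, 1.2, by = 0.01)
  curve <- structure(list(s = s, r_mean = 10 + 35 * s^2,
                          sigma = 4 + 3 * s, branch = "upper",
                          converged = rep(TRUE, length(s)), degrees = 1L,
                          weights = 1), class = "response_curve")
  ch <- channel_model(curve, n = 5000)
  i_sn <- mutual_information_small_noise(ch, dead_eps = 1e-9)$I
  i_dq <- mutual_information_direct(ch, dead_eps = 1e-9)$I
  expect_lt(abs(i_sn - i_dq) / i_sn, 0.05)
})

test_that("a quiescent region forms an atom with closed-form information", {
  # dead below s0, linear above: exact small-noise MI is
  #   -w log2 w - (1-w) log2((1-w)/b) - (1-w)/2 log2(2 pi e sd^2)
  s <- seq(0, 1.2, by = 0.005)
  s0 <- 0.4; b <- 50; sigma <- 5; n <- 2500
  r <- ifelse(s < s0, 0, b * (s - s0))
  sg <- ifelse(s < s0, 0, sigma)
  curve <- structure(list(s = s, r_mean = r, sigma = sg, branch = "upper",
                          converged = rep(TRUE, length(s)), degrees = 1L,
                          weights = 1), class = "response_curve")
  ch <- channel_model(curve, n = n)
  w <- s0
  sd_n <- sigma / sqrt(n)
  I_exact <- -w * log2(w) + (1 - w) * log2(b) -
    (1 - w) * 0.5 * log2(2 * pi * exp(1) * sd_n^2)
  sn <- mutual_information_small_noise(ch)
  expect_equal(sn$w_dead, w, tolerance = 0.02)
  expect_equal(sn$I, I_exact, tolerance = 0.02)
  dq <- mutual_information_direct(ch)
  expect_equal(dq$I, I_exact, tolerance = 0.05)
  expect_gte(dq$I, 0)
})
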