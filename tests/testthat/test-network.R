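test_that("configuration model yields a simple graph with consistent degrees", {
  d <- truncated_powerlaw(-2, 5, 60)
  target <- sample_degree_sequence(d, 2000, seed = 1)
  net <- configuration_model(target, seed = 2)
  expect_s3_class(net, "lif_network")
  expect_false(any(net$from == net$to))
  expect_false(anyDuplicated(paste(net$from, net$to)) > 0)
  expect_identical(net$in_degree, tabulate(net$to, net$n))
  expect_identical(net$out_degree, tabulate(net$from, net$n))
  expect_equal(sum(net$in_degree), length(net$from))
  expect_true(all(net$delay_ms >= 0 & net$delay_ms <= 6))
  # duplicate/self-loop removal only ever lowers degrees below target
  expect_true(all(net$in_degree <= target))
  expect_true(all(net$out_degree <= target))
  expect_lt(mean(target - net$in_degree) / mean(target), 0.05)
  expect_error(configuration_model(integer(0)), "empty")
})

test_that("two-node mutual pair survives removal with invariants intact", {
  net <- configuration_model(c(1L, 1L), seed = 4)
  expect_true(all(net$from != net$to))
  expect_lte(length(net$from), 2L)
})

test_that("Pearson coefficient matches brute-force enumeration on toy graphs", {
  for (nm in c("hand5", "two-class-assortative", "two-class-disassortative")) {
    net <- build_toy_network(nm)
    st <- pearson_in_degree_correlation(net)
    expect_equal(st$p, ref_pearson(net), tolerance = 1e-9)
    expect_equal(sum(st$e_kk$prob), 1, tolerance = 1e-12)
    expect_equal(sum(st$Q_in$prob), 1, tolerance = 1e-12)
    expect_gt(st$sigma_in_sq, 0)
  }
})

test_that("perfectly assortative link ends give edge-sample correlation 1", {
  net <- build_toy_network("two-class-assortative")
  st <- pearson_in_degree_correlation(net)
  expect_equal(st$p_edge, 1, tolerance = 1e-12)
  # the disassortative toy is perfectly anti-aligned
  netd <- build_toy_network("two-class-disassortative")
  expect_equal(pearson_in_degree_correlation(netd)$p_edge, -1,
               tolerance = 1e-12)
})

test_that("regular in-degrees make the Pearson coefficient undefined", {
  expect_error(pearson_in_degree_correlation(build_toy_network("ring")),
               "undefined")
})

test_that("Metropolis rewiring preserves both degree sequences exactly", {
  d <- truncated_powerlaw(-2, 5, 40)
  net <- configuration_model(sample_degree_sequence(d, 800, seed = 5), seed = 6)
  rw <- metropolis_rewire(net, "assortative", g = 1,
                          n_attempts = 20 * length(net$from), seed = 7)
  expect_identical(rw$in_degree, net$in_degree)
  expect_identical(rw$out_degree, net$out_degree)
  expect_identical(rw$from, net$from)
  expect_equal(length(rw$from), length(net$from))
  expect_false(any(rw$from == rw$to))
  expect_false(anyDuplicated(paste(rw$from, rw$to)) > 0)
  expect_error(metropolis_rewire(configuration_model(c(1L, 1L)), "assortative",
                                 n_attempts = 5),
               "2 edges")
})

test_that("strictly improving swaps make p exactly nondecreasing", {
  d <- truncated_powerlaw(-2, 5, 40)
  net <- configuration_model(sample_degree_sequence(d, 800, seed = 8), seed = 9)
  set.seed(10)
  p_trace <- pearson_in_degree_correlation(net)$p
  for (b in 1:8) {
    net <- metropolis_rewire(net, "assortative", g = 1,
                             n_attempts = 5 * length(net$from))
    p_trace <- c(p_trace, pearson_in_degree_correlation(net)$p)
  }
  # at g = 1 every accepted swap raises sum(k_src k_tgt) while the degree
  # sequences (hence the normalization) stay fixed
  expect_true(all(diff(p_trace) >= -1e-12))
  expect_gt(p_trace[length(p_trace)], p_trace[1L] + 0.1)
})

test_that("g = 0 rewiring scrambles targets without building correlations", {
  d <- truncated_powerlaw(-2, 5, 40)
  net <- configuration_model(sample_degree_sequence(d, 2000, seed = 12), seed = 13)
  st0 <- pearson_in_degree_correlation(net)
  rw <- metropolis_rewire(net, "assortative", g = 0,
                          n_attempts = 20 * length(net$from), seed = 14)
  st <- pearson_in_degree_correlation(rw)
  # unconditional swaps keep the link ends uncorrelated; the sample Pearson
  # correlation stays near zero and the excess-normalized coefficient keeps
  # only its distribution-dependent finite-size offset
  expect_lt(abs(st$p_edge), 0.05)
  expect_lt(abs(st$p - st0$p), 0.05)
  expect_gt(attr(rw, "accepted_swaps"), 0)
})

test_that("rewiring to a target Pearson level stops near the target", {
  d <- truncated_powerlaw(-2, 5, 40)
  net <- configuration_model(sample_degree_sequence(d, 1500, seed = 15), seed = 16)
  set.seed(17)
  rw <- rewire_to_assortativity(net, 0.4)
  expect_gte(rw$p_achieved, 0.4)
  expect_lt(rw$p_achieved, 0.6)
  expect_equal(pearson_in_degree_correlation(rw$network)$p, rw$p_achieved)
})

test_that("edge lists round-trip through TSV files", {
  net <- build_toy_network("hand5")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, path)
  back <- read_edge_list(path)
  expect_identical(back$from, net$from)
  expect_identical(back$to, net$to)
  expect_equal(back$delay_ms, net$delay_ms)
  expect_identical(back$n, net$n)
})
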