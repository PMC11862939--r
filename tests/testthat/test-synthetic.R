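test_that("identical seeds give byte-identical datasets", {
  sc <- default_scenarios()$cage_1_1_2
  a <- gen_cage_time_course(sc, 5e-5, noise_spec("multiplicative-lognormal", 0.05, 7))
  b <- gen_cage_time_course(sc, 5e-5, noise_spec("multiplicative-lognormal", 0.05, 7))
  expect_identical(a, b)
  c <- gen_cage_time_course(sc, 5e-5, noise_spec("multiplicative-lognormal", 0.05, 8))
  expect_false(identical(a$C.P, c$C.P))
  bk <- default_scenarios()$bulk_25mM
  expect_identical(gen_bulk_time_course(bk, 5.6e-8, 2.8e-8,
                                        noise_spec("additive-gaussian", 0.03, 3)),
                   gen_bulk_time_course(bk, 5.6e-8, 2.8e-8,
                                        noise_spec("additive-gaussian", 0.03, 3)))
})

test_that("generators do not disturb the global RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(gen_cage_time_course(default_scenarios()$cage_1_1_1, 5e-5,
                                 noise_spec("multiplicative-lognormal", 0.05, 1)))
  expect_identical(.Random.seed, before)
})

test_that("zero noise reproduces the forward model exactly", {
  sc <- default_scenarios()$cage_1_1_2
  tc <- gen_cage_time_course(sc, 5e-5, noise_spec("multiplicative-lognormal", 0, 1))
  net <- attr(tc, "network")
  sim <- simulate_network(net, sc$schedule_s)
  expect_identical(tc$C.P, sim$C.P)
  bk <- default_scenarios()$bulk_25mM
  tb <- gen_bulk_time_course(bk, 5.6e-8, 2.8e-8, noise_spec("additive-gaussian", 0, 1))
  expect_equal(tb$P14 / tb$P15, rep(2, nrow(tb)), tolerance = 1e-7)
})

test_that("noisy replicate means converge to the forward model", {
  sc <- default_scenarios()$cage_1_1_1
  truth <- gen_cage_time_course(sc, 5e-5,
                                noise_spec("multiplicative-lognormal", 0, 1))$C.P
  n <- 200
  level <- 0.05
  sums <- numeric(length(truth))
  for (i in seq_len(n)) {
    sums <- sums + gen_cage_time_course(
      sc, 5e-5, noise_spec("multiplicative-lognormal", level, 1e4 + i))$C.P
  }
  m <- sums / n
  # lognormal mean bias exp(level^2/2) is ~0.1%, well under the 3 sigma band
  tol <- 3 * level / sqrt(n)
  expect_true(all(abs(m / truth - 1) < tol + 0.005))
})

test_that("recovery summaries are exact at zero noise", {
  rs <- recovery_suite(2, "k_bulk", noise_level = 0, seed = 1)
  expect_lt(rs$median_rel_error, 1e-6)
  expect_lt(rs$rmse_rel, 1e-6)
  expect_equal(rs$coverage25, 1)
})

test_that("k_intra recovery over seeded replicates is tight", {
  rs <- recovery_suite(10, "k_intra", seed = 2)
  expect_lt(rs$median_rel_error, 0.10)
})
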