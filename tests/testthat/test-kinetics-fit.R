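test_that("initial rates on exact first-order data recover k exactly", {
  k <- 5e-5
  conc <- c(0.54, 0.32, 0.10) * 1e-3
  times <- seq(0, 48 * 3600, length.out = 97)
  runs <- lapply(conc, function(c0) {
    # exactly linear early phase: p = k c0 t, capped to create a plateau
    data.frame(time_s = times, C.P = pmin(k * c0 * times, 0.8 * c0 * 48 * 3600 * k))
  })
  est <- initial_rates_estimate(runs, conc)
  expect_equal(est$k_intra, k, tolerance = 1e-12)
  expect_equal(est$v0[1], 2.7e-8, tolerance = 1e-9)   # v0 at 0.54 mM
})

test_that("initial rates need multiple runs, distinct levels and enough points", {
  tc <- data.frame(time_s = c(0, 100, 1e6), C.P = c(0, 1e-6, 1e-3))
  expect_error(initial_rates_estimate(list(tc), 1e-4), "at least two")
  expect_error(initial_rates_estimate(list(tc, tc), c(1e-4, 1e-4)), "distinct")
  expect_error(initial_rates_estimate(list(tc, tc), c(1e-4, 2e-4)),
               "window")
})

test_that("seeded noisy triplicates recover k_intra within the reported band", {
  sc <- default_scenarios()$cage_1_1_2
  ternary <- c(0.54, 0.32, 0.10) * 1e-3
  models <- lapply(ternary, function(ct) {
    calibrate_ternary_composition(guest_pair_model("4b", "5", sc$totals), ct)
  })
  tcs <- lapply(seq_along(models), function(j) {
    gen_cage_time_course(sc, 5e-5,
                         noise_spec("multiplicative-lognormal", 0.05, 300 + j),
                         model = models[[j]])
  })
  est <- initial_rates_estimate(tcs, ternary)
  expect_lt(abs(est$k_intra - 5e-5), 3e-5)
})

test_that("full-curve fitting is self-consistent on noise-free data", {
  sc <- default_scenarios()$cage_1_1_2
  tc <- gen_cage_time_course(sc, 5e-5,
                             noise_spec("multiplicative-lognormal", 0, 1))
  fit <- fit_k_intra_full_curve(tc, attr(tc, "network"))
  expect_equal(fit$k_intra, 5e-5, tolerance = 1e-5)
  expect_true(fit$unimodal)
})

test_that("full-curve fitting recovers k_intra within 20% at 5% noise", {
  sc <- default_scenarios()$cage_1_1_2
  tc <- gen_cage_time_course(sc, 5e-5,
                             noise_spec("multiplicative-lognormal", 0.05, 2025))
  fit <- fit_k_intra_full_curve(tc, attr(tc, "network"))
  expect_lt(abs(fit$k_intra / 5e-5 - 1), 0.20)
})

test_that("the three molar-ratio scenarios give a consistent average", {
  scs <- default_scenarios()[c("cage_1_1_2", "cage_1_1_1", "cage_1_5_5")]
  ks <- vapply(seq_along(scs), function(i) {
    tc <- gen_cage_time_course(scs[[i]], 5e-5,
                               noise_spec("multiplicative-lognormal", 0.05, 50 + i))
    fit_k_intra_full_curve(tc, attr(tc, "network"))$k_intra
  }, 0)
  expect_lt(abs(mean(ks) / 5e-5 - 1), 0.20)
  expect_true(all(abs(ks / 5e-5 - 1) < 0.30))
})

test_that("the fitted k_intra is insensitive to the reference on-rate", {
  sc <- default_scenarios()$cage_1_1_2
  tc <- gen_cage_time_course(sc, 5e-5,
                             noise_spec("multiplicative-lognormal", 0, 1))
  m <- guest_pair_model("4b", "5", sc$totals)
  ks <- vapply(c(1e6, 1e7, 1e8), function(kon) {
    net <- build_cage_network(m, 1e-5, k_on_reference = kon)
    fit_k_intra_full_curve(tc, net)$k_intra
  }, 0)
  expect_lt((max(ks) - min(ks)) / min(ks), 0.01)
})
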