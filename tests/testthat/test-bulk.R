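test_that("zero rate constants give no product", {
  m <- bulk_reaction_model(0, 0, 25e-3, 25e-3)
  tc <- simulate_bulk(m, c(1e5, 1e7))
  expect_identical(tc$P14, c(0, 0))
  expect_identical(tc$P15, c(0, 0))
})

test_that("single-channel product follows the integrated second-order law", {
  m <- bulk_reaction_model(5.6e-8, 0, 25e-3, 25e-3)
  tc <- simulate_bulk(m, 1e6)
  expect_equal(tc$P14, second_order_equal(25e-3, 5.6e-8, 1e6), tolerance = 1e-6)
  expect_equal(tc$P14, 3.50e-5, tolerance = 1e-3)
})

test_that("regioisomer ratio equals the channel rate ratio at every time", {
  m <- bulk_reaction_model(5.6e-8, 2.8e-8, 25e-3, 25e-3)
  tc <- simulate_bulk(m, c(1e4, 1e5, 1e6, 1e7))
  expect_equal(tc$P14 / tc$P15, rep(2, 4), tolerance = 1e-7)
})

test_that("bulk fitting recovers the rate constant", {
  sc <- default_scenarios()$bulk_25mM
  skel <- bulk_reaction_model(1e-8, 0.5e-8, 25e-3, 25e-3)
  # noise-free self-consistency
  tc0 <- gen_bulk_time_course(sc, 5.6e-8, 2.8e-8,
                              noise_spec("additive-gaussian", 0, 1))
  expect_equal(fit_k_bulk(tc0, skel)$k_14, 5.6e-8, tolerance = 1e-6)
  # HPLC-like noise, seeded
  tc <- gen_bulk_time_course(sc, 5.6e-8, 2.8e-8,
                             noise_spec("additive-gaussian", 0.03, 99))
  expect_lt(abs(fit_k_bulk(tc, skel)$k_14 / 5.6e-8 - 1), 0.15)
  # the slower two-methylene analogue
  tc2 <- gen_bulk_time_course(sc, 3.6e-8, 1.8e-8,
                              noise_spec("additive-gaussian", 0.03, 100))
  expect_lt(abs(fit_k_bulk(tc2, skel)$k_14 / 3.6e-8 - 1), 0.15)
  expect_error(fit_k_bulk(data.frame(time_s = 1:3, P14 = 0), skel), "zero")
})

test_that("time to a target conversion inverts the integrated law", {
  m <- bulk_reaction_model(5.6e-8, 0, 2e-3, 2e-3)
  expect_identical(time_to_conversion(m, 0), 0)
  # 1 mM product from 2 mM reactants: t = 500 / k ~ 283 years
  t1 <- time_to_conversion(m, 1e-3)
  expect_equal(t1, 500 / 5.6e-8, tolerance = 1e-12)
  expect_equal(t1 / (365.25 * 86400), 283, tolerance = 0.01)
  # consistency with forward simulation, equal and unequal concentrations
  for (m2 in list(bulk_reaction_model(5.6e-8, 2.8e-8, 25e-3, 25e-3),
                  bulk_reaction_model(5.6e-8, 2.8e-8, 25e-3, 10e-3))) {
    target <- 1e-3
    t2 <- time_to_conversion(m2, target)
    expect_equal(simulate_bulk(m2, t2)$P14, target, tolerance = 1e-6)
  }
  # divergence as the target approaches the reachable limit
  tt <- vapply(c(0.5, 0.9, 0.99, 0.999) * 2e-3, function(x)
    time_to_conversion(m, x), 0)
  expect_true(all(diff(tt) > 0))
  expect_error(time_to_conversion(m, 2e-3), "reachable")
})
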