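test_that("predicted ratios come from the equilibrium solve", {
  m <- model_4a5_122()
  comp <- c(cage = 2e-3, `4a` = 4e-3, `5` = 4e-3)
  expect_identical(predict_ratio(m, comp, "C.4a.4a", "C.4a.4a"), 1)
  # homo/hetero ratio of the 1:2:2 mixture ~ 0.9/0.8
  r <- predict_ratio(m, comp, "C.4a.4a", "C.4a.5")
  expect_equal(r, 0.9 / 0.8, tolerance = 0.02)
  # 1:1 toy matches the quadratic oracle
  m1 <- binding_model(
    list(component("H", 2e-3), component("G", 1e-3)),
    list(complex_species("HG", c(H = 1, G = 1), log10(5e3))))
  hg <- quadratic_hg(2e-3, 1e-3, 5e3)
  expect_equal(predict_ratio(m1, c(H = 2e-3, G = 1e-3), "HG", "H"),
               hg / (2e-3 - hg), tolerance = 1e-9)
  # ratio against an absent species is undefined
  expect_error(predict_ratio(m, c(cage = 2e-3, `4a` = 4e-3, `5` = 0),
                             "C.4a.4a", "C.5.5"), "1e-15")
})

test_that("noise-free self-generated ratios are recovered exactly", {
  m_true <- guest_homo_model("4a", 2e-3, 0, use = "stepwise")
  comps <- lapply(c(1e-3, 2e-3, 3e-3, 4e-3), function(g) c(cage = 2e-3, `4a` = g))
  ds <- gen_titration_dataset(m_true, "C.4a.4a", comps,
                              noise_spec("multiplicative-lognormal", 0, 1))
  fit <- fit_stepwise_constants(ds, center = c(C.4a.4a = 8.5), window = 2)
  expect_equal(fit$estimates[["C.4a.4a"]], log10(2.0e4 * 3.1e4),
               tolerance = 1e-6)
  expect_lt(fit$objective_value, 1e-6)
})

test_that("seeded noisy titration recovers both stepwise constants within 25%", {
  m_true <- guest_homo_model("4a", 2e-3, 0, use = "stepwise")
  comps <- lapply(c(0.5, 1, 1.5, 2) * 2e-3, function(g) c(cage = 2e-3, `4a` = g))
  free <- c("C.4a", "C.4a.4a")
  ds <- gen_titration_dataset(m_true, free, comps,
                              noise_spec("multiplicative-lognormal", 0.05, 2024))
  fit <- fit_stepwise_constants(
    ds, center = c(C.4a = 4.3, C.4a.4a = 8.8), window = 2)
  K1 <- fit$K[["C.4a"]]
  K2 <- fit$K[["C.4a.4a"]] / K1
  expect_lt(abs(K1 / 2.0e4 - 1), 0.25)
  expect_lt(abs(K2 / 3.1e4 - 1), 0.25)
})

test_that("hetero constant is recovered with homo constants fixed", {
  m_true <- model_4a5_122()
  comps <- list(c(cage = 2e-3, `4a` = 4e-3, `5` = 4e-3),
                c(cage = 2e-3, `4a` = 2e-3, `5` = 2e-3),
                c(cage = 2e-3, `4a` = 3e-3, `5` = 5e-3))
  ds <- gen_titration_dataset(
    m_true, "C.4a.5", comps,
    noise_spec("multiplicative-lognormal", 0.05, 77),
    ratio_pairs = data.frame(numerator = c("C.4a.5", "C.4a.4a"),
                             denominator = c("C.4a.4a", "C.5.5")))
  fit <- fit_stepwise_constants(ds, center = c(C.4a.5 = 8), window = 2)
  expect_lt(abs(fit$K[["C.4a.5"]] / 2.8e8 - 1), 0.25)
})

test_that("a parameter with no influence on the observations is flagged", {
  # guest 5 absent from every composition: its homo constant cannot be
  # identified from the observed ratios
  m_true <- model_4a5_122()
  comps <- list(c(cage = 2e-3, `4a` = 2e-3, `5` = 0),
                c(cage = 2e-3, `4a` = 4e-3, `5` = 0))
  ds <- gen_titration_dataset(
    m_true, "C.5.5", comps,
    noise_spec("multiplicative-lognormal", 0, 1),
    ratio_pairs = data.frame(numerator = "C.4a.4a", denominator = "C.4a"))
  expect_error(fit_stepwise_constants(ds, center = c(C.5.5 = 7.6)),
               "not identifiable")
})

test_that("recovery is unbiased across seeded replicates", {
  rs <- recovery_suite(12, "binding", seed = 5)
  expect_lt(rs$median_rel_error[rs$parameter == "K1"], 0.10)
  expect_lt(rs$median_rel_error[rs$parameter == "K2"], 0.10)
  expect_gte(min(rs$coverage25), 0.9)
})
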