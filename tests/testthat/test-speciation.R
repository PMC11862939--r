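test_that("a model with no complexes returns free = totals", {
  m <- binding_model(list(component("H", 1e-3), component("G", 5e-4)))
  sp <- solve_free_concentrations(m)
  expect_equal(sp$free, c(H = 1e-3, G = 5e-4))
  expect_length(sp$complexes, 0)
})

test_that("1:1 speciation matches the closed-form quadratic root", {
  cases <- expand.grid(H0 = c(2e-3, 5e-4), G0 = c(2e-3, 1e-2), K = c(2e4, 1e2, 1e7))
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], {
      m <- binding_model(
        list(component("H", H0), component("G", G0)),
        list(complex_species("HG", c(H = 1, G = 1), log10(K))))
      got <- solve_free_concentrations(m)$complexes[["HG"]]
      expect_equal(got, quadratic_hg(H0, G0, K), tolerance = 1e-10)
    })
  }
  # the reference case: host 2 mM, guest 2 mM, K = 2e4 -> 1.708 mM
  m <- binding_model(
    list(component("H", 2e-3), component("G", 2e-3)),
    list(complex_species("HG", c(H = 1, G = 1), log10(2e4))))
  expect_equal(solve_free_concentrations(m)$complexes[["HG"]],
               (81 - sqrt(161)) / 4e4, tolerance = 1e-10)
})

test_that("the five-species mixture reproduces the NMR speciation", {
  sp <- solve_free_concentrations(model_4a5_122())
  expect_lte(sp$residual_norm, 1e-9)
  expect_equal(round(sp$complexes[["C.4a.4a"]] * 1e3, 1), 0.9)
  expect_equal(round(sp$complexes[["C.4a.5"]] * 1e3, 1), 0.8)
  # mass balance of every component
  mm <- suprakin:::.model_matrices(model_4a5_122())
  bal <- sp$free + as.vector(t(mm$nu) %*% sp$complexes)
  expect_equal(unname(bal), unname(mm$totals), tolerance = 1e-9)
})

test_that("Newton solution matches brute-force bisection on random 2-component models", {
  set.seed(42)
  for (rep in 1:12) {
    H0 <- 10^runif(1, -4, -2)
    G0 <- 10^runif(1, -4, -2)
    K1 <- 10^runif(1, 2, 6)
    b2 <- K1 * 10^runif(1, 2, 6)
    m <- binding_model(
      list(component("H", H0), component("G", G0)),
      list(complex_species("HG", c(H = 1, G = 1), log10(K1)),
           complex_species("HG2", c(H = 1, G = 2), log10(b2))))
    got <- solve_free_concentrations(m)
    nu <- rbind(HG = c(1, 1), HG2 = c(1, 2))
    oracle <- bisect_speciation_oracle(c(H0, G0), nu, c(K1, b2))
    expect_equal(unname(got$free), unname(oracle$free), tolerance = 1e-8)
    expect_equal(unname(got$complexes), unname(oracle$complexes),
                 tolerance = 1e-8)
  }
})

test_that("raising a formation constant raises that species' concentration", {
  base <- model_4a5_122()
  sp0 <- solve_free_concentrations(base)
  for (s in names(sp0$complexes)) {
    lb <- vapply(base$species, `[[`, 0, "log10_beta")
    names(lb) <- vapply(base$species, `[[`, "", "name")
    m2 <- set_log10_beta(base, setNames(lb[[s]] + 0.3, s))
    sp2 <- solve_free_concentrations(m2)
    expect_gte(sp2$complexes[[s]], sp0$complexes[[s]])
  }
})

test_that("speciation is scale-consistent in dimensionless form", {
  # scaling all totals by s and beta_(order n) by s^(1-n) leaves bound
  # fractions unchanged
  fracs <- vapply(c(0.1, 1, 10), function(s) {
    m <- binding_model(
      list(component("H", 2e-3 * s), component("G", 4e-3 * s)),
      list(complex_species("HG", c(H = 1, G = 1), log10(2e4 / s)),
           complex_species("HG2", c(H = 1, G = 2), log10(6.2e8 / s^2))))
    sp <- solve_free_concentrations(m)
    (sp$complexes[["HG"]] + sp$complexes[["HG2"]]) / (2e-3 * s)
  }, 0)
  expect_equal(fracs[2], fracs[1], tolerance = 1e-9)
  expect_equal(fracs[3], fracs[1], tolerance = 1e-9)
})

test_that("zero totals are degenerate but legal", {
  m <- guest_pair_model("4a", "5", c(2e-3, 4e-3, 0))
  sp <- solve_free_concentrations(m)
  expect_identical(sp$free[["5"]], 0)
  expect_identical(sp$complexes[["C.5"]], 0)
  expect_identical(sp$complexes[["C.4a.5"]], 0)
  expect_gt(sp$complexes[["C.4a.4a"]], 0)
})

test_that("solver refuses models with free parameters", {
  m <- binding_model(
    list(component("H", 1e-3), component("G", 1e-3)),
    list(complex_species("HG", c(H = 1, G = 1), NA_real_)))
  expect_error(solve_free_concentrations(m), "free")
})

test_that("titration profiles are monotone and identify the dominant species", {
  m <- binding_model(
    list(component("H", 2e-3), component("G", 0)),
    list(complex_species("HG", c(H = 1, G = 1), log10(2e4))))
  grid <- seq(0, 4e-3, length.out = 9)
  pr <- speciation_profile(m, "G", grid)
  expect_equal(nrow(pr), 9)
  expect_true(all(diff(pr$HG) > 0))   # bound fraction strictly increases
  expect_equal(pr$HG, vapply(grid, function(g) quadratic_hg(2e-3, g, 2e4), 0),
               tolerance = 1e-9)
  # one-point grid degenerates to a single solve
  one <- speciation_profile(m, "G", 2e-3)
  expect_equal(one$HG, quadratic_hg(2e-3, 2e-3, 2e4), tolerance = 1e-9)
  # 2:1 complex dominates the host species at 2 equivalents of guest 4a
  mh <- guest_homo_model("4a", 2e-3, 0)
  ph <- speciation_profile(mh, "4a", c(2e-3, 4e-3))
  at2 <- ph[2, ]
  expect_gt(at2$C.4a.4a, at2$C.4a)
  expect_gt(at2$C.4a.4a, at2$free_cage)
})

test_that("model YAML round-trips through read/write", {
  m <- model_4a5_122()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_binding_model(m, path)
  m2 <- read_binding_model(path)
  expect_equal(solve_free_concentrations(m2)$complexes,
               solve_free_concentrations(m)$complexes, tolerance = 1e-12)
})
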