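model_4b5 <- function(totals = c(2, 2, 4) * 1e-3) {
  guest_pair_model("4b", "5", totals)
}

test_that("the cage network has the expected topology", {
  net <- build_cage_network(model_4b5(), 5e-5)
  expect_length(net$initial, 9L)    # cage, 2 guests, 5 complexes, product
  rev <- vapply(net$reactions, function(r) !is.na(r$k_reverse), TRUE)
  expect_identical(sum(rev), 6L)
  expect_identical(sum(!rev), 1L)
  expect_identical(attr(net, "ternary"), "C.4b.5")
  # every reversible step honours its stepwise constant
  mm <- suprakin:::.model_matrices(model_4b5())
  beta <- setNames(10^mm$log10_beta, rownames(mm$nu))
  r <- net$reactions[[5]]  # C.4b + 5 <-> C.4b.5
  expect_equal(r$k_forward / r$k_reverse, unname(beta["C.4b.5"] / beta["C.4b"]))
})

test_that("a missing complex species is a construction error", {
  m <- binding_model(
    list(component("cage", 2e-3), component("4b", 2e-3), component("5", 4e-3)),
    list(complex_species("C.4b", c(cage = 1, `4b` = 1), log10(4e5))))
  expect_error(build_cage_network(m, 1e-5), "C.5")
})

test_that("dead networks hold constant trajectories", {
  net <- kinetic_network(c(A = 1e-3, B = 2e-3, P = 0),
                         list(reaction(c(A = 1, B = 1), c(P = 1), 0)))
  tc <- simulate_network(net, c(10, 1e4, 1e6))
  expect_equal(tc$A, rep(1e-3, 3))
  expect_equal(tc$P, rep(0, 3))
})

test_that("a single irreversible bimolecular step matches the closed form", {
  A0 <- 25e-3; k <- 5.6e-8
  net <- kinetic_network(c(A = A0, B = A0, P = 0),
                         list(reaction(c(A = 1, B = 1), c(P = 1), k)))
  times <- c(1e4, 1e5, 1e6, 5e6)
  tc <- simulate_network(net, times)
  expect_equal(tc$P, second_order_equal(A0, k, times), tolerance = 1e-6)
})

test_that("with no reaction the network relaxes to the equilibrium speciation", {
  m <- model_4b5()
  net <- build_cage_network(m, 0, init = "unmixed")
  tc <- simulate_network(net, c(0.1, 1, 10))
  eq <- solve_free_concentrations(m)
  ref <- c(eq$free, eq$complexes)
  last <- unlist(tc[nrow(tc), names(ref)])
  expect_equal(last, ref, tolerance = 1e-6)
})

test_that("host and guest moieties are conserved along reactive trajectories", {
  net <- build_cage_network(model_4b5(), 5e-5)
  tc <- simulate_network(net, c(0.5, 1, 2, 4, 8, 12, 24, 36, 48) * 3600)
  expect_lt(max(conservation_error(net, tc)), 1e-7)
})

test_that("the bound product dominates the host species by 48 h", {
  net <- build_cage_network(model_4b5(), 5e-5)
  tc <- simulate_network(net, 48 * 3600)
  host_species <- c("C.4b", "C.5", "C.4b.4b", "C.5.5", "C.4b.5", "cage")
  expect_true(all(tc$C.P > unlist(tc[host_species])))
  expect_gt(tc$C.P / 2e-3, 0.75)
})

test_that("composition calibration hits a target ternary concentration", {
  for (target in c(0.54, 0.32, 0.10) * 1e-3) {
    m <- calibrate_ternary_composition(model_4b5(), target)
    got <- solve_free_concentrations(m)$complexes[["C.4b.5"]]
    expect_equal(got, target, tolerance = 1e-8)
  }
  expect_error(calibrate_ternary_composition(model_4b5(), 5),
               "not bracketed")
})
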