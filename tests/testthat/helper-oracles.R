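# Independent oracles, deliberately implemented with different numerics than
# the package (arithmetic-scale interval halving, closed forms).

# closed-form 1:1 complex concentration for H + G <-> HG with constant K
quadratic_hg <- function(H0, G0, K) {
  b <- H0 + G0 + 1 / K
  (b - sqrt(b^2 - 4 * H0 * G0)) / 2
}

# brute-force speciation for models with <= 2 components: nested interval
# halving on the free concentrations (arithmetic scale)
bisect_speciation_oracle <- function(totals, nu, beta, iters = 120) {
  excess <- function(x, j) {
    cs <- beta * apply(nu, 1, function(v) prod(x^v))
    x[j] + sum(nu[, j] * cs) - totals[j]
  }
  solve_j <- function(x, j) {
    lo <- 0; hi <- totals[j]
    for (i in seq_len(iters)) {
      mid <- (lo + hi) / 2
      x[j] <- mid
      if (excess(x, j) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  x <- totals
  for (outer in 1:200) {
    x_old <- x
    for (j in seq_along(totals)) x[j] <- solve_j(x, j)
    if (max(abs(x - x_old)) < 1e-18) break
  }
  cs <- beta * apply(nu, 1, function(v) prod(x^v))
  list(free = x, complexes = cs)
}

# integrated second-order product for A + B -> P with A0 = B0
second_order_equal <- function(A0, k, t) A0^2 * k * t / (1 + A0 * k * t)

# the reference five-species binding model of guests 4a and 5 at the
# 1:2:2 mixture composition
model_4a5_122 <- function() guest_pair_model("4a", "5", c(2e-3, 4e-3, 4e-3))
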