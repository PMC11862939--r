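#' Stepwise binding-constant pair
#'
#' The two stepwise macroscopic constants of a sequential two-site binding
#' process: \code{K_first} for guest addition to the host solvate and
#' \code{K_second} for addition of the second guest to the 1:1 complex
#' (both M^-1).
#'
#' @param K_first,K_second Stepwise constants in M^-1, both > 0.
#' @return An object of class \code{"stepwise_pair"}.
#' @export
stepwise_pair <- function(K_first, K_second) {
  if (!is.numeric(K_first) || !is.numeric(K_second) ||
      length(K_first) != 1L || length(K_second) != 1L ||
      !is.finite(K_first) || !is.finite(K_second) ||
      K_first <= 0 || K_second <= 0) {
    stop("stepwise constants must be single positive finite numbers (M^-1)")
  }
  structure(list(K_first = as.numeric(K_first), K_second = as.numeric(K_second)),
            class = "stepwise_pair")
}

.as_pair <- function(pair) {
  if (inherits(pair, "stepwise_pair")) return(pair)
  if (is.numeric(pair) && length(pair) == 2L) return(stepwise_pair(pair[1], pair[2]))
  stop("expected a stepwise_pair or a numeric vector of length 2")
}

#' Overall formation constant of a 2:1 complex
#'
#' beta_2:1 = K_1:1 x K_1:1->2:1, the constant of the one-step equilibrium
#' host + guest1 + guest2 <-> ternary complex (units M^-2).
#'
#' @param pair A \code{\link{stepwise_pair}} (or numeric length-2 vector).
#' @return Overall constant in M^-2.
#' @examples
#' overall_beta(stepwise_pair(2.0e4, 3.1e4))  # 6.2e8
#' @export
overall_beta <- function(pair) {
  pair <- .as_pair(pair)
  pair$K_first * pair$K_second
}

#' Cooperativity factor of sequential two-site binding
#'
#' The statistically corrected ratio alpha = (2 K_second) / (K_first / 2)
#' = 4 K_second / K_first. For two independent identical sites the statistical
#' relation K_second = K_first / 4 gives alpha = 1; alpha > 1 indicates
#' positive and alpha < 1 negative cooperativity.
#'
#' @inheritParams overall_beta
#' @return Dimensionless cooperativity factor.
#' @examples
#' cooperativity_alpha(stepwise_pair(2.0e4, 3.1e4))  # 6.2
#' cooperativity_alpha(stepwise_pair(3.2e4, 1.2e3))  # 0.15
#' @export
cooperativity_alpha <- function(pair) {
  pair <- .as_pair(pair)
  4 * pair$K_second / pair$K_first
}

#' Disproportionation constant of homo- into heteroternary complexes
#'
#' Equilibrium constant of (A)2-host + (B)2-host <-> 2 (A.B)-host, expressed
#' through the overall formation constants:
#' K_dispro = beta_het^2 / (beta_AA x beta_BB). For non-cooperative identical
#' sites the statistical value is 4.
#'
#' @param beta_hetero Overall constant of the heteroternary complex (M^-2).
#' @param beta_homo_A,beta_homo_B Overall constants of the two homoternary
#'   complexes (M^-2).
#' @return Dimensionless equilibrium constant.
#' @examples
#' disproportionation_constant(2.8e8, 6.2e8, 4.0e7)  # ~3.2, reported as 3
#' @export
disproportionation_constant <- function(beta_hetero, beta_homo_A, beta_homo_B) {
  b <- c(beta_hetero, beta_homo_A, beta_homo_B)
  if (!is.numeric(b) || length(b) != 3L || any(!is.finite(b)) || any(b <= 0)) {
    stop("all overall constants must be positive finite numbers (M^-2)")
  }
  beta_hetero^2 / (beta_homo_A * beta_homo_B)
}

#' Consistency of two stepwise paths to the same ternary complex
#'
#' A heteroternary complex can be reached by binding either guest first; both
#' stepwise paths must give the same overall constant. Returns the relative
#' residual |beta1 - beta2| / max(beta1, beta2) and a pass flag at the given
#' tolerance.
#'
#' @param path1,path2 \code{\link{stepwise_pair}}s for the two addition orders.
#' @param rel_tol Relative tolerance for the pass flag (default 0.01).
#' @return List with \code{beta1}, \code{beta2}, \code{residual}, \code{pass}.
#' @examples
#' path_consistency(stepwise_pair(2.0e4, 1.4e4), stepwise_pair(3.2e4, 8.8e3))
#' @export
path_consistency <- function(path1, path2, rel_tol = 0.01) {
  b1 <- overall_beta(path1)
  b2 <- overall_beta(path2)
  residual <- abs(b1 - b2) / max(b1, b2)
  list(beta1 = b1, beta2 = b2, residual = residual, pass = residual <= rel_tol)
}

#' Round to a number of significant figures
#'
#' Reporting helper mirroring the two-significant-figure convention of binding
#' tables; internal math is always full precision.
#'
#' @param x Numeric.
#' @param digits Significant figures (default 2).
#' @return Rounded numeric.
#' @export
signif_report <- function(x, digits = 2) signif(x, digits)
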