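#' Define the bulk two-channel bimolecular reaction model
#'
#' The uncatalysed azide + alkyne cycloaddition in solution: a single
#' second-order reaction A + B feeding two parallel irreversible product
#' channels, the 1,4- and the 1,5-triazole regioisomer, with rate constants
#' \code{k_14} and \code{k_15} (M^-1 s^-1). The product ratio P14/P15 equals
#' k_14/k_15 at all times.
#'
#' @param k_14,k_15 Channel rate constants (M^-1 s^-1, >= 0).
#' @param A0,B0 Initial reactant concentrations (M).
#' @return Object of class \code{"bulk_model"}.
#' @export
bulk_reaction_model <- function(k_14, k_15, A0, B0) {
  stopifnot(k_14 >= 0, k_15 >= 0, A0 >= 0, B0 >= 0)
  structure(list(k_14 = k_14, k_15 = k_15, A0 = A0, B0 = B0),
            class = "bulk_model")
}

#' Simulate the bulk reaction
#'
#' Integrates dA/dt = dB/dt = -(k14 + k15) A B, dP14/dt = k14 A B,
#' dP15/dt = k15 A B with the stiff-capable integrator used throughout.
#'
#' @param model A \code{\link{bulk_reaction_model}}.
#' @param times Strictly increasing output times (s).
#' @inheritParams simulate_network
#' @return Data frame with columns \code{time_s}, \code{A}, \code{B},
#'   \code{P14}, \code{P15} (M).
#' @export
simulate_bulk <- function(model, times, rtol = 1e-8, atol = 1e-15) {
  stopifnot(inherits(model, "bulk_model"))
  init <- c(A = model$A0, B = model$B0, P14 = 0, P15 = 0)
  rx <- list()
  if (model$k_14 > 0) {
    rx <- c(rx, list(reaction(c(A = 1, B = 1), c(P14 = 1), model$k_14)))
  }
  if (model$k_15 > 0) {
    rx <- c(rx, list(reaction(c(A = 1, B = 1), c(P15 = 1), model$k_15)))
  }
  if (!length(rx)) {
    out <- data.frame(time_s = times, A = model$A0, B = model$B0,
                      P14 = 0, P15 = 0)
    return(out)
  }
  net <- kinetic_network(init, rx)
  simulate_network(net, times, rtol = rtol, atol = atol)
}

#' Fit the bulk 1,4-channel rate constant from a product time course
#'
#' Least-squares fit of the observed 1,4-product concentrations to the
#' two-channel second-order model, with k_14 as the only free parameter; the
#' 1,5 channel keeps the skeleton's k_15/k_14 ratio (fixed regioselectivity).
#'
#' @param observed Data frame with columns \code{time_s} and \code{P14} (M).
#' @param model_skeleton A \code{\link{bulk_reaction_model}} carrying the
#'   initial concentrations and the channel ratio.
#' @param bracket log10 search bracket for k_14 (default \code{c(-10, -5)}).
#' @return List with \code{k_14}, \code{objective_value}.
#' @export
fit_k_bulk <- function(observed, model_skeleton, bracket = c(-10, -5)) {
  stopifnot(inherits(model_skeleton, "bulk_model"))
  if (!all(c("time_s", "P14") %in% names(observed))) {
    stop("observed must have columns time_s and P14")
  }
  if (all(observed$P14 == 0)) stop("all observed product concentrations are zero")
  ratio <- if (model_skeleton$k_14 > 0) {
    model_skeleton$k_15 / model_skeleton$k_14
  } else 0
  sse <- function(log10k) {
    k14 <- 10^log10k
    m <- bulk_reaction_model(k14, k14 * ratio, model_skeleton$A0,
                             model_skeleton$B0)
    sim <- simulate_bulk(m, observed$time_s)
    sum((sim$P14 - observed$P14)^2)
  }
  op <- optimize(sse, bracket, tol = 1e-8)
  list(k_14 = 10^op$minimum, objective_value = op$objective)
}

#' Time for the bulk reaction to reach a target 1,4-product concentration
#'
#' Inverts the integrated second-order rate law. With x the total converted
#' concentration (both channels) and k_tot = k14 + k15: for A0 = B0,
#' t = (1/(A0 - x) - 1/A0) / k_tot; for A0 != B0 the unequal-concentration
#' integrated law is inverted in closed form. The target 1,4-product
#' concentration corresponds to x = target / (k14/k_tot).
#'
#' @param model A \code{\link{bulk_reaction_model}} with k_14 > 0.
#' @param target_P14 Target 1,4-product concentration (M).
#' @return Time in seconds.
#' @examples
#' m <- bulk_reaction_model(5.6e-8, 0, 2e-3, 2e-3)
#' time_to_conversion(m, 1e-3) / 3.154e7   # years to 1 mM product
#' @export
time_to_conversion <- function(model, target_P14) {
  stopifnot(inherits(model, "bulk_model"))
  if (target_P14 < 0) stop("target must be >= 0")
  if (target_P14 == 0) return(0)
  k_tot <- model$k_14 + model$k_15
  if (model$k_14 <= 0 || k_tot <= 0) stop("k_14 must be positive")
  frac <- model$k_14 / k_tot
  x <- target_P14 / frac
  A0 <- model$A0; B0 <- model$B0
  if (x >= min(A0, B0)) {
    stop("target exceeds the reachable product concentration (",
         format(min(A0, B0) * frac), " M)")
  }
  if (isTRUE(all.equal(A0, B0))) {
    (1 / (A0 - x) - 1 / A0) / k_tot
  } else {
    log(((B0 - x) * A0) / ((A0 - x) * B0)) / ((B0 - A0) * k_tot)
  }
}
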