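#' Effective molarity of a container-accelerated reaction
#'
#' EM = k_intra / k_bulk: the reactant concentration at which the bulk
#' bimolecular reaction would match the first-order in-cage rate. Units M.
#'
#' @param k_intra In-cage first-order rate constant (s^-1).
#' @param k_bulk Bulk second-order rate constant (M^-1 s^-1), > 0.
#' @return Effective molarity (M).
#' @examples
#' effective_molarity(5.0e-5, 5.6e-8)  # ~893 M, order 1e3
#' @export
effective_molarity <- function(k_intra, k_bulk) {
  if (!is.numeric(k_bulk) || k_bulk <= 0) stop("k_bulk must be > 0")
  if (!is.numeric(k_intra) || k_intra < 0) stop("k_intra must be >= 0")
  k_intra / k_bulk
}

#' Entropy and free-energy equivalents of an effective molarity
#'
#' Interprets EM as a purely entropic advantage via EM = exp(dS/R) with the
#' convention that confining the bimolecular reaction saves the entropy cost
#' dS = -R ln(EM / 1 M) (negative for EM > 1 M, in entropy units
#' e.u. = cal mol^-1 K^-1), worth |dS| T in free energy.
#'
#' @param EM Effective molarity (M), > 0.
#' @param T Temperature (K), default 298.15.
#' @param R Gas constant in cal mol^-1 K^-1, default 1.9872.
#' @return List with \code{delta_S} (e.u.) and \code{delta_G} (kcal/mol,
#'   magnitude of T dS).
#' @examples
#' em_to_entropy(1.0e3)   # dS = -13.7 e.u., dG = 4.1 kcal/mol
#' entropy_to_em(-35)     # 4e7 M
#' @export
em_to_entropy <- function(EM, T = .T_REF, R = .R_CAL) {
  if (!is.numeric(EM) || EM <= 0) stop("EM must be > 0")
  dS <- -R * log(EM)
  list(delta_S = dS, delta_G = T * abs(dS) / 1000)
}

#' @rdname em_to_entropy
#' @param delta_S Entropy in e.u. (cal mol^-1 K^-1).
#' @export
entropy_to_em <- function(delta_S, R = .R_CAL) {
  exp(-delta_S / R)
}

#' Bundle paired in-cage and bulk rate constants with acceleration metrics
#'
#' @param k_intra In-cage rate constant (s^-1).
#' @param k_bulk Bulk rate constant (M^-1 s^-1).
#' @param T Temperature (K).
#' @param R Gas constant (cal mol^-1 K^-1).
#' @return Object of class \code{"acceleration_result"}: k_intra, k_bulk,
#'   EM (M), delta_S (e.u.), delta_G (kcal/mol), T, R.
#' @export
acceleration_result <- function(k_intra, k_bulk, T = .T_REF, R = .R_CAL) {
  EM <- effective_molarity(k_intra, k_bulk)
  ent <- em_to_entropy(EM, T, R)
  structure(list(k_intra = k_intra, k_bulk = k_bulk, EM = EM,
                 delta_S = ent$delta_S, delta_G = ent$delta_G, T = T, R = R),
            class = "acceleration_result")
}

#' @export
print.acceleration_result <- function(x, ...) {
  cat("<acceleration_result>\n")
  cat(sprintf("  k_intra  %.3g s^-1\n", x$k_intra))
  cat(sprintf("  k_bulk   %.3g M^-1 s^-1\n", x$k_bulk))
  cat(sprintf("  EM       %.2g M\n", signif(x$EM, 2)))
  cat(sprintf("  delta_S  %.1f e.u.\n", x$delta_S))
  cat(sprintf("  delta_G  %.1f kcal/mol at %.2f K\n", x$delta_G, x$T))
  invisible(x)
}
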