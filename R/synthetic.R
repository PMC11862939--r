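# Seeded synthetic observations with the statistical structure of NMR
# integrals (multiplicative lognormal error) and HPLC quantitation (additive
# Gaussian error), so every estimation stage is testable without instrument
# data.

#' Specify an observation-noise model
#'
#' @param kind \code{"multiplicative-lognormal"} (NMR-integral-like; level is
#'   the standard deviation of log observation) or \code{"additive-gaussian"}
#'   (HPLC-like; level is the standard deviation as a fraction of the largest
#'   signal).
#' @param level Noise level, >= 0.
#' @param seed Integer seed; required so no generator touches implicit global
#'   RNG state.
#' @return Object of class \code{"noise_spec"}.
#' @export
noise_spec <- function(kind = c("multiplicative-lognormal", "additive-gaussian"),
                       level = 0.05, seed) {
  kind <- match.arg(kind)
  if (missing(seed)) stop("an explicit integer seed is required")
  stopifnot(is.numeric(level), level >= 0, is.numeric(seed))
  structure(list(kind = kind, level = level, seed = as.integer(seed)),
            class = "noise_spec")
}

# evaluate expr under a private RNG stream, restoring global state after
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.apply_noise <- function(x, noise, ref = max(abs(x), 1e-300)) {
  if (noise$level == 0) return(x)
  switch(noise$kind,
    "multiplicative-lognormal" = x * exp(rnorm(length(x), 0, noise$level)),
    "additive-gaussian" = pmax(x + rnorm(length(x), 0, noise$level * ref), 0))
}

#' Define a kinetic scenario
#'
#' A named study condition: the guest pair, the mixture totals and the
#' sampling schedule of one monitored run.
#'
#' @param name Scenario label.
#' @param guests Character vector of two guest labels.
#' @param totals Numeric length 3: totals of cage, first guest, second guest
#'   (M).
#' @param schedule_s Strictly increasing sampling times (s).
#' @return Object of class \code{"sk_scenario"}.
#' @export
kinetic_scenario <- function(name, guests, totals, schedule_s) {
  stopifnot(length(guests) == 2L, length(totals) == 3L, all(totals >= 0),
            all(diff(schedule_s) > 0))
  structure(list(name = name, guests = guests, totals = as.numeric(totals),
                 schedule_s = as.numeric(schedule_s)),
            class = "sk_scenario")
}

#' Shipped default scenarios
#'
#' The study conditions of the monitored experiments: cage kinetics at 2 mM
#' cage with guest molar ratios 1:1:2, 1:1:1 and 1:5:5, sampled at 0.5, 1, 2,
#' 4, 8, 12, 24, 36 and 48 h (NMR monitoring window); bulk kinetics at 25 mM
#' of each reactant, 8 HPLC points over 10 days.
#'
#' @return Named list of \code{\link{kinetic_scenario}} objects.
#' @export
default_scenarios <- function() {
  nmr_sched <- c(0.5, 1, 2, 4, 8, 12, 24, 36, 48) * 3600
  hplc_sched <- c(0.5, 1, 2, 3, 5, 7, 9, 10) * 86400
  list(
    cage_1_1_2 = kinetic_scenario("cage_1_1_2", c("4b", "5"),
                                  c(2, 2, 4) * 1e-3, nmr_sched),
    cage_1_1_1 = kinetic_scenario("cage_1_1_1", c("4b", "5"),
                                  c(2, 2, 2) * 1e-3, nmr_sched),
    cage_1_5_5 = kinetic_scenario("cage_1_5_5", c("4b", "5"),
                                  c(2, 10, 10) * 1e-3, nmr_sched),
    bulk_25mM = kinetic_scenario("bulk_25mM", c("4b", "5"),
                                 c(0, 25, 25) * 1e-3, hplc_sched)
  )
}

#' Generate a synthetic titration dataset
#'
#' Computes true equilibrium concentration ratios from a fully specified
#' binding model over a set of compositions, applies multiplicative noise and
#' packages the result with a fitting skeleton in which the chosen species
#' are free. By default each complex species is observed as its ratio to the
#' free host (the first component), the observable an NMR titration provides.
#'
#' @param model_true Fully specified \code{\link{binding_model}}.
#' @param free_species Species whose constants the skeleton leaves free.
#' @param compositions List of named numeric vectors of component totals (M).
#' @param noise A \code{\link{noise_spec}} (multiplicative kind).
#' @param ratio_pairs Optional data frame with columns \code{numerator},
#'   \code{denominator}; default: every complex vs the free host.
#' @return A \code{\link{titration_dataset}}; the generating constants are in
#'   attribute \code{"truth"}.
#' @export
gen_titration_dataset <- function(model_true, free_species, compositions,
                                  noise, ratio_pairs = NULL) {
  stopifnot(inherits(model_true, "binding_model"), inherits(noise, "noise_spec"))
  comp_names <- vapply(model_true$components, `[[`, "", "name")
  sp_names <- vapply(model_true$species, `[[`, "", "name")
  if (is.null(ratio_pairs)) {
    ratio_pairs <- data.frame(numerator = sp_names,
                              denominator = comp_names[1],
                              stringsAsFactors = FALSE)
  }
  rows <- list()
  for (comp in compositions) {
    for (j in seq_len(nrow(ratio_pairs))) {
      r <- tryCatch(predict_ratio(model_true, comp, ratio_pairs$numerator[j],
                                  ratio_pairs$denominator[j]),
                    error = function(e) NA_real_)
      if (!is.finite(r) || r <= 0) next    # species below detection: skip
      row <- as.list(setNames(comp[comp_names], paste0("total_", comp_names)))
      row$numerator_species <- ratio_pairs$numerator[j]
      row$denominator_species <- ratio_pairs$denominator[j]
      row$observed_ratio <- r
      row$relative_sigma <- max(noise$level, 1e-3)
      rows[[length(rows) + 1L]] <- row
    }
  }
  obs <- do.call(rbind, lapply(rows, as.data.frame))
  obs$observed_ratio <- .with_seed(noise$seed,
                                   .apply_noise(obs$observed_ratio, noise))
  skeleton <- set_log10_beta(model_true,
                             setNames(rep(NA_real_, length(free_species)),
                                      free_species))
  ds <- titration_dataset(obs, skeleton)
  lb <- vapply(model_true$species, `[[`, 0, "log10_beta")
  attr(ds, "truth") <- setNames(lb, sp_names)[free_species]
  ds
}

#' Generate a synthetic in-cage kinetic time course
#'
#' Simulates the full binding + reaction network for a scenario and returns
#' the bound-product trajectory at the sampling schedule with multiplicative
#' noise, emulating NMR monitoring of the product complex.
#'
#' @param scenario A \code{\link{kinetic_scenario}}.
#' @param k_intra In-cage rate constant (s^-1).
#' @param noise A \code{\link{noise_spec}}.
#' @param constants Binding-constants table.
#' @param k_on_reference Binding on-rate (M^-1 s^-1).
#' @param model Optional pre-built \code{\link{binding_model}} overriding the
#'   scenario totals (e.g. from
#'   \code{\link{calibrate_ternary_composition}}).
#' @return Data frame with \code{time_s} and the noisy product column
#'   \code{C.P} (M). Attributes: \code{"truth"} (k_intra), \code{"ternary0"}
#'   (initial ternary concentration, M), \code{"network"}.
#' @export
gen_cage_time_course <- function(scenario, k_intra, noise,
                                 constants = cage_binding_constants(),
                                 k_on_reference = 1e7, model = NULL) {
  stopifnot(inherits(scenario, "sk_scenario"), inherits(noise, "noise_spec"))
  if (is.null(model)) {
    model <- guest_pair_model(scenario$guests[1], scenario$guests[2],
                              scenario$totals, constants = constants)
  }
  net <- build_cage_network(model, k_intra, k_on_reference = k_on_reference)
  sim <- simulate_network(net, scenario$schedule_s)
  prod <- attr(net, "product")
  out <- data.frame(time_s = sim$time_s, check.names = FALSE)
  out[[prod]] <- .with_seed(noise$seed, .apply_noise(sim[[prod]], noise))
  attr(out, "truth") <- k_intra
  attr(out, "ternary0") <- unname(net$initial[attr(net, "ternary")])
  attr(out, "network") <- net
  out
}

#' Generate a synthetic bulk kinetic time course
#'
#' Simulates the two-channel bulk reaction and applies additive Gaussian
#' noise (scaled to the largest 1,4-product signal) to both isomer channels,
#' emulating HPLC quantitation against calibration curves.
#'
#' @param scenario A \code{\link{kinetic_scenario}} (totals: the last two
#'   entries are the reactant concentrations).
#' @param k_14,k_15 Channel rate constants (M^-1 s^-1).
#' @param noise A \code{\link{noise_spec}} (additive kind).
#' @return Data frame with \code{time_s}, \code{P14}, \code{P15} (M);
#'   attribute \code{"truth"} carries the generating constants.
#' @export
gen_bulk_time_course <- function(scenario, k_14, k_15, noise) {
  stopifnot(inherits(scenario, "sk_scenario"), inherits(noise, "noise_spec"))
  m <- bulk_reaction_model(k_14, k_15, scenario$totals[2], scenario$totals[3])
  sim <- simulate_bulk(m, scenario$schedule_s)
  ref <- max(sim$P14, 1e-300)
  out <- data.frame(time_s = sim$time_s)
  noisy <- .with_seed(noise$seed, {
    list(P14 = .apply_noise(sim$P14, noise, ref),
         P15 = .apply_noise(sim$P15, noise, ref))
  })
  out$P14 <- noisy$P14
  out$P15 <- noisy$P15
  attr(out, "truth") <- c(k_14 = k_14, k_15 = k_15)
  out
}

#' Seeded parameter-recovery study
#'
#' Repeats a generate-then-fit round trip over seeded replicates and
#' summarises recovery quality per parameter: median relative error, RMSE of
#' the relative error and coverage of a +/-25% interval around the truth.
#'
#' @param n_replicates Number of replicates (>= 2).
#' @param what \code{"k_intra"} (initial-rates estimation at the three
#'   reference Michaelis-complex concentrations), \code{"k_bulk"} (bulk-curve
#'   fitting at 25 mM) or \code{"binding"} (stepwise-constant fitting from a
#'   homo titration of guest 4a).
#' @param noise_level Noise level (default 0.05 NMR-like, 0.03 HPLC-like for
#'   \code{"k_bulk"}).
#' @param seed Base seed; replicate i uses \code{seed + i}.
#' @return Data frame: one row per parameter with columns \code{parameter},
#'   \code{truth}, \code{median_rel_error}, \code{rmse_rel}, \code{coverage25}.
#' @export
recovery_suite <- function(n_replicates, what = c("k_intra", "k_bulk", "binding"),
                           noise_level = NULL, seed = 1L) {
  what <- match.arg(what)
  stopifnot(n_replicates >= 2L)
  if (is.null(noise_level)) noise_level <- if (what == "k_bulk") 0.03 else 0.05
  est <- switch(what,
    k_intra = .recover_k_intra(n_replicates, noise_level, seed),
    k_bulk = .recover_k_bulk(n_replicates, noise_level, seed),
    binding = .recover_binding(n_replicates, noise_level, seed))
  out <- lapply(names(est$truth), function(p) {
    rel <- est$estimates[, p] / est$truth[[p]] - 1
    data.frame(parameter = p, truth = est$truth[[p]],
               median_rel_error = median(abs(rel)),
               rmse_rel = sqrt(mean(rel^2)),
               coverage25 = mean(abs(rel) <= 0.25))
  })
  do.call(rbind, out)
}

# initial-rates recovery at the reference ternary concentrations
.recover_k_intra <- function(n, level, seed, k_true = 5.0e-5,
                             ternary = c(0.54, 0.32, 0.10) * 1e-3) {
  sc <- default_scenarios()$cage_1_1_2
  models <- lapply(ternary, function(ct) {
    calibrate_ternary_composition(
      guest_pair_model("4b", "5", sc$totals), ct)
  })
  ks <- vapply(seq_len(n), function(i) {
    tcs <- lapply(seq_along(models), function(j) {
      gen_cage_time_course(sc, k_true,
                           noise_spec("multiplicative-lognormal", level,
                                      seed + 1000L * j + i),
                           model = models[[j]])
    })
    initial_rates_estimate(tcs, ternary)$k_intra
  }, 0)
  list(truth = c(k_intra = k_true), estimates = cbind(k_intra = ks))
}

.recover_k_bulk <- function(n, level, seed, k_true = 5.6e-8, ratio = 2) {
  sc <- default_scenarios()$bulk_25mM
  skel <- bulk_reaction_model(1e-8, 1e-8 / ratio, sc$totals[2], sc$totals[3])
  ks <- vapply(seq_len(n), function(i) {
    tc <- gen_bulk_time_course(sc, k_true, k_true / ratio,
                               noise_spec("additive-gaussian", level, seed + i))
    fit_k_bulk(tc, skel)$k_14
  }, 0)
  list(truth = c(k_14 = k_true), estimates = cbind(k_14 = ks))
}

.recover_binding <- function(n, level, seed) {
  truth <- cage_stepwise("4a", "4a")
  model <- guest_homo_model("4a", 2e-3, 0, use = "stepwise")
  comps <- lapply(c(0.5, 1, 1.5, 2) * 2e-3, function(g) c(cage = 2e-3, `4a` = g))
  free <- c("C.4a", "C.4a.4a")
  center <- setNames(c(log10(truth$K_first),
                       log10(truth$K_first * truth$K_second)), free)
  est <- t(vapply(seq_len(n), function(i) {
    ds <- gen_titration_dataset(model, free, comps,
                                noise_spec("multiplicative-lognormal", level,
                                           seed + i))
    fit <- fit_stepwise_constants(ds, center = center, window = 1.5,
                                  grid_step = 0.25)
    K1 <- fit$K[["C.4a"]]
    c(K1 = K1, K2 = fit$K[["C.4a.4a"]] / K1)
  }, c(K1 = 0, K2 = 0)))
  list(truth = c(K1 = truth$K_first, K2 = truth$K_second), estimates = est)
}
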