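# Workflow orchestration: the two analysis chains (binding characterisation;
# kinetics & acceleration) as plain functions over the module surface, plus
# the long-format CSV schema shared by the generators and the fitters.

#' Read / write time-course CSV files
#'
#' Long format, one row per observation: columns \code{time_s},
#' \code{species}, \code{concentration_M}, \code{sigma_rel}.
#'
#' @param path CSV path.
#' @return \code{read_time_course_csv}: a wide data frame (\code{time_s} plus
#'   one column per species) with a \code{"sigma_rel"} attribute.
#' @export
read_time_course_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "species", "concentration_M")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("malformed time-course CSV '", path, "': missing column(s) ",
         paste(miss, collapse = ", "))
  }
  if (nrow(d) == 0L) stop("time-course CSV '", path, "' has no observations")
  wide <- data.frame(time_s = sort(unique(d$time_s)))
  for (sp in unique(d$species)) {
    sub <- d[d$species == sp, ]
    wide[[sp]] <- sub$concentration_M[match(wide$time_s, sub$time_s)]
  }
  if ("sigma_rel" %in% names(d)) {
    attr(wide, "sigma_rel") <- tapply(d$sigma_rel, d$species, mean)
  }
  wide
}

#' @rdname read_time_course_csv
#' @param tc Wide time course (\code{time_s} plus species columns).
#' @param sigma_rel Relative noise level to record (default NA).
#' @export
write_time_course_csv <- function(tc, path, sigma_rel = NA_real_) {
  sp_cols <- setdiff(names(tc), "time_s")
  long <- do.call(rbind, lapply(sp_cols, function(sp) {
    data.frame(time_s = tc$time_s, species = sp,
               concentration_M = tc[[sp]], sigma_rel = sigma_rel)
  }))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Run the binding-characterisation workflow
#'
#' Fits the free constants of a model skeleton to titration observations,
#' then derives the standard binding metrics (stepwise constants,
#' cooperativity where a homo pair is identifiable, speciation of the fitted
#' model at the observed compositions) and writes a machine-readable report.
#'
#' @param observations_csv CSV of ratio observations (columns
#'   \code{total_<component>} in mM, \code{numerator_species},
#'   \code{denominator_species}, \code{observed_ratio},
#'   \code{relative_sigma}).
#' @param model_yaml Model-skeleton YAML (see \code{\link{read_binding_model}};
#'   free species have \code{log10_beta: ~}).
#' @param out_dir Output directory (created if needed); writes
#'   \code{binding_report.json} and \code{speciation.csv}.
#' @param center,window,grid_step Passed to
#'   \code{\link{fit_stepwise_constants}}.
#' @return The report list, invisibly.
#' @export
run_binding_workflow <- function(observations_csv, model_yaml, out_dir,
                                 center = NULL, window = 3, grid_step = 0.1) {
  skeleton <- read_binding_model(model_yaml)
  obs <- read.csv(observations_csv, stringsAsFactors = FALSE)
  if (nrow(obs) == 0L) stop("observation file '", observations_csv, "' is empty")
  tot_cols <- grep("^total_", names(obs), value = TRUE)
  obs[tot_cols] <- lapply(obs[tot_cols], function(x) x * 1e-3)  # mM -> M
  ds <- titration_dataset(obs, skeleton)
  fit <- fit_stepwise_constants(ds, center = center, window = window,
                                grid_step = grid_step)
  fitted_model <- set_log10_beta(skeleton, fit$estimates)

  # speciation of the fitted model at every observed composition
  comp_names <- vapply(skeleton$components, `[[`, "", "name")
  comps <- unique(obs[paste0("total_", comp_names)])
  spec_rows <- lapply(seq_len(nrow(comps)), function(i) {
    tt <- setNames(as.numeric(comps[i, ]), comp_names)
    sp <- solve_free_concentrations(set_totals(fitted_model, tt))
    c(setNames(tt, paste0("total_", comp_names)), sp$free, sp$complexes)
  })
  spec_tab <- as.data.frame(do.call(rbind, spec_rows), check.names = FALSE)

  report <- list(
    estimates_log10_beta = as.list(fit$estimates),
    estimates_beta = as.list(fit$K),
    estimates_beta_2sf = as.list(signif_report(fit$K)),
    objective_value = fit$objective_value,
    converged = fit$convergence_flag,
    fixed_log10_beta = {
      lb <- vapply(skeleton$species, `[[`, 0, "log10_beta")
      nm <- vapply(skeleton$species, `[[`, "", "name")
      as.list(setNames(lb, nm)[!is.na(lb)])
    }
  )
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, file.path(out_dir, "binding_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out_spec <- spec_tab
  out_spec[] <- lapply(out_spec, function(x) signif(x * 1e3, 6))  # M -> mM
  names(out_spec) <- paste0(names(out_spec), "_mM")
  write.csv(out_spec, file.path(out_dir, "speciation.csv"), row.names = FALSE)
  invisible(report)
}

#' Run the kinetics and acceleration workflow
#'
#' Estimates the in-cage rate constant from cage time courses (full-curve
#' fitting, plus initial rates when two or more runs are supplied), the bulk
#' rate constant from a bulk time course (or takes it as given), and derives
#' the acceleration metrics EM, dS and ddG. Writes
#' \code{kinetics_report.json}.
#'
#' @param cage_csvs Character vector of cage time-course CSVs (long format;
#'   product species \code{C.P}).
#' @param ternary_conc Initial ternary-complex concentration (M) of each cage
#'   run (needed for the initial-rates estimate).
#' @param scenario_totals Numeric length 3: cage/guest totals (M) of the cage
#'   runs.
#' @param guests Guest-pair labels (default \code{c("4b", "5")}).
#' @param bulk_csv Optional bulk time-course CSV (species \code{P14},
#'   \code{P15}); alternatively give \code{k_bulk} directly.
#' @param k_bulk Optional known bulk rate constant (M^-1 s^-1).
#' @param bulk_totals Reactant concentrations for the bulk fit (M), default
#'   25 mM each.
#' @param out_dir Output directory.
#' @return The report list, invisibly.
#' @export
run_kinetics_workflow <- function(cage_csvs, ternary_conc = NULL,
                                  scenario_totals = c(2, 2, 4) * 1e-3,
                                  guests = c("4b", "5"),
                                  bulk_csv = NULL, k_bulk = NULL,
                                  bulk_totals = c(25, 25) * 1e-3,
                                  out_dir) {
  tcs <- lapply(cage_csvs, read_time_course_csv)
  model <- guest_pair_model(guests[1], guests[2], scenario_totals)
  template <- build_cage_network(model, 1e-5)

  fits <- vapply(tcs, function(tc) {
    fit_k_intra_full_curve(tc, template)$k_intra
  }, 0)
  k_intra <- mean(fits)

  k_initial <- NULL
  if (!is.null(ternary_conc) && length(tcs) >= 2L) {
    k_initial <- initial_rates_estimate(tcs, ternary_conc)
  }

  if (is.null(k_bulk) && !is.null(bulk_csv)) {
    btc <- read_time_course_csv(bulk_csv)
    if (!"P14" %in% names(btc)) {
      stop("bulk time course must contain species 'P14'")
    }
    skel <- bulk_reaction_model(1e-8, 0.5e-8, bulk_totals[1], bulk_totals[2])
    k_bulk <- fit_k_bulk(btc, skel)$k_14
  }

  report <- list(
    k_intra_full_curve = unname(fits),
    k_intra_mean = k_intra,
    k_intra_initial_rates = if (is.null(k_initial)) NULL else k_initial$k_intra,
    k_bulk = k_bulk
  )
  if (is.null(k_bulk)) {
    report$note <- "no bulk data or k_bulk supplied; EM not computed"
  } else {
    acc <- acceleration_result(k_intra, k_bulk)
    tbulk <- time_to_conversion(
      bulk_reaction_model(k_bulk, 0, 2e-3, 2e-3), 1e-3)
    report <- c(report, list(
      EM = acc$EM, EM_2sf = signif_report(acc$EM),
      delta_S_eu = round(acc$delta_S, 1),
      delta_G_kcal_mol = acc$delta_G,
      bulk_years_to_1mM_at_2mM = tbulk / (365.25 * 86400)
    ))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, file.path(out_dir, "kinetics_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
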