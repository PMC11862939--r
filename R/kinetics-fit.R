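#' Estimate the in-cage rate constant by the initial-rates method
#'
#' For each kinetic run, the initial rate v0 of bound-product formation is
#' taken as the slope of a linear regression of product concentration against
#' time over the early window (points where product <= \code{window_frac} of
#' the run's final/plateau level, minimum \code{min_points} points). Under the
#' first-order rate law v0 = k_intra [ternary complex], k_intra is the slope
#' of a through-origin regression of v0 against the known initial ternary
#' concentrations of the runs.
#'
#' @param time_courses List of wide time courses (data frames with
#'   \code{time_s} and the product column), one per run.
#' @param ternary_conc Numeric vector: initial ternary (Michaelis) complex
#'   concentration (M) of each run.
#' @param product_species Name of the product column (default \code{"C.P"}).
#' @param window_frac Early-window threshold as a fraction of the plateau
#'   (default 0.1).
#' @param min_points Minimum points required in the window (default 3).
#' @param assume_zero_origin If TRUE (default), a (t = 0, product = 0) point
#'   is included in each run's regression: the product concentration is zero
#'   at mixing by construction of the experiment.
#' @return List with \code{k_intra} (s^-1), \code{std_error}, \code{v0}
#'   (per-run initial rates, M/s), \code{window_points}.
#' @export
initial_rates_estimate <- function(time_courses, ternary_conc,
                                   product_species = "C.P",
                                   window_frac = 0.1, min_points = 3L,
                                   assume_zero_origin = TRUE) {
  if (inherits(time_courses, "data.frame")) time_courses <- list(time_courses)
  stopifnot(length(time_courses) == length(ternary_conc))
  if (length(time_courses) < 2L) {
    stop("need at least two runs at distinct ternary concentrations")
  }
  if (anyDuplicated(ternary_conc)) {
    stop("ternary concentrations must be distinct across runs")
  }
  v0 <- numeric(length(time_courses))
  npts <- integer(length(time_courses))
  for (i in seq_along(time_courses)) {
    tc <- time_courses[[i]]
    if (!product_species %in% names(tc)) {
      stop("run ", i, " lacks product column '", product_species, "'")
    }
    p <- tc[[product_species]]
    tt <- tc$time_s
    if (assume_zero_origin && !any(tt == 0)) {
      tt <- c(0, tt)
      p <- c(0, p)
    }
    plateau <- max(p)
    win <- p <= window_frac * plateau
    if (sum(win) < min_points) {
      stop("run ", i, ": only ", sum(win), " point(s) in the initial-rate ",
           "window (need >= ", min_points, ")")
    }
    fit <- lm(p[win] ~ tt[win])
    v0[i] <- coef(fit)[2]
    npts[i] <- sum(win)
  }
  # through-origin least squares of v0 on ternary concentration
  k <- sum(v0 * ternary_conc) / sum(ternary_conc^2)
  res <- v0 - k * ternary_conc
  se <- sqrt(sum(res^2) / (length(v0) - 1) / sum(ternary_conc^2))
  list(k_intra = k, std_error = se, v0 = v0, window_points = npts)
}

#' Fit the in-cage rate constant over the full kinetic curve
#'
#' Least-squares fit of the bound-product trajectory with the in-cage rate
#' constant as the only free parameter: for each candidate k_intra the full
#' binding + reaction network is re-simulated and compared with the observed
#' time course. The search minimises over log10(k) inside a bracket; a coarse
#' scan first locates the basin and warns if the objective is not unimodal.
#'
#' @param observed Wide time course with \code{time_s} and the product column.
#' @param net_template A network from \code{\link{build_cage_network}} (its
#'   k_intra is replaced per candidate).
#' @param product_species Product column name (default the template's
#'   product attribute).
#' @param bracket log10 search bracket for k_intra in s^-1 (default
#'   \code{c(-7, -2)}).
#' @return List with \code{k_intra}, \code{objective_value},
#'   \code{unimodal}.
#' @export
fit_k_intra_full_curve <- function(observed, net_template,
                                   product_species = NULL,
                                   bracket = c(-7, -2)) {
  stopifnot(inherits(net_template, "kinetic_network"))
  if (is.null(product_species)) product_species <- attr(net_template, "product")
  if (!product_species %in% names(observed)) {
    stop("observed time course lacks column '", product_species, "'")
  }
  model <- attr(net_template, "model")
  kon <- net_template$reactions[[1]]$k_forward
  times <- observed$time_s
  obs <- observed[[product_species]]
  sse <- function(log10k) {
    net <- build_cage_network(model, 10^log10k, k_on_reference = kon,
                              product_name = product_species)
    sim <- simulate_network(net, times)
    sum((sim[[product_species]] - obs)^2)
  }
  scan <- seq(bracket[1], bracket[2], length.out = 11L)
  vals <- vapply(scan, sse, 0)
  # interior local minima of the coarse scan
  locmin <- which(diff(sign(diff(vals))) > 0) + 1L
  unimodal <- length(locmin) <= 1L
  if (!unimodal) {
    warning("objective not unimodal in bracket; local minima near 10^",
            paste(format(scan[locmin], digits = 3), collapse = " and 10^"))
  }
  i <- which.min(vals)
  lo <- scan[max(1L, i - 1L)]
  hi <- scan[min(length(scan), i + 1L)]
  op <- optimize(sse, c(lo, hi), tol = 1e-7)
  list(k_intra = 10^op$minimum, objective_value = op$objective,
       unimodal = unimodal)
}
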