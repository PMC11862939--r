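#' Define an elementary mass-action reaction
#'
#' @param reactants,products Named integer vectors, species -> stoichiometric
#'   count (>= 1).
#' @param k_forward Forward rate constant (mass-action units).
#' @param k_reverse Reverse rate constant, or \code{NA} for an irreversible
#'   step.
#' @return Object of class \code{"sk_reaction"}.
#' @export
reaction <- function(reactants, products, k_forward, k_reverse = NA_real_) {
  chk <- function(v, what) {
    if (is.null(names(v)) || any(!nzchar(names(v))) || any(v < 1) ||
        any(v != round(v))) {
      stop(what, " must be a named vector of counts >= 1")
    }
  }
  chk(reactants, "reactants"); chk(products, "products")
  if (!is.numeric(k_forward) || k_forward < 0) stop("k_forward must be >= 0")
  if (!is.na(k_reverse) && k_reverse < 0) stop("k_reverse must be >= 0 or NA")
  structure(list(reactants = reactants, products = products,
                 k_forward = as.numeric(k_forward),
                 k_reverse = as.numeric(k_reverse)),
            class = "sk_reaction")
}

#' Assemble a kinetic network
#'
#' @param initial Named numeric vector: initial concentration (M) of every
#'   species.
#' @param reactions List of \code{\link{reaction}} objects.
#' @param composition Optional species x conserved-moiety count matrix used
#'   for conservation checks (rows = species, columns = moieties).
#' @return Object of class \code{"kinetic_network"}.
#' @export
kinetic_network <- function(initial, reactions, composition = NULL) {
  if (is.null(names(initial)) || any(!nzchar(names(initial)))) {
    stop("initial concentrations must be named by species")
  }
  if (any(initial < 0)) stop("initial concentrations must be >= 0")
  if (inherits(reactions, "sk_reaction")) reactions <- list(reactions)
  stopifnot(all(vapply(reactions, inherits, TRUE, "sk_reaction")))
  for (r in reactions) {
    bad <- setdiff(c(names(r$reactants), names(r$products)), names(initial))
    if (length(bad)) stop("reaction references undeclared species: ",
                          paste(bad, collapse = ", "))
  }
  if (!is.null(composition)) {
    stopifnot(is.matrix(composition),
              setequal(rownames(composition), names(initial)))
  }
  structure(list(initial = initial, reactions = reactions,
                 composition = composition),
            class = "kinetic_network")
}

# stoichiometric matrix (species x reaction-direction) and rate evaluator
.network_ops <- function(net) {
  sp <- names(net$initial)
  nr <- length(net$reactions)
  # columns: forward for each reaction, then reverse where present
  cols <- list()
  ks <- numeric(0)
  orders <- list()
  for (r in net$reactions) {
    v <- setNames(numeric(length(sp)), sp)
    v[names(r$reactants)] <- v[names(r$reactants)] - r$reactants
    v[names(r$products)] <- v[names(r$products)] + r$products
    cols[[length(cols) + 1L]] <- v
    ks <- c(ks, r$k_forward)
    orders[[length(orders) + 1L]] <- r$reactants
    if (!is.na(r$k_reverse)) {
      cols[[length(cols) + 1L]] <- -v
      ks <- c(ks, r$k_reverse)
      orders[[length(orders) + 1L]] <- r$products
    }
  }
  S <- do.call(cbind, cols)
  rates <- function(conc) {
    vapply(seq_along(ks), function(j) {
      o <- orders[[j]]
      ks[j] * prod(conc[names(o)]^o)
    }, 0)
  }
  # analytic Jacobian of the rate vector: d r_j / d y_i
  rate_jac <- function(conc) {
    R <- matrix(0, length(ks), length(sp), dimnames = list(NULL, sp))
    for (j in seq_along(ks)) {
      o <- orders[[j]]
      for (nm in names(o)) {
        others <- o[setdiff(names(o), nm)]
        R[j, nm] <- ks[j] * o[[nm]] * conc[nm]^(o[[nm]] - 1) *
          prod(conc[names(others)]^others)
      }
    }
    R
  }
  list(S = S, rates = rates, rate_jac = rate_jac)
}

#' Integrate a mass-action kinetic network
#'
#' Solves the mass-action ODE system with \code{deSolve::ode} using the
#' stiff-capable \code{lsoda} integrator (rtol 1e-8, atol 1e-15 M by default:
#' rate constants in these networks span many orders of magnitude).
#'
#' @param net A \code{\link{kinetic_network}}.
#' @param times Strictly increasing output times (s); 0 is prepended if
#'   absent.
#' @param rtol,atol Integrator tolerances.
#' @return A "wide" time course: data frame with column \code{time_s} and one
#'   concentration column (M) per species.
#' @export
simulate_network <- function(net, times, rtol = 1e-8, atol = 1e-15) {
  stopifnot(inherits(net, "kinetic_network"))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  tt <- if (times[1] > 0) c(0, times) else times
  ops <- .network_ops(net)
  rhs <- function(t, y, p) {
    y <- pmax(y, 0)
    list(as.vector(ops$S %*% ops$rates(y)))
  }
  jac <- function(t, y, p) {
    y <- pmax(y, 0)
    ops$S %*% ops$rate_jac(y)
  }
  sol <- deSolve::ode(y = net$initial, times = tt, func = rhs, parms = NULL,
                      method = "lsoda", jacfunc = jac, jactype = "fullusr",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE integration failed around t = ",
         format(max(sol[, "time"])), " s")
  }
  out <- as.data.frame(sol)
  names(out)[1] <- "time_s"
  out <- out[match(times, out$time_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Check conservation of moieties along a trajectory
#'
#' @param net Network whose \code{composition} matrix defines the conserved
#'   moieties.
#' @param tc Wide time course from \code{\link{simulate_network}}.
#' @return Named vector: max relative drift of each moiety total.
#' @export
conservation_error <- function(net, tc) {
  if (is.null(net$composition)) stop("network has no composition matrix")
  sp <- rownames(net$composition)
  conc <- as.matrix(tc[, sp, drop = FALSE])
  totals <- conc %*% net$composition
  ref <- as.vector(net$initial[sp] %*% net$composition)
  apply(abs(sweep(totals, 2, ref)) / pmax(abs(ref), 1e-300), 2, max)
}

#' Build the in-cage reaction network for a guest pair
#'
#' Constructs the mass-action network of a container-accelerated bimolecular
#' reaction: the six reversible binding equilibria of a five-complex binding
#' model (two 1:1, two 2:1 homoternary, one heteroternary reached via either
#' 1:1 complex) plus the irreversible first-order reaction of the ternary
#' (Michaelis) complex to the bound product. On-rates are set to a common
#' reference value and off-rates to \code{k_on / K_step}, so every equilibrium
#' honours its stepwise constant; fitted in-cage rate constants are
#' insensitive to the reference on-rate as long as binding pre-equilibrates
#' fast.
#'
#' @param model A five-species \code{\link{binding_model}} from
#'   \code{\link{guest_pair_model}} (components: cage + two guests).
#' @param k_intra In-cage first-order rate constant (s^-1); 0 gives a purely
#'   equilibrating network.
#' @param k_on_reference Common on-rate (M^-1 s^-1), default 1e7.
#' @param init \code{"equilibrium"} (default; binding pre-equilibrated before
#'   t = 0, matching fast-binding experiments) or \code{"unmixed"} (all
#'   components free).
#' @param product_name Name for the bound-product species (default
#'   \code{"C.P"}).
#' @return A \code{\link{kinetic_network}} with a composition matrix for
#'   cage/guest conservation checks. The ternary-complex species name is in
#'   attribute \code{"ternary"}.
#' @export
build_cage_network <- function(model, k_intra, k_on_reference = 1e7,
                               init = c("equilibrium", "unmixed"),
                               product_name = "C.P") {
  init <- match.arg(init)
  stopifnot(inherits(model, "binding_model"), k_intra >= 0, k_on_reference > 0)
  comp_names <- vapply(model$components, `[[`, "", "name")
  if (length(comp_names) != 3L) stop("expected a cage + two-guest model")
  host <- comp_names[1]; gA <- comp_names[2]; gB <- comp_names[3]
  mm <- .model_matrices(model)
  beta <- setNames(10^mm$log10_beta, rownames(mm$nu))
  need <- c(paste0("C.", gA), paste0("C.", gB),
            paste0("C.", gA, ".", gA), paste0("C.", gB, ".", gB),
            paste0("C.", gA, ".", gB))
  miss <- setdiff(need, names(beta))
  if (length(miss)) stop("binding model lacks species: ", paste(miss, collapse = ", "))
  sAB <- need[5]

  # stepwise constants from the beta table
  K <- c(
    A1  = unname(beta[need[1]]),
    B1  = unname(beta[need[2]]),
    A2  = unname(beta[need[3]] / beta[need[1]]),
    B2  = unname(beta[need[4]] / beta[need[2]]),
    ABa = unname(beta[sAB] / beta[need[1]]),   # B joins C.A
    ABb = unname(beta[sAB] / beta[need[2]])    # A joins C.B
  )
  kon <- k_on_reference
  rx <- list(
    reaction(setNames(c(1, 1), c(host, gA)), setNames(1, need[1]), kon, kon / K["A1"]),
    reaction(setNames(c(1, 1), c(host, gB)), setNames(1, need[2]), kon, kon / K["B1"]),
    reaction(setNames(c(1, 1), c(need[1], gA)), setNames(1, need[3]), kon, kon / K["A2"]),
    reaction(setNames(c(1, 1), c(need[2], gB)), setNames(1, need[4]), kon, kon / K["B2"]),
    reaction(setNames(c(1, 1), c(need[1], gB)), setNames(1, sAB), kon, kon / K["ABa"]),
    reaction(setNames(c(1, 1), c(need[2], gA)), setNames(1, sAB), kon, kon / K["ABb"]),
    reaction(setNames(1, sAB), setNames(1, product_name), k_intra)
  )

  species <- c(host, gA, gB, need, product_name)
  initial <- setNames(numeric(length(species)), species)
  if (init == "equilibrium") {
    sp <- solve_free_concentrations(model)
    initial[names(sp$free)] <- sp$free
    initial[names(sp$complexes)] <- sp$complexes
  } else {
    initial[comp_names] <- mm$totals
  }

  comp <- matrix(0, length(species), 3,
                 dimnames = list(species, c(host, gA, gB)))
  comp[host, host] <- 1; comp[gA, gA] <- 1; comp[gB, gB] <- 1
  comp[need[1], ] <- c(1, 1, 0); comp[need[2], ] <- c(1, 0, 1)
  comp[need[3], ] <- c(1, 2, 0); comp[need[4], ] <- c(1, 0, 2)
  comp[sAB, ] <- c(1, 1, 1)
  comp[product_name, ] <- c(1, 1, 1)  # product retains one of each guest

  net <- kinetic_network(initial, rx, composition = comp)
  attr(net, "ternary") <- sAB
  attr(net, "product") <- product_name
  attr(net, "model") <- model
  net
}

#' Calibrate a mixture composition to a target ternary-complex concentration
#'
#' Scales host and guest totals by a common factor (keeping their molar ratio)
#' until the equilibrium concentration of the heteroternary (Michaelis)
#' complex equals a target value; used to set up kinetic runs at prescribed
#' Michaelis-complex concentrations.
#'
#' @param model A \code{\link{guest_pair_model}} whose stored totals define
#'   the molar ratio.
#' @param target Target ternary-complex concentration (M).
#' @param interval Search interval for the scale factor (default
#'   \code{c(1e-3, 1e3)}).
#' @return The recalibrated \code{\link{binding_model}}; the applied scale is
#'   in attribute \code{"scale"}.
#' @export
calibrate_ternary_composition <- function(model, target,
                                          interval = c(1e-3, 1e3)) {
  stopifnot(inherits(model, "binding_model"), target > 0)
  comp_names <- vapply(model$components, `[[`, "", "name")
  base <- setNames(vapply(model$components, `[[`, 0, "total"), comp_names)
  sp_names <- vapply(model$species, `[[`, "", "name")
  ternary <- sp_names[vapply(model$species, function(s) {
    length(s$stoichiometry) == 3L
  }, TRUE)]
  if (length(ternary) != 1L) {
    stop("model must contain exactly one heteroternary species")
  }
  f <- function(s) {
    sp <- solve_free_concentrations(set_totals(model, base * s))
    sp$complexes[[ternary]] - target
  }
  if (f(interval[1]) > 0 || f(interval[2]) < 0) {
    stop("target ternary concentration not bracketed by the scale interval")
  }
  s <- uniroot(f, interval, tol = 1e-12)$root
  out <- set_totals(model, base * s)
  attr(out, "scale") <- s
  out
}
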