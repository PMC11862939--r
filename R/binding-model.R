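#' Define a component of a binding model
#'
#' A component is a conserved chemical entity with a known analytical (total)
#' concentration: the host cage or one of the guests. The acetonitrile solvate
#' of the cage is the reference "free host" state, so solvent is never an
#' explicit component.
#'
#' @param name Component identifier (character scalar).
#' @param total_concentration Total (analytical) concentration in M. May be 0.
#' @return An object of class \code{"sk_component"}.
#' @export
component <- function(name, total_concentration) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(total_concentration) || length(total_concentration) != 1L ||
      is.na(total_concentration) || total_concentration < 0) {
    stop("total_concentration must be a single non-negative number (M)")
  }
  structure(list(name = name, total = as.numeric(total_concentration)),
            class = "sk_component")
}

#' Define a complex species
#'
#' A complex is assembled from components with integer stoichiometry and an
#' overall formation constant beta, stored as log10(beta). beta has units
#' M^(1 - sum(counts)): e.g. M^-1 for a 1:1 complex, M^-2 for a ternary
#' host + 2 guest complex.
#'
#' @param name Species identifier.
#' @param stoichiometry Named integer vector or list, component -> count >= 0;
#'   at least one count must be positive.
#' @param log10_beta log10 of the overall formation constant.
#' @return An object of class \code{"sk_species"}.
#' @export
complex_species <- function(name, stoichiometry, log10_beta) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  st <- unlist(stoichiometry)
  if (is.null(names(st)) || any(!nzchar(names(st)))) {
    stop("stoichiometry must be named by component")
  }
  if (any(st < 0) || any(st != round(st))) {
    stop("stoichiometry counts must be non-negative integers")
  }
  if (sum(st) < 1) stop("species '", name, "' must contain at least one component")
  if (!is.numeric(log10_beta) || length(log10_beta) != 1L ||
      (!is.na(log10_beta) && !is.finite(log10_beta))) {
    stop("log10_beta must be a single finite number (or NA for a free parameter)")
  }
  structure(list(name = name, stoichiometry = st[st > 0],
                 log10_beta = as.numeric(log10_beta)),
            class = "sk_species")
}

#' Assemble a multi-component binding model
#'
#' The equilibrium problem definition: components with total concentrations
#' plus complex species with overall formation constants. An NA
#' \code{log10_beta} marks a species whose constant is to be fitted
#' (see \code{\link{fit_stepwise_constants}}).
#'
#' @param components List of \code{\link{component}} objects.
#' @param species List of \code{\link{complex_species}} objects (may be empty).
#' @return An object of class \code{"binding_model"}.
#' @examples
#' m <- binding_model(
#'   list(component("cage", 2e-3), component("G", 2e-3)),
#'   list(complex_species("C.G", c(cage = 1, G = 1), log10(2e4))))
#' solve_free_concentrations(m)
#' @export
binding_model <- function(components, species = list()) {
  if (inherits(components, "sk_component")) components <- list(components)
  if (inherits(species, "sk_species")) species <- list(species)
  stopifnot(all(vapply(components, inherits, TRUE, "sk_component")),
            all(vapply(species, inherits, TRUE, "sk_species")))
  comp_names <- vapply(components, `[[`, "", "name")
  if (anyDuplicated(comp_names)) stop("component names must be unique")
  sp_names <- vapply(species, `[[`, "", "name")
  if (anyDuplicated(sp_names)) stop("species names must be unique")
  if (length(intersect(sp_names, comp_names))) {
    stop("species names must not collide with component names")
  }
  for (s in species) {
    bad <- setdiff(names(s$stoichiometry), comp_names)
    if (length(bad)) {
      stop("species '", s$name, "' references undeclared component(s): ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(components = components, species = species),
            class = "binding_model")
}

#' @export
print.binding_model <- function(x, ...) {
  cat("<binding_model>", length(x$components), "components,",
      length(x$species), "complex species\n")
  for (cp in x$components) {
    cat(sprintf("  %-12s total %.4g mM\n", cp$name, cp$total * 1e3))
  }
  for (s in x$species) {
    st <- paste(sprintf("%s:%d", names(s$stoichiometry), s$stoichiometry),
                collapse = " ")
    cat(sprintf("  %-12s [%s]  log10(beta) = %s\n", s$name, st,
                if (is.na(s$log10_beta)) "free" else format(s$log10_beta, digits = 4)))
  }
  invisible(x)
}

# internal matrix view of a model: totals vector, stoichiometry matrix
# (species x components), beta vector
.model_matrices <- function(model) {
  comp_names <- vapply(model$components, `[[`, "", "name")
  totals <- setNames(vapply(model$components, `[[`, 0, "total"), comp_names)
  ns <- length(model$species)
  nu <- matrix(0, ns, length(comp_names),
               dimnames = list(vapply(model$species, `[[`, "", "name"), comp_names))
  for (i in seq_len(ns)) {
    st <- model$species[[i]]$stoichiometry
    nu[i, names(st)] <- st
  }
  log10_beta <- vapply(model$species, `[[`, 0, "log10_beta")
  list(totals = totals, nu = nu, log10_beta = log10_beta)
}

#' Replace formation constants in a model
#'
#' @param model A \code{\link{binding_model}}.
#' @param log10_beta Named numeric vector, species name -> log10(beta).
#' @return The modified model.
#' @export
set_log10_beta <- function(model, log10_beta) {
  stopifnot(inherits(model, "binding_model"), !is.null(names(log10_beta)))
  sp_names <- vapply(model$species, `[[`, "", "name")
  bad <- setdiff(names(log10_beta), sp_names)
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  for (nm in names(log10_beta)) {
    model$species[[match(nm, sp_names)]]$log10_beta <- as.numeric(log10_beta[[nm]])
  }
  model
}

#' Replace component totals in a model
#'
#' @param model A \code{\link{binding_model}}.
#' @param totals Named numeric vector, component name -> total concentration (M).
#' @return The modified model.
#' @export
set_totals <- function(model, totals) {
  stopifnot(inherits(model, "binding_model"), !is.null(names(totals)))
  comp_names <- vapply(model$components, `[[`, "", "name")
  bad <- setdiff(names(totals), comp_names)
  if (length(bad)) stop("unknown component: ", paste(bad, collapse = ", "))
  if (any(totals < 0)) stop("totals must be non-negative")
  for (nm in names(totals)) {
    model$components[[match(nm, comp_names)]]$total <- as.numeric(totals[[nm]])
  }
  model
}

#' Read a binding model from a YAML definition file
#'
#' File layout: a \code{components} map of name -> total in mM, and a
#' \code{species} map of name -> list(stoichiometry = map, log10_beta = number
#' or ~ for a free parameter). Concentrations are mM in files and converted
#' to M on read.
#'
#' @param path Path to the YAML file.
#' @return A \code{\link{binding_model}}.
#' @seealso \code{\link{write_binding_model}}
#' @export
read_binding_model <- function(path) {
  def <- yaml::read_yaml(path)
  if (is.null(def$components)) stop("model file has no 'components' section")
  comps <- lapply(names(def$components), function(nm) {
    component(nm, as.numeric(def$components[[nm]]) * 1e-3)
  })
  sps <- lapply(names(def$species), function(nm) {
    s <- def$species[[nm]]
    lb <- if (is.null(s$log10_beta)) NA_real_ else as.numeric(s$log10_beta)
    complex_species(nm, unlist(s$stoichiometry), lb)
  })
  binding_model(comps, sps)
}

#' Write a binding model to a YAML definition file
#'
#' @param model A \code{\link{binding_model}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_binding_model <- function(model, path) {
  stopifnot(inherits(model, "binding_model"))
  def <- list(
    components = lapply(setNames(model$components,
                                 vapply(model$components, `[[`, "", "name")),
                        function(cp) cp$total * 1e3),
    species = lapply(setNames(model$species,
                              vapply(model$species, `[[`, "", "name")),
                     function(s) list(stoichiometry = as.list(s$stoichiometry),
                                      log10_beta = s$log10_beta))
  )
  yaml::write_yaml(def, path, precision = 15)
  invisible(path)
}
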