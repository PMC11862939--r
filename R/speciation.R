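#' Solve equilibrium speciation of a binding model
#'
#' Solves the simultaneous mass-balance equations
#' \deqn{T_j = x_j + \sum_s \nu_{sj}\, \beta_s \prod_k x_k^{\nu_{sk}}}
#' for the free component concentrations \eqn{x_j}, where every complex
#' concentration is \eqn{c_s = \beta_s \prod_k x_k^{\nu_{sk}}}. The iteration
#' is a damped Newton method on the log free concentrations, which keeps all
#' concentrations strictly positive even for overall constants spanning
#' 1e7-1e9. Components with total exactly 0 are eliminated (their free
#' concentration and every complex containing them is 0). For models with at
#' most two non-zero components a nested bisection fallback is attempted if
#' Newton fails.
#'
#' @param model A \code{\link{binding_model}} with all \code{log10_beta} set.
#' @param tol Relative mass-balance tolerance (default 1e-12; the result is
#'   guaranteed to 1e-9 or the solver errors).
#' @param max_iter Maximum Newton iterations (default 200).
#' @return An object of class \code{"speciation_result"}: list with
#'   \code{free} (named vector, M), \code{complexes} (named vector, M),
#'   \code{residual_norm} (max relative balance error) and \code{iterations}.
#' @examples
#' m <- binding_model(
#'   list(component("cage", 2e-3), component("G", 2e-3)),
#'   list(complex_species("C.G", c(cage = 1, G = 1), log10(2e4))))
#' solve_free_concentrations(m)$complexes  # 1.708 mM, the quadratic root
#' @export
solve_free_concentrations <- function(model, tol = 1e-12, max_iter = 200L) {
  stopifnot(inherits(model, "binding_model"))
  mm <- .model_matrices(model)
  if (anyNA(mm$log10_beta)) {
    stop("model has free (NA) log10_beta entries; set them before solving")
  }
  totals <- mm$totals
  nu <- mm$nu
  beta <- 10^mm$log10_beta

  # eliminate zero-total components and the species that contain them
  zero <- totals <= 0
  keep_sp <- if (nrow(nu)) rowSums(nu[, zero, drop = FALSE]) == 0 else logical(0)
  act <- !zero

  free <- setNames(numeric(length(totals)), names(totals))
  complexes <- setNames(numeric(nrow(nu)), rownames(nu))
  residual <- 0
  iterations <- 0L

  if (any(act)) {
    nu_a <- nu[keep_sp, act, drop = FALSE]
    beta_a <- beta[keep_sp]
    # drop species with zero counts on all active components
    nz <- rowSums(nu_a) > 0
    nu_a <- nu_a[nz, , drop = FALSE]
    beta_a <- beta_a[nz]
    sol <- .newton_speciation(totals[act], nu_a, beta_a, tol, max_iter)
    if (!sol$converged && sum(act) <= 2L) {
      sol2 <- .bisect_speciation(totals[act], nu_a, beta_a)
      if (sol2$converged) sol <- sol2
    }
    if (!sol$converged || sol$residual > 1e-9) {
      stop(sprintf(
        "speciation solver did not converge (last relative residual %.3g)",
        sol$residual))
    }
    free[act] <- sol$free
    if (length(beta_a)) {
      cs <- beta_a * apply(nu_a, 1L, function(v) prod(sol$free^v))
      complexes[rownames(nu_a)] <- cs
    }
    residual <- sol$residual
    iterations <- sol$iterations
  }

  structure(list(free = free, complexes = complexes,
                 residual_norm = residual, iterations = iterations),
            class = "speciation_result")
}

#' @export
print.speciation_result <- function(x, ...) {
  cat("<speciation_result>  max relative balance error",
      format(x$residual_norm, digits = 3), "\n")
  cat("free (mM):\n")
  print(round(x$free * 1e3, 6))
  if (length(x$complexes)) {
    cat("complexes (mM):\n")
    print(round(x$complexes * 1e3, 6))
  }
  invisible(x)
}

# damped Newton on u = log(free); residuals scaled by totals
.newton_speciation <- function(totals, nu, beta, tol, max_iter) {
  nc <- length(totals)
  has_sp <- length(beta) > 0L
  balance <- function(x) {
    cs <- if (has_sp) beta * apply(nu, 1L, function(v) prod(x^v)) else numeric(0)
    bound <- if (has_sp) as.vector(t(nu) %*% cs) else numeric(nc)
    list(cs = cs, F = (x + bound - totals) / totals)
  }
  u <- log(totals)   # initial guess: free = totals (always feasible)
  it <- 0L
  res <- Inf
  repeat {
    it <- it + 1L
    x <- exp(u)
    b <- balance(x)
    res <- max(abs(b$F))
    if (res < tol || it > max_iter) break
    # Jacobian wrt u: d(balance_j)/du_k = (delta_jk x_j + sum_s nu_sj nu_sk c_s)/T_j
    J <- diag(x, nc, nc)
    if (has_sp) {
      for (s in seq_along(b$cs)) J <- J + b$cs[s] * tcrossprod(nu[s, ])
    }
    J <- J / totals
    du <- tryCatch(solve(J, -b$F), error = function(e) NULL)
    if (is.null(du)) break
    du <- pmin(pmax(du, -5), 5)      # cap log step
    f0 <- sum(b$F^2)
    step <- 1
    repeat {                          # backtracking line search
      F1 <- balance(exp(u + step * du))$F
      if (sum(F1^2) < f0 || step < 1e-8) break
      step <- step / 2
    }
    u <- u + step * du
  }
  list(free = setNames(exp(u), names(totals)), residual = res,
       iterations = it, converged = res < 1e-9)
}

# nested bisection fallback for one or two components: monotone excess
# functions of the free concentrations
.bisect_speciation <- function(totals, nu, beta, tol = 1e-13) {
  nc <- length(totals)
  has_sp <- length(beta) > 0L
  excess <- function(x, j) {
    cs <- if (has_sp) beta * apply(nu, 1L, function(v) prod(x^v)) else numeric(0)
    bound <- if (has_sp) sum(nu[, j] * cs) else 0
    x[j] + bound - totals[j]
  }
  solve1 <- function(fix, j) {
    lo <- totals[j] * 1e-16; hi <- totals[j]
    f <- function(xj) { x <- fix; x[j] <- xj; excess(x, j) }
    for (i in 1:200) {
      mid <- sqrt(lo * hi)
      if (f(mid) > 0) hi <- mid else lo <- mid
      if (hi / lo - 1 < tol) break
    }
    sqrt(lo * hi)
  }
  x <- totals
  if (nc == 1L) {
    x[1] <- solve1(x, 1L)
  } else {
    for (outer in 1:300) {
      x_old <- x
      x[1] <- solve1(x, 1L)
      x[2] <- solve1(x, 2L)
      if (max(abs(x - x_old) / totals) < tol) break
    }
  }
  cs <- if (has_sp) beta * apply(nu, 1L, function(v) prod(x^v)) else numeric(0)
  bound <- if (has_sp) as.vector(t(nu) %*% cs) else numeric(nc)
  res <- max(abs((x + bound - totals) / totals))
  list(free = x, residual = res, iterations = NA_integer_, converged = res < 1e-9)
}

#' Compute a speciation profile along a titration grid
#'
#' Batch wrapper over \code{\link{solve_free_concentrations}}: the total
#' concentration of one component (the titrant) is varied over a grid while
#' all other totals stay fixed, reproducing the speciation-profile plots used
#' to interpret NMR titrations.
#'
#' @param model A \code{\link{binding_model}} (the titrant's stored total is
#'   ignored).
#' @param titrant Name of the component being titrated.
#' @param grid Numeric vector of titrant totals (M), non-negative and
#'   non-decreasing.
#' @return A data frame with columns \code{index}, \code{<titrant>_total_M},
#'   one column per free component and one per complex (all M).
#' @export
speciation_profile <- function(model, titrant, grid) {
  stopifnot(inherits(model, "binding_model"))
  comp_names <- vapply(model$components, `[[`, "", "name")
  if (!titrant %in% comp_names) stop("unknown titrant component: ", titrant)
  if (any(grid < 0)) stop("grid totals must be non-negative")
  if (is.unsorted(grid)) stop("grid totals must be non-decreasing")
  rows <- lapply(seq_along(grid), function(i) {
    m <- set_totals(model, setNames(grid[i], titrant))
    sp <- tryCatch(solve_free_concentrations(m), error = function(e) {
      stop("speciation failed at grid point ", i, " (titrant total ",
           format(grid[i]), " M): ", conditionMessage(e))
    })
    c(index = i, setNames(grid[i], paste0(titrant, "_total_M")),
      setNames(sp$free, paste0("free_", names(sp$free))), sp$complexes)
  })
  as.data.frame(do.call(rbind, rows), check.names = FALSE)
}

#' Write a speciation profile as CSV
#'
#' Concentrations are written in mM with 6 significant digits, matching the
#' file conventions of the titration observables.
#'
#' @param profile Data frame from \code{\link{speciation_profile}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_speciation_csv <- function(profile, path) {
  out <- profile
  conc_cols <- setdiff(names(out), "index")
  out[conc_cols] <- lapply(out[conc_cols], function(x) signif(x * 1e3, 6))
  names(out) <- sub("_M$", "_mM", names(out))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
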