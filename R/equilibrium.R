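#' Site occupancy fractions at given free concentrations
#'
#' Evaluates the binding isotherms of the competition model. A specific site
#' is free, TF-bound (as a concerted Hill-`n` complex) or histone-bound with
#' statistical weights `1 : x^n : h` where `x = T_f/K_s` and `h = H_f/K_h`;
#' unspecific sites follow the same three-state scheme with `y = T_f/K_u`
#' and Hill coefficient 1.
#'
#' @param T_f Free TF concentration (nM), >= 0.
#' @param H_f Free histone concentration (nM), >= 0.
#' @param system A [binding_system()].
#' @return An object of class `occupancy_profile`: list with
#'   `theta_T_specific`, `theta_H_specific`, `theta_T_unspecific`,
#'   `theta_H_unspecific`, each a fraction in \[0, 1\].
#' @examples
#' sys <- binding_system()
#' occupancies(T_f = sys$K_s, H_f = 0, sys)$theta_T_specific  # 0.5
#' @export
occupancies <- function(T_f, H_f, system) {
  validate_binding_system(system)
  if (!is.finite(T_f) || !is.finite(H_f) || T_f < 0 || H_f < 0) {
    stop("occupancies: T_f and H_f must be finite and >= 0")
  }
  x <- T_f / system$K_s
  y <- T_f / system$K_u
  h <- H_f / system$K_h
  n <- system$hill_n
  den_s <- 1 + x^n + h
  den_u <- 1 + y + h
  out <- list(
    theta_T_specific = x^n / den_s,
    theta_H_specific = h / den_s,
    theta_T_unspecific = y / den_u,
    theta_H_unspecific = h / den_u
  )
  class(out) <- "occupancy_profile"
  out
}

#' Scaled mass-conservation residuals
#'
#' For trial free concentrations `(T_f, H_f)` the bound TF mass is
#' `tf_per_site * Ns_total * theta_T_specific + Nu_total * theta_T_unspecific`
#' and the bound histone mass is
#' `Ns_total * theta_H_specific + Nu_total * theta_H_unspecific`. The
#' residuals compare free + bound mass against the totals, scaled by the
#' respective total (by 1 nM when a total is zero, in which case the free
#' concentration must also be zero). Free-site concentrations are implied:
#' `Ns_f = Ns_total * (1 - theta_T_specific - theta_H_specific)` and
#' analogously for `Nu_f`, so the four-unknown conservation system reduces
#' to this two-dimensional root problem.
#'
#' @inheritParams occupancies
#' @return Named numeric vector `c(r_T, r_H)` (dimensionless).
#' @export
conservation_residuals <- function(T_f, H_f, system) {
  o <- occupancies(T_f, H_f, system)
  bound_T <- system$tf_per_site * system$Ns_total * o$theta_T_specific +
    system$Nu_total * o$theta_T_unspecific
  bound_H <- system$Ns_total * o$theta_H_specific +
    system$Nu_total * o$theta_H_unspecific
  sT <- if (system$T_total > 0) system$T_total else 1
  sH <- if (system$H_total > 0) system$H_total else 1
  c(r_T = (T_f + bound_T - system$T_total) / sT,
    r_H = (H_f + bound_H - system$H_total) / sH)
}

## Inner 1-D solve: free TF at fixed free histone. r_T is strictly
## increasing in T_f with r_T(0) = -1 and r_T(T_total) >= 0.
.solve_Tf_given_Hf <- function(H_f, system) {
  if (system$T_total == 0) return(0)
  f <- function(Tf) conservation_residuals(Tf, H_f, system)[["r_T"]]
  if (f(system$T_total) <= 0) return(system$T_total)
  stats::uniroot(f, c(0, system$T_total), tol = .Machine$double.eps)$root
}

## Nested-bisection fallback: outer root in H_f of r_H evaluated at the
## conditional TF root. r_H is increasing in H_f along that path.
.solve_nested_bisection <- function(system) {
  if (system$H_total == 0) {
    H_f <- 0
  } else {
    g <- function(Hf) {
      conservation_residuals(.solve_Tf_given_Hf(Hf, system), Hf,
                             system)[["r_H"]]
    }
    H_f <- if (g(system$H_total) <= 0) system$H_total else
      stats::uniroot(g, c(0, system$H_total),
                     tol = .Machine$double.eps)$root
  }
  c(T_f = .solve_Tf_given_Hf(H_f, system), H_f = H_f)
}

#' Solve the competition model for its equilibrium free concentrations
#'
#' Finds the unique physical root of the mass-conservation residuals with
#' `0 <= T_f <= T_total` and `0 <= H_f <= H_total`. The solver is a damped
#' Newton iteration on log-transformed free concentrations (positivity by
#' construction, finite-difference Jacobian, step halving on non-decreasing
#' residual norm) with a nested-bisection fallback that exploits the
#' monotonicity of each residual in its own variable. Degenerate systems
#' (no sites, or a zero total) are resolved exactly.
#'
#' @param system A [binding_system()].
#' @param tol Convergence tolerance on `max(|r_T|, |r_H|)`. Default 1e-12.
#' @param max_iter Maximum Newton iterations. Default 200.
#' @return An object of class `free_state`: list with `T_f`, `H_f`, `Ns_f`,
#'   `Nu_f` (nM), `residual_norm`, `converged`, `iterations`, `method`.
#' @examples
#' solve_equilibrium(binding_system(K_s = 10, K_h = 10))
#' @export
solve_equilibrium <- function(system, tol = 1e-12, max_iter = 200) {
  validate_binding_system(system)
  if (!is.finite(tol) || tol <= 0) stop("solve_equilibrium: tol must be > 0")

  finish <- function(T_f, H_f, iterations, method) {
    r <- conservation_residuals(T_f, H_f, system)
    o <- occupancies(T_f, H_f, system)
    st <- list(
      T_f = T_f, H_f = H_f,
      Ns_f = system$Ns_total * (1 - o$theta_T_specific - o$theta_H_specific),
      Nu_f = system$Nu_total *
        (1 - o$theta_T_unspecific - o$theta_H_unspecific),
      residual_norm = max(abs(r)),
      converged = max(abs(r)) < tol,
      iterations = iterations, method = method
    )
    class(st) <- "free_state"
    st
  }

  ## exact degenerate cases
  if (system$Ns_total == 0 && system$Nu_total == 0) {
    return(finish(system$T_total, system$H_total, 0L, "exact"))
  }
  if (system$T_total == 0 || system$H_total == 0) {
    sol <- .solve_nested_bisection(system)
    return(finish(sol[["T_f"]], sol[["H_f"]], 0L, "bisection"))
  }

  rnorm2 <- function(u) {
    r <- conservation_residuals(exp(u[1]), exp(u[2]), system)
    max(abs(r))
  }
  rvec <- function(u) conservation_residuals(exp(u[1]), exp(u[2]), system)

  u <- log(c(system$T_total, system$H_total))
  r <- rvec(u)
  iter <- 0L
  ok <- TRUE
  while (max(abs(r)) >= tol && iter < max_iter) {
    iter <- iter + 1L
    ## finite-difference Jacobian in log coordinates
    hstep <- 1e-7
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      up <- u; up[j] <- up[j] + hstep
      um <- u; um[j] <- um[j] - hstep
      J[, j] <- (rvec(up) - rvec(um)) / (2 * hstep)
    }
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) { ok <- FALSE; break }
    ## damping: halve until the residual norm decreases
    lambda <- 1
    repeat {
      unew <- u + lambda * step
      if (all(is.finite(unew)) && rnorm2(unew) < max(abs(r))) break
      lambda <- lambda / 2
      if (lambda < 1e-10) { ok <- FALSE; break }
    }
    if (!ok) break
    u <- u + lambda * step
    r <- rvec(u)
  }

  if (ok && max(abs(r)) < tol) {
    return(finish(exp(u[1]), exp(u[2]), iter, "newton"))
  }
  ## fallback: nested bisection is slower but guaranteed by monotonicity
  sol <- .solve_nested_bisection(system)
  st <- finish(sol[["T_f"]], sol[["H_f"]], iter, "bisection")
  if (!st$converged) {
    stop(sprintf(paste0("solve_equilibrium: no convergence after %d ",
                        "iterations (residual %.3e)"),
                 max_iter, st$residual_norm))
  }
  st
}

#' @export
print.free_state <- function(x, ...) {
  cat(sprintf(paste0("equilibrium free concentrations (nM): T_f = %.6g, ",
                     "H_f = %.6g\n  Ns_f = %.6g, Nu_f = %.6g\n"),
              x$T_f, x$H_f, x$Ns_f, x$Nu_f))
  cat(sprintf("  residual = %.3e, converged = %s (%s, %d iterations)\n",
              x$residual_norm, x$converged, x$method, x$iterations))
  invisible(x)
}

#' Binding specificity of the specific (enhancer) sites
#'
#' The probability that a specific site is TF-bound at equilibrium,
#' `(T_f/K_s)^n / (1 + (T_f/K_s)^n + H_f/K_h)`, i.e. the fraction of
#' enhancer sites productively occupied by the TF rather than free or
#' histone-occluded.
#'
#' @param state A [free_state][solve_equilibrium()] (or any list with `T_f`
#'   and `H_f` in nM).
#' @param system The [binding_system()] the state was solved under.
#' @return A fraction in \[0, 1\].
#' @export
specificity <- function(state, system) {
  occupancies(state$T_f, state$H_f, system)$theta_T_specific
}

#' Specificity landscape over a (K_s, K_h) affinity grid
#'
#' Re-solves the equilibrium at every grid point and records the binding
#' specificity, producing the affinity landscape in which simultaneous
#' strengthening of TF-DNA and histone-DNA binding boosts productive
#' enhancer occupancy far beyond either change alone.
#'
#' @param system Template [binding_system()]; totals, `hill_n` and (unless
#'   `couple_Ku = FALSE`) nothing else are taken from it.
#' @param ks_grid,kh_grid Positive K_s / K_h values (nM). Default: `n_grid`
#'   log-spaced points spanning `range`.
#' @param n_grid Grid size per axis when grids are not supplied. Default 50.
#' @param range Affinity range in nM for default grids. Default `c(1, 100)`.
#' @param couple_Ku If `TRUE` (default), `K_u = 10 * K_s` is re-derived at
#'   every grid point; otherwise the template's `K_u` is kept fixed.
#' @return An object of class `specificity_surface`: list with `ks_grid`,
#'   `kh_grid` and `values`, a `length(kh_grid) x length(ks_grid)` matrix of
#'   fractions (rows follow `kh_grid`).
#' @examples
#' surf <- specificity_surface(binding_system(), n_grid = 5)
#' surf$values
#' @export
specificity_surface <- function(system, ks_grid = NULL, kh_grid = NULL,
                                n_grid = 50, range = c(1, 100),
                                couple_Ku = TRUE) {
  validate_binding_system(system)
  if (is.null(ks_grid)) {
    ks_grid <- exp(seq(log(range[1]), log(range[2]), length.out = n_grid))
  }
  if (is.null(kh_grid)) {
    kh_grid <- exp(seq(log(range[1]), log(range[2]), length.out = n_grid))
  }
  if (length(ks_grid) == 0 || length(kh_grid) == 0 ||
      any(ks_grid <= 0) || any(kh_grid <= 0)) {
    stop("specificity_surface: grids must be non-empty and positive")
  }
  vals <- matrix(NA_real_, length(kh_grid), length(ks_grid),
                 dimnames = list(K_h = signif(kh_grid, 6),
                                 K_s = signif(ks_grid, 6)))
  for (i in seq_along(kh_grid)) {
    for (j in seq_along(ks_grid)) {
      sys_ij <- system
      sys_ij$K_s <- ks_grid[j]
      sys_ij$K_h <- kh_grid[i]
      if (couple_Ku) sys_ij$K_u <- 10 * ks_grid[j]
      st <- tryCatch(
        solve_equilibrium(sys_ij),
        error = function(e) {
          stop(sprintf("specificity_surface: solve failed at K_s = %g, K_h = %g: %s",
                       ks_grid[j], kh_grid[i], conditionMessage(e)))
        }
      )
      vals[i, j] <- specificity(st, sys_ij)
    }
  }
  structure(list(ks_grid = ks_grid, kh_grid = kh_grid, values = vals),
            class = "specificity_surface")
}

#' @export
print.specificity_surface <- function(x, ...) {
  cat(sprintf("specificity surface: %d x %d grid, K_s in [%g, %g], K_h in [%g, %g] nM\n",
              length(x$kh_grid), length(x$ks_grid),
              min(x$ks_grid), max(x$ks_grid),
              min(x$kh_grid), max(x$kh_grid)))
  cat(sprintf("  specificity range: [%.4f, %.4f]\n",
              min(x$values), max(x$values)))
  invisible(x)
}
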