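#' Mass-action kinetic scheme matching a binding system
#'
#' Builds an elementary-reaction scheme whose equilibrium coincides with the
#' algebraic competition model, for use as an independent dynamical check of
#' [solve_equilibrium()]. Species are the free pools (`T`, `H`, `Ns`, `Nu`)
#' and the complexes (`TnNs` - the concerted Hill-n TF complex on a specific
#' site -, `HNs`, `TNu`, `HNu`). All association rates are set to
#' `timescale`; dissociation rates are derived from the dissociation
#' constants so that detailed balance holds exactly (`K_s^n` for the
#' concerted specific complex, `K_u` and `K_h` for the others).
#'
#' With `sequential = TRUE` (only meaningful for `hill_n = 2`) the concerted
#' step is replaced by two sequential TF-binding steps with `K1 = 10 * K_s`
#' and `K2 = K_s / 10`, so `K1 >> K2` and `K1 * K2 = K_s^2`: the overall
#' site equilibrium is preserved while a sparsely populated single-TF
#' intermediate (`TNs`) is made explicit, for sensitivity analysis of the
#' concerted-complex idealisation.
#'
#' @param system A [binding_system()].
#' @param timescale Common association rate (per nM^k per time). Default 1.
#' @param sequential Use the sequential two-step specific-binding variant.
#' @return An object of class `kinetic_scheme`: list with `species` (named
#'   initial concentrations, nM), `reactions` (list of stoichiometry/rate
#'   records) and the originating `system`.
#' @export
build_scheme <- function(system, timescale = 1, sequential = FALSE) {
  validate_binding_system(system)
  if (!is.finite(timescale) || timescale <= 0) {
    stop("build_scheme: timescale must be > 0")
  }
  if (sequential && system$hill_n != 2L) {
    stop("build_scheme: sequential variant requires hill_n = 2")
  }
  n <- system$hill_n
  species <- c(T = system$T_total, H = system$H_total,
               Ns = system$Ns_total, Nu = system$Nu_total,
               TnNs = 0, HNs = 0, TNu = 0, HNu = 0)
  rx <- function(reactants, products, kon, koff) {
    list(reactants = reactants, products = products, kon = kon, koff = koff)
  }
  if (!sequential) {
    reactions <- list(
      specific_T = rx(c(T = n, Ns = 1), c(TnNs = 1),
                      timescale, timescale * system$K_s^n),
      specific_H = rx(c(H = 1, Ns = 1), c(HNs = 1),
                      timescale, timescale * system$K_h),
      unspecific_T = rx(c(T = 1, Nu = 1), c(TNu = 1),
                        timescale, timescale * system$K_u),
      unspecific_H = rx(c(H = 1, Nu = 1), c(HNu = 1),
                        timescale, timescale * system$K_h)
    )
  } else {
    species <- c(species, TNs = 0)
    reactions <- list(
      specific_T1 = rx(c(T = 1, Ns = 1), c(TNs = 1),
                       timescale, timescale * 10 * system$K_s),
      specific_T2 = rx(c(T = 1, TNs = 1), c(TnNs = 1),
                       timescale, timescale * system$K_s / 10),
      specific_H = rx(c(H = 1, Ns = 1), c(HNs = 1),
                      timescale, timescale * system$K_h),
      unspecific_T = rx(c(T = 1, Nu = 1), c(TNu = 1),
                        timescale, timescale * system$K_u),
      unspecific_H = rx(c(H = 1, Nu = 1), c(HNu = 1),
                        timescale, timescale * system$K_h)
    )
  }
  structure(list(species = species, reactions = reactions,
                 system = system, sequential = sequential),
            class = "kinetic_scheme")
}

#' Dissociation constants implied by a kinetic scheme
#'
#' Inverts [build_scheme()]: recovers each reaction's equilibrium constant
#' as `koff / kon` (the n-th root is taken for the concerted specific step).
#'
#' @param scheme A [build_scheme()] result.
#' @return Named numeric vector with `K_s`, `K_u`, `K_h` (nM).
#' @export
implied_constants <- function(scheme) {
  rs <- scheme$reactions
  n <- scheme$system$hill_n
  K_s <- if (scheme$sequential) {
    sqrt((rs$specific_T1$koff / rs$specific_T1$kon) *
           (rs$specific_T2$koff / rs$specific_T2$kon))
  } else {
    (rs$specific_T$koff / rs$specific_T$kon)^(1 / n)
  }
  c(K_s = K_s,
    K_u = rs$unspecific_T$koff / rs$unspecific_T$kon,
    K_h = rs$specific_H$koff / rs$specific_H$kon)
}

## net deterministic fluxes and species derivatives for a scheme
.scheme_derivs <- function(y, scheme) {
  dy <- numeric(length(y))
  names(dy) <- names(y)
  for (r in scheme$reactions) {
    fwd <- r$kon
    for (sp in names(r$reactants)) fwd <- fwd * y[[sp]]^r$reactants[[sp]]
    rev <- r$koff
    for (sp in names(r$products)) rev <- rev * y[[sp]]^r$products[[sp]]
    net <- fwd - rev
    for (sp in names(r$reactants)) {
      dy[[sp]] <- dy[[sp]] - r$reactants[[sp]] * net
    }
    for (sp in names(r$products)) {
      dy[[sp]] <- dy[[sp]] + r$products[[sp]] * net
    }
  }
  dy
}

#' Integrate the kinetic scheme to steady state
#'
#' Integrates the mass-action rate equations from the all-free state with a
#' stiff-capable solver ([deSolve::lsoda]), doubling the time horizon until
#' every normalized derivative `|dy/dt| / max(total, 1)` drops below `tol`.
#'
#' @param scheme A [build_scheme()] result.
#' @param t_max Maximum integration time (in units of 1/`timescale` rates).
#' @param tol Stationarity tolerance on normalized derivatives. Default 1e-10.
#' @return A `free_state` (as from [solve_equilibrium()]) with the steady
#'   free concentrations; `residual_norm` reports the largest normalized
#'   derivative at the returned state.
#' @export
integrate_to_steady_state <- function(scheme, t_max = 1e8, tol = 1e-10) {
  if (!inherits(scheme, "kinetic_scheme")) {
    stop("integrate_to_steady_state: scheme must come from build_scheme()")
  }
  totals <- pmax(c(scheme$system$T_total, scheme$system$H_total,
                   scheme$system$Ns_total, scheme$system$Nu_total), 1)
  norm_scale <- max(totals)
  derivs <- function(t, y, parms) list(.scheme_derivs(y, scheme))
  y <- scheme$species
  t_now <- 0
  t_next <- 1
  repeat {
    dnorm <- max(abs(.scheme_derivs(y, scheme))) / norm_scale
    if (dnorm < tol) break
    if (t_now >= t_max) {
      stop(sprintf(paste0("integrate_to_steady_state: not stationary at ",
                          "t = %g (normalized derivative %.3e)"),
                   t_now, dnorm))
    }
    sol <- deSolve::lsoda(y, c(t_now, t_next), derivs, parms = NULL,
                          rtol = 1e-10, atol = 1e-10 * norm_scale,
                          maxsteps = 50000)
    y <- sol[nrow(sol), -1]
    t_now <- t_next
    t_next <- min(2 * t_next, t_max)
  }
  st <- list(
    T_f = unname(y[["T"]]), H_f = unname(y[["H"]]),
    Ns_f = unname(y[["Ns"]]), Nu_f = unname(y[["Nu"]]),
    residual_norm = max(abs(.scheme_derivs(y, scheme))) / norm_scale,
    converged = TRUE, iterations = NA_integer_, method = "ode"
  )
  class(st) <- "free_state"
  st
}

#' Stochastic (Gillespie) occupancy of the kinetic scheme
#'
#' Exact stochastic simulation of the scheme at finite copy numbers.
#' Concentrations are converted to integer copies via `volume` (copies per
#' nM); propensities use factorial counts (`T*(T-1)` for the concerted
#' two-TF step), so the deterministic limit is recovered as `volume` grows.
#' Occupancies are time-averaged after a burn-in and reported with batch-
#' means Monte Carlo standard errors.
#'
#' @param scheme A [build_scheme()] result (concerted form only).
#' @param volume Copies per nM; every nonzero total must map to >= 1 copy.
#' @param n_events Number of reaction events to simulate.
#' @param burn_in Events discarded before averaging (< `n_events`).
#' @param seed Integer seed for reproducibility.
#' @param n_batches Batches for the standard-error estimate. Default 10.
#' @return An `occupancy_profile` with attributes `se` (named standard
#'   errors) and `events_used`.
#' @export
ssa_occupancy <- function(scheme, volume, n_events, burn_in, seed,
                          n_batches = 10) {
  if (!inherits(scheme, "kinetic_scheme") || scheme$sequential) {
    stop("ssa_occupancy: requires a concerted-form kinetic_scheme")
  }
  if (burn_in >= n_events) {
    stop("ssa_occupancy: burn_in must be smaller than n_events")
  }
  sys <- scheme$system
  n <- sys$hill_n
  if (n > 2L) stop("ssa_occupancy: implemented for hill_n <= 2")
  tot <- c(T = sys$T_total, H = sys$H_total,
           Ns = sys$Ns_total, Nu = sys$Nu_total)
  copies <- round(tot * volume)
  if (any(tot > 0 & copies < 1)) {
    stop("ssa_occupancy: volume too small, a nonzero species has 0 copies")
  }
  set.seed(as.integer(seed))

  ## state vector: T, H, Ns, Nu, TnNs, HNs, TNu, HNu (copy numbers)
  x <- c(copies, TnNs = 0, HNs = 0, TNu = 0, HNu = 0)
  ts <- scheme$reactions$specific_T$kon
  ## stochastic rate constants: kon / volume^(order - 1)
  c_sT <- ts / volume^n
  c_sT_off <- scheme$reactions$specific_T$koff
  c_sH <- scheme$reactions$specific_H$kon / volume
  c_sH_off <- scheme$reactions$specific_H$koff
  c_uT <- scheme$reactions$unspecific_T$kon / volume
  c_uT_off <- scheme$reactions$unspecific_T$koff
  c_uH <- scheme$reactions$unspecific_H$kon / volume
  c_uH_off <- scheme$reactions$unspecific_H$koff

  ## columns: state changes of the 8 reactions (4 forward, 4 reverse)
  nu <- cbind(
    c(-n, 0, -1, 0, +1, 0, 0, 0), c(+n, 0, +1, 0, -1, 0, 0, 0),
    c(0, -1, -1, 0, 0, +1, 0, 0), c(0, +1, +1, 0, 0, -1, 0, 0),
    c(-1, 0, 0, -1, 0, 0, +1, 0), c(+1, 0, 0, +1, 0, 0, -1, 0),
    c(0, -1, 0, -1, 0, 0, 0, +1), c(0, +1, 0, +1, 0, 0, 0, -1)
  )
  fact <- function(m, k) if (k == 1) m else m * (m - 1)  # falling factorial
  occ_time <- numeric(4)  # time-weighted sums: TnNs, HNs, TNu, HNu
  batch <- matrix(0, n_batches, 5)  # 4 occupancy sums + time, per batch
  total_time <- 0
  events_per_batch <- ceiling((n_events - burn_in) / n_batches)

  for (ev in seq_len(n_events)) {
    a <- c(
      c_sT * fact(x[1], n) * x[3], c_sT_off * x[5],
      c_sH * x[2] * x[3], c_sH_off * x[6],
      c_uT * x[1] * x[4], c_uT_off * x[7],
      c_uH * x[2] * x[4], c_uH_off * x[8]
    )
    a0 <- sum(a)
    if (a0 <= 0) break  # absorbing (no sites): state cannot change
    dt <- stats::rexp(1, a0)
    j <- sample.int(8, 1, prob = a)
    if (ev > burn_in) {
      w <- x[5:8] * dt
      occ_time <- occ_time + w
      total_time <- total_time + dt
      b <- min(n_batches, 1L + (ev - burn_in - 1L) %/% events_per_batch)
      batch[b, ] <- batch[b, ] + c(w, dt)
    }
    x <- x + nu[, j]
  }
  if (total_time <= 0) {
    stop("ssa_occupancy: no post-burn-in events recorded")
  }
  denom <- c(copies[["Ns"]], copies[["Ns"]], copies[["Nu"]], copies[["Nu"]])
  denom[denom == 0] <- NA_real_
  theta <- occ_time / total_time / denom
  ## batch means standard error
  bm <- sweep(batch[batch[, 5] > 0, 1:4, drop = FALSE], 1,
              batch[batch[, 5] > 0, 5], "/")
  bm <- sweep(bm, 2, denom, "/")
  se <- apply(bm, 2, stats::sd) / sqrt(nrow(bm))
  out <- list(
    theta_T_specific = theta[1], theta_H_specific = theta[2],
    theta_T_unspecific = theta[3], theta_H_unspecific = theta[4]
  )
  class(out) <- "occupancy_profile"
  attr(out, "se") <- c(theta_T_specific = se[1], theta_H_specific = se[2],
                       theta_T_unspecific = se[3], theta_H_unspecific = se[4])
  attr(out, "events_used") <- n_events - burn_in
  out
}
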