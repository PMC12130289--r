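#' Transcription factor / histone / binding-site system
#'
#' Bundles the total concentrations and dissociation constants of the
#' competition model in which a transcription factor (TF) binds its specific
#' enhancer sites cooperatively (Hill coefficient `hill_n`) while competing
#' with histones for both the specific sites and a large pool of unspecific
#' genomic sites.
#'
#' All quantities are held internally in nM. Defaults correspond to a
#' pluripotency-factor setting: 0.1 uM total TF, 10 uM total histone,
#' 0.01 uM specific sites and 10 uM unspecific sites, Hill coefficient 2,
#' and unspecific binding tenfold weaker than specific (`K_u = 10 * K_s`).
#'
#' @param T_total Total TF concentration (nM). Default 100.
#' @param H_total Total histone concentration (nM). Default 10000.
#' @param Ns_total Total specific-site concentration (nM). Default 10.
#' @param Nu_total Total unspecific-site concentration (nM). Default 10000.
#' @param K_s TF dissociation constant at specific sites (nM). Default 10,
#'   the log-midpoint of the 1-100 nM range usually swept.
#' @param K_h Histone dissociation constant (nM), shared by specific and
#'   unspecific sites. Default 10.
#' @param K_u TF dissociation constant at unspecific sites (nM). Defaults to
#'   `10 * K_s`; supply a value to decouple it.
#' @param hill_n Integer Hill coefficient for cooperative specific binding
#'   (>= 1). Default 2.
#' @param tf_per_site Number of TF molecules consumed per occupied specific
#'   site in the mass balance. Defaults to `hill_n` (the Hill-n site is a
#'   concerted n-TF complex); set to 1 for phenomenological single-molecule
#'   bookkeeping.
#' @param unit Unit of the supplied concentrations/constants: `"nM"`
#'   (default) or `"uM"` (converted on entry).
#'
#' @return An object of class `binding_system`: a named list with the fields
#'   above, always in nM.
#' @examples
#' sys <- binding_system(K_s = 10, K_h = 10)
#' st <- solve_equilibrium(sys)
#' specificity(st, sys)
#' @export
binding_system <- function(T_total = 100, H_total = 10000,
                           Ns_total = 10, Nu_total = 10000,
                           K_s = 10, K_h = 10, K_u = 10 * K_s,
                           hill_n = 2L, tf_per_site = hill_n,
                           unit = c("nM", "uM")) {
  unit <- match.arg(unit)
  scale <- if (unit == "uM") 1000 else 1
  sys <- list(
    T_total = T_total * scale, H_total = H_total * scale,
    Ns_total = Ns_total * scale, Nu_total = Nu_total * scale,
    K_s = K_s * scale, K_u = K_u * scale, K_h = K_h * scale,
    hill_n = as.integer(hill_n), tf_per_site = as.numeric(tf_per_site)
  )
  class(sys) <- "binding_system"
  validate_binding_system(sys)
  sys
}

validate_binding_system <- function(sys) {
  num <- vapply(sys[c("T_total", "H_total", "Ns_total", "Nu_total",
                      "K_s", "K_u", "K_h")], is.numeric, logical(1))
  if (!all(num)) {
    stop("binding_system: all concentrations and constants must be numeric")
  }
  tot <- unlist(sys[c("T_total", "H_total", "Ns_total", "Nu_total")])
  if (any(!is.finite(tot)) || any(tot < 0)) {
    stop("binding_system: total concentrations must be finite and >= 0")
  }
  ks <- unlist(sys[c("K_s", "K_u", "K_h")])
  if (any(!is.finite(ks)) || any(ks <= 0)) {
    stop("binding_system: dissociation constants must be finite and > 0")
  }
  if (is.na(sys$hill_n) || sys$hill_n < 1L) {
    stop("binding_system: hill_n must be an integer >= 1")
  }
  if (!is.finite(sys$tf_per_site) || sys$tf_per_site < 1) {
    stop("binding_system: tf_per_site must be >= 1")
  }
  invisible(sys)
}

#' @export
print.binding_system <- function(x, ...) {
  cat("TF-histone competition system (nM)\n")
  cat(sprintf("  totals:    T = %g, H = %g, Ns = %g, Nu = %g\n",
              x$T_total, x$H_total, x$Ns_total, x$Nu_total))
  cat(sprintf("  constants: K_s = %g, K_u = %g, K_h = %g\n",
              x$K_s, x$K_u, x$K_h))
  cat(sprintf("  cooperativity: hill_n = %d (TF per site: %g)\n",
              x$hill_n, x$tf_per_site))
  invisible(x)
}
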