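#' Two-sided Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Computes the Mann-Whitney U statistic for `group_a` versus `group_b`
#' (number of (a, b) pairs with a > b, counting ties as 1/2) and a
#' two-sided p-value. Small samples (`n1 + n2 <= 16`, or `mode = "exact"`)
#' are handled exactly: via the exact Mann-Whitney null distribution when
#' there are no ties, and by enumeration of all group assignments of the
#' combined values when there are; larger samples use the normal
#' approximation with tie correction and continuity correction. If every
#' value in both groups is identical the comparison is degenerate and
#' p = 1 is returned with `degenerate = TRUE`.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @param mode `"auto"` (default), `"exact"` or `"normal"`.
#' @param label Optional comparison label carried into the result.
#' @return An object of class `ranksum_result`: list with `label`, `U`,
#'   `p_raw`, `n1`, `n2`, `method`, `degenerate` (and `p_bonferroni` after
#'   [bonferroni()]).
#' @examples
#' ranksum_test(c(1, 2), c(3, 4))$p_raw  # exact 1/3
#' @export
ranksum_test <- function(group_a, group_b,
                         mode = c("auto", "exact", "normal"),
                         label = NULL) {
  mode <- match.arg(mode)
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("ranksum_test: both groups must be non-empty")
  }
  if (any(!is.finite(c(group_a, group_b)))) {
    stop("ranksum_test: values must be finite")
  }
  n1 <- length(group_a)
  n2 <- length(group_b)
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  res <- list(label = label, U = U, p_raw = NA_real_, n1 = n1, n2 = n2,
              method = NA_character_, degenerate = FALSE)
  class(res) <- "ranksum_result"

  if (length(unique(pooled)) == 1) {
    res$p_raw <- 1
    res$method <- "degenerate"
    res$degenerate <- TRUE
    return(res)
  }

  use_exact <- mode == "exact" || (mode == "auto" && n1 + n2 <= 16)
  if (use_exact && anyDuplicated(pooled) == 0) {
    ## tie-free: exact Mann-Whitney null distribution
    p_lo <- stats::pwilcox(U, n1, n2)
    p_hi <- stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    res$p_raw <- min(1, 2 * min(p_lo, p_hi))
    res$method <- "exact"
  } else if (use_exact) {
    ## ties: permutation enumeration over all group assignments
    if (choose(n1 + n2, n1) > 2e6) {
      stop("ranksum_test: exact test with ties infeasible at this size; use mode = 'normal'")
    }
    idx <- utils::combn(n1 + n2, n1)
    ustats <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p_lo <- mean(ustats <= U)
    p_hi <- mean(ustats >= U)
    res$p_raw <- min(1, 2 * min(p_lo, p_hi))
    res$method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    N <- n1 + n2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma <- sqrt(n1 * n2 / 12 * (N + 1 - tie_term))
    cc <- sign(U - mu) * 0.5  # continuity correction toward the mean
    z <- (U - mu - cc) / sigma
    res$p_raw <- min(1, 2 * stats::pnorm(-abs(z)))
    res$method <- "normal"
  }
  res
}

#' @export
print.ranksum_result <- function(x, ...) {
  cat(sprintf("rank-sum%s: U = %g (n1 = %d, n2 = %d), p = %.4g [%s]%s\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$U, x$n1, x$n2, x$p_raw, x$method,
              if (!is.null(x$p_bonferroni)) {
                sprintf(", p_bonferroni = %.4g", x$p_bonferroni)
              } else ""))
  invisible(x)
}

#' Bonferroni correction across declared comparisons
#'
#' Sets `p_bonferroni = min(1, m * p_raw)` for each result, with `m`
#' defaulting to the number of comparisons actually performed.
#'
#' @param results List of [ranksum_test()] results.
#' @param m Number of declared comparisons (>= `length(results)`).
#' @return The list with `p_bonferroni` filled in, order preserved.
#' @export
bonferroni <- function(results, m = length(results)) {
  if (inherits(results, "ranksum_result")) results <- list(results)
  if (m < length(results)) {
    stop("bonferroni: m must be >= the number of results")
  }
  lapply(results, function(r) {
    r$p_bonferroni <- min(1, m * r$p_raw)
    r
  })
}

#' Tidy table of rank-sum results
#'
#' @param results List of (possibly Bonferroni-corrected) rank-sum results.
#' @return data.frame with columns `comparison`, `U`, `n1`, `n2`, `p_raw`,
#'   `p_bonferroni`.
#' @export
ranksum_table <- function(results) {
  if (inherits(results, "ranksum_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(
      comparison = if (is.null(r$label)) NA_character_ else r$label,
      U = r$U, n1 = r$n1, n2 = r$n2, p_raw = r$p_raw,
      p_bonferroni = if (is.null(r$p_bonferroni)) NA_real_ else
        r$p_bonferroni
    )
  }))
}
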