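#' Configuration for the synthetic enhancer-landscape generator
#'
#' Describes the synthetic study the generator emulates: a small interval-
#' level genome carrying planted enhancers whose accessibility opens,
#' closes or stays stable between two conditions, with negative-binomial
#' replicate counts, imperfect replicate peak calling, and a planted
#' three-TF co-binding structure enriched at opening enhancers.
#'
#' @param chrom_sizes Named integer vector of chromosome sizes in bp.
#'   Default two 5-Mb chromosomes.
#' @param n_opening,n_closing,n_stable Planted enhancer counts per class.
#'   Defaults 40 / 40 / 120.
#' @param region_width Planted enhancer width in bp. Default 500.
#' @param effect_log2fc Planted |log2 fold change| for opening/closing
#'   regions. Default 2.
#' @param baseline_mean Expected fragments per planted region per sample in
#'   the reference condition. Default 200.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`). Default 0.1.
#' @param depth Total fragments per sample. Default 200000.
#' @param replicates Replicates per condition. Default 3.
#' @param peak_sensitivity Probability a true region is called per
#'   replicate. Default 0.9.
#' @param fpr_peaks Spurious peaks per Mb per replicate. Default 5.
#' @param cobind_prob Named per-class probabilities that an enhancer is
#'   co-bound by all three TFs. Defaults opening 0.6, closing 0.1,
#'   stable 0.2.
#' @param fragment_len_mean,fragment_len_sd Fragment length distribution
#'   (normal, truncated at 50 bp). Defaults 150 / 20.
#' @param summit_jitter Laplace scale (bp) of fragment centers around the
#'   true summit. Default 50.
#' @param seed Integer seed. Default 1.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(chrom_sizes = c(chr1 = 5e6, chr2 = 5e6),
                             n_opening = 40, n_closing = 40, n_stable = 120,
                             region_width = 500,
                             effect_log2fc = 2, baseline_mean = 200,
                             nb_dispersion = 0.1, depth = 200000,
                             replicates = 3,
                             peak_sensitivity = 0.9, fpr_peaks = 5,
                             cobind_prob = c(opening = 0.6, closing = 0.1,
                                             stable = 0.2),
                             fragment_len_mean = 150, fragment_len_sd = 20,
                             summit_jitter = 50, seed = 1) {
  cfg <- list(chrom_sizes = chrom_sizes, n_opening = n_opening,
              n_closing = n_closing, n_stable = n_stable,
              region_width = region_width, effect_log2fc = effect_log2fc,
              baseline_mean = baseline_mean, nb_dispersion = nb_dispersion,
              depth = depth, replicates = replicates,
              peak_sensitivity = peak_sensitivity, fpr_peaks = fpr_peaks,
              cobind_prob = cobind_prob,
              fragment_len_mean = fragment_len_mean,
              fragment_len_sd = fragment_len_sd,
              summit_jitter = summit_jitter, seed = as.integer(seed))
  if (is.null(names(chrom_sizes)) || any(chrom_sizes <= 0)) {
    stop("synthetic_config: chrom_sizes must be named and positive")
  }
  if (any(c(n_opening, n_closing, n_stable) < 0)) {
    stop("synthetic_config: region counts must be >= 0")
  }
  probs <- c(peak_sensitivity, cobind_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("synthetic_config: probabilities must lie in [0, 1]")
  }
  if (!all(c("opening", "closing", "stable") %in% names(cobind_prob))) {
    stop("synthetic_config: cobind_prob needs opening/closing/stable entries")
  }
  if (nb_dispersion <= 0 || baseline_mean <= 0 || effect_log2fc < 0) {
    stop("synthetic_config: invalid count-model parameters")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

## draw n non-overlapping starts on [1, size] with >= gap bp between
## region ends and next starts, by spacing a uniform order statistic
.spaced_starts <- function(n, size, width, gap) {
  if (n == 0) return(integer(0))
  slack <- size - n * (width + gap)
  if (slack <= 0) {
    stop("plant_truth: genome too small for the requested regions")
  }
  y <- sort(stats::runif(n, 0, slack))
  as.integer(floor(y + (seq_len(n) - 1) * (width + gap))) + 1L
}

#' Plant the ground-truth enhancer landscape
#'
#' Places the configured numbers of opening, closing and stable enhancers
#' uniformly over the synthetic genome with at least 1 kb spacing, assigns
#' each a true summit (region center), a co-binding flag drawn with its
#' class probability, and per-condition expected mean counts
#' (`baseline * 2^(+/- effect_log2fc)` in condition 2 for opening/closing
#' regions). Deterministic under the config seed.
#'
#' @param config A [synthetic_config()].
#' @return A `GRanges` with metadata columns `class`, `summit`, `score`,
#'   `cobound`, `mean_cond1`, `mean_cond2`.
#' @export
plant_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n_tot <- config$n_opening + config$n_closing + config$n_stable
  sizes <- config$chrom_sizes
  ## allocate regions to chromosomes proportionally to size
  alloc <- floor(n_tot * sizes / sum(sizes))
  rem <- n_tot - sum(alloc)
  if (rem > 0) {
    extra <- order(sizes, decreasing = TRUE)[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1
  }
  grl <- lapply(names(sizes), function(ch) {
    st <- .spaced_starts(alloc[[ch]], sizes[[ch]], config$region_width, 1000)
    if (length(st) == 0) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(ch, IRanges::IRanges(st, width = config$region_width))
  })
  gr <- suppressWarnings(do.call(c, grl))
  cls <- sample(rep(c("opening", "closing", "stable"),
                    c(config$n_opening, config$n_closing, config$n_stable)))
  S4Vectors::mcols(gr)$class <- cls
  S4Vectors::mcols(gr)$summit <-
    (GenomicRanges::start(gr) + GenomicRanges::end(gr)) %/% 2L
  S4Vectors::mcols(gr)$score <- 1
  S4Vectors::mcols(gr)$cobound <-
    stats::rbinom(length(gr), 1, config$cobind_prob[cls]) == 1
  fc <- 2^config$effect_log2fc
  m1 <- rep(config$baseline_mean, length(gr))
  m2 <- ifelse(cls == "opening", config$baseline_mean * fc,
               ifelse(cls == "closing", config$baseline_mean / fc,
                      config$baseline_mean))
  S4Vectors::mcols(gr)$mean_cond1 <- m1
  S4Vectors::mcols(gr)$mean_cond2 <- m2
  GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(gr))
}

## Laplace(0, scale) deviates
.rlaplace <- function(n, scale) {
  u <- stats::runif(n) - 0.5
  -scale * sign(u) * log(1 - 2 * abs(u))
}

## fragments around given centers with the configured length model
.make_fragments <- function(centers, chrom, config, chrom_size) {
  len <- pmax(50, round(stats::rnorm(length(centers),
                                     config$fragment_len_mean,
                                     config$fragment_len_sd)))
  start <- pmax(1L, as.integer(round(centers - len / 2)))
  end <- pmin(as.integer(chrom_size), start + as.integer(len) - 1L)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, pmax(start, end)))
}

#' Simulate per-sample fragment sets
#'
#' For every sample (condition x replicate) each planted region receives a
#' negative-binomial fragment count with the region's condition mean and
#' the configured dispersion; fragment centers scatter around the true
#' summit with Laplace jitter and the remaining depth is filled with
#' uniform background fragments. Fragment lengths are normal (mean 150 bp,
#' sd 20, truncated at 50). Deterministic under the config seed.
#'
#' @param truth A [plant_truth()] result.
#' @param config The same [synthetic_config()].
#' @return Named list of fragment `GRanges`, one per sample
#'   (`cond<k>_rep<j>`), with a `samples` data.frame attribute
#'   (`name`, `condition`, `replicate`).
#' @export
simulate_fragments <- function(truth, config) {
  stopifnot(inherits(config, "synthetic_config"))
  sizes <- config$chrom_sizes
  cls <- S4Vectors::mcols(truth)$class
  summit <- S4Vectors::mcols(truth)$summit
  chrom <- as.character(GenomeInfoDb::seqnames(truth))
  size_nb <- 1 / config$nb_dispersion
  samples <- expand.grid(replicate = seq_len(config$replicates),
                         condition = c("cond1", "cond2"),
                         stringsAsFactors = FALSE)
  samples$name <- sprintf("%s_rep%d", samples$condition, samples$replicate)
  out <- vector("list", nrow(samples))
  names(out) <- samples$name
  for (s in seq_len(nrow(samples))) {
    set.seed(config$seed + 1000L + s)
    mu <- if (samples$condition[s] == "cond1") {
      S4Vectors::mcols(truth)$mean_cond1
    } else {
      S4Vectors::mcols(truth)$mean_cond2
    }
    if (config$depth == 0) {
      out[[s]] <- GenomicRanges::GRanges()
      next
    }
    counts <- stats::rnbinom(length(truth), mu = mu, size = size_nb)
    frag_list <- list()
    if (sum(counts) > 0) {
      idx <- rep(seq_along(truth), counts)
      centers <- summit[idx] + .rlaplace(length(idx), config$summit_jitter)
      frag_list <- lapply(split(seq_along(idx), chrom[idx]), function(ii) {
        ch <- chrom[idx[ii[1]]]
        .make_fragments(centers[ii], ch, config, sizes[[ch]])
      })
    }
    n_bg <- max(0, config$depth - sum(counts))
    if (n_bg > 0) {
      bg_chr <- sample(names(sizes), n_bg, replace = TRUE,
                       prob = sizes / sum(sizes))
      bg_list <- lapply(split(seq_len(n_bg), bg_chr), function(ii) {
        ch <- bg_chr[ii[1]]
        centers <- stats::runif(length(ii), 1, sizes[[ch]])
        .make_fragments(centers, ch, config, sizes[[ch]])
      })
      frag_list <- c(frag_list, bg_list)
    }
    gr <- if (length(frag_list) == 0) GenomicRanges::GRanges() else
      suppressWarnings(do.call(c, unname(frag_list)))
    out[[s]] <- GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(gr))
  }
  attr(out, "samples") <- samples[, c("name", "condition", "replicate")]
  out
}

## one replicate's called peaks over the truth, plus spurious calls
.call_one_replicate <- function(truth, called, config) {
  sizes <- config$chrom_sizes
  gr <- truth[called]
  if (length(gr) > 0) {
    noisy <- S4Vectors::mcols(gr)$summit +
      as.integer(round(stats::rnorm(length(gr), 0, 20)))
    S4Vectors::mcols(gr)$summit <- pmin(pmax(noisy, GenomicRanges::start(gr)),
                                        GenomicRanges::end(gr))
    S4Vectors::mcols(gr)$score <- stats::runif(length(gr), 1, 10)
  }
  keep <- c("summit", "score")
  S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)[, keep]
  n_fp <- stats::rpois(1, config$fpr_peaks * sum(sizes) / 1e6)
  if (n_fp > 0) {
    fp_chr <- sample(names(sizes), n_fp, replace = TRUE,
                     prob = sizes / sum(sizes))
    fp_start <- vapply(fp_chr, function(ch) {
      as.integer(stats::runif(1, 1, sizes[[ch]] - config$region_width))
    }, integer(1))
    fp <- peaks(fp_chr, fp_start, fp_start + config$region_width - 1L,
                score = stats::runif(n_fp, 0.5, 3))
    gr <- suppressWarnings(c(gr, fp))
  }
  GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(gr))
}

#' Simulate replicate peak calls for marks and TFs
#'
#' Histone marks call every planted region (per replicate, with probability
#' `peak_sensitivity` and summit noise of sd 20 bp); TF peak sets respect
#' the planted co-binding structure: all three TFs are called at co-bound
#' regions, exactly one (uniformly chosen) TF elsewhere, again thinned by
#' `peak_sensitivity` per replicate. Spurious peaks arrive as a Poisson
#' process at `fpr_peaks` per Mb. Deterministic under the config seed.
#'
#' @param truth A [plant_truth()] result.
#' @param config The same [synthetic_config()].
#' @param marks Histone-mark names. Default `c("H3K27ac", "H3K4me1")`.
#' @param tfs TF names. Default `c("SOX2", "KLF4", "TEAD1")`.
#' @return Named list (one entry per mark/TF) of lists of replicate peak
#'   `GRanges`.
#' @export
simulate_peak_calls <- function(truth, config,
                                marks = c("H3K27ac", "H3K4me1"),
                                tfs = c("SOX2", "KLF4", "TEAD1")) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 500L)
  cob <- S4Vectors::mcols(truth)$cobound
  ## which TFs target which region (independent of replicate dropout)
  solo_tf <- sample(seq_along(tfs), length(truth), replace = TRUE)
  out <- list()
  for (m in marks) {
    out[[m]] <- lapply(seq_len(config$replicates), function(r) {
      called <- stats::runif(length(truth)) < config$peak_sensitivity
      .call_one_replicate(truth, called, config)
    })
  }
  for (k in seq_along(tfs)) {
    target <- cob | solo_tf == k
    out[[tfs[k]]] <- lapply(seq_len(config$replicates), function(r) {
      called <- target & stats::runif(length(truth)) < config$peak_sensitivity
      .call_one_replicate(truth, called, config)
    })
  }
  out
}

#' Random panel of binding systems
#'
#' Draws `n` systems with log-uniform parameters inside the given bounds;
#' `K_u` is coupled to `10 * K_s`. Degenerate bounds (lo = hi) reproduce a
#' value exactly, so the all-degenerate default panel with `n = 1` returns
#' the default system.
#'
#' @param n Number of systems (>= 1).
#' @param seed Integer seed.
#' @param ranges Named list of `c(lo, hi)` bounds (nM) for any of
#'   `T_total`, `H_total`, `Ns_total`, `Nu_total`, `K_s`, `K_h`. Defaults:
#'   totals fixed at the default system, `K_s` and `K_h` in `[1, 100]`.
#' @param hill_n Hill coefficient for all systems. Default 2.
#' @return List of [binding_system()] objects.
#' @export
sample_systems <- function(n, seed, ranges = list(), hill_n = 2L) {
  if (n < 1) stop("sample_systems: n must be >= 1")
  set.seed(as.integer(seed))
  def <- list(T_total = c(100, 100), H_total = c(10000, 10000),
              Ns_total = c(10, 10), Nu_total = c(10000, 10000),
              K_s = c(1, 100), K_h = c(1, 100))
  unknown <- setdiff(names(ranges), names(def))
  if (length(unknown) > 0) {
    stop("sample_systems: unknown parameter(s): ",
         paste(unknown, collapse = ", "))
  }
  def[names(ranges)] <- ranges
  draw <- function(b) {
    if (b[1] == b[2]) rep(b[1], n) else
      exp(stats::runif(n, log(b[1]), log(b[2])))
  }
  par <- lapply(def, draw)
  lapply(seq_len(n), function(i) {
    binding_system(T_total = par$T_total[i], H_total = par$H_total[i],
                   Ns_total = par$Ns_total[i], Nu_total = par$Nu_total[i],
                   K_s = par$K_s[i], K_h = par$K_h[i],
                   K_u = 10 * par$K_s[i], hill_n = hill_n)
  })
}
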