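test_that("planted truth respects counts, spacing and the seed", {
  cfg <- synthetic_config(n_opening = 10, n_closing = 10, n_stable = 30,
                          seed = 21)
  tr <- plant_truth(cfg)
  expect_equal(length(tr), 50L)
  expect_equal(as.integer(table(tr$class)[c("closing", "opening", "stable")]),
               c(10L, 10L, 30L))
  ## >= 1 kb between consecutive regions on each chromosome
  by_chr <- split(tr, GenomeInfoDb::seqnames(tr))
  for (g in by_chr) {
    if (length(g) < 2) next
    gaps <- GenomicRanges::start(g)[-1] -
      GenomicRanges::end(g)[-length(g)]
    expect_true(all(gaps >= 1000))
  }
  expect_identical(plant_truth(cfg), tr)  # same seed, same truth
  expect_false(identical(plant_truth(synthetic_config(seed = 22)), tr))
  expect_error(plant_truth(synthetic_config(chrom_sizes = c(chr1 = 10000),
                                            seed = 1)),
               "too small")
})

test_that("planted condition means encode the configured effect", {
  cfg <- synthetic_config(seed = 3)
  tr <- plant_truth(cfg)
  expect_equal(unique(tr$mean_cond2[tr$class == "opening"] /
                        tr$mean_cond1[tr$class == "opening"]), 4)
  expect_equal(unique(tr$mean_cond2[tr$class == "closing"] /
                        tr$mean_cond1[tr$class == "closing"]), 0.25)
  expect_equal(unique(tr$mean_cond2[tr$class == "stable"] /
                        tr$mean_cond1[tr$class == "stable"]), 1)
})

test_that("simulated fragment counts match the negative-binomial design", {
  cfg <- synthetic_config(n_opening = 0, n_closing = 0, n_stable = 500,
                          baseline_mean = 100, depth = 80000, seed = 5)
  tr <- plant_truth(cfg)
  fr <- simulate_fragments(tr, cfg)
  se <- count_fragments(summit_windows(tr), fr, attr(fr, "samples"))
  cnt <- SummarizedExperiment::assay(se)
  ## per-region means across 500 regions: mean 100 within 3 SE (plus a
  ## small uniform-background contribution inside each 400 bp window)
  mu <- 100
  sdv <- sqrt(mu + 0.1 * mu^2)
  for (s in seq_len(ncol(cnt))) {
    bg <- 80000 * 400 / 1e7  # expected background fragments per window
    expect_lt(abs(mean(cnt[, s]) - (mu + bg)), 3 * sdv / sqrt(500) + bg)
    ## empirical variance reflects overdispersion: the NB design value is
    ## mu + 0.1 mu^2 = 1100, far above the Poisson 100
    expect_gt(stats::var(cnt[, s]), 400)
    expect_lt(stats::var(cnt[, s]), 2500)
  }
})

test_that("fragment simulation is seed-stable and honours depth 0", {
  cfg <- synthetic_config(n_opening = 2, n_closing = 2, n_stable = 6,
                          seed = 9)
  tr <- plant_truth(cfg)
  expect_identical(simulate_fragments(tr, cfg), simulate_fragments(tr, cfg))
  cfg0 <- synthetic_config(n_opening = 2, n_closing = 2, n_stable = 6,
                           depth = 0, seed = 9)
  fr0 <- simulate_fragments(plant_truth(cfg0), cfg0)
  expect_true(all(vapply(fr0, length, integer(1)) == 0))
})

test_that("a zero planted effect yields an unbiased log2 fold change", {
  cfg <- synthetic_config(effect_log2fc = 0, n_opening = 100, n_closing = 0,
                          n_stable = 100, seed = 13)
  tr <- plant_truth(cfg)
  fr <- simulate_fragments(tr, cfg)
  se <- count_fragments(summit_windows(tr), fr, attr(fr, "samples"))
  dt <- simple_differential(se)
  ## mean log2FC across 200 null regions ~ 0 within 3 SE
  se_mean <- stats::sd(dt$log2FC) / sqrt(nrow(dt))
  expect_lt(abs(mean(dt$log2FC)), 3 * se_mean)
})

test_that("the differential estimator is unbiased for the planted effect", {
  cfg <- synthetic_config(seed = 17)
  tr <- plant_truth(cfg)
  fr <- simulate_fragments(tr, cfg)
  se <- count_fragments(summit_windows(tr), fr, attr(fr, "samples"))
  dt <- simple_differential(se)
  op <- tr$class == "opening"
  se_mean <- stats::sd(dt$log2FC[op]) / sqrt(sum(op))
  expect_lt(abs(mean(dt$log2FC[op]) - cfg$effect_log2fc), 3 * se_mean + 0.1)
})

test_that("perfect peak calling tiles the truth; zero sensitivity leaves noise", {
  cfg <- synthetic_config(n_opening = 5, n_closing = 5, n_stable = 10,
                          peak_sensitivity = 1, fpr_peaks = 0, seed = 31)
  tr <- plant_truth(cfg)
  pk <- simulate_peak_calls(tr, cfg)
  for (rep_pk in pk$H3K27ac) {
    expect_identical(df_from_granges(rep_pk), df_from_granges(tr))
  }
  cfg0 <- synthetic_config(n_opening = 5, n_closing = 5, n_stable = 10,
                           peak_sensitivity = 0, fpr_peaks = 10, seed = 31)
  pk0 <- simulate_peak_calls(plant_truth(cfg0), cfg0)
  for (rep_pk in pk0$H3K27ac) {
    ## only spurious calls remain: none starts at a planted region start
    expect_false(any(GenomicRanges::start(rep_pk) %in%
                       GenomicRanges::start(tr)))
    expect_gt(length(rep_pk), 0)  # Poisson false positives present
  }
})

test_that("replicate dropout is consistent with binomial reproducibility", {
  cfg <- synthetic_config(n_opening = 100, n_closing = 100, n_stable = 200,
                          fpr_peaks = 0, seed = 37)
  tr <- plant_truth(cfg)
  pk <- simulate_peak_calls(tr, cfg)
  rep3 <- reproducible_peaks(pk$H3K27ac, 3)
  frac <- mean(GenomicRanges::countOverlaps(tr, rep3) > 0)
  p3 <- cfg$peak_sensitivity^3
  expect_gt(frac, p3 - 3 * sqrt(p3 * (1 - p3) / length(tr)))
})

test_that("TF peak calls respect the planted co-binding structure", {
  cfg <- synthetic_config(n_opening = 40, n_closing = 40, n_stable = 80,
                          peak_sensitivity = 1, fpr_peaks = 0, seed = 41)
  tr <- plant_truth(cfg)
  pk <- simulate_peak_calls(tr, cfg)
  tfs <- lapply(pk[c("SOX2", "KLF4", "TEAD1")], function(reps) reps[[1]])
  n_tf <- sapply(tfs, function(g) GenomicRanges::countOverlaps(tr, g) > 0)
  hits <- rowSums(n_tf)
  expect_true(all(hits[tr$cobound] == 3))      # co-bound: all three called
  expect_true(all(hits[!tr$cobound] <= 1))     # elsewhere at most one
})

test_that("random system panels respect bounds, coupling and the seed", {
  panel <- sample_systems(25, seed = 51)
  expect_length(panel, 25)
  for (sys in panel) {
    expect_s3_class(sys, "binding_system")
    expect_true(sys$K_s >= 1 && sys$K_s <= 100)
    expect_true(sys$K_h >= 1 && sys$K_h <= 100)
    expect_equal(sys$K_u, 10 * sys$K_s)
  }
  expect_identical(sample_systems(25, seed = 51), panel)
  ## degenerate bounds reproduce the default system exactly
  one <- sample_systems(1, seed = 1,
                        ranges = list(K_s = c(10, 10), K_h = c(10, 10)))[[1]]
  expect_equal(one[c("T_total", "H_total", "Ns_total", "Nu_total",
                     "K_s", "K_u", "K_h")],
               binding_system(K_s = 10, K_h = 10)[
                 c("T_total", "H_total", "Ns_total", "Nu_total",
                   "K_s", "K_u", "K_h")])
  expect_error(sample_systems(2, seed = 1, ranges = list(bogus = c(1, 2))),
               "unknown parameter")
})
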