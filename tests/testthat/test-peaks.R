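test_that("reproducible peaks handle the unanimous and singleton corners", {
  pk <- peaks("chr1", 100, 500, summit = 300, score = 5)
  reps <- list(pk, pk, pk)
  out <- reproducible_peaks(reps, 3)
  expect_equal(length(out), 1L)
  expect_equal(GenomicRanges::start(out), 100)
  expect_equal(GenomicRanges::end(out), 500)
  expect_equal(out$summit, 300L)
  ## a peak present in 1/3 replicates is dropped at min_reps = 2
  lone <- list(pk, peaks("chr1", 5000, 5400), peaks("chr1", 7000, 7400))
  expect_equal(length(reproducible_peaks(lone, 2)), 0L)
  expect_error(reproducible_peaks(list(), 1), "non-empty")
  expect_error(reproducible_peaks(reps, 4), "min_reps")
})

test_that("merged peaks inherit summit and score from the strongest contributor", {
  r1 <- peaks("chr1", 100, 600, summit = 200, score = 2)
  r2 <- peaks("chr1", 400, 900, summit = 700, score = 9)
  out <- reproducible_peaks(list(r1, r2), 1)
  expect_equal(length(out), 1L)
  expect_equal(out$score, 9)
  expect_equal(out$summit, 700L)
})

test_that("reproducible peaks equal the per-base depth oracle", {
  L <- 50000
  for (seed in 1:10) {
    set.seed(seed)
    n_reps <- sample(2:4, 1)
    reps <- lapply(seq_len(n_reps), function(i) rand_peakset(10, L))
    k <- sample(seq_len(n_reps), 1)
    out <- reproducible_peaks(reps, k)
    expect_identical(df_from_granges(out), oracle_reproducible(reps, k, L))
  }
})

test_that("active enhancers are the all-replicate intersection of both marks", {
  pk <- peaks("chr1", 100, 500, summit = 250, score = 3)
  enh <- define_active_enhancers(list(pk, pk), list(pk, pk))
  expect_equal(length(enh), 1L)
  expect_equal(GenomicRanges::start(enh), 100)
  ## disjoint marks give no enhancers
  far <- peaks("chr1", 9000, 9400)
  expect_equal(length(define_active_enhancers(list(pk), list(far))), 0L)
})

test_that("active enhancers equal the per-base AND oracle", {
  L <- 50000
  for (seed in 11:20) {
    set.seed(seed)
    ac <- lapply(1:3, function(i) rand_peakset(12, L))
    me <- lapply(1:2, function(i) rand_peakset(12, L))
    enh <- define_active_enhancers(ac, me)
    expect_identical(df_from_granges(enh), oracle_enhancers(ac, me, L))
    if (length(enh) > 0) {
      expect_true(all(enh$summit >= GenomicRanges::start(enh) &
                        enh$summit <= GenomicRanges::end(enh)))
    }
  }
})

test_that("summit windows span +/- flank and clip at the chromosome start", {
  ## summit at 0-based 1000 -> window [800, 1200) in 0-based half-open
  enh <- peaks("chr1", 900, 1200, summit = 1001, score = 1)
  w <- summit_windows(enh, 200)
  expect_equal(GenomicRanges::start(w) - 1L, 800L)  # 0-based start
  expect_equal(GenomicRanges::end(w), 1200L)        # 0-based exclusive end
  expect_equal(GenomicRanges::width(w), 400L)
  ## summit at 0-based 100 clips to [0, 300)
  enh2 <- peaks("chr1", 50, 400, summit = 101, score = 1)
  w2 <- summit_windows(enh2, 200)
  expect_equal(GenomicRanges::start(w2), 1L)
  expect_equal(GenomicRanges::end(w2), 300L)
  expect_error(summit_windows(enh, 0), "flank")
})

test_that("fragment counting matches the brute-force overlap oracle", {
  set.seed(77)
  win <- summit_windows(rand_peakset(50, 90000), 200)
  frags <- list(s1 = rand_fragments(1000, 90000),
                s2 = rand_fragments(500, 90000))
  se <- count_fragments(win, frags)
  cnt <- SummarizedExperiment::assay(se, "counts")
  expect_identical(cnt[, "s1"], oracle_counts(win, frags$s1))
  expect_identical(cnt[, "s2"], oracle_counts(win, frags$s2))
  ## no fragments -> all zero
  empty <- count_fragments(win, list(s = GenomicRanges::GRanges()))
  expect_true(all(SummarizedExperiment::assay(empty) == 0))
  ## one fragment exactly equal to one window counts once
  one <- count_fragments(win[1], list(s = GenomicRanges::granges(win[1])))
  expect_equal(unname(SummarizedExperiment::assay(one)[1, 1]), 1L)
})

test_that("counting is invariant under sample and fragment order", {
  set.seed(78)
  win <- summit_windows(rand_peakset(20, 40000), 200)
  fr <- rand_fragments(400, 40000)
  se1 <- count_fragments(win, list(a = fr, b = fr[1:100]))
  se2 <- count_fragments(win, list(b = fr[1:100], a = fr[sample(400)]))
  expect_identical(SummarizedExperiment::assay(se1)[, "a"],
                   SummarizedExperiment::assay(se2)[, "a"])
  expect_identical(SummarizedExperiment::assay(se1)[, "b"],
                   SummarizedExperiment::assay(se2)[, "b"])
})

test_that("co-binding fractions follow the three-way intersection oracle", {
  enh <- peaks("chr1", c(100, 1000, 2000), c(400, 1400, 2400))
  cls <- factor(c("opening", "opening", "non_changing"),
                levels = c("opening", "closing", "non_changing"))
  blanket <- peaks("chr1", 1, 3000)
  ## all three TFs blanket everything -> 100% in every non-empty class
  fr <- cobound_overlap_fraction(enh, cls, list(blanket, blanket, blanket))
  expect_equal(unname(fr[c("opening", "non_changing")]), c(100, 100))
  expect_true(is.na(fr[["closing"]]))  # empty class undefined
  ## one empty TF set -> 0% everywhere
  fr0 <- cobound_overlap_fraction(
    enh, cls, list(blanket, blanket, peaks(character(), integer(), integer())))
  expect_equal(unname(fr0[c("opening", "non_changing")]), c(0, 0))
  expect_error(cobound_overlap_fraction(enh, cls, list(blanket, blanket)),
               "three")
})

test_that("co-binding fractions match the per-base oracle on random sets", {
  L <- 60000
  for (seed in 21:30) {
    set.seed(seed)
    enh <- rand_peakset(20, L)
    enh <- enh[!duplicated(df_from_granges(enh))]
    cls <- factor(sample(c("opening", "closing", "non_changing"),
                         length(enh), replace = TRUE),
                  levels = c("opening", "closing", "non_changing"))
    tfs <- lapply(1:3, function(i) rand_peakset(15, L))
    got <- cobound_overlap_fraction(enh, cls, tfs)
    hits <- oracle_cobound_hits(enh, tfs, L)
    for (cl in levels(cls)) {
      idx <- which(cls == cl)
      want <- if (length(idx) == 0) NA_real_ else 100 * mean(hits[idx])
      expect_equal(unname(got[[cl]]), want)
    }
  }
})
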