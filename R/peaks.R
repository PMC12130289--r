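## Peaks are GRanges with metadata columns `summit` (1-based absolute
## position inside the peak) and `score` (>= 0). Files use the BED
## 0-based half-open convention; conversion happens in the readers/writers.

.assert_peaks <- function(gr, what = "peaks") {
  if (!methods::is(gr, "GRanges")) {
    stop(sprintf("%s must be a GRanges", what))
  }
  mc <- S4Vectors::mcols(gr)
  if (!all(c("summit", "score") %in% colnames(mc))) {
    stop(sprintf("%s must carry 'summit' and 'score' metadata columns", what))
  }
  if (length(gr) > 0) {
    bad <- mc$summit < GenomicRanges::start(gr) |
      mc$summit > GenomicRanges::end(gr)
    if (any(bad)) stop(sprintf("%s: summit outside its peak", what))
    if (any(mc$score < 0)) stop(sprintf("%s: negative score", what))
  }
  invisible(gr)
}

#' Construct a peak GRanges
#'
#' Convenience constructor for the peak representation used throughout the
#' pipeline: a `GRanges` with `summit` (1-based absolute position) and
#' `score` metadata columns.
#'
#' @param chrom,start,end Interval coordinates (1-based, closed, as in
#'   `GRanges`).
#' @param summit Absolute summit position within each interval; defaults to
#'   the interval midpoint.
#' @param score Non-negative signal value; default 0.
#' @return A `GRanges` with `summit` and `score` metadata columns.
#' @export
peaks <- function(chrom, start, end, summit = NULL, score = 0) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  if (is.null(summit)) {
    summit <- (GenomicRanges::start(gr) + GenomicRanges::end(gr)) %/% 2L
  }
  S4Vectors::mcols(gr)$summit <- as.integer(summit)
  S4Vectors::mcols(gr)$score <- rep_len(as.numeric(score), length(gr))
  .assert_peaks(gr)
  gr
}

## pick summit/score for each target region from the highest-scoring
## overlapping source peak; summit clamped into the region
.inherit_summits <- function(regions, source) {
  n <- length(regions)
  summit <- (GenomicRanges::start(regions) + GenomicRanges::end(regions)) %/% 2L
  score <- rep(0, n)
  if (length(source) > 0 && n > 0) {
    hits <- GenomicRanges::findOverlaps(regions, source)
    if (length(hits) > 0) {
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      sc <- S4Vectors::mcols(source)$score[sh]
      ord <- order(qh, -sc)
      keep <- !duplicated(qh[ord])
      qi <- qh[ord][keep]
      si <- sh[ord][keep]
      summit[qi] <- pmin(
        pmax(S4Vectors::mcols(source)$summit[si],
             GenomicRanges::start(regions)[qi]),
        GenomicRanges::end(regions)[qi])
      score[qi] <- S4Vectors::mcols(source)$score[si]
    }
  }
  S4Vectors::mcols(regions)$summit <- as.integer(summit)
  S4Vectors::mcols(regions)$score <- score
  regions
}

#' Replicate-reproducible peaks
#'
#' Retains the genomic regions covered by peaks in at least `min_reps` of
#' the supplied replicate peak sets (overlap means >= 1 shared base) and
#' merges them. Each merged region inherits the summit and score of the
#' highest-scoring contributing replicate peak (summit clamped into the
#' merged region if that peak extends beyond it).
#'
#' @param replicate_peaksets List of peak `GRanges` (see [peaks()]), one per
#'   replicate.
#' @param min_reps Minimum number of replicates that must cover a base.
#' @return A merged, sorted peak `GRanges`.
#' @export
reproducible_peaks <- function(replicate_peaksets, min_reps) {
  if (!is.list(replicate_peaksets) || length(replicate_peaksets) == 0) {
    stop("reproducible_peaks: need a non-empty list of replicate peak sets")
  }
  lapply(replicate_peaksets, .assert_peaks)
  if (min_reps < 1 || min_reps > length(replicate_peaksets)) {
    stop("reproducible_peaks: min_reps must be in 1..number of replicates")
  }
  ## common coordinate frame: every chromosome seen, at its max extent
  all_chr <- unique(unlist(lapply(replicate_peaksets, function(g) {
    as.character(unique(GenomeInfoDb::seqnames(g)))
  })))
  if (length(all_chr) == 0 ||
      all(vapply(replicate_peaksets, length, integer(1)) == 0)) {
    return(peaks(character(), integer(), integer()))
  }
  widths <- stats::setNames(rep(0L, length(all_chr)), all_chr)
  for (g in replicate_peaksets) {
    if (length(g) == 0) next
    mx <- tapply(GenomicRanges::end(g),
                 as.character(GenomeInfoDb::seqnames(g)), max)
    widths[names(mx)] <- pmax(widths[names(mx)], as.integer(mx))
  }
  ## per-base replicate support: each replicate contributes depth <= 1
  support <- NULL
  for (g in replicate_peaksets) {
    g <- GenomicRanges::reduce(GenomicRanges::granges(g))
    GenomeInfoDb::seqlevels(g) <- all_chr
    cv <- GenomicRanges::coverage(g, width = widths)[all_chr]
    support <- if (is.null(support)) cv else support + cv
  }
  kept <- IRanges::slice(support, lower = min_reps, rangesOnly = TRUE)
  merged <- GenomicRanges::reduce(GenomicRanges::GRanges(kept))
  merged <- GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(merged))
  all_peaks <- suppressWarnings(do.call(c, unname(replicate_peaksets)))
  .inherit_summits(merged, all_peaks)
}

#' Active enhancers from two histone marks
#'
#' Defines active enhancers as the regions carrying reproducible peaks for
#' both marks in all replicates: the base-level intersection of
#' `reproducible_peaks(mark, all replicates)` for H3K27ac and H3K4me1,
#' merged and sorted. Each enhancer inherits its summit from the
#' highest-scoring reproducible peak of `summit_from` (default H3K27ac,
#' since that is the signal later counted around summits).
#'
#' @param h3k27ac_reps,h3k4me1_reps Lists of replicate peak `GRanges` for
#'   the two marks.
#' @param summit_from Which mark donates the summit: `"h3k27ac"` (default)
#'   or `"h3k4me1"`.
#' @return A peak `GRanges` of enhancers (summit + score metadata).
#' @export
define_active_enhancers <- function(h3k27ac_reps, h3k4me1_reps,
                                    summit_from = c("h3k27ac", "h3k4me1")) {
  summit_from <- match.arg(summit_from)
  rep_ac <- reproducible_peaks(h3k27ac_reps, length(h3k27ac_reps))
  rep_me <- reproducible_peaks(h3k4me1_reps, length(h3k4me1_reps))
  enh <- GenomicRanges::reduce(suppressWarnings(
    GenomicRanges::intersect(rep_ac, rep_me, ignore.strand = TRUE)))
  enh <- GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(enh))
  src <- if (summit_from == "h3k27ac") rep_ac else rep_me
  .inherit_summits(enh, src)
}

#' Summit-centered counting windows
#'
#' Builds the +/- `flank` bp window around each enhancer summit: in 0-based
#' half-open terms `[summit - flank, summit + flank)`, clipped at the
#' chromosome start, so each window spans `2 * flank` bases unless clipped.
#'
#' @param enhancers A peak `GRanges` with a `summit` column.
#' @param flank Half-width in bp (> 0). Default 200.
#' @return A `GRanges` of windows (metadata dropped).
#' @export
summit_windows <- function(enhancers, flank = 200) {
  .assert_peaks(enhancers, "enhancers")
  if (!is.finite(flank) || flank <= 0) {
    stop("summit_windows: flank must be > 0")
  }
  s0 <- S4Vectors::mcols(enhancers)$summit - 1L  # 0-based summit
  start0 <- pmax(s0 - as.integer(flank), 0L)
  end0 <- s0 + as.integer(flank)
  GenomicRanges::GRanges(GenomeInfoDb::seqnames(enhancers),
                         IRanges::IRanges(start0 + 1L, end0))
}

#' Fragment counts over windows
#'
#' Counts, per sample, the fragments overlapping each window by >= 1 base.
#' A fragment overlapping several windows contributes to each of them.
#'
#' @param windows `GRanges` of counting windows (e.g. [summit_windows()]).
#' @param fragments Named list of `GRanges`, one per sample.
#' @param samples Optional data.frame with columns `name`, `condition`,
#'   `replicate` describing the samples (rows aligned with `fragments`).
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts` (regions x samples), `rowRanges = windows` and the sample
#'   table as `colData`.
#' @export
count_fragments <- function(windows, fragments, samples = NULL) {
  if (!methods::is(windows, "GRanges")) {
    stop("count_fragments: windows must be a GRanges")
  }
  if (!is.list(fragments) || length(fragments) == 0) {
    stop("count_fragments: fragments must be a non-empty list of GRanges")
  }
  counts <- vapply(fragments, function(fr) {
    GenomicRanges::countOverlaps(windows, fr, ignore.strand = TRUE)
  }, integer(length(windows)))
  counts <- matrix(as.integer(counts), nrow = length(windows),
                   dimnames = list(NULL, names(fragments)))
  if (is.null(samples)) {
    nm <- names(fragments)
    if (is.null(nm)) nm <- paste0("sample", seq_along(fragments))
    samples <- S4Vectors::DataFrame(name = nm, condition = NA_character_,
                                    replicate = NA_integer_)
  }
  samples <- S4Vectors::DataFrame(samples)
  ## total fragments per sample, for library-size (CPM) normalization
  samples$lib_size <- vapply(fragments, length, integer(1))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowRanges = windows,
    colData = samples
  )
}

#' Fraction of enhancers per class overlapping TF co-bound regions
#'
#' Co-bound regions are the positions where all three reproducible TF peak
#' sets mutually overlap (three-way base-level intersection, merged). For
#' each accessibility class the percentage of its enhancers overlapping any
#' co-bound region by >= 1 base is reported; empty classes yield `NA`.
#'
#' @param enhancers Enhancer `GRanges` (one row per classified region).
#' @param classes Factor/character of classes aligned with `enhancers`
#'   (levels `opening`, `closing`, `non_changing`).
#' @param tf_peaksets List of exactly three reproducibility-filtered peak
#'   `GRanges`.
#' @return Named numeric vector of percentages, one entry per class level.
#' @export
cobound_overlap_fraction <- function(enhancers, classes, tf_peaksets) {
  if (length(tf_peaksets) != 3) {
    stop("cobound_overlap_fraction: exactly three TF peak sets required")
  }
  if (length(classes) != length(enhancers)) {
    stop("cobound_overlap_fraction: classes must align with enhancers")
  }
  red <- lapply(tf_peaksets, function(g) {
    GenomicRanges::reduce(methods::as(g, "GRanges"))
  })
  cobound <- GenomicRanges::reduce(suppressWarnings(
    GenomicRanges::intersect(
      GenomicRanges::intersect(red[[1]], red[[2]], ignore.strand = TRUE),
      red[[3]], ignore.strand = TRUE)))
  hit <- GenomicRanges::countOverlaps(enhancers, cobound,
                                      ignore.strand = TRUE) > 0
  lv <- if (is.factor(classes)) levels(classes) else
    c("opening", "closing", "non_changing")
  classes <- factor(as.character(classes), levels = lv)
  vapply(stats::setNames(lv, lv), function(cl) {
    idx <- which(classes == cl)
    if (length(idx) == 0) return(NA_real_)
    100 * mean(hit[idx])
  }, numeric(1))
}
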