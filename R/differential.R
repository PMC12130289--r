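#' Classify regions by differential accessibility
#'
#' Applies the standard significance thresholds to a differential table:
#' a region is `opening` if `log2FC > fc_thresh` and `padj < p_thresh`,
#' `closing` if `log2FC < -fc_thresh` and `padj < p_thresh`, otherwise
#' `non_changing`. Inequalities are strict. Regions with missing `log2FC`
#' or `padj` are classified `non_changing` and counted in the
#' `n_missing` attribute (with a warning).
#'
#' @param diff_table data.frame with numeric columns `log2FC` and `padj`
#'   (other columns are passed through).
#' @param fc_thresh Absolute log2 fold-change threshold. Default 1.
#' @param p_thresh Adjusted-p threshold. Default 0.01.
#' @return `diff_table` with an added factor column `class` (levels
#'   `opening`, `closing`, `non_changing`) and attribute `n_missing`.
#' @export
classify_regions <- function(diff_table, fc_thresh = 1, p_thresh = 0.01) {
  if (!all(c("log2FC", "padj") %in% names(diff_table))) {
    stop("classify_regions: diff_table needs 'log2FC' and 'padj' columns")
  }
  lfc <- diff_table$log2FC
  p <- diff_table$padj
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("classify_regions: padj must lie in [0, 1]")
  }
  miss <- !is.finite(lfc) | !is.finite(p)
  cls <- rep("non_changing", nrow(diff_table))
  sig <- !miss & p < p_thresh
  cls[sig & lfc > fc_thresh] <- "opening"
  cls[sig & lfc < -fc_thresh] <- "closing"
  if (any(miss)) {
    warning(sprintf("classify_regions: %d region(s) with missing values set to non_changing",
                    sum(miss)))
  }
  diff_table$class <- factor(cls,
                             levels = c("opening", "closing", "non_changing"))
  attr(diff_table, "n_missing") <- sum(miss)
  diff_table
}

#' Simple differential-accessibility stand-in
#'
#' A deliberately simple per-region differential test used for synthetic
#' end-to-end runs; real analyses should supply an externally produced
#' differential table (e.g. from a negative-binomial GLM framework).
#' Counts are library-size normalized to counts per million (CPM);
#' `log2FC` is `log2(mean CPM_cond2 + pc) - log2(mean CPM_cond1 + pc)`;
#' the p-value is a pooled-variance two-sample t-test on `log2(CPM + pc)`
#' across replicates, adjusted by Benjamini-Hochberg.
#'
#' @param se A `SummarizedExperiment` from [count_fragments()] with a
#'   `condition` column in its `colData`.
#' @param conditions Optional length-2 character giving the reference and
#'   contrast condition; defaults to the two unique values in order of
#'   appearance.
#' @param pseudocount Added inside the logs. Default 0.5.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `mean_cpm_1`, `mean_cpm_2`, `log2FC`, `p`, `padj`.
#' @export
simple_differential <- function(se, conditions = NULL, pseudocount = 0.5) {
  cd <- SummarizedExperiment::colData(se)
  if (!"condition" %in% colnames(cd)) {
    stop("simple_differential: colData needs a 'condition' column")
  }
  cond <- as.character(cd$condition)
  if (is.null(conditions)) conditions <- unique(cond)
  if (length(conditions) != 2) {
    stop("simple_differential: exactly two conditions required")
  }
  i1 <- which(cond == conditions[1])
  i2 <- which(cond == conditions[2])
  if (length(i1) < 2 || length(i2) < 2) {
    stop("simple_differential: need >= 2 replicates per condition")
  }
  counts <- SummarizedExperiment::assay(se, "counts")
  ## library size: total fragments per sample when recorded by
  ## count_fragments(), otherwise the in-matrix column sums
  libsize <- if ("lib_size" %in% colnames(cd)) cd$lib_size else
    colSums(counts)
  libsize[libsize == 0] <- 1
  cpm <- sweep(counts, 2, libsize, "/") * 1e6
  lg <- log2(cpm + pseudocount)
  m1 <- rowMeans(cpm[, i1, drop = FALSE])
  m2 <- rowMeans(cpm[, i2, drop = FALSE])
  pvals <- vapply(seq_len(nrow(lg)), function(i) {
    a <- lg[i, i1]
    b <- lg[i, i2]
    if (stats::sd(c(a, b)) == 0) return(1)
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      ## zero within-group variance but different means: infinite t
      return(0)
    }
    stats::t.test(a, b, var.equal = TRUE)$p.value
  }, numeric(1))
  rr <- SummarizedExperiment::rowRanges(se)
  data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    start = GenomicRanges::start(rr) - 1L,
    end = GenomicRanges::end(rr),
    mean_cpm_1 = m1, mean_cpm_2 = m2,
    log2FC = log2(m2 + pseudocount) - log2(m1 + pseudocount),
    p = pvals,
    padj = stats::p.adjust(pvals, method = "BH"),
    row.names = NULL
  )
}
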