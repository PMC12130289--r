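## Readers/writers for the plain-text formats the pipeline consumes.
## Files follow BED conventions (0-based half-open); in memory everything
## is a GRanges (1-based closed). Output ordering is deterministic:
## natural-aware chromosome order, then start, then end.

.read_lines_table <- function(path, min_cols, what) {
  if (!file.exists(path)) stop(sprintf("%s: file not found: %s", what, path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) return(NULL)
  fields <- strsplit(lines, "[ \t]+")
  ncol <- lengths(fields)
  bad <- which(ncol < min_cols)
  if (length(bad) > 0) {
    stop(sprintf("%s:%d: expected >= %d columns, found %d",
                 path, bad[1], min_cols, ncol[bad[1]]))
  }
  fields
}

.check_coords <- function(start0, end0, path) {
  bad <- which(is.na(start0) | is.na(end0) | start0 < 0 | start0 >= end0)
  if (length(bad) > 0) {
    stop(sprintf("%s:%d: invalid interval (start %s, end %s)",
                 path, bad[1], start0[bad[1]], end0[bad[1]]))
  }
}

#' Read a BED3/BED6 file of intervals
#'
#' @param path Path to a BED file (0-based half-open). Comment, `track` and
#'   `browser` lines are skipped. Malformed lines raise an error naming
#'   `file:line`.
#' @return A sorted `GRanges`; columns 4-5 become `name`/`score` when
#'   present.
#' @export
read_bed <- function(path) {
  fields <- .read_lines_table(path, 3, "read_bed")
  if (is.null(fields)) return(GenomicRanges::GRanges())
  chrom <- vapply(fields, `[`, character(1), 1)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3)))
  .check_coords(start0, end0, path)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0))
  if (all(lengths(fields) >= 4)) {
    S4Vectors::mcols(gr)$name <- vapply(fields, `[`, character(1), 4)
  }
  if (all(lengths(fields) >= 5)) {
    S4Vectors::mcols(gr)$score <-
      suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 5)))
  }
  GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(gr))
}

#' Read a narrowPeak-dialect peak file
#'
#' Expects the 10-column ENCODE narrowPeak layout: chrom, start, end, name,
#' score, strand, signalValue, pValue, qValue, summit offset from start.
#' A summit offset of -1 (no summit) falls back to the interval midpoint
#' with a warning.
#'
#' @param path Path to the file (0-based half-open coordinates).
#' @param score_col Column used as the peak score: 5 (`score`, default) or
#'   7 (`signalValue`).
#' @return A sorted peak `GRanges` with `summit` and `score` columns.
#' @export
read_narrowpeak <- function(path, score_col = 5) {
  if (!score_col %in% c(5, 7)) {
    stop("read_narrowpeak: score_col must be 5 or 7")
  }
  fields <- .read_lines_table(path, 10, "read_narrowpeak")
  if (is.null(fields)) return(peaks(character(), integer(), integer()))
  chrom <- vapply(fields, `[`, character(1), 1)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3)))
  .check_coords(start0, end0, path)
  score <- suppressWarnings(
    as.numeric(vapply(fields, `[`, character(1), score_col)))
  offset <- suppressWarnings(
    as.integer(vapply(fields, `[`, character(1), 10)))
  bad <- which(is.na(offset) | (offset != -1 & (offset < 0 | offset >= end0 - start0)))
  if (length(bad) > 0) {
    stop(sprintf("%s:%d: summit offset %s outside peak",
                 path, bad[1], offset[bad[1]]))
  }
  no_summit <- offset == -1
  if (any(no_summit)) {
    warning(sprintf("read_narrowpeak: %d peak(s) without summit; using midpoints",
                    sum(no_summit)))
    offset[no_summit] <- as.integer((end0 - start0)[no_summit] %/% 2)
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0))
  S4Vectors::mcols(gr)$summit <- as.integer(start0 + offset + 1)
  S4Vectors::mcols(gr)$score <- score
  gr <- GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(gr))
  .assert_peaks(gr)
  gr
}

#' Write intervals as BED
#'
#' @param gr A `GRanges`; a `name` column becomes BED column 4 (`class`
#'   labels can be passed this way), a `score` column BED column 5.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  gr <- GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(gr))
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  mc <- S4Vectors::mcols(gr)
  if ("name" %in% colnames(mc)) {
    df$name <- mc$name
    if ("score" %in% colnames(mc)) df$score <- mc$score
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write peaks as narrowPeak
#'
#' Inverse of [read_narrowpeak()]: summits are serialized as offsets from
#' the interval start.
#'
#' @param gr A peak `GRanges` (`summit`, `score` columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(gr, path) {
  .assert_peaks(gr)
  gr <- GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = start0,
                   end = GenomicRanges::end(gr),
                   name = sprintf("peak_%d", seq_along(gr)),
                   score = S4Vectors::mcols(gr)$score,
                   strand = ".",
                   signalValue = S4Vectors::mcols(gr)$score,
                   pValue = -1, qValue = -1,
                   summit = S4Vectors::mcols(gr)$summit - 1L - start0)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a count matrix as TSV
#'
#' Emits one row per region with its coordinates (0-based half-open), the
#' raw counts per sample and, optionally, `log2(CPM + 0.5)` columns
#' (suffix `.log2cpm`).
#'
#' @param se A `SummarizedExperiment` from [count_fragments()].
#' @param path Output path.
#' @param log2cpm Also emit log2(CPM + 0.5) columns. Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(se, path, log2cpm = TRUE) {
  rr <- SummarizedExperiment::rowRanges(se)
  counts <- SummarizedExperiment::assay(se, "counts")
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(rr)),
                   start = GenomicRanges::start(rr) - 1L,
                   end = GenomicRanges::end(rr))
  df <- cbind(df, as.data.frame(counts))
  if (log2cpm) {
    cd <- SummarizedExperiment::colData(se)
    lib <- if ("lib_size" %in% colnames(cd)) cd$lib_size else
      colSums(counts)
    lib[lib == 0] <- 1
    lg <- log2(sweep(counts, 2, lib, "/") * 1e6 + 0.5)
    colnames(lg) <- paste0(colnames(counts), ".log2cpm")
    df <- cbind(df, as.data.frame(lg))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a specificity surface as a matrix TSV
#'
#' First row and first column carry the grid values: cell (1,1) is the
#' literal `K_h\\K_s`, the remaining header row the `K_s` grid, the first
#' column the `K_h` grid.
#'
#' @param surface A [specificity_surface()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  m <- cbind(surface$kh_grid, surface$values)
  header <- c("K_h\\K_s", format(surface$ks_grid, trim = TRUE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  utils::write.table(m, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load a run/model configuration file
#'
#' Reads a flat YAML (or JSON, which YAML subsumes) key/value file and
#' validates it against the known keys; unknown keys are rejected so typos
#' fail loudly. Concentration parameters accept an optional `unit` key
#' (`nM`, the default, or `uM`).
#'
#' @param path Path to the YAML config.
#' @return Named list of validated parameters with class `run_config`.
#' @examples
#' cfg <- load_config(system.file("extdata", "params_default.yaml",
#'                                package = "chromspec"))
#' config_to_system(cfg)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("load_config: config must be a key/value mapping")
  known <- c("T_total", "H_total", "Ns_total", "Nu_total",
             "K_s", "K_u", "K_h", "hill_n", "unit",
             "fc_thresh", "p_thresh", "flank", "min_reps",
             "pseudocount", "seed", "out_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("load_config: unknown key(s): ", paste(unknown, collapse = ", "))
  }
  num_keys <- setdiff(intersect(names(cfg), known), c("unit", "out_dir"))
  for (k in num_keys) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 ||
        !is.finite(cfg[[k]])) {
      stop(sprintf("load_config: key '%s' must be a single finite number", k))
    }
  }
  if (!is.null(cfg$unit) && !cfg$unit %in% c("nM", "uM")) {
    stop("load_config: unit must be 'nM' or 'uM'")
  }
  if (!is.null(cfg$p_thresh) && (cfg$p_thresh <= 0 || cfg$p_thresh > 1)) {
    stop("load_config: p_thresh must lie in (0, 1]")
  }
  if (!is.null(cfg$flank) && cfg$flank <= 0) {
    stop("load_config: flank must be > 0")
  }
  class(cfg) <- "run_config"
  cfg
}

#' Build a binding system from a config
#'
#' @param cfg A [load_config()] result (model keys optional; defaults fill
#'   the gaps).
#' @return A [binding_system()].
#' @export
config_to_system <- function(cfg) {
  args <- cfg[intersect(names(cfg),
                        c("T_total", "H_total", "Ns_total", "Nu_total",
                          "K_s", "K_u", "K_h", "hill_n", "unit"))]
  do.call(binding_system, args)
}
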