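## Independent oracles: written directly from the model/operation
## definitions, sharing no code with the implementation they check.

## --- equilibrium: 2-D nested bisection on the raw conservation balances ---
oracle_solve <- function(sys, iters = 120) {
  n <- sys$hill_n
  stoich <- sys$tf_per_site
  bal_T <- function(Tf, Hf) {
    x <- Tf / sys$K_s; y <- Tf / sys$K_u; h <- Hf / sys$K_h
    Tf + stoich * sys$Ns_total * x^n / (1 + x^n + h) +
      sys$Nu_total * y / (1 + y + h) - sys$T_total
  }
  bal_H <- function(Tf, Hf) {
    x <- Tf / sys$K_s; y <- Tf / sys$K_u; h <- Hf / sys$K_h
    Hf + sys$Ns_total * h / (1 + x^n + h) +
      sys$Nu_total * h / (1 + y + h) - sys$H_total
  }
  bisect <- function(f, lo, hi) {
    for (i in seq_len(iters)) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  tf_at <- function(Hf) {
    if (sys$T_total == 0) return(0)
    bisect(function(Tf) bal_T(Tf, Hf), 0, sys$T_total)
  }
  Hf <- if (sys$H_total == 0) 0 else
    bisect(function(Hf) bal_H(tf_at(Hf), Hf), 0, sys$H_total)
  c(T_f = tf_at(Hf), H_f = Hf)
}

## closed-form single-site 1:1 binding (hill_n = 1, no histones, no
## unspecific sites): positive root of Tf^2 + (Ks + Ns - T) Tf - Ks T = 0
oracle_quadratic_Tf <- function(T_total, Ns_total, K_s) {
  b <- K_s + Ns_total - T_total
  (-b + sqrt(b^2 + 4 * K_s * T_total)) / 2
}

## --- per-base interval oracles on a toy chromosome of length L ---
mask_of <- function(gr, L) {
  m <- logical(L)
  st <- GenomicRanges::start(gr)
  en <- pmin(GenomicRanges::end(gr), L)
  for (i in seq_along(gr)) m[st[i]:en[i]] <- TRUE
  m
}

mask_to_df <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

oracle_reproducible <- function(peaksets, min_reps, L) {
  depth <- Reduce(`+`, lapply(peaksets, function(g) as.integer(mask_of(g, L))))
  mask_to_df(depth >= min_reps)
}

oracle_enhancers <- function(ac_sets, me_sets, L) {
  ac <- oracle_reproducible(ac_sets, length(ac_sets), L)
  me <- oracle_reproducible(me_sets, length(me_sets), L)
  to_mask <- function(df) {
    m <- logical(L)
    for (i in seq_len(nrow(df))) m[df$start[i]:df$end[i]] <- TRUE
    m
  }
  mask_to_df(to_mask(ac) & to_mask(me))
}

oracle_counts <- function(windows, frags) {
  ws <- GenomicRanges::start(windows); we <- GenomicRanges::end(windows)
  fs <- GenomicRanges::start(frags); fe <- GenomicRanges::end(frags)
  wc <- as.character(GenomeInfoDb::seqnames(windows))
  fc <- as.character(GenomeInfoDb::seqnames(frags))
  vapply(seq_along(windows), function(i) {
    sum(fc == wc[i] & fs <= we[i] & fe >= ws[i])
  }, integer(1))
}

oracle_cobound_hits <- function(enh, tf_sets, L) {
  m <- Reduce(`&`, lapply(tf_sets, function(g) mask_of(g, L)))
  vapply(seq_along(enh), function(i) {
    any(m[GenomicRanges::start(enh)[i]:min(GenomicRanges::end(enh)[i], L)])
  }, logical(1))
}

## --- exact rank-sum p by brute-force enumeration over assignments ---
oracle_ranksum_p <- function(a, b) {
  n1 <- length(a); N <- n1 + length(b)
  pooled <- c(a, b)
  u_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(N, n1), 2, u_of)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

## --- random fixtures ---
rand_peakset <- function(n, L = 50000, chrom = "chrT",
                         wmin = 50, wmax = 1500) {
  if (n == 0) return(peaks(character(), integer(), integer()))
  start <- sample.int(L - wmax, n, replace = TRUE)
  w <- sample(wmin:wmax, n, replace = TRUE)
  end <- pmin(start + w - 1L, L)
  summit <- start + vapply(end - start, function(d) sample.int(d + 1L, 1L),
                           integer(1)) - 1L
  peaks(chrom, start, end, summit = summit,
        score = stats::runif(n, 0, 10))
}

rand_fragments <- function(n, L = 50000, chrom = "chrT") {
  start <- sample.int(L - 300, n, replace = TRUE)
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start, width = sample(50:300, n,
                                                                replace = TRUE)))
}

df_from_granges <- function(gr) {
  data.frame(start = GenomicRanges::start(gr), end = GenomicRanges::end(gr))
}
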