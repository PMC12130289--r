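---
title: "Methods: TF-nucleosome competition and enhancer dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TF-nucleosome competition and enhancer dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromspec)
```

## The competition model

Pluripotency transcription factors such as SOX2 occupy a small set of
functional enhancer sites while facing two competitors for the genome: a
vast excess of unspecific DNA sites, and histones, which can occlude any
site by nucleosome formation. `chromspec` models this as a three-way
equilibrium. A *specific* site can be free, occupied by a cooperative
TF complex, or occupied by a histone; with free concentrations $T_f$ and
$H_f$ the statistical weights are $1 : (T_f/K_s)^n : H_f/K_h$, so the
probability that an enhancer site is productively bound — which we call
the **specificity** — is

$$ S \;=\; \frac{(T_f/K_s)^n}{1 + (T_f/K_s)^n + H_f/K_h}, $$

with Hill coefficient $n = 2$ by default (cooperative pairing of TF
molecules at the specific site). Unspecific sites follow the same scheme
with $n = 1$ and a tenfold weaker constant, $K_u = 10\,K_s$.

### Parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `T_total` | 100 | nM | total TF (0.1 µM) |
| `H_total` | 10000 | nM | total competent histone (10 µM) |
| `Ns_total` | 10 | nM | specific (enhancer) sites (0.01 µM) |
| `Nu_total` | 10000 | nM | unspecific sites (10 µM) |
| `K_s`, `K_h` | 1–100 (default point 10) | nM | TF-specific-site and histone dissociation constants |
| `K_u` | `10 * K_s` | nM | TF-unspecific-site dissociation constant |
| `hill_n` | 2 | — | cooperativity of specific binding |

All quantities are held in nM internally; µM inputs are converted at the
constructor boundary (`unit = "uM"`), since the interesting sweeps of
`K_s` and `K_h` live on the 1–100 nM scale.

### Mass conservation and the solver

$T_f$ and $H_f$ are fixed by mass conservation: free plus bound TF mass
must equal `T_total`, and likewise for histones, where the bound amounts
follow from the site occupancy fractions. Although the underlying system
has four unknown free concentrations (TF, histone, specific and
unspecific free sites), under the isotherm formulation the free-site
concentrations are determined by $(T_f, H_f)$, so
`solve_equilibrium()` works on a two-dimensional residual system and
reconstructs `Ns_f`, `Nu_f` afterwards — the same fixed point with far
better conditioning.

Two bookkeeping choices deserve note:

* **Stoichiometry of the cooperative complex.** The Hill-2 site is
  modeled as a concerted two-TF complex, so an occupied specific site
  consumes `hill_n` TF molecules in the mass balance. This is a modeling
  convention, not an observable of the isotherm itself;
  `binding_system(tf_per_site = 1)` switches to single-molecule
  bookkeeping. At the default parameters the difference is small because
  specific sites hold at most 20 nM of the 100 nM TF pool.
* **Histone stoichiometry.** One histone particle occupies one site with
  the same `K_h` at specific and unspecific sites, since a single
  histone constant governs both in the model.

The solver is a damped Newton iteration on $(\log T_f, \log H_f)$ —
positivity by construction — with a finite-difference Jacobian, step
halving whenever the residual norm fails to decrease, and a
nested-bisection fallback that is guaranteed to converge because each
scaled residual is monotone in its own variable with opposite signs at
the box edges. Convergence demands
$\max(|r_T|, |r_H|) < 10^{-12}$ (residuals scaled by the totals).
Degenerate inputs (no sites, or a zero TF/histone total) are resolved
exactly rather than iteratively. Totals are allowed to be zero —
limiting systems are legitimate and well-defined — while dissociation
constants must be strictly positive.

### The affinity landscape

`specificity_surface()` re-solves the equilibrium on a grid of
$(K_s, K_h)$ values, by default 50×50 log-spaced points spanning
1–100 nM (the biologically motivated range for both constants), with
`K_u = 10 K_s` re-derived at each point. The landscape is reported on
the natural $[0, 1]$ specificity scale. Its headline feature is
synergy: strengthening TF-DNA affinity alone (low $K_s$) mostly fills
unspecific sites, and strengthening histone-DNA affinity alone (low
$K_h$) occludes enhancers too; lowering both together raises enhancer
occupancy far more than the sum of the single-axis gains, because
histones suppress the unspecific TF sink while cooperativity lets the
specific sites out-compete the histones locally.

### Kinetic verification

The algebraic fixed point is independently checked by dynamics.
`build_scheme()` maps a system onto elementary mass-action reactions
whose off/on ratios reproduce the equilibrium constants exactly
($K_s^n$ for the concerted complex); `integrate_to_steady_state()`
integrates them with a stiff-capable solver (`deSolve::lsoda`) from the
all-free state, doubling the horizon until all normalized derivatives
fall below tolerance — deterministic and basin-independent since the
equilibrium is unique. The concerted two-TF step mirrors the Hill-2
algebra exactly; a sequential variant with a sparsely populated
intermediate ($K_1 = 10 K_s$, $K_2 = K_s/10$, $K_1 K_2 = K_s^2$) is
available behind `sequential = TRUE` for sensitivity analysis.
`ssa_occupancy()` adds a Gillespie sampler at finite copy numbers
(`volume` copies per nM) whose time-averaged occupancies approach the
deterministic values as the volume grows; equilibration from the
all-free state needs a number of events proportional to the total copy
number, which is why the bundled checks use deliberately small systems.

## The enhancer pipeline

The pipeline mirrors a standard CUT&Tag/ATAC analysis downstream of peak
calling. Coordinates follow the BED convention on disk (0-based
half-open) and live as `GRanges` in memory (1-based closed); summits are
stored as absolute positions and serialized as narrowPeak offsets.

* **Reproducible peaks** (`reproducible_peaks()`): bases covered by
  peaks in at least `min_reps` replicates, merged; each merged region
  inherits summit and score from its highest-scoring contributing peak
  (clamped into the region if the contributor extends beyond it).
  Overlap means ≥ 1 shared base throughout the package.
* **Active enhancers** (`define_active_enhancers()`): the base-level
  intersection of the all-replicate reproducible peaks of H3K27ac and
  H3K4me1. The summit is inherited from the H3K27ac side by default
  because the signal subsequently counted around summits is the
  acetylation-linked accessibility signal; this is configurable.
* **Counting** (`summit_windows()`, `count_fragments()`): ± 200 bp
  windows around enhancer summits, clipped at the chromosome start;
  fragments count toward every window they overlap. Counts are returned
  as a `SummarizedExperiment` carrying each sample's *total* fragment
  count (`lib_size`) — CPM normalization uses these totals rather than
  in-matrix column sums, which would be composition-biased by the very
  signal under test.
* **Classification** (`classify_regions()`): opening iff
  `log2FC > 1` and `padj < 0.01`, closing for the mirrored condition,
  otherwise non-changing. Inequalities are strict, exactly as the
  thresholds are usually printed; missing values classify as
  non-changing with a warning counter.
* **Statistics** (`ranksum_test()`, `bonferroni()`): two-sided
  Mann–Whitney U with an exact small-sample path (exact null
  distribution when tie-free, permutation enumeration under ties) and a
  tie- and continuity-corrected normal approximation otherwise;
  Bonferroni multiplies by the number of comparisons actually declared
  in the run, mirroring per-figure corrections.
* **Co-binding** (`cobound_overlap_fraction()`): co-bound regions are
  the three-way mutual base-level intersection of the three TF peak
  sets (a shared common base, not merely pairwise overlaps — the
  stricter of the two readings, chosen because it is the one that is a
  single well-defined region set); per class, the percentage of
  enhancers touching any co-bound region, `NA` for empty classes.
* **Differential stand-in** (`simple_differential()`): CPM
  normalization, fold change on mean CPM, pooled-variance t-test on
  `log2(CPM + 0.5)` across replicates, Benjamini–Hochberg adjustment.
  This is deliberately *not* a negative-binomial GLM: it exists so that
  synthetic end-to-end runs are self-contained, and real analyses
  should feed an externally produced differential table into
  `classify_regions()` instead.

## The synthetic-data generator

`synthetic_config()` fixes the study conditions: a 10 Mb interval-level
genome on two chromosomes (no nucleotide sequence is generated — no
stage needs one); 40 opening, 40 closing and 120 stable enhancers of
500 bp with ≥ 1 kb spacing (stable regions in the majority, as in real
enhancer landscapes); planted |log2FC| of 2; negative-binomial counts
with dispersion 0.1 (variance $\mu + 0.1\mu^2$, replicate-to-replicate
variability typical of bulk chromatin assays) around a baseline of 200
fragments per region; 200,000 fragments per sample and 3 replicates per
condition; per-replicate peak-call sensitivity 0.9 with 5 spurious
peaks/Mb; and three-TF co-binding probabilities of 0.6 / 0.1 / 0.2 for
opening / closing / stable enhancers. Fragment lengths are N(150, 20)
truncated at 50 bp and centers scatter around the true summit with
Laplace jitter of scale 50 bp. Every generator is deterministic under
the configured seed (per-sample streams are derived from it), and the
baseline of 200 was chosen so that window counts sit far above the
Poisson-noise floor — at that depth the NB dispersion term dominates the
variance.

What the generator does *not* emulate: mappability and GC bias,
copy-number structure, fragment-length differences between conditions,
correlated replicates, and peak-width variation at true regions.
Passing end-to-end tests therefore demonstrate the pipeline's logic and
statistics, not robustness to those artefacts.

### What the defaults imply for recovery

Two consequences of these conditions are worth stating plainly, because
the test suite measures them honestly rather than hiding them. First,
requiring peaks in *all* replicates of both marks retains
$0.9^6 \approx 53\%$ of planted regions as active enhancers; the
remainder never reach the classifier. Second, with NB dispersion 0.1
the per-replicate standard deviation of log2 counts has a floor of
$\sqrt{0.1}/\ln 2 \approx 0.46$, so a 3-vs-3 per-region t-test on a
log2FC of 2 has noncentral-$t$ power of only ~0.68 at raw
$p < 0.01$ — and far less at the BH-adjusted threshold. Under these
study conditions the classifier therefore recovers only a small
fraction of planted opening/closing enhancers at `padj < 0.01`; the
estimates themselves are unbiased (median planted-class log2FC ≈ ±2),
and the co-binding enrichment of opening enhancers is detected
robustly. Recovering most planted regions at these thresholds would
require either ~6 replicates per condition, dispersion an order of
magnitude lower, or a variance-moderated differential model — all
outside these fixed conditions.

## Numerical choices

* Solver tolerance $10^{-12}$ on scaled residuals; the bisection oracle
  used in the tests runs 120 halvings per axis and shares no code with
  the solver. The histone-free limit is exercised at
  $K_h = 10^{14}$ nM, where the residual histone term
  ($H_f/K_h \sim 10^{-10}$) sits comfortably below the $10^{-9}$
  relative agreement demanded of the Hill-isotherm limit.
* ODE stationarity is declared when all derivatives, normalized by the
  largest total, fall below $10^{-10}$; agreement with the algebraic
  solve is then verified at $10^{-6}$ relative.
* Tie-breaks: when several contributing peaks share the top score, the
  first in sorted order donates the summit. Exact rank-sum two-sided
  p-values use twice the smaller tail, capped at 1, matching the
  convention of `wilcox.test`.
* Region classification treats threshold equality as non-significant
  (strict inequalities), so `log2FC = 1` is non-changing by definition.
* Problem sizes in the bundled checks (100-system solver panels,
  20 interval-oracle configurations on ≤ 100 kb toy chromosomes, 1000
  null simulations for rank-sum calibration, one full-default synthetic
  end-to-end run) were chosen as the smallest sizes at which the
  distributional claims are sharp.

## Known limitations

* The equilibrium model has a single histone constant and no nucleosome
  positioning, remodeling kinetics, or sequence-specific binding
  energies; it is a mean-field competition picture.
* Whether 10 µM "total histone" means competent free histone or total
  incorporated histone cannot be resolved from concentration estimates
  alone; the model treats it as the competent pool.
* The Gillespie sampler covers `hill_n ≤ 2` (the concerted scheme) and
  its batch-means standard errors assume batches longer than the
  slowest autocorrelation time; use larger event counts for small
  volumes if in doubt.
* The differential stand-in is intentionally underpowered relative to
  moderated NB models; see above.
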