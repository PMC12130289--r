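# chromspec

Pluripotency transcription factors such as SOX2 must find a handful of
functional enhancer sites in a genome that offers a vast excess of
unspecific binding sites — all while histones compete for the same DNA.
`chromspec` is an R package for people studying this problem
quantitatively in chromatin biology. It provides two connected toolkits:

1. **An equilibrium competition model of binding specificity.** A TF
   binds its specific (enhancer) sites cooperatively with Hill
   coefficient *n* while competing with histones at both specific and
   unspecific sites. The probability that an enhancer site is
   productively TF-bound is

   *S* = (*T*<sub>f</sub>/*K*<sub>s</sub>)<sup>n</sup> / (1 + (*T*<sub>f</sub>/*K*<sub>s</sub>)<sup>n</sup> + *H*<sub>f</sub>/*K*<sub>h</sub>),

   with the free concentrations *T*<sub>f</sub>, *H*<sub>f</sub> fixed by
   mass conservation. The package solves this equilibrium (damped Newton
   with a guaranteed bisection fallback), sweeps the (*K*<sub>s</sub>,
   *K*<sub>h</sub>) affinity landscape, and verifies the fixed point
   independently through mass-action ODE integration and Gillespie
   simulation.

2. **An enhancer-dynamics pipeline** for CUT&Tag/ATAC-style data
   downstream of peak calling: replicate-reproducible peak filtering,
   active-enhancer definition (H3K27ac ∩ H3K4me1 in all replicates),
   ± 200 bp summit-window fragment counting, opening/closing
   classification (log2FC > 1, adjusted p < 0.01), Mann–Whitney rank-sum
   tests with Bonferroni correction, and three-TF co-binding overlap
   summaries — plus a seeded synthetic-data generator so the whole
   pipeline runs and is tested without any external data.

## Worked example

```r
library(chromspec)

sys <- binding_system(K_s = 10, K_h = 10)  # nM; totals default to
                                           # T = 100, H = 10000,
                                           # Ns = 10, Nu = 10000
st <- solve_equilibrium(sys)
st
#> equilibrium free concentrations (nM): T_f = 25.4606, H_f = 343.831
#>   Ns_f = 0.23886, Nu_f = 280.601
#>   residual = 1.833e-14, converged = TRUE (newton, 7 iterations)

specificity(st, sys)
#> [1] 0.155
```

Only 15.5% of enhancer sites are productively bound at mid-range
affinities: most free TF is soaked up by the unspecific sink and most
sites are histone-occluded. Strengthening both TF–DNA and histone–DNA
binding changes that dramatically:

```r
surf <- specificity_surface(sys, n_grid = 50)   # K_s, K_h in 1-100 nM
surf$values[1, 1]    # K_s = 1, K_h = 1: both affinities strong
#> [1] 0.477
surf$values[50, 50]  # K_s = 100, K_h = 100: both weak
#> [1] 0.024
```

The joint gain (0.477 − 0.024 ≈ 0.45) far exceeds the sum of the two
single-axis gains (≈ 0.06): tighter histone binding suppresses the
unspecific TF sink while cooperativity lets enhancers out-compete the
histones locally. The pipeline half of the package is demonstrated
end-to-end in the test suite and the methods vignette
(`vignettes/chromspec-methods.Rmd`), which also documents every model
assumption, default and numerical choice.

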