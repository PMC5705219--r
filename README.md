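# meiomap

Tools for building and interrogating direct binding maps of meiotic
zinc-finger proteins such as PRDM9, the protein that positions human and
mouse recombination hotspots. The package re-implements, as a tested and
reusable pipeline, the bespoke computations such a study needs:

* **Likelihood-based ChIP-seq peak calling.** At every base the two
  replicate fragment-coverage counts are modelled as
  x_s ~ Poisson(r_s · b · (1 + e)), where `b` is the local background
  estimated as a running window mean of the input (total chromatin)
  coverage — which absorbs regional coverage differences such as
  aneuploidy — and `r_s` is the replicate/input library-size ratio. The
  shared enrichment `e ≥ 0` has the closed-form MLE
  ê = max(0, Σx / (b·Σr) − 1); the one-sided test uses the χ²₁ boundary
  mixture (½δ₀ + ½χ²₁), and confidence intervals are profile-likelihood
  intervals at a deviance drop of 3.84. Enrichment is reported as
  signal/background − 1, floored at zero, at the base with the smallest
  p-value in each peak. Fixed intervals can be force-called, and single
  samples split into pseudo-replicates.
* **Bayesian mixture de novo motif discovery.** Peak-centered sequences
  are explained by a mixture of motifs over an order-1 Markov background:
  10-mer seeding by central over-representation, EM refinement with
  strand-aware posterior placement, flank extension, joint refinement of
  up to 20 motifs, force-scanning with frozen PWMs, and
  centrality/information-content filters. PWMs are read and written in
  MEME minimal format.
* **Chance-corrected overlap statistics.** For n query points and t
  target intervals of widths w on a genome of size g, the expected chance
  overlap is c = Σᵢ (1 − ((g − wᵢ)/g)ⁿ), and the corrected overlap
  fraction solves (1 − f/t) = (1 − o/t)(1 − c/t). A randomized-shift
  estimator covers interval-vs-interval comparisons.
* **Repeat-family cis-modifier association.** Repeat copies are aligned
  to their family consensus, scored for 7-mer presence, and tested by
  conditional logistic regression with greedy forward selection under
  Bonferroni control, additive DNA-based scoring, and a co-binding GLM
  reporting log2-odds effects of co-binding factors on hotspot odds.
* **Aggregate profiles** around anchor positions with enrichment-quartile
  stratification and `ksmooth`-convention kernel smoothing.
* **A synthetic-data generator with recorded truth** — planted PWM
  binding sites with three internal-spacing variants, Poisson fragment
  counts over ploidy blocks, a 354-bp repeat family carrying a planted
  binding motif and a 7-bp modifier that multiplies hotspot odds
  (default odds ratio 0.32) — so every stage is testable end to end
  without downloads.

## Worked example

Simulate a 1-Mb genome with 80 planted binding sites (one triploid
block), call peaks, and measure the chance-corrected overlap with the
planted truth:

```r
library(meiomap)

cfg <- sim_config(genome_length = 1e6, block_length = 2e5,
                  gc_blocks = c(0.4, 0.5, 0.45, 0.55, 0.42),
                  ploidy_blocks = c(1, 1, 3, 1, 1),
                  n_sites = 80, n_copies = 2000, seed = 7L)
sim  <- simulate_genome(cfg)
frag <- simulate_chip(sim$truth, cfg)

rep1  <- fragments_to_coverage(frag$rep1, sim$genome, "rep1")
rep2  <- fragments_to_coverage(frag$rep2, sim$genome, "rep2")
input <- fragments_to_coverage(frag$input, sim$genome, "input")
peaks <- call_peaks(rep1, rep2, input, alpha = 1e-6)
nrow(peaks)
#> [1] 47
head(as.data.frame(peaks)[, c("chrom", "center", "p", "e", "e_lo", "e_hi")], 3)
#>   chrom center            p         e      e_lo     e_hi
#> 1  chr1   1958 3.096657e-49 3.5232034 2.8330766 4.291577
#> 2  chr1  27098 1.569720e-50 3.7652590 3.0287322 4.586509
#> 3  chr1  52530 4.967271e-07 0.9874356 0.5362096 1.519397
```

47 of the 80 planted sites clear the genome-wide p < 10⁻⁶ threshold at
this depth (the rest are weakly occupied instances), with per-peak
enrichment `e` near the simulated enrichment scale λ·occupancy and
profile-likelihood CIs around it. The chance-corrected overlap with 1-kb
windows around the planted sites:

```r
targets <- interval_set(sim$truth$sites$chrom,
                        sim$truth$sites$center - 500,
                        sim$truth$sites$center + 500)
overlap_summary(peaks, targets, g = sim$genome$g)
#>    n  t  f        c   f_t        c_t       o_t valid
#> 1 47 80 46 3.674803 0.575 0.04593504 0.5545377  TRUE
```

46 of 80 truth windows contain a called peak center (f/t = 57.5%), of
which 4.6 percentage points are expected by chance; the corrected
overlap fraction o/t is 55.5%. Finally, the repeat-family association
recovers the planted hotspot modifier:

```r
fam <- simulate_repeat_family(cfg)
single_association(fam$copies$modifier_present, fam$copies$hotspot,
                   covariates = cbind(bound = fam$copies$bound),
                   kmer = cfg$modifier)[, c("kmer", "beta", "se", "p", "or")]
#>      kmer      beta        se            p       or
#> 1 ATCCATG -1.182446 0.1384696 6.086792e-20 0.306528
```

The estimated odds ratio 0.31 (log-OR −1.18 ± 0.14) matches the planted
OR of 0.32 (ln 0.32 = −1.139). `run_demo(dir)` chains all the stages —
simulate → callpeaks → findmotifs → overlap → repeatassoc → profile —
and writes every artifact plus an md5 manifest.

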