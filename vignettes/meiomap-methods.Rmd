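---
title: "Models and methods behind meiomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind meiomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

meiomap implements the computational core of a direct binding-map study
of a meiotic zinc-finger protein such as PRDM9: peak calling from
paired-end ChIP-seq fragment coverage against an input control, mixture
motif discovery in peak-centered sequences, chance-corrected overlap
statistics between genomic feature sets, and repeat-family k-mer
association for cis-modifiers of recombination. This vignette records
the models, their assumptions, the tunable parameters, and the design
choices made where the design was genuinely open. Everything here is
exercised by the test-suite on synthetic data with recorded truth; no
empirical claim in this document goes beyond what those tests compute.

## Coordinates and containers

All coordinates are 0-based half-open (the BED convention) everywhere
inside the package; only report text is ever 1-based. Coverage is stored
as dense per-base numeric vectors per sequence (`coverage_track`), which
keeps per-base addressability trivial at the genome sizes the package
targets (megabases in tests, tens of megabases comfortably). Fragment
ends beyond a sequence boundary are invalid; readers drop out-of-bounds
records with a counted warning and refuse malformed lines with the line
number.

## The peak-calling model

At a single base, the two replicate fragment-coverage counts are modelled
as independent Poisson draws

$$x_s \sim \mathrm{Poisson}\!\big(r_s\, b\, (1+e)\big), \qquad e \ge 0,$$

with `b` the local background rate on the input scale and
`r_s = N_s / N_{\mathrm{input}}` the library-size ratio. The shared
enrichment has closed-form MLE
$\hat e = \max\!\big(0, \sum_s x_s / (b \sum_s r_s) - 1\big)$, and the
likelihood-ratio statistic for $e > 0$ is
$\Lambda = 2\big[(\sum_s x_s)\log(1+\hat e) - b(\sum_s r_s)\hat e\big]$.
Because the null value sits on the boundary of the parameter space, the
p-value uses the mixture $\tfrac12\delta_0 + \tfrac12\chi^2_1$:
$p = \tfrac12 P(\chi^2_1 \ge \Lambda)$ for $\Lambda > 0$ and $p = 1$ at
$\hat e = 0$. Reported enrichment is therefore "estimated signal divided
by background, minus one, floored at zero", evaluated at the base with
the smallest p-value within each peak (leftmost on ties, for
determinism). Confidence intervals are profile-likelihood intervals at a
deviance drop of 3.84, truncated at zero.

Assumptions worth stating:

* **Local background.** `b` at base i is the plain mean input coverage
  in a window of width `W_bg` (default 10,000 bp, truncated at
  chromosome ends). A window mean is the simplest estimator that absorbs
  block-scale copy-number structure (aneuploidy) while ignoring
  base-scale noise; `W_bg` should sit well below the copy-number block
  scale and well above the fragment length. All-zero input sequences are
  floored at 0.5/`W_bg` with a warning.
* **Independence across bases is not assumed** for inference at one
  base, but neighbouring bases share fragments, so per-base p-values are
  correlated along the genome. Peak-level error rates are controlled by
  the stringent threshold (default α = 10⁻⁶) rather than by a
  multiple-testing argument.
* **Calibration is asymptotic in the expected counts.** The χ²
  approximation is accurate in the deep-coverage regime (around 100
  expected fragments per replicate per base and above); at low counts
  the discreteness of the Poisson makes the test conservative (the
  realized P(p < α) falls below α). The calibration test in the suite
  runs at per-replicate depth 100 for this reason.

Bases with p below the threshold are merged into peaks when separated by
gaps of at most 250 bp — below a typical fragment length, so adjacent
binding events remain distinct. Force-calling applies the same LRT to
window-summed counts for predefined intervals (default 1 kb); window
coverage mass is converted to approximate fragment counts by dividing by
the sample's mean insert size so the Poisson model stays on the
fragment-count scale, and results with at most 5 input fragments in the
window are flagged undefined. The pre-motif-discovery filter applies the
six stringent criteria (p < 10⁻¹⁰, enrichment > 2, enrichment-CI width
≤ 50, no repeat overlap, input count between the 10th and 90th
percentile, ≥ 30 combined replicate reads) and keeps the top 5,000 peaks
by enrichment. The CI-width criterion is interpreted in enrichment
units; the threshold is configurable.

## The motif mixture model

Each peak-centered sequence (default 300 bp) is explained by a
zero-or-one-occurrence mixture: with probability π₀ the whole sequence
is order-1 Markov background; with probability π_k one instance of motif
k sits at a uniformly chosen position and strand, its window emitted by
the PWM columns and everything else by the background. The background
model is fitted from all input sequences with add-one pseudocounts and
captures GC and dinucleotide skew; its order is a design choice — peak
sets from GC-rich genomes are badly served by an order-0 model.

Discovery proceeds exactly in the two printed stages. *Seeding*: count
all 10-mers on both strands (canonical form), take the 50 most frequent,
and seed from the word most over-represented in the central 100 bp
(observed central-start fraction over the uniform expectation
100/(L−9)); the seed PWM puts 0.7 on the seed base and 0.1 elsewhere.
The seed is refined alone for up to 100 EM iterations, sequences whose
posterior probability of containing the refined motif exceeds 0.5 are
removed, and the cycle repeats up to 20 times. *Joint refinement*: all
surviving motifs are refined together on the full, re-admitted sequence
set for up to 200 iterations. The M-step uses a Dirichlet pseudocount of
0.5 per column; motifs whose weight falls below 10⁻⁴ are dropped.
Every 10 iterations a one-column flank extension is accepted when the
candidate column carries more than 0.05 bits of expected information —
the package's mechanism for letting motifs grow beyond the 10-bp seed.
Iteration stops early once the observed-data log-likelihood gain falls
below 10⁻⁶ and a final extension check adds nothing; EM monotonicity at
that tolerance is asserted in the tests.

Three internal choices keep related motif variants (the same half-sites
at different internal spacings) from collapsing into one blurred PWM:

* During seeding rounds only the PWM columns are updated; the seed's
  mixture weight stays fixed at the joint-phase symmetric value
  0.9/(max_seeds + 1), and extension is off. A lone seed allowed to grow
  its weight and width on a mixed set absorbs every variant before the
  others can seed.
* Flank-extension evidence accumulates only from confident placements
  (posterior > 0.5), so ambiguous cross-variant matches cannot steer
  growth; when a round has at least 20 high-confidence (posterior > 0.9)
  matches, the round's motif is additionally specialized to full width
  on exactly those sequences.
* `discover_motifs(runs = n)` performs verification runs in which each
  round's seed is redrawn among words whose central ratio is at least
  80% of the maximum, and returns the run whose filtered model keeps the
  most motifs (ties broken by final log-likelihood). A single run is
  deterministic; which word wins the seeding rule can decide whether the
  first seed anchors a window shared between variants, and the multi-run
  consensus removes that sensitivity.

Post-hoc filters mirror the discovery contract: keep motifs with at
least 85% of match midpoints (posterior ≥ 0.75) inside the central
100 bp and mean information content of at least 0.5 bits/column over
their best 8-column window. Centrality enters only here — the position
prior during EM stays uniform. Force-scanning freezes the model, runs a
single E-step, and reports per sequence the best motif at posterior
≥ 0.75 with its placement and strand. On pure background the EM does
*not* drive a seeded motif's weight to zero — it converges to a
degenerate attractor that soaks up the best random window per sequence —
and it is the centrality/degeneracy filter stage that removes such
motifs; this is asserted in the tests and is the reason the filters
exist.

## Chance-corrected overlap

For n single-base query points placed uniformly on a genome of size g,
the expected number of the t target intervals (widths wᵢ) overlapped by
chance is $c = \sum_i \big(1 - ((g-w_i)/g)^n\big)$, evaluated with
`log1p` so that very large n is stable. Writing f for the observed
overlap count, independence of chance and systematic overlap gives
$(1 - f/t) = (1 - o/t)(1 - c/t)$, so the corrected overlap fraction is
$o/t = 1 - (1-f/t)/(1-c/t)$. The correction is only meaningful when
chance overlaps are fewer than observed overlaps; the return value
carries a validity flag for exactly that condition. For
interval-vs-interval comparisons the chance count is estimated by
randomly shifting one set uniformly in ±60,000 bp (one draw per interval
by default; a per-set mode is provided) and counting target intervals
hit by at least one shifted query. Shifted intervals leaving their
sequence are discarded for that replicate, which biases the estimator
downward when the shift range is comparable to the sequence length — use
shift ranges small relative to the genome. The genome size g defaults to
the sum of sequence lengths; on real genomes the caller should pass the
non-gap length, which is why the worked desk-scale computation takes g
as an explicit argument.

## Repeat-family association

Copies are aligned to the family consensus by global affine-gap
alignment (match +1, mismatch −1, a gap of length L costs 5 + L, via
Biostrings), giving each copy base a consensus coordinate; copies
shorter than half the consensus are excluded from positional reporting.
K-mer presence (default k = 7) is binary — at least one occurrence on
the consensus-oriented strand — and each retained k-mer is annotated
with the median consensus start of its occurrences.

Association uses logistic regression throughout. A single test fits
`outcome ~ presence (+ covariates)` by maximum likelihood and reports
the presence coefficient (the natural-log odds ratio), its Wald SE, and
a likelihood-ratio p-value; with no covariates this reproduces the
closed-form 2×2 log-OR and Woolf SE, which the tests assert to 10⁻³.
Complete separation is flagged and the point estimate replaced by a
Firth-penalized (Jeffreys prior) fit. Forward selection tests every
remaining k-mer conditional on those already selected plus any fixed
covariates, selects the minimum-p k-mer while its LRT p-value stays
below the Bonferroni threshold α/м (m counting only columns present in
at least one copy), and stops otherwise. For speed, rounds with many
candidates rank them by the Rao score test against the current model and
compute exact LRT refits for the 20 leaders only; reported p-values are
always LRTs. Unselected k-mers correlating above 0.9 with a selected
k-mer and overlapping it in consensus position are recorded as its
shadows. The additive DNA-based score per copy is the presence-weighted
sum of selected log-odds ratios, binned into deciles with per-bin
outcome frequencies; it is invariant to selection order. The co-binding
GLM fits each factor with at least 30 co-bound instances separately and
reports effects as log2-odds (natural-log estimates divided by ln 2)
with 95% Wald CIs.

## Profiles

`aggregate_profile` averages a track over windows centered on anchors,
mirroring minus-strand anchors when strands are present (anchors are
weighted equally; coverage weighting is deliberately not offered).
Quartile stratification uses the empirical 25/50/75 percentiles with
ties assigned to the lower quartile. Smoothing is Nadaraya–Watson via
`stats::ksmooth`, whose kernels are scaled so their quartiles sit at
±0.25·bandwidth — the convention under which bandwidths like 25 or
200 bp are quoted; note a box kernel therefore spans ±0.5·bandwidth.
Ratio profiles floor the denominator at 10⁻⁶ and can normalize to 1 at
the profile edges (mean over the outer 5% of offsets on each side).

## What the generator emulates — and what it does not

The synthetic-data module defines the study conditions under which
everything above is validated. Its defaults: a 5-Mb single-chromosome
genome built from an order-1 Markov background (a persistence-mixture
chain, sampled in vector time) with GC varying across 1-Mb blocks and
one triploid block emulating aneuploidy; 300 planted binding sites drawn
from truth PWMs with two half-sites and an internal spacer of 2, 5 or
6 bp (probabilities 0.5/0.3/0.2) on random strands; two ChIP replicates
at fragment-start depths 0.08 and 0.04 per base plus an input at 0.08,
fragment lengths Normal(250, 50) truncated to [50, 1000]; enrichment
scale λ = 4 acting on fragments whose midpoint falls within half a mean
fragment length of a site (this midpoint convention keeps the coverage
apex on the planted site); and a 354-bp repeat family of 3,000 copies
(10,000 in the association validation) mutated at rate μ = 0.03 with
rare 1-bp indels, carrying the binding motif in half the copies and the
modifier 7-mer ATCCATG (retained in 40% of copies) whose presence
multiplies hotspot odds by 0.32 on top of a baseline hotspot probability
of 0.15 and a bound-copy odds ratio of 5.

Site occupancy is `plogis(a·(score − b))` of the planted instance's PWM
log-odds score, with `b` anchored 6 log-units below the perfect-instance
score: perfect instances sit near 0.998 occupancy and one-mismatch
instances near 0.94, so a population of effectively fully occupied sites
exists for the recall analyses, alongside weaker instances. The spacer
columns of the truth PWMs carry a weak pyrimidine (T-leaning) preference
rather than uniform noise — matching the low-but-nonzero information of
the variably spaced region in real zinc-finger logos — because with
uniform spacers the spacing variants are information-theoretically
indistinguishable at sub-motif widths, and with a preference matching
the flanking half-sites' composition they blend into them. The modifier
regressor in the hotspot logistic is the *realized* presence of the
7-mer in the copy's final sequence, so association on the k-mer
presence column estimates ln(OR) without attenuation from chance
occurrences elsewhere in the copy.

The generator deliberately does not model read sequences, sequencing
error, mapping ambiguity, duplicate fragments, chromatin accessibility,
or the tail shape of real binding-strength distributions. Passing tests
therefore demonstrate correctness of the statistical machinery under a
known generative model, not robustness to alignment artifacts or
cell-type-specific chromatin structure.

## Problem sizes and numerical choices

The test-suite validates at these scales (chosen as the smallest that
make the statistical claims meaningful): type-I calibration on 10⁵
null bases at per-replicate depth 100; peak recall on the default 5-Mb
genome; motif recovery on 2,000 sequences of 300 bp with two planted
motifs and, separately, two spacing variants (three consensus runs);
exact-inference checks on ≤ 8-bp toys against brute-force enumeration to
10⁻⁹; the overlap expectation against 20,000-replicate Monte-Carlo
placement; odds-ratio CI coverage over 50 families of 10,000 copies; and
family-wise error over 200 null datasets of 1,000 copies × 500 k-mers.
The whole suite runs in a few minutes on one CPU.

Numerical conventions: EM log-likelihoods are compared at tolerance
10⁻⁶; posterior normalization uses log-sum-exp; profile-CI roots are
bracketed and solved to 10⁻⁸; background rates are floored at
0.5/`W_bg`; argmin/argmax ties resolve leftmost; all randomness flows
through explicit integer seeds, and equal seeds give byte-identical
outputs (the simulator consumes draws in a fixed documented order:
genome, then ChIP fragments, then the repeat family, at seed offsets
0/+1/+2).

## Known limitations

* The two-replicate shared-enrichment Poisson model ignores biological
  overdispersion between replicates; a strongly discordant replicate
  pair will inflate significance rather than flag heterogeneity.
* Per-base p-values are correlated within a fragment length; the peak
  count is controlled by the stringent α, not by FDR machinery.
* The motif model allows at most one occurrence per sequence; tandem or
  clustered sites are reported as the single best placement.
* The internal scanner targets peak-scale sequence sets; genome-wide
  scanning of billions of bases is out of scope.
* k-mers are tested at fixed length; variable-length extension of
  selected seeds (e.g. long co-binding motifs) is not implemented.
* The shift-based chance estimator is biased downward when shift ranges
  approach the sequence length, because out-of-bounds shifts are
  discarded rather than wrapped.
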