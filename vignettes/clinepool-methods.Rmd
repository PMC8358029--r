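---
title: "Models and methods behind clinepool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clinepool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

clinepool analyses pooled whole-genome sequencing data collected along a
fine-scale geographic gradient between two ecologically distinct habitats —
the motivating system is a parapatric lake–stream stickleback pair sampled at
11 sites over less than 2 km.  This vignette describes the statistical models
and the design choices behind each module, what the synthetic-data generator
does and does not emulate, and the known limitations.

## From nucleotide counts to SNPs

The pipeline's universal input is a count table: per site, chromosome and
position, the read counts of the four nucleotides.  SNP discovery mirrors
standard pool-seq practice: counts are summed within a lake discovery pool
(the two lake sites) and a stream discovery pool (the two most distant stream
sites); a position is retained iff its total depth lies within 50–400x in
*each* pool (excluding poorly covered and repetitive regions) and the minor
allele frequency — computed on the two most frequent nucleotides of the
combined pools — is at least 0.25.  Retained SNPs are genotyped in every
sample from the raw counts of the two SNP alleles; reads of a third
nucleotide are ignored and frequencies renormalized over the two alleles
(the paper base is silent on multi-allelic handling; this convention treats
every SNP as biallelic, which is how the downstream statistics are defined).
Depth filtering uses the total four-nucleotide depth; per-sample pairwise
profiles additionally require 50–200x in each of the two samples, and SNPs
failing the filter are *missing*, never imputed as zero.

Differentiation is quantified primarily by the absolute allele frequency
difference, AFD = |p1 − p2| for biallelic SNPs, which is more sensitive to
weak differentiation than Fst.  An Fst variant is provided as the
Nei/Hudson-style (Ht − Hs)/Ht on pool frequencies; the source analyses never
name an estimator, so this is a documented convention, returned as 0 when
Ht = 0.

## Marker panels

Three panels are ascertained from the endpoint (most-distant-pair) profile,
all restricted to autosomes:

* **selected** — SNPs with endpoint AFD ≥ 0.97.  Candidates closer than
  50 kb are chained into clusters by single linkage (any sub-threshold gap
  merges) and one member per cluster is drawn uniformly, giving statistical
  independence.
* **neutral** — SNPs whose AFD deviates from the genome-wide median by at
  most 0.001; **loDiff** — the same around half the median.  The "0.1%"
  tolerance is read as 0.001 in absolute AFD units (0.1 percentage point):
  a relative reading (~0.00035) would leave almost no candidates, and the
  quoted targets are printed to 2–3 decimals.  Both panels are drawn by
  greedy rejection sampling against the 50 kb spacing, because the source
  methods state only that the spacing was "again applied".

The stream allele at each SNP is the allele more frequent in the most
distant stream sample than in the most distant lake sample; exact ties are
broken toward the alphabetically first nucleotide and flagged.

## Geographic cline model

Site frequencies of the stream allele are fit to the classical hybrid-zone
cline: a central sigmoid `Phi(x) = (1 + tanh(2(x − c)/w))/2` on
`[c − delta_L, c + delta_R]`, with Szymura–Barton exponential tails outside
(tail slope ratio `tau` in [0, 1], continuity enforced by construction), and
`p(x) = pmin + (pmax − pmin) Phi(x)`.  The width `w` is the inverse maximum
slope of the scaled cline.  `pmin`/`pmax` are fixed at the observed extreme
frequencies — whether the original analysis estimated them is ambiguous;
fixing them is the conservative reading of "intervals set to the observed
maximum values".  A no-tail variant (`model = "none"`) is provided since
"models without tails produced qualitatively similar results".

The likelihood is binomial in the stream-allele read counts with predicted
frequencies clamped to `[1e-6, 1 − 1e-6]` so fixed sites keep a finite
log-likelihood (clamp configurable).  Optimization is multi-start
Nelder-Mead on a transformed scale (log width, log tail lengths, logit tail
ratios); the 10 "replicates" of the original MCMC-based fits become 10
random restarts, and the reported estimate is the element-wise median across
converged restarts.  One deviation from a literal median-across-replicates:
restarts more than 2 log-likelihood units below the best restart are
discarded first, because a stalled Nelder-Mead run is not a maximum
likelihood estimate; without this filter a single bad restart can drag the
median of six parameters in inconsistent directions.

The width-artifact experiment regenerates the same abrupt step at the
habitat transition scaled to different endpoint AFD levels (0.97 / 0.35 /
0.175 by default), adds two-stage pool-seq noise, and fits clines: fitted
widths and the spread of fitted centers and widths increase as the level
decreases, which is why wider fitted clines at weakly differentiated markers
must not be read as evidence of wider true clines.

## CCBD

Chromosome-center-biased differentiation summarizes how much differentiation
is elevated in low-recombination chromosome centers: with the outer 5 Mb per
chromosome end defined as high-recombination periphery, CCBD is the median
across chromosomes of (median central AFD)/(median peripheral AFD) — a
median of ratios, not a pooled ratio, so no chromosome dominates.
Chromosomes with an empty zone, no center (length ≤ 10 Mb), or a zero
peripheral median are dropped with a warning rather than contributing
infinite ratios.

## High-differentiation windows and the drift benchmark

Mean AFD is computed in 10 kb windows stepped by 5 kb (half-open intervals
on a fixed grid, ≥ 5 SNPs per window).  The within-lake window value is
subtracted from the lake-versus-first-stream-site value; the top 0.5% of
windows by this delta are the HDW, compared against an equal-size random
control set in the endpoint comparison via the difference in median AFD,
with percentile bootstrap CIs over windows.

The neutral benchmark is an individual-based haploid Wright–Fisher
population (default n = 200, g = 1000): two sets of 178 unlinked loci with
initial minor-allele frequencies uniform on [0.05, 0.5], the HDL set shifted
up by 0.1 (the observed HDW excess at ascertainment).  Offspring are drawn
with replacement; "swapping alleles between the haplotypes within pairs of
offspring" is implemented as: offspring paired consecutively, and at each
locus independently the pair swaps alleles with probability 1/2 — this
realizes free recombination among haploid lineages, and the suite verifies
the construction is distributionally identical to independent per-locus
binomial Wright–Fisher sampling (KS test) with the correct variance decay
`1 − (1 − 1/n)^g`.  Initial frequencies are realized exactly (rounded to
achievable counts) and AFD is measured against realized, not nominal,
frequencies.  Bootstrap is over replicates (simulated) versus windows
(empirical), matching the two designs.

## Stepping-stone simulator

The forward simulator is a diploid stepping-stone model: nine demes in a
line, deme 1 the lake (n = 2000), eight stream demes (n = 200), 100
biallelic loci starting at frequency 0.5 everywhere, discrete generations of
migration followed by fitness-weighted reproduction, run for 1000
generations.  Implementation choices worth recording:

* Migrant counts are deterministic, `round(m N)` per adjacent neighbor —
  the randomness is in *who* migrates, drawn without replacement, and the
  two migrant sets of an interior deme are disjoint; all moves happen
  simultaneously on the pre-migration state.  Endpoint demes emigrate `m`,
  interior demes `2m`.
* Additive fitness is `max(0, 1 − s k)` with `k` the count of locally
  maladaptive allele copies (stream allele maladaptive in the lake deme,
  lake allele elsewhere).  At the top of the default grid (s = 0.0075,
  k up to 200) the floor binds for pure migrants — which is exactly the
  strong selection against migrants the model is meant to express.  A
  multiplicative variant `(1 − s)^k` is available.
* Parents are drawn proportional to fitness, independently with
  replacement; hermaphrodites may self (the parsimonious reading of the
  mating scheme; a flag forbids it).  Each mating yields one offspring
  until the deme's target size is restored exactly.
* Genotypes are stored as two haplotype arrays so the single-chromosome
  robustness variant can place exactly one crossover uniformly between
  loci per meiosis (with a Poisson(1)-count alternative).  Unlinked mode
  segregates each locus independently.
* Locus-specific selection coefficients (exponential with rate 1/s) are
  drawn once per replicate and shared across demes.
* All randomness comes from R's RNG, so a single integer seed reproduces a
  run bit-for-bit; the C++ core consumes random bits carved from single
  uniform draws for gamete assembly.

The neutral limit of the machinery is validated against the diploid
Wright–Fisher variance `p0(1-p0)(1 − (1 − 1/(2N))^g)`, single-generation
selection against the exact fitness-weighted expectation, and the
no-gene-flow limit against the diffusion fixation probability.

## Flood mixture and ABC

Temporal samples of the marsh site (before / during / one year after a
flood) are compared at SNPs with lake-pool versus stream-pool AFD ≥ 0.75 and
≥ 50x depth in each temporal sample.  "Monomorphic for the lake allele"
means an observed stream-allele read count of zero — pool-seq cannot
distinguish true fixation from non-sampling, so this is an observational
definition.  The during-flood sample is modeled as a linear frequency
mixture `lambda p_lake + (1 − lambda) p_before` ("averaging allele frequency
data" is read as mixing frequencies, not counts; a count-weighted variant
would differ only through depth imbalance).

The proportion `lambda` is estimated by rejection ABC: draw `lambda` from a
uniform prior, simulate read counts binomially at the observed depths,
summarize the simulated frequency distribution by (mean, median, fraction of
SNPs at exactly 0, fraction below 0.05), and accept the draws closest in
standardized Euclidean distance.  These four summaries are exactly the
features the temporal comparison reports (the original ABC details live in
inaccessible supplementary material, so this scheme is the package's own,
documented stand-in); the suite checks parameter recovery at
`lambda = 0.9` and interval coverage over scenarios with
`lambda ~ U(0.2, 0.95)`.

## The synthetic world

`make_gradient_truth()` plants loci with known stream-allele frequencies on
a synthetic genome (21 chromosomes of 28 Mb, one flagged as the sex
chromosome): selected loci follow a hard step at the habitat transition
(default break at 1071 m, endpoint AFD 1.0), background loci the same step
scaled to a drift-level endpoint AFD (default 0.35, matching the genome-wide
median of the motivating system) around a per-locus uniform base frequency.
Default site distances (L1 = 0 … S7 = 1950 m, habitat boundaries at 600 and
1045 m) are synthetic stand-ins chosen to reproduce the published gradient
span and cline-center geometry, not claims about the real system; real
metadata override them.  `simulate_pool_counts()` adds the two stages of
pool-seq noise — binomial sampling of 2N chromosomes into the pool, then
binomial read sampling at Poisson depth (floor 1, default mean 103x) — whose
compound variance `p(1−p)(1/(2N) + 1/D)` is verified by Monte Carlo.

What the generator does *not* emulate: linkage disequilibrium and local
haplotype structure (loci are independent), spatially autocorrelated drift
among neighboring sites (background differentiation is a pure step plus
sampling noise), mapping artifacts, reference bias, and indels.  A green
test on synthetic data therefore establishes the correctness of the
estimators and filters under the stated sampling model — not robustness to
alignment pathology or demographic history beyond the planted truth.

The pipeline's synthetic flood stage composes the pre-flood marsh as a
lake-dominated mixture with a modest stream fraction (default 0.15):
contact-zone sites are genomically near-identical to the lake but carry a
detectable stream component from hybridization, and the flood analysis is
only informative when that component exists to be displaced.  The fraction
is configurable (`flood$before_stream_frac`), chosen once as a realistic
contact-zone value, and is deliberately distinct from the admixture pulse
`lambda_true` (default 0.9) that the ABC stage must recover.

## Numerical and degenerate-input choices

Coordinates are 1-based; windows are half-open `[start, start + size)`.
Window grids start at position 1 per chromosome.  Ties in panel orientation
and HDW ranking are broken deterministically (alphabetical allele, smallest
genomic coordinate) so fixed seeds reproduce byte-identical outputs.  A
single master seed fans out to stage-level child seeds through a fixed
integer hash, keeping stages independently reproducible.  Degenerate inputs
fail loudly: empty site lists, out-of-range frequencies, missing temporal
samples, clines with fewer than four sites, extinct demes.

## Known limitations

* Cline "replicates" are optimizer restarts, not posterior samples; no
  credible intervals on per-SNP cline parameters are produced (panel-level
  uncertainty comes from bootstrapping across SNPs).
* The drift benchmark is haploid by design and not a demographic model of
  the real populations; it only calibrates how much HDW/control divergence
  drift alone produces.
* The ABC scheme's summaries and tolerance are package conventions; only
  qualitative conclusions (e.g. a lower bound on the admixture proportion)
  should be compared across implementations.
* At high migration and weak selection the stepping-stone system is not at
  equilibrium at generation 1000 — distal stream demes still sit on a
  shallow gradient that flattens only as selection strengthens.
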