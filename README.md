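# clinepool

Clinal pool-seq population genomics for parapatric ecotype pairs.

## The problem

When two populations adapt to adjoining habitats without any physical
barrier — the motivating system is a lake–stream stickleback pair sampled at
11 sites over < 2 km — the strength of reproductive isolation is written
into the *spatial* pattern of allele frequencies: how steep the genome-wide
cline is, where its center sits relative to the habitat transition, and how
heterogeneous differentiation is along chromosomes.  `clinepool` implements
the full analysis chain from pooled whole-genome nucleotide counts to those
inferences, for researchers working with pool-seq data sampled along a
geographic gradient:

* **SNP discovery and genotyping** from per-site nucleotide count tables
  (depth 50–400x per discovery pool, combined minor-allele frequency
  ≥ 0.25), with allele frequencies computed directly from raw counts.
* **Differentiation statistics**: absolute allele frequency difference
  AFD = |p₁ − p₂| (primary) and Fst = (H_T − H_S)/H_T, per-SNP pairwise
  profiles, 10 kb / 5 kb sliding-window means, spline smoothing.
* **Marker panels**: selected (endpoint AFD ≥ 0.97), neutral (AFD at the
  genome-wide median) and loDiff (half the median), each with 50 kb
  independence spacing and stream-allele orientation.
* **Geographic cline fitting** by maximum likelihood: p(x) = p_min +
  (p_max − p_min)·Φ(x) with Φ the tanh sigmoid (center c, width w = 1/max
  slope) and Szymura–Barton exponential tails; 10-restart fits, panel
  medians with bootstrap compatibility intervals, and the width-estimation
  artifact experiment.
* **CCBD** — chromosome-center-biased differentiation, the median across
  chromosomes of (median central AFD)/(median peripheral AFD) with a 5 Mb
  periphery, traced along the gradient.
* **High-differentiation windows** with an individual-based haploid
  Wright–Fisher drift benchmark (n = 200, g = 1000, 2 × 178 loci, 25
  replicates) for the deltaAFD contrast.
* **Stepping-stone simulator**: diploid, nine demes (lake n = 2000, eight
  stream demes n = 200), 100 unlinked loci under divergent selection,
  migrate-then-reproduce generations, (m, s) parameter grids and five
  robustness variants — Rcpp core, bit-reproducible from a single seed.
* **Flood mixture / ABC**: temporal comparison of a perturbed contact-zone
  site and rejection-ABC estimation of the admixture proportion λ.
* A **synthetic-data generator** with known ground truth emulating the
  11-site design (pools of ~56 diploids, ~103x depth, two-stage pool-seq
  sampling noise), so every stage is testable without the original data.

## Worked example

```r
library(clinepool)

sites  <- default_sites()             # 11 sites, L1 (0 m) ... S7 (1950 m)
layout <- default_layout()            # 21 chromosomes, chrXIX flagged sex

# synthetic world: 50 step-like selected loci + 2000 drift-level background
truth  <- make_gradient_truth(layout, sites, n_selected = 50,
                              n_background = 2000, seed = 1)
counts <- simulate_pool_counts(truth, sites, mean_depth = 103, seed = 2)

snps <- discover_snps(counts, pool_a_sites = c("L1", "L2"),
                      pool_b_sites = c("S6", "S7"))
snps <- orient_stream_allele(snps, "L1", "S7")
prof <- pairwise_profile(snps, "L1", "S7")
cat("SNPs in endpoint profile:", nrow(prof),
    "| median AFD:", round(median(prof$afd), 3), "\n")

panel <- pick_selected_panel(prof, layout, threshold = 0.97, seed = 3)
cat("selected panel:", nrow(panel), "independent SNPs\n")

g <- snps[snps$chrom == panel$chrom[1] & snps$pos == panel$pos[1], ]
g <- g[match(sites$site_id, g$site_id), ]
fit <- fit_cline(g$freq_stream, g$n1 + g$n2, sites$distance_m, seed = 4)
print(fit)

ccbd <- ccbd_for_pair(prof, layout)
print(ccbd)
```

Output:

```
SNPs in endpoint profile: 1568 | median AFD: 0.359
selected panel: 50 independent SNPs
<cline_fit two_tail> center = 1083.2 m, width = 5.4 m (logLik -0.00, 10/10 converged)
<ccbd_result> L1-S7: CCBD = 0.995 (20 chromosomes)
```

Reading the numbers: the median endpoint AFD (0.359) recovers the planted
background differentiation (0.35); all 50 planted selected loci survive the
AFD ≥ 0.97 / 50 kb ascertainment; the fitted cline centers at 1083 m —
between the sites flanking the planted break at 1071 m — with a width of a
few meters, as expected for a locus whose true frequencies are a hard step;
and CCBD ≈ 1 because this synthetic world plants no recombination-dependent
structure, so differentiation is unbiased between chromosome centers and
peripheries.

The full pipeline (discovery → panels → clines → CCBD → HDW scan → flood
mixture/ABC) runs from one configuration object:

```r
cfg <- pipeline_config(out_dir = "out", seed = 1)
res <- run_pipeline(cfg)
```

or from the command line via `inst/cli/clinepool`
(`all` | `simulate-data` | `simulate-grid` subcommands).

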