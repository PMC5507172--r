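# magladder

Coverage-based recovery of draft metagenome-assembled genomes (MAGs) from
multi-sample assemblies, with marker-gene quality triage and an iterative
refinement ladder.

## What it does, and for whom

When one co-assembly is surveyed with reads from several samples, contigs
from the same genome share a *coverage profile* — the vector of per-sample
read densities (reads/bp). magladder is for microbial ecologists and
bioinformaticians who have such a multi-sample assembly (contigs plus
per-contig per-sample read counts, plus single-copy marker hits) and want
draft genomes out of it:

1. **Bin** contigs ≥ 7.5 kb by affinity propagation on transformed
   (×5) coverage profiles, with similarity
   s(i,k) = −‖x<sub>i</sub> − x<sub>k</sub>‖² and preference p = −3
   (damping 0.9, ≤ 4,000 iterations, convergence after 400 stable
   iterations).
2. **Triage** every bin on a universal single-copy marker set:
   completeness, contamination, strain heterogeneity, and *cumulative
   redundancy* = contamination − contamination × strain heterogeneity / 100.
   Bins are drafts (≥ 50% complete, ≤ 10% cumulative redundancy),
   high-contamination, or low-completion.
3. **Refine** contaminated bins by local re-clustering with preferences
   keyed to the estimated genome count (−1,000 / −500 / −100 for ≈2 / 3 /
   ≥4 genomes), then a final round at −100 (optionally adding canonical
   tetranucleotide composition); leftovers are re-binned on raw coverage
   with the same ladder ending at −10. Low-completion bins need ≥ 5
   contigs; drafts, once called, are frozen.
4. **Quantify** each draft genome's length-normalized relative abundance
   per sample:
   (reads/bp per genome ÷ Σ reads/bp all genomes) ×
   (Σ reads recruited to genomes ÷ Σ reads recruited to all contigs ≥ 2 kb)
   × 100.

A synthetic multi-sample community generator with known truth
(`simulate_community()`) and truth-based evaluation (`evaluate_bins()`:
per-genome recovery, adjusted Rand index) make the whole ladder testable
without any external data.

## Worked example

```r
library(magladder)

cfg <- community_config(n_genomes = 5, n_samples = 4,
                        genome_length_range = c(4e5, 6e5), seed = 42)
com <- simulate_community(cfg)
fit <- mag_pipeline(com)
summary(fit)
```

```
5 draft genomes, 0 low-completion bins, 0 unbinned of 237 contigs
Draft genome QC:
 bin_id n_contigs completeness contamination strain_heterogeneity
   MAG1        52          100             0                    0
   MAG2        48          100             0                    0
   MAG3        40          100             0                    0
   MAG4        50          100             0                    0
   MAG5        47          100             0                    0
```

All 237 contigs of the five simulated genomes land in five bins, each with
all 104 markers present exactly once (100% complete, 0% contamination), so
every bin is triaged a draft genome. Against the generator's truth:

```r
evaluate_bins(fit, com)
#> Bin evaluation: 100% of genomes recovered, ARI 1.000
#>   5 draft bins, 0 low-completion bins, 0 unbinned contigs
#>   truth completeness mean 100.0%, truth contamination mean 0.0%

summarize_abundance(relative_abundance(fit))
#>   sample_id total top_n_total
#> 1       S01   100         100
#> ...
```

Recovery is perfect (adjusted Rand index 1), and because the drafts cover
every data-rich contig, their per-sample abundances sum to 100% of the
recruited reads.

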