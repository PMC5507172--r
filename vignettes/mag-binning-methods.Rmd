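---
title: "Coverage-profile MAG binning: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-profile MAG binning: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magladder)
```

## The problem

Shotgun metagenomes of a microbial community yield assembled contigs whose
genome of origin is unknown. When the same assembly is surveyed across
several samples, contigs from one genome share a characteristic *coverage
profile*: the vector of per-sample read recruitment densities. magladder
reconstructs draft metagenome-assembled genomes (MAGs) by clustering contigs
on these profiles, scoring the clusters against a universal single-copy
marker set, and iteratively re-clustering contaminated clusters.

## Coverage model and transform

Coverage of contig $c$ in sample $s$ is the recruited read count divided by
the contig length,
$$x_{cs} = \frac{\mathrm{reads}_{cs}}{L_c} \quad (\text{reads/bp}),$$
computed by `compute_coverage()`. Marine surface metagenomes are typically
low coverage, so raw profiles of distinct genomes sit close together in
Euclidean space; `transform_coverage()` multiplies every value by a constant
(default 5) to spread profiles apart before clustering. The factor is
exposed as the single coverage knob (`ladder_config(scale_factor = )`).

Two length cutoffs frame the analysis: contigs $\ge$ 7,500 bp enter binning
(`binned_min_length`), while the read-recruitment universe used for
relative abundance is every contig $\ge$ 2,000 bp (`data_rich_min_length`).
Both cutoffs are inclusive.

## Affinity propagation

Clustering uses affinity propagation on the similarity
$s(i,k) = -\lVert x_i - x_k\rVert^2$ with the shared *preference* $p$ on the
diagonal. Damped responsibility/availability messages are iterated
(`ap_cluster()`, compiled core):

* $r(i,k) \leftarrow s(i,k) - \max_{k' \ne k}\,[a(i,k') + s(i,k')]$
* $a(i,k) \leftarrow \min\{0,\; r(k,k) + \sum_{i' \notin \{i,k\}} \max(0, r(i',k))\}$,
  and $a(k,k) \leftarrow \sum_{i' \ne k} \max(0, r(i',k))$,

each damped as $m_{\text{new}} = d\,m_{\text{old}} + (1-d)\,m_{\text{computed}}$.
Exemplars are the items with $r(k,k)+a(k,k) > 0$; every other item joins its
most similar exemplar. The default operating point is $p=-3$, damping
$d=0.9$, at most 4,000 iterations with convergence declared after 400
iterations of an unchanged exemplar set. The preference is the cluster-count
dial: more negative values yield fewer, larger bins.

Numerical choices:

* **Tie breaking.** Exact similarity ties (duplicate coverage profiles) can
  make messages oscillate. A seeded uniform jitter of at most $10^{-12}$
  relative to the similarity range is added once to the similarity matrix
  (disable with `jitter = FALSE`); argmax ties resolve to the lowest index,
  which also makes the fit equivariant under input permutation.
* **Degenerate fixed point.** When all items are near-identical relative to
  $|p|$, damped message passing can settle on the spurious
  "everything is an exemplar" fixed point. `ap_cluster()` therefore also
  evaluates the best single-exemplar solution in closed form and returns it
  whenever it attains strictly higher net similarity. On small instances
  ($n \le 12$) the test suite checks the returned exemplar set against an
  exhaustive search over all exemplar subsets.
* **Non-convergence** within the iteration budget returns the current
  exemplar set with `converged = FALSE` rather than failing; if no exemplar
  emerges at all, every contig is reported unbinned.
* **Scale.** The similarity matrix is dense, so memory grows as $O(n^2)$;
  the intended working range is up to a few tens of thousands of contigs.

## Marker-based quality control

Bin quality is estimated from a universal single-copy marker table
(`bin_qc()`), a deliberately simplified stand-in for lineage-specific
marker machinery: one expected set of $M$ markers (default 104, roughly the
size of widely used bacterial single-copy panels), each expected exactly
once per genome.

* completeness $= 100\,|\{m : n_m \ge 1\}| / M$
* contamination $= 100 \sum_m \max(0, n_m - 1) / M$
* strain heterogeneity = percentage of duplicate marker-copy pairs with
  pairwise identity $\ge 0.9$
* cumulative redundancy $=$ contamination $-$ contamination $\times$
  strain heterogeneity$/100$.

Marker rows carry the copy's identity to the marker reference; the pairwise
identity of two copies is taken as $1 - |d_i - d_j|$ in divergence terms
(copies diverged from the reference at overlapping sites), which keeps QC
computable from the table alone, without alignment. Fully strain-level
duplication (identical copies) therefore cancels out of cumulative
redundancy, while copies from unrelated genomes do not.

Bins are triaged into three categories: **draft** (completeness $\ge 50\%$
and cumulative redundancy $\le 10\%$), **high contamination** (complete but
redundant), **low completion** ($< 50\%$ complete). Both draft boundaries
are inclusive: the two printed category rules overlap at exactly 10%
redundancy, and the draft category wins there. The number of genomes in a
contaminated bin is estimated as $1 + \mathrm{round}(\text{contamination}/100)$,
since $k$ merged complete genomes score about $(k-1)\times 100\%$
contamination under the copy-count definition.

## The refinement ladder

`mag_pipeline()` orchestrates the multi-round procedure:

1. **Initial binning** of admitted contigs on transformed coverage
   ($p=-3$, $m=4{,}000$, $v=400$, $d=0.9$), then triage.
2. **Schedule refine.** Each high-contamination bin is independently
   re-clustered on its own contigs (local AP, budget $m=2{,}000$,
   $v=200$), with the preference keyed to the estimated genome count:
   $-1{,}000$ for $\approx$2 genomes, $-500$ for 3, $-100$ for $\ge 4$
   (estimates of 1, which can occur below 50% contamination, use the
   2-genome rung). Sub-bins are re-triaged; drafts are frozen and never
   revisited.
3. **Final refine** of remaining high-contamination bins at $p=-100$,
   optionally on coverage plus composition features (below). Bins still
   contaminated afterwards are demoted to low completion, matching the
   two terminal categories of the procedure.
4. **Raw-coverage phase.** Every contig not captured in a draft genome is
   re-binned on *raw* coverage with the initial budget, followed by the
   same two refinement rounds with the final round at $p=-10$.
5. **Finalization.** Drafts are labelled sequentially
   (`label_prefix`, default `MAG`); non-draft bins with at least 5 contigs
   become low-completion bins (`MAGlc<n>`), smaller ones dissolve into the
   unbinned set. The three terminal sets always partition the admitted
   contig universe, which the pipeline verifies on every run.

Composition features for the final refine rounds are the 136 canonical
tetranucleotide frequencies (4-mers pooled with reverse complements),
z-scored over the bin's contigs and scaled by $\sqrt{d_{\text{cov}}/d_{\text{comp}}}$
so the coverage and composition blocks contribute comparable squared
distance. They are used only when sequences are supplied and
`use_composition_in_refine` is set.

All tie-breaking seeds derive deterministically from `ladder_config(seed=)`,
so a rerun with identical inputs and configuration is byte-identical.

## Relative abundance

For draft genome $g$ and sample $s$ (`relative_abundance()`):
$$A_{gs} = \frac{(\mathrm{reads/bp})_{gs}}{\sum_{g'} (\mathrm{reads/bp})_{g's}}
\times \frac{\sum \text{reads recruited to genomes}}
{\sum \text{reads recruited to all contigs} \ge 2\,\mathrm{kb}} \times 100.$$

A genome's reads/bp is its total recruited reads over its total length
(length-weighted). The unweighted mean of per-contig reads/bp is available
behind `per_contig_mean = TRUE`; the weighted form is the default because it
matches the length normalization and is robust to contig-size skew. Per
sample, the abundances of all drafts sum exactly to
$100 \times$ (genome-recruited reads / data-rich reads), never exceed 100,
and are invariant to rescaling a sample's counts. A sample with no
data-rich reads yields missing values, not zeros.

## The synthetic community generator

Real inputs to the pipeline are a counts table and a marker table; the
generator (`simulate_community()`) produces both with known truth so every
stage is testable without external data. What it emulates, and the defaults
chosen as the study conditions:

* **Abundance structure.** Genome mean coverages are log-normal across
  genomes (`sigma_log = 1.0`) around a low median of 0.3 reads/bp — the
  low-coverage regime the $\times 5$ transform exists for — with per-sample
  log-normal variation (sd 0.6) correlated $\rho = 0.3$ between samples, so
  each genome keeps a recognisable profile.
* **Fragmentation.** Contig lengths follow a log-normal law
  (meanlog $=\log 8500$, sdlog 0.45) truncated at 7,500 bp; genome lengths
  are uniform on 2.4–3.0 Mbp, giving at least 200 contigs per genome.
* **Counts.** Reads are negative binomial with mean = coverage × length and
  variance = mean × (1 + dispersion), dispersion 0.5; dispersion 0 is
  Poisson. Real recruitment counts are overdispersed; the paper-scale data
  come from real mappings, so this parameterization is a convention.
* **Markers.** 104 markers of 900 bp placed once per genome (length-weighted
  contig choice, 0-based half-open coordinates), identity $1-\delta_g$ with
  per-genome reference divergence $\delta_g \sim U(0, 0.5)$. A duplication
  knob (`marker_copy_number`, `marker_copy_identity`) builds contamination
  fixtures.
* **Noise.** `unassigned_fraction` adds markerless contigs with independent
  coverage profiles that no bin should recover.
* **Sequences** are i.i.d. uniform nucleotides by default; a per-genome
  Dirichlet-perturbed transition table (`composition_bias`) adds 4-mer
  signal when composition-based refinement is under study.

What it does **not** emulate: read-level errors, assembly artefacts,
chimeric contigs, shared (conserved or horizontally transferred) sequence
between genomes, uneven within-genome coverage, and realistic k-mer
composition. Passing the synthetic recovery tests therefore demonstrates
the correctness and calibration of the procedure under its own model
assumptions, not field performance on real assemblies.

## Validation problem sizes

The test suite exercises the full ladder on a 20-genome, 6-sample community
(about 4,600 contigs; typically recovering $\ge 90\%$ of genomes with
adjusted Rand index $\ge 0.9$ against truth), exhaustive-search optimality
of the clustering core on $n \le 12$ fixtures, hand-constructed merged-bin
and boundary fixtures, and determinism by byte-identical reruns. These
sizes were chosen so the whole suite runs comfortably on a laptop-class
single core.

## Known limitations

* Dense $O(n^2)$ similarity limits the contig count; very large assemblies
  need pre-filtering by length (as the default 7.5 kb cutoff does).
* Genomes whose coverage profiles coincide across all samples are not
  separable by any coverage-based method; such merges surface as
  high-contamination bins and end up demoted to low completion unless
  composition separates them.
* The marker QC uses one universal single-copy set; it has no notion of
  lineage-specific marker sets or collocation, so absolute completeness
  values are not comparable to lineage-aware tools.
* `est_genomes` is derived from the implemented contamination definition
  and is only a heuristic for choosing the re-binning preference.
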