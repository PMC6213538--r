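---
title: "Linking phosphosignaling rewiring to exon-level splice variation: methods and design"
author: "SpliceRewire authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking phosphosignaling rewiring to exon-level splice variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(SpliceRewire))
```

# The analysis problem

Tumorigenic progression of an isogenic cell-line panel (here the
MCF10A-lineage naming is used throughout: 10A → AT → TG3B / CA1a) rewires
intracellular signaling. Two global read-outs capture complementary sides
of that rewiring:

* **Phosphoproteomics by spectral counting.** After phosphopeptide
  enrichment and LC-MS/MS, the number of spectra matched to each
  phosphosite proxies its abundance. Comparing two cell lines site by site
  yields a sparse, overdispersed table of integer counts.
* **Exon-level microarrays.** Probes tiled 5′→3′ along each gene quantify
  expression per exon, so a change in splicing shows up as *heterogeneity*
  of the per-probe differences between two cell lines, distinct from a
  uniform expression shift.

SpliceRewire implements the bespoke statistics connecting the two: a
per-protein *net phosphorylation score* built from thresholded site
changes, interaction-network cluster summaries and tiered keynode ranking
on the phospho side; and a per-gene *exon-probe SD* statistic of splice
variation with binned fold-change summaries, rank-sum contrasts,
positional probe profiles and gene-set enrichment on the transcriptomic
side. Every stage can be exercised end to end on synthetic data with known
ground truth.

# Phosphosite scoring model

For a comparison written `"numerator/denominator"` (e.g. `"CA1a/AT"`), the
spectral counts of each site are first summed over the runs of each
condition (`aggregateRuns()`; nine runs per cell line in the emulated
design). The site ratio is

$$r = \frac{c_\mathrm{num} + c_0}{c_\mathrm{den} + c_0},$$

with a symmetric pseudocount $c_0 = 0.5$. Spectral-count tables are
dominated by zeros, and a site going from 0 to 12 spectra is clearly a
qualifying change; the symmetric pseudocount makes such ratios finite
(here $12.5/0.5 = 25$), leaves a doubly-unobserved site at exactly $r = 1$,
and preserves antisymmetry: reversing the comparison maps $r \mapsto 1/r$
and negates every score. The score is

$$s = \begin{cases} +1 & r \ge T\\ -1 & r \le 1/T\\ 0 & \text{otherwise}\end{cases}$$

with $T = 3$ by default and *inclusive* boundaries. No minimum-count gate
is applied by default: low-count changes such as 0 → 8 are treated as
qualifying, matching how sparse spectral-count profiling is read in
practice.

The **net protein score** is the sum of its site scores; `n_qualifying`
counts nonzero-score sites, so $|net| \le n_\mathrm{qualifying}$ and
$net = n_+ - n_-$. A protein with four sites up and two down has net +2
and is rendered "hyperphosphorylated" (`nodeStatus()` maps net < 0 / = 0 /
> 0 to hypo / neutral / hyper, with $|net|$ as shading magnitude).

**Cluster summaries** report, per network cluster and comparison:
`a` = sum of member net scores, `b` = a divided by the cluster's node
count (displayed to 2 decimals) and `c` = the percentage of nodes with at
least one qualifying change (1 decimal). The denominator is the cluster's
full node count, held fixed across comparisons, so the three comparisons
of one cluster are directly comparable; unrounded values are also
returned.

# Network clustering and keynodes

`clusterNetwork()` partitions the interaction network by greedy modularity
maximization (`igraph::cluster_fast_greedy`), keeping clusters of at least
3 nodes and labeling smaller communities unclustered. The specific
algorithm is exchangeable by design — the contract is only that clusters
are communities of a simple undirected graph with a minimum size — and the
greedy method is deterministic, which the tests rely on.

**Keynodes** summarize large differential networks by their hubs.
Candidates are the nodes with net status ≤ −1 or ≥ +1; degree is counted
*within the candidate-induced subgraph*, since the display this statistic
supports is restricted to differential proteins. Selection is iterative:
the highest-degree candidate becomes the primary keynode and its candidate
neighbors its partners; the next tier is chosen among candidates that are
neither keynodes nor partners, while earlier selections stay in the graph,
so a partner adjacent to two keynodes is flagged *shared*. Ties are broken
lexicographically by identifier, making results reproducible. Connection
counts are non-increasing across tiers by construction.

# The exon-probe SD statistic

For each gene with at least 3 coding exon probes (junction probes are
excluded), the per-probe delta is

$$\delta_e = \overline{\log_2 I_{e,\mathrm{num}}} - \overline{\log_2 I_{e,\mathrm{den}}},$$

the difference of replicate means, taken in 5′→3′ probe order. The
**splice variation statistic** is the sample standard deviation
($n-1$ denominator) of the $\delta_e$. The estimator choice is material at
3–12 probes per gene; the sample SD is the conventional reading. The
statistic is shift-invariant: a pure expression change moves all probes
equally and scores SD 0 regardless of magnitude, while differential exon
usage inflates it. SD thresholds are inclusive (SD ≥ 1, SD ≥ 2).

The **signed fold** of a gene is $2^m$ for $m \ge 0$ and $-2^{-m}$
otherwise, where $m$ is the mean delta — the convention of array analysis
consoles, in which no value falls strictly between −1 and 1.

Downstream summaries:

* `binBySd()` groups genes into SD bins [0,1), [1,2), [2,∞) and reports
  the mean ± SD of *signed folds* per bin plus the percentage of genes.
  Signed folds (not log-scale values) are averaged, which is what allows a
  bin with mixed up/down changes to average near zero with a large SD.
* `compareSdDistributions()` contrasts the SD distributions of two
  comparisons by a two-sided Wilcoxon rank-sum test, by default restricted
  to genes with SD ≥ 1 (the population in which splice variation is
  visible; the all-genes variant is available via `restrictMinSd = 0`).
  `stats::wilcox.test` supplies the exact distribution for small tie-free
  samples and the tie-corrected normal approximation otherwise.
* `topFoldEnrichment()` ranks genes by |signed fold| (ties broken by gene
  id for determinism), takes the top N (default 100) and tests
  over-representation of SD ≥ 1 genes by the one-sided hypergeometric
  upper tail against the cohort-wide rate.
* `positionalProfile()` asks *where* along the mRNA the difference lies:
  per gene, the 5′-most probe is group 1, the 3′-most probe the last
  group, and the interior probes are split 5′→3′ into three contiguous
  near-equal runs (earlier runs absorb the remainder; an 8-probe gene
  splits its middle six probes 2/2/2). One probe per end is used by
  default — the natural reading when gene lengths vary — and the number of
  interior groups is a parameter. Group values are per-gene means; the
  gene is the replication unit of the one-way ANOVA across groups.

# Gene-set enrichment

`enrichTerms()` computes, per term, the one-sided hypergeometric tail
$P(X \ge k)$ — equivalent to a one-sided Fisher's exact test on the 2×2
table — with Benjamini–Hochberg correction across all tested terms, and
stars at p ≤ 0.05 (*) and p ≤ 0.001 (**). The background is the tested
universe: all genes entering the SD computation for splicing enrichment,
or all network nodes for cluster enrichment. Terms are intersected with
the background first; no term-size filter is applied by default, though
`minTermSize`/`maxTermSize` are available.

# Synthetic data: what it emulates and what it does not

The generators reproduce the *statistical structure* the pipeline must
cope with, each a pure function of (parameters, seed):

* `simulatePhosphoCounts()` draws run-level counts from a negative
  binomial (mean `baselineMean`/`nRuns` per run, size `dispersion`) —
  spectral counts are overdispersed and produce many exact zeros at low
  means. Planted differential sites have their mean multiplied or divided
  by `effectFold` in the numerator condition of a randomly chosen
  comparison. Defaults: 9 runs, baseline mean 20 per condition, dispersion
  5, effect fold 10, 30% of proteins differential (about a third of
  profiled phosphoproteins pass the 3-fold criterion in the emulated
  study design).
* `simulateNetwork()` is a stochastic block model; default block sizes
  (54, 45, 28, 28, 25, 18, 11, 9, 4, 3) mirror a typical clustered
  differential-protein network.
* `simulateExonData()` gives every gene a baseline per-probe intensity
  shared across conditions plus N(0, `noiseSd`) replicate noise
  (default 0.25 log2 units, triplicates). Spliced genes (default 4% —
  exon-array cohorts show roughly 1–4% of genes at SD ≥ 1) receive a
  downward divergence in the numerator condition. **Amplitude
  convention:** `divergenceAmplitude` is the *gene-averaged* divergence in
  log2 units. The default ramp rises linearly from zero at the 5′-most
  probe to 2×amplitude at the 3′ end, so the 5′ end stays concordant and
  the transcript has visibly diverged by its midpoint; a step profile
  (3′ half shifted by 2×amplitude) is available by flag. This convention
  is what makes the default amplitude of 2 separate cleanly at the SD ≥ 1
  threshold (ramp SD ≈ 1.15–1.6 depending on probe count): any monotone
  profile whose *total range* were 2 would cap at SD ≈ 1 and the
  threshold would sit on top of the signal. `foldCoupling` (default 3
  log2 units) adds a whole-gene downward shift to spliced genes, coupling
  large negative signed folds to high SD without affecting the SD itself.
  15% of probes are emitted as junction probes so the exclusion path is
  always exercised.
* `simulateAnnotations()` draws random gene sets plus one planted term
  with ≥ 90% of members from a designated subset.

Ground truth (flags, directions, amplitudes, parameters, seed) is
returned alongside each dataset and `writeSimulation()` serializes both,
so any dataset can be regenerated bit-identically.

What the generators deliberately do **not** emulate: probe-sequence and
GC effects, probe-level correlated noise, partial-isoform mixtures,
cassette-exon/intron-retention event structure (event calling is out of
scope), realistic protein-network degree distributions, shared-peptide
ambiguity in spectral counts, and batch structure. Passing recovery tests
therefore demonstrates the statistics behave as designed under their
stated noise model — not that the thresholds are optimal for any
particular real platform.

# Numerical choices and degenerate inputs

* Threshold comparisons are inclusive on both sides (ratio ≥ 3 or
  ≤ 1/3; SD ≥ 1); `scoreSite(1/r) = -scoreSite(r)` exactly.
* A site observed in neither condition is "no evidence" (ratio 1,
  score 0), never an error.
* Genes with fewer than 3 coding probes are *skipped with a message*, not
  an error — they are outside the statistic's domain.
* `b` and `c` cluster values are displayed at 2 and 1 decimals
  (`round()`), with unrounded values emitted alongside.
* Keynode and top-fold ties break lexicographically; community detection
  is deterministic — the full pipeline is reproducible from a seed.
* An empty candidate set yields zero keynodes; an empty graph an empty
  labeling; an empty gene list an empty bin summary.

# Problem sizes

The test suite validates oracle equivalence on 10^4 random vectors
(SD, site scoring), exhaustive enumeration up to N = 30 (hypergeometric),
n ≤ 8 (rank-sum) and 12-node graphs (keynodes), and parameter recovery on
cohorts of 250–500 genes, 300–400 proteins and 30-node networks;
`scripts/acceptance.R` uses 400 proteins, 30 network nodes and
500–2000 genes. These sizes give stable stochastic margins while keeping
a full run inside a few minutes on one CPU.

# Limitations

The exon SD statistic detects probe-level heterogeneity, not specific
splice events; it cannot distinguish alternative splicing from 3′ decay
or transcription–termination effects, which is why the positional profile
is reported alongside it. The net phosphorylation score weighs all sites
equally and ignores site stoichiometry. Cluster summaries depend on the
community structure found by the clustering stage; different modularity
algorithms can shift cluster boundaries even though each satisfies the
stated contract.
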