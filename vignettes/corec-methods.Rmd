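---
title: "Recruitment motifs from cofactor PBM data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recruitment motifs from cofactor PBM data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corec)
```

# The measurement and its model

A cofactor recruitment (CoRec) experiment applies cell nuclear extract to a
double-stranded DNA microarray and labels one cofactor (COF) — for example a
lysine acetyltransferase — with a fluorescent antibody. The array carries,
for each consensus transcription-factor binding site, the consensus probe
plus every single-nucleotide variant (SV) probe. The fluorescence pattern
across a consensus + SV probe set is the recruitment fingerprint of all
TF–COF complexes that bind that site; `corec` turns these patterns into
recruitment motifs, networks, and genomic predictions.

## From spots to z-scores

Each probe is printed as replicate spots (5 by default). The probe-level
signal is the **median** spot fluorescence — robust against single-spot
artifacts — followed by a natural log. Each array carries background probes
(261 in the published design) drawn from genomic sequence; with their mean
`mu_bg` and sample standard deviation `sigma_bg` of log fluorescence, every
probe gets

$$ z = \frac{f - \mu_{bg}}{\sigma_{bg}}. $$

Two conventions had to be fixed because "log" and the normalisation group
are not otherwise determined: the log is natural (z is invariant to the
base only jointly with `mu`/`sigma`, so one base is fixed globally), and
background statistics are computed per array and channel, so every
COF/condition experiment is standardised by its own backgrounds. By
construction the background probes then have mean z = 0 and SD 1 exactly,
and z is invariant to any global rescaling of fluorescence units.
Degenerate inputs fail fast: fewer than two background probes, or zero
background variance, are errors rather than silent NaNs.

## The delta-z recruitment motif

For a consensus site of length $L$, the $L \times 4$ matrix $z_{ik}$ holds
the z-score of the probe carrying base $k$ at position $i$: SV probes fill
the non-consensus cells, and the consensus probe's single z-score is
re-used at every position's consensus-base cell (the consensus probe is the
shared reference of all SV comparisons). With $\mu_i$ the median of the
four variants at position $i$,

$$ \Delta z_{ik} = z_{ik} - \mu_i $$

is a binding-energy-matrix-like description of each substitution's effect.
The median of four values is the mean of the middle two, so each row of
$\Delta z$ has median exactly zero — a useful invariant that the tests
assert.

**Motif strength** (MS) is the median z-score of the 10 top-scoring probes
of the set (roughly the top 15% of a 10-mer's 31 probes) — an aggregate,
cell-specific recruitment activity that is more robust than the single best
probe. Sets with fewer than 10 probes (sites shorter than 3 nt) use all
probes, with a warning rather than an error, so short half-sites still
produce a score.

## Adaptive-beta Boltzmann probabilities

To compare recruitment motifs with reference TF motif libraries, z-scores
are mapped to a position probability matrix by a Boltzmann transform

$$ P_{ik} = \frac{e^{\beta z_{ik}}}{\sum_{k=1}^4 e^{\beta z_{ik}}}, $$

computed as a row softmax stabilised by row-max subtraction. Because
$\mu_i$ is constant within a row, using $\Delta z$ or $z$ gives the
identical matrix. The magnitude of z-score changes scales with overall
recruitment strength, so a fixed $\beta$ would over-sharpen weak motifs and
over-flatten strong ones; $\beta$ is therefore set per motif:

$$
\beta = \begin{cases}
4 & MS \le 0 \\
4 - 0.5\,MS & 0 < MS < 6 \\
1 & MS \ge 6
\end{cases}
$$

— continuous, non-increasing, with range $[1, 4]$.

## Quality, replicate, and condition filters

A motif is kept when (i) MS > 0.4 and (ii) the minimum over all windows of
5 consecutive positions of the mean information content exceeds 1.0 bits,
with $IC_i = 2 + \sum_k P_{ik} \log_2 P_{ik}$ (the uniform-background
two-bit convention; the IC formula itself was an open choice). Motifs
shorter than the window average over all positions.

Replicate consistency and cross-condition conservation use a direct
Euclidean distance between probability matrices at shared consensus + SV
coordinates:

$$ ED = \frac{1}{L} \sum_i \sqrt{\sum_k (P_{ik} - Q_{ik})^2}. $$

The **mean** per-column normalisation (rather than the sum) makes the
thresholds length-independent; it is exposed as a `normalize` switch since
the normalisation behind the published thresholds is not printed. A probe
set is *replicated* when any pair of replicate motifs has ED < 0.4, and
*conserved* across two conditions when any cross-condition pair has
ED < 0.25.

# Matching motifs to reference libraries

Recruitment motifs are aligned to each reference motif over every ungapped
offset with at least 5 overlapping columns, in both orientations (the
reverse complement of a probability matrix reverses column order and swaps
A/T and C/G), scoring each alignment by the mean per-column Euclidean
distance over the overlap only — overhangs carry no penalty. Significance
comes from a seeded Monte-Carlo null: the query's columns are shuffled
`n_null` times (10,000 by default) and the ED re-evaluated **at the
observed best alignment**, giving

$$ p = \frac{1 + \#\{ED_{null} \le ED_{obs}\}}{n_{null} + 1}, $$

with a library-size (Bonferroni) adjustment `p_adj = min(1, p * #refs)` and
significance at `p_adj < 0.01`.

Holding the alignment fixed under the null was a genuine design decision.
Re-optimising the offset for every shuffle lets 5-column chance alignments
of a sharp motif's own columns tie the observed distance with probability
around $10^{-3}$–$10^{-2}$, which destroys the test's power for any query
that is not bit-identical to a reference; conditioning on the observed
alignment turns the statistic into a clean permutation test of the
column-to-column correspondence. A related, openly stated limitation is
low-complexity motifs (long single-base runs): shuffling nearly identical
columns reproduces the observed correspondence by symmetry, so such motifs
can never reach small p under a column-shuffle null, whatever the method.

Cluster assignment is decided by the single member motif with the lowest
adjusted p-value among all significant matches of the replicate group, with
ties broken by lower ED and then lexicographic target id; groups with no
significant match stay unassigned.

# TF motif clusters

Reference motifs are grouped into specificity clusters. Pairwise
comparison p-values (symmetrised by taking the smaller of the two directed
comparisons) are mapped to distances

$$ d = \max(15 + \log_{10} p,\ 0) \in [0, 15] $$

and clustered by complete-linkage agglomeration (`stats::hclust` +
`cutree`): clusters merge only while the maximal inter-member distance
stays at or below the cut height. The cut height is a required parameter
with no default — the published cluster set was partly manually curated, so
any automatic cut is a user decision, and cluster names are user-supplied
labels. Cluster labels are relabelled by lexicographically smallest member
so the partition is invariant to input order. External motifs (e.g. a
TF-compendium entry) are mapped onto existing clusters through their best
reference match at raw p < 0.0005.

# Recruitment networks

The network is a COF x condition x TF-cluster matrix whose cells hold the
maximum motif strength among the quality-passing, replicated, assigned
probe sets, with probe-set provenance retained. Between two conditions an
interaction is *gained* (present only after), *lost* (present only
before), or *conserved* (present in both with the cross-condition ED
filter satisfied). A both-present cell whose motifs diverge across
conditions is reported separately as *discordant* rather than silently
forced into a class.

Per-cluster response classes across the profiled COFs use the change in
the max-MS cells, `delta MS`, with threshold 1.5: *strongly induced* when
every recruiting COF exceeds +1.5; *partially induced* / *diminished* when
at least two COFs pass +1.5 / -1.5 and at least one other COF is
constitutive (present, conserved, |delta MS| <= 1.5 — the explicit,
configurable reading of "constitutive"); *kat-specific* when exactly one
COF recruits; otherwise *none*. The rules are applied in that order, so a
single-COF induced cluster counts as strongly induced. Constitutive
promiscuity asks for strictly more than 4 COFs with MS strictly above 3 in
both conditions.

Cell-type specificity is tested by permutation on the clusters x
experiment presence matrix: the statistic is the number of clusters
present in exactly one of two cell types (presence per cell type being the
OR over that type's experiment columns), and the null permutes each row's
entries across columns independently. The z-score is the distance of the
observed statistic from the null mean in null SDs. The exact permutation
scheme is not uniquely determined by the published description; this
choice keeps rows independent, which also gives the closed-form oracle
used in the tests (the null statistic is a sum of independent per-row
Bernoullis). A matrix whose statistic is permutation-invariant (e.g.
all-ones) has zero null variance and errors.

# Genomic scanning and promoter acetylation

Probability matrices become log2-odds PWMs against a uniform 0.25
background with fractional pseudocount 0.01 (the scanning tool this
emulates defaults to a genome-derived background; uniform + 0.01 is
declared and configurable). Column scores are discretised at granularity
1e-3 and the exact distribution of a single window's total score under an
i.i.d. uniform background is computed by dynamic-programming convolution,
so every occurrence gets an exact tail p-value; the tests verify the DP
against full $4^L$ enumeration. Non-ACGT bases take the worst column score
(conservative), and zero probability cells are floored at 1e-12 so a zero
pseudocount stays finite.

A region's motif score is $-\log_{10} p$ of the single best occurrence
over both strands, or 0 when no occurrence reaches p <= 1e-5; cluster
scores take the maximum over member motifs. Site counts are greedy,
left-to-right, non-overlapping occurrences at the same p floor (whether
the published counts allowed overlaps is unknown; greedy non-overlap is
the documented choice). Promoters are strand-aware windows from 500 bp
upstream to 100 bp downstream of the first TSS per gene, in 0-based
half-open coordinates, clipped at contig bounds with a warning. The
promoter acetylation level is the maximum $-\log_{10} p$ score of any
overlapping acetylation peak; promoters overlapping an open-chromatin peak
but no acetylation peak score 0, and promoters overlapping neither are
excluded. Differential classes come from overlap with differential-binding
regions: induced at log2 FC >= 1.5, unchanged at <= 0.1, with conflicts
resolved to induced (a promoter with one changing and one static peak is
treated as changing). Enrichment between element groups uses the
two-sided Wilcoxon rank-sum test (exact for small tie-free samples).

# The synthetic generator

Every stage is testable without downloads through a generator that
emulates the experiment:

* **Design**: planted reference PPMs are collapsed to consensus sites and
  expanded into consensus + SV probe sets exactly as a real library would
  be; background probes are drawn from a random contig. Planted motifs are
  JASPAR-consensus-like — mostly sharp columns (dominant base 0.85), a
  fraction of medium two-base columns, and dominant-base composition
  bounded at half the positions, emulating the sequence diversity of a
  curated nonredundant library (and avoiding the low-complexity regime
  where column-shuffle nulls are uninformative, as discussed above).
* **Fluorescence**: spot signal is $B\,(1 + g\,e^{-E})\,\eta$ with
  per-probe log-normal background $B$ (sdlog 0.3), per-spot multiplicative
  noise $\eta$ at 10% CV, 5 spots per probe, and a mismatch-additive probe
  energy $E = \sum_i \varepsilon_i$, $\varepsilon_i(k) = -\log(P_{ik} /
  \max_k P_{ik})$ against the planted PPM — a simple Boltzmann occupancy
  without saturation. The recruitment gain $g \ge 0$ is the per-(COF,
  condition) signal dial; $g = 0$ probe sets are true negatives. A fixed
  seed makes runs bit-identical, and holding the seed fixed across gain
  settings gives paired (common-random-numbers) experiments in which
  motif strength is monotone in $g$ probe by probe.
* **Condition shifts**: gained / lost / conserved plans set the two
  conditions' gains to (0, high), (high, 0), (high, high).
* **Genome**: one random contig with evenly spaced promoters; cluster
  consensus sites are planted at non-overlapping random offsets, and the
  promoter acetylation peak score follows `level = a + b*k + noise` in the
  number of distinct planted recruiting clusters `k` (defaults a = 3,
  b = 2, sd = 0.5), with `k = 0` promoters left open but unacetylated.

What the generator does **not** emulate: spatial array artifacts, signal
saturation, dye chemistry, probe-sequence composition biases, and —
importantly — the softness of real reference motifs relative to recovered
ones. With background sdlog 0.3 and beta in [1, 4], recovered motifs are
systematically sharper than the planted probability matrices (the
recovered log-odds scale is beta/sigma times the planted one), which is why
recovery is validated as mean column ED < 0.25 rather than near-zero.
Passing the synthetic suites therefore demonstrates internal correctness
of the inference chain — normalisation, motif construction, filtering,
matching, network calls, scanning — under a plausible noise model, not
calibration against real arrays.

# Problem sizes and numerics

The validation suites run at deliberately desk-friendly sizes chosen as
the package's own test conditions: 20 planted 12-mers with two replicates
for recovery and cluster assignment (Monte-Carlo null n = 2,999, giving a
minimum adjusted p of 0.0067 against a 20-motif library), 12 probe sets
across two conditions for gained/lost/conserved recovery, a gain ladder
{0, 1, 4, 16, 64}, and 48 promoters across heterotypic cluster counts
0..5. Larger runs only tighten the Monte-Carlo resolution. All randomised
steps take explicit seeds; softmax rows are max-stabilised; ties break
deterministically (A < C < G < T for consensus bases, forward strand and
leftmost position for scan hits, lower ED then lexicographic id for match
ties, smallest member id for cluster labels).

# Known limitations

* Monte-Carlo match p-values have resolution 1/(n_null + 1); significance
  thresholds tighter than that require more shuffles.
* Column-shuffle nulls are uninformative for low-complexity motifs.
* The cluster set depends on the user-chosen cut height; the published,
  partly curated cluster table is not reproduced.
* The network's `discordant` class (present in both conditions, motifs
  divergent) is reported but deliberately excluded from the three
  canonical status classes.
* Genomic scanning assumes a uniform background; GC-biased genomes will
  shift occurrence p-values relative to tools that fit a background model.
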