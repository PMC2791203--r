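---
title: "Scoring co-occurring DNA copy number alterations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring co-occurring DNA copy number alterations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CNAcooccur)
```

## The problem

Tumor genomes accumulate DNA copy number alterations (CNAs): gains that can
activate oncogenes and losses that can remove tumor suppressors. When two
distinct genomic regions are recurrently aberrated *in the same samples*,
this co-occurrence can point at a functional collaboration between genes in
the two regions. The difficulty is separating genuine co-occurrence from two
confounders visible in any large panel:

* **passenger noise** — random, low-amplitude fluctuations;
* **constitutive aberrations** — regions aberrated in nearly every sample,
  which co-occur with everything simply because they are always present.

CNAcooccur scores every pair of genomic loci across a panel of copy number
profiles with a statistic designed to be high only when both loci are
recurrently aberrated *and* vary together across samples.

## The model

### From probes to a genomic grid

Array probes are irregularly spaced, and pairwise analysis at probe
resolution scales quadratically with probe count. All computation therefore
happens on an equally spaced genomic grid (default spacing $\Delta g$ =
20 kb, a lever that trades resolution against memory). For sample $i$ and
grid point $g_j$, the interpolated value is a kernel-weighted regression of
the probe values within $\Delta g$ of $g_j$:

$$a_{ij} = \frac{\sum_{k : |m_k - g_j| < \Delta g} w_k x_{ik}}
                {\sum_k w_k},\qquad
  w_k = 1 - \frac{|m_k - g_j|}{\Delta g},$$

a triangular kernel of width $2\Delta g$ and unit peak. Values are convex
combinations of nearby probe values, so interpolation cannot overshoot, is
exact on constant profiles, and copies the probe value when a probe sits on
a grid point in isolation. Three deliberate conventions (the underlying
method leaves them open):

* grids are anchored at each arm's start coordinate and never cross arm
  boundaries, so the arm-pair decomposition is exact and no signal is
  smoothed across a centromere;
* a grid point with no probe in range is masked and set to 0, keeping all
  downstream minima and covariances finite (the mask is reported);
* a probe at exactly $\Delta g$ receives weight 0 (strict inequality);
  coordinates are 0-based half-open everywhere internally, with BED I/O in
  BED's native convention.

### Gain and loss channels

Positive and negative log2 ratios must not cancel, so the grid matrix $A$
is split into $G_{ij} = \max(A_{ij}, 0)$ and $L_{ij} = \max(-A_{ij}, 0)$.
The channels reconstruct $A = G - L$ exactly and have disjoint support.
Two loci and two channels give four modes: gain–gain, loss–loss, gain–loss
and loss–gain.

### The co-occurrence score

For grid columns $u$ (locus $j$, arm a) and $v$ (locus $k$, arm b):

$$M_{jk} = \sum_t \min(u_t, v_t), \qquad
  C_{jk} = \frac{1}{T}\sum_t (u_t - \bar u)(v_t - \bar v), \qquad
  S_{jk} = M_{jk}\, C_{jk}.$$

$M$ is the continuous AND: it is large only when both loci are aberrated in
the same samples. But $M$ alone is also large for a constitutively
aberrated locus paired with anything recurrent — the classic failure mode.
Weighting by the covariance $C$ suppresses these pairs ($C \approx 0$ when
one member never varies) and drives mutually exclusive pairs negative.
On the four archetypes (random / constitutive-member / co-occurring /
mutually exclusive) the score $S$ singles out the co-occurring pair, while
the bare min-sum cannot distinguish it from the constitutive pair — the
package's acceptance suite checks exactly this contrast.

The covariance uses the population ($1/T$) normalization, matching the
expectation form of the definition; ranking is invariant to the choice, and
`pair_covariance(..., denominator = "sample")` provides the $1/(T-1)$
variant. Negative scores are retained (peak extraction takes maxima, so
they never rank) because they are informative diagnostics for mutual
exclusivity.

### Multi-scale smoothing

Co-occurrence is expected to be spatially smooth, so $S$ is convolved with
a sampled isotropic 2D Gaussian. The kernel's standard deviation $\sigma$
sets the analysis scale, defined as $6\sigma$ (the truncated support: the
kernel is cut at $3\sigma$, i.e. half-width $\lceil 3\sigma/\Delta g\rceil$
grid points). The canonical scales are 2 Mb ($\sigma$ = 1/3 Mb), 10 Mb
($\sigma$ = 5/3 Mb) and 20 Mb ($\sigma$ = 10/3 Mb): small scales resolve
focal events, large scales favor broad, low-amplitude changes.

Before convolution the matrix is padded by mirroring the data about each
boundary *without* repeating the edge sample (row $(a,b,c)$ padded by two
becomes $(c,b,a,b,c,b,a)$); either mirroring convention differs by one
sample and the choice here is fixed and tested. Two further numerical
choices: the kernel is normalized to sum 1 — the rank order of peaks is
unchanged and a flat matrix convolves to itself exactly — and the Gaussian
is separable, so the 2D convolution is computed as two exact 1D passes.
If a padding depth ever exceeds the matrix extent the reflection continues
periodically, with a warning.

### Peaks and ranking

Peaks are extracted greedily: take the global maximum of the convolved
matrix, zero a square neighborhood of half-width $2\sigma$ (the same window
later used to collect genes), repeat until the requested count or no
positive value remains. Greedy extraction with an exclusion window —
rather than strict local-maxima detection — guarantees that reported loci
are distinct; ties break by (row, column) ascending. Per-arm-pair peaks are
pooled, pairs on one chromosome are removed (physical linkage trivially
co-varies), sorted, and truncated to the top $N$ (default 50 for reporting,
500 for network construction). Score ties at ranking break by genomic
coordinates. Statistical significance of individual peaks is out of scope:
a permutation null over all arm pairs is computationally prohibitive, which
is why downstream analyses work with top-$N$ lists.

For a genome of $n$ arms, $s$ scales and 4 modes the pipeline computes
$\binom{n}{2}\, s \cdot 4$ convolved matrices — 8892 for the 39 usable
human autosome arms at three scales. Each task is independent and only one
arm-pair matrix is held in memory at a time.

## Annotation and enrichment

Genes are assigned to a peak locus when their midposition falls within
$\pm\sigma$ of the peak coordinate (boundary inclusive — a deterministic
convention where the method itself is silent). Two enrichment questions are
supported:

* **Cancer-gene categories.** A two-sided Fisher exact test on the 2×2
  table of category membership versus presence on co-occurring loci, over a
  user-supplied gene universe (typically all protein-coding genes in the
  annotation; any category genes absent from the universe are dropped
  first). Two-sided is used throughout for consistency.
* **Functional interactions.** From a generic gene–gene interaction table
  with confidences in $[0,1]$ (e.g. a STRING export), the *interaction
  ratio* is the fraction of genes on co-occurring loci that take part in at
  least one cross-locus interaction above a confidence threshold (default
  0.9, exclusive; within-locus pairs never count). The observed ratio is
  compared with the pooled ratio of random, size-matched locus pairs (arms
  sampled proportional to grid length, default 100 pairs, seeded) by a
  two-sided Fisher exact test on interacting versus non-interacting gene
  counts.

## Networks

The loci of the top co-occurrences (default: top 500 of the smallest
scale) are clustered by genomic distance — same-arm distance is the
absolute bp difference, cross-arm pairs get a constant $10^8$ bp — with
single-linkage clustering cut at $10^7$ bp. The cut is strict (a merge at
exactly the cutoff is not taken) and, since distances are integer base
pairs, implemented by cutting the dendrogram half a base pair below the
cutoff. Clusters become nodes, annotated with the spanned interval
$\pm\sigma$ and the best rank among member loci; edges count the
co-occurrences linking loci of two different clusters; within-cluster
co-occurrences are dropped and reported. The *core network* keeps edges
supported by at least 5% of the co-occurrence list — with 500
co-occurrences, support 25 is retained and 24 removed — and discards
isolated nodes.

## The simulator

`simulate_dataset()` generates probe-level log2 tables on arbitrary arm
definitions: probes at a fixed spacing with integer positional jitter
strictly below half the spacing (so probes and grid never align, and the
triangular-kernel regression is exercised nontrivially), baseline 0,
planted lesions of chosen sign/amplitude/carrier fraction, i.i.d. Gaussian
noise. Lesions sharing a `group_id` are planted in identical carriers,
which is how co-occurrence is planted; a `purity` parameter can scale
amplitudes but defaults to 1, appropriate for clonal cell lines. The noise
model is deliberately minimal: no allele-specific signal, GC waves,
segmentation artifacts or tumor-cell admixture. Passing tests on these
data shows the scoring machinery recovers planted covariance structure at
realistic amplitude-to-noise; it does not certify performance on raw array
data, whose artifacts the simulator does not emulate.

`lineage_scenario()` is the package's positive-control configuration,
emulating lineage-specific programmed co-deletions (as V(D)J recombination
produces at T-cell receptor loci in T-cell malignancies and immunoglobulin
loci in B-cell malignancies): 60 samples split into two lineages, lineage A
carrying co-deletions at two loci on two arms and lineage B at three loci
on three arms, deletion length 2 Mb, amplitude 1, noise sd 0.2
(amplitude/noise = 5), on a compact four-arm, 12 Mb-per-arm genome kept
small enough that a 20-replicate recovery experiment runs in a couple of
minutes. Within-lineage pairs are perfectly co-occurring; cross-lineage
pairs are mutually exclusive and must never rank. The acceptance suite
requires the two top-ranked loss–loss peaks to fall within $2\sigma$ of
planted within-lineage pairs in at least 95% of 20 seeded replicates.

## Worked example

```{r example, eval = FALSE}
sim <- lineage_scenario(seed = 7)
tracks <- lapply(names(sim$probes)[-(1:2)], function(s)
  probe_track(sim$probes$chrom, sim$probes$pos, sim$probes[[s]], s))
grid <- build_grid(sim$arms, spacing = 20000)
A <- interpolate_dataset(tracks, grid)
ch <- separate_signals(A)
pooled <- scan_arm_pairs(ch$gain, ch$loss, "loss-loss", sigma_bp = 2e6 / 6)
rank_global(pooled, n_top = 4)[, c("arm_a", "pos_a", "arm_b", "pos_b",
                                   "score", "rank")]
```

On seed 7 the four top-ranked peaks recover the four planted within-lineage
pairs (see the README for the printed output). `run_pipeline()` wraps the
same steps, adds enrichment and network construction, and writes TSV/BEDPE
peak lists, enrichment reports and GraphML/SIF networks.

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `spacing` | 20 kb | grid resolution; memory/accuracy lever |
| `scales` | 2, 10, 20 Mb | kernel support $6\sigma$; expected lesion size |
| `top_n` | 50 | reported peaks per (mode, scale) |
| `network_top_n` | 500 | co-occurrences fed to clustering |
| `interaction_threshold` | 0.9 | confidence cutoff, exclusive |
| `cluster_cutoff_bp` | 10 Mb | single-linkage cut, strict |
| `off_arm_distance` | 1e8 bp | cross-arm distance constant |
| `core_fraction` | 0.05 | minimum edge support fraction |
| `n_random` | 100 | random locus pairs in the control |

## Known limitations

* The gain–loss and loss–gain modes are computed separately; when a single
  combined list is wanted the caller merges them (the direction is in the
  `mode` column). No canonical merge rule is imposed.
* Peak lists carry no p-values; interpretation rests on ranks and on the
  enrichment analyses.
* The kernel is isotropic; differently sized co-occurring lesions (an
  ellipsoid kernel) are not modeled.
* Raw array preprocessing (normalization, segmentation, ploidy correction)
  is upstream of this package.
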