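---
title: "Methods: models, parameters and design choices in tfbindevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in tfbindevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfbindevo)
```

`tfbindevo` reimplements, as a tested pipeline, the comparative analysis of
tissue-specific transcription-factor (TF) binding across five closely
related mouse taxa (C57BL/6J, A/J, CAST/EiJ, SPRET/EiJ, Caroli/EiJ) and rat,
for the liver master regulators CEBPA, HNF4A and FOXA1 with CTCF as a
control.  Because the underlying ChIP-seq primary data are not an input to
this package, every stage is driven by a synthetic-data generator whose
parameters are set to the summary statistics that the study design
prescribes, giving each analysis stage a parameter-recovery test with known
ground truth.  This vignette records the models, the tunable parameters
(with units and defaults), and the design decisions that were genuinely
open, including the numerical choices that matter.

## 1. TF-bound regions and cross-species sharing

A TF-bound region (TFBR) is a pooled-sample peak called in both biological
replicates (`define_tfbrs()`, condition `"Inter-pool"`).  Coordinates are
0-based half-open (BED convention) throughout; narrowPeak summit offsets
follow the ENCODE convention, with the interval midpoint as fallback when
the offset is $-1$.  Peaks are strandless; only motif scanning is
strand-aware.  Intensities are untransformed enrichment scores at I/O time;
all log transforms happen downstream.

Cross-species comparison projects anchor intervals through an orthology map
of colinear, equal-length, non-overlapping blocks.  When an interval spans
several blocks, only the portion in the block with the largest intersection
is projected — a deterministic, conservative policy appropriate for genomes
with few large-scale rearrangements.  A projected anchor peak is `shared`
when it overlaps a same-TF partner peak by at least `min_overlap_bp`
(default 1 bp; ties broken by largest overlap, then leftmost partner),
`unshared` otherwise, and `unalignable` when no block is touched.
Unalignable peaks are excluded from sharing denominators and reported
separately.  The overlap threshold is exposed because no canonical value
exists for "reciprocal overlap"; 1 bp is the most permissive and therefore
the most conservative for claiming *loss*.

## 2. Turnover and the exponential decay fit

The generator's presence model is anchored: every locus exists in the
anchor species and survives in a species that split $t$ million years (MY)
ago with probability $e^{-\lambda t}$, independently per species, with
$\lambda = 0.12$/MY by default — the fitted decay constant of the observed
sharing-versus-divergence relation.  Parameterizing the *anchored sharing*
directly (rather than a per-lineage rate) matches the axis on which the
decay is fitted; a per-lineage mode (`mode = "lineage"`, sharing
$e^{-2\lambda t}$) is available because the two are not distinguishable
from anchored sharing alone.  Gains are off by default so that the fitted
decay targets the injected $\lambda$ exactly; the stationary gain option
depresses anchored sharing when the partner is used as anchor and is
documented as such.

`fit_decay()` regresses $\ln(\text{fraction})$ on $t$ by ordinary least
squares with a free intercept, and reports $\hat\lambda = -\text{slope}$.
The intercept is free because replicate overlap is below 1 even at $t = 0$
(interindividual replicate $R^2$ of 0.76–0.83); an option constrains the
intercept to a replicate-overlap baseline.  A/J sits at $t \approx 0$ and
is excluded from decay fits by default, since a log-linear fit cannot
accommodate it.  Divergence-time defaults are CAST 1, SPRET 3, Caroli 6 and
rat 20 MY, with A/J at 0.5 MY.

## 3. The synthetic-data generator

The generator emulates the *statistical structure* of multi-species liver
ChIP data; it does not emulate read-level artifacts (mappability, genome
assembly quality, GC bias), so passing recovery tests demonstrates the
correctness of the estimators, not robustness to those real-data nuisances.
Loci sit on synthetic chromosomes 1 kb apart with 200-bp peaks; partner
genomes are the anchor shifted by a species offset, so orthology maps are
single identity-plus-offset blocks and projection is exactly invertible.
All randomness flows from one seed through fixed per-stage stream indices
(`sim_seed()`), making every output byte-reproducible.

Key calibrated defaults (all overridable in `sim_config()`):

* `loss_rate = 0.12`/MY, the fitted turnover constant.
* `replicate_noise = 0.69` (log2 units).  Replicate measurements are
  truth $+\,N(0, s)$; with the leaf-intensity mixture variance implied by
  the defaults below, the replicate Pearson $R^2 =
  \left(\sigma_t^2 / (\sigma_t^2 + s^2)\right)^2$ lands mid-way in the
  observed 0.76–0.83 interindividual band.  Peak-level baseline
  intensities are $\log_2 \sim N(8, 1.5)$.
* `cluster_composition = c(0.49, 0.23, 0.18, 0.09)/0.99` over
  1TF/2TF/3TF/multiplicity, counted per bound region.  The printed
  composition sums to 99% (rounding); it is renormalized so the generator's
  class probabilities sum to one.
* `delta_intensity_corr = sqrt(0.4)`: between-species log2-intensity
  changes of co-bound members share a cluster-level factor giving pairwise
  correlation $\rho$, so the co-evolution $R^2$ recovers the typical 0.4.
* `snv_prob_shared = 0.141`, `snv_prob_unshared = 0.312`: motif-SNV
  probabilities at the Caroli distance (the CEBPA values; both exposed as
  the shared/unshared contrast drives the contingency test).
* `ko_retention = list(contains_deleted = 0.66, lacks_deleted = 0.96,
  CTCF = 1)`: knockout retention by cluster relation to the deleted
  factor.
* `regime_mix = c(conserved = 0.50, progressive = 0.05, random = 0.45)`,
  near the observed class proportions.

Cluster geometry guarantees unambiguous truth: member summits are 120 bp
apart (every pair within the 300-bp linkage window) and cluster centers
2 kb apart (inter-cluster separation far above the 400-bp minimum needed
for categorization to be identifiable).  Motif windows embed the PWM
consensus at the summit so that every anchor locus carries a recoverable
top-scoring site; sampling motif bases from the PWM columns instead is
available (`sample_motif = TRUE`) but makes hit recovery depend on the
scan threshold, conflating generator and scanner in recovery tests.

## 4. Intensity-evolution regimes and their dispersions

Three regimes generate leaf log2 intensities on the mouse clade:

* **conserved** — leaf $=$ base $+\,N(0, \sigma_c)$ with
  $\sigma_c = 0.12$;
* **progressive** — a monotone drift of total size drawn uniformly from
  2–4 log2 units (random sign) accumulates along the backbone lineage, so
  species that split earlier carry older values;
* **random** — i.i.d. $N(\text{base}, \sigma_r)$ per species with
  $\sigma_r = 1.8$.

The dispersions were chosen once so that the separations dwarf the
classification tolerance $\tau$ (below): $\sigma_c \ll \tau$,
$\sigma_r \gg \tau$, and the minimum progressive drift (2) is several
times $\tau$.  Under these settings the classifier recovers at least 90%
of each regime's labels at $n = 5{,}000$ loci, measured against generator
truth.

## 5. Wagner parsimony and trajectory classification

Ancestral intensities at the four mouse ancestors (A1, the C57BL/6J–A/J
ancestor, through A4, the mouse-clade root) are reconstructed by
continuous Wagner (L1) parsimony.  The Farris downpass gives each node an
interval: the intersection of its children's intervals when non-empty (no
cost), otherwise the closed gap between them, adding the gap width to the
cost.  The total cost is the exact minimum of $\sum |parent - child|$ over
all internal assignments — verified against exhaustive enumeration in the
test suite — and branch lengths are ignored (unweighted Wagner parsimony;
a branch-length-weighted variant was considered and rejected because the
classification below is deliberately about *shape*, not rate).

**Point estimates.**  L1 reconstructions are not unique, and the choice of
point estimate within the optimal intervals matters more than is usually
appreciated.  The textbook uppass — root at its interval midpoint, each
descendant snapped to the point of its interval closest to its parent's
estimate — has a structural property on a pectinate (caterpillar) tree
like this one: every snap lands exactly on the child-interval boundary
that the parent approached, so the resulting ancestor sequence A4→A1 is
always monotone.  A classifier reading those estimates can therefore
*never* observe a non-directional trajectory, and the random class
vanishes by construction.  `tfbindevo` instead uses tip-proximal
estimates: each internal node takes the point of its Farris interval
closest to the downpass midpoint of its smaller (more recently diverged)
child subtree — on this tree, the value carried by the taxon splitting at
that node — and balanced ties (the A1 cherry) take the interval midpoint.
This keeps successive ancestral estimates from inheriting each other's
values, so non-directional leaf patterns reconstruct as non-monotone
trajectories while genuinely directional drift still reconstructs as
monotone.  The reported cost is unaffected (it is the exact L1 minimum
either way), and all estimates remain inside their optimal intervals,
which quantify the reconstruction uncertainty.

**Classification.**  With ancestors ordered root-to-recent
(A4, A3, A2, A1) and tolerance $\tau = 0.585$ log2 units (1.5-fold;
configurable — results are robust to this choice over a wide range):

* *conserved*: ancestral spread $\max - \min \le \tau$;
* *progressive*: the sequence is monotone (non-strict) **and**
  $|A1 - A4| > \tau$ (for a monotone sequence the spread equals the net
  change, so the two classes are mutually exclusive by construction);
* *random*: neither;
* *undetermined*: moving the midpoint-convention estimates to their
  interval endpoints flips the conserved decision — the ancestral spread
  genuinely straddles $\tau$ within the reconstruction's freedom.  Only
  the similarity boundary is checked: directional disagreement between
  alternative reconstructions reflects estimator freedom on wide
  intervals, not data ambiguity, and flagging it would swallow a tenth of
  the random class; such loci resolve to random through the "neither"
  rule.  Under generator defaults, under one percent of loci are
  undetermined.

Intensities are log2-transformed and per-species median-normalized before
reconstruction, removing global enrichment-scale differences between
experiments without touching locus-level structure.

**Permutation null.**  `randomization_null()` permutes each species'
intensity column independently across loci, re-runs reconstruction and
classification, and reports the enrichment p for conserved
($p = (1 + \#\{\text{perm} \ge \text{obs}\})/(n_{perm}+1)$) and depletion
p for progressive and random.  The statistic is a class *fraction*, hence
discrete: when the conserved fraction is nearly degenerate (e.g., zero
under very dispersed null data) ties make the p conservative and pile it
near 1.  The calibration test therefore draws null data with a dispersion
giving a non-degenerate conserved fraction and enough loci for fine
granularity (2,000 loci, $\sigma = 0.6$), where the p is uniform to the
resolution a Kolmogorov–Smirnov test at 200 replicates can see.

## 6. Motifs, SNVs and the exact test

Motif scanning is plain log2-odds scoring against a background (uniform
0.25 by default) on both strands, with a pseudocount of 0.01 per PFM cell
and windows containing `N` skipped.  The default hit threshold is 60% of
the maximal attainable score; no canonical threshold exists, and the value
only gates which loci enter motif-level analyses.  For the SNV analysis
the above-threshold hit nearest the summit is chosen (ties: higher score,
then `+` strand), the footprint is judged on the anchor species, and
aligned partner bases are compared within it; indels are out of scope
(sequences must be equal-length gapless alignments).  The per-SNV score
change decomposes additively: $\Delta = \sum \log_2(p_{pos,new} /
p_{pos,old})$, with the background cancelling position-wise.

The shared/unshared × SNV/no-SNV contingency is tested with a two-sided
Fisher exact test computed by the point-probability method — summing
hypergeometric point probabilities not exceeding the observed table's —
which matches the convention of standard statistical software.
Probabilities are accumulated in log space so the $p < 10^{-15}$ regime of
the knockout contrasts neither underflows nor loses the log-p.  The sample
odds ratio gets a 0.5 continuity correction (flagged) only when a cell is
zero.

## 7. Co-binding clusters, fates and co-evolution

Clusters are single-linkage components of "summit distance ≤ 300 bp",
anchored on summits rather than region boundaries because summits are the
best-localized coordinate (the window is configurable).  On one axis this
reduces to chaining sorted summits, which the tests verify against a
quadratic transitive-closure oracle.  Classes: singleton (1TF), two or
three distinct factors (2TF/3TF), and multiplicity (MULTI) when any factor
repeats.  Fates against a partner species are evaluated member-wise with
the same sharing machinery as the pairwise divergence analysis — by
design, so cluster-level and genome-wide sharing numbers cannot drift
apart — and read from the anchor TF's viewpoint: `shared`, `part_shared`
(a co-bound partner missing), `part_unshared` (the anchor missing),
`totally_unshared` (no member bound).

Co-evolution takes, within 2TF/3TF clusters whose factor pair is shared
with the partner species, the per-member change $\Delta = \log_2 I_{partner}
- \log_2 I_{anchor}$ (median-normalized per species) and reports the
Pearson correlation per factor pair.  Pairs with any unshared member are
excluded, matching the analysis the co-evolution claim is based on.

## 8. Knockout destabilization

`retention_by_class()` reports, per cluster class (CH, CF, HF, CHF in
CEBPA/FOXA1/HNF4A initials) and assayed factor, the fraction of wild-type
peaks with an overlapping KO-condition peak.  Knockout completeness is a
QC gate: more than 20% self-retention of the deleted factor's own peaks
flags the report (the threshold is a convention; a validated knockout
shows near-complete loss).  Because the percentages could count either
clusters or member peaks, both are reported (`per_member`, the default
reading, and `per_cluster`).  The containing-versus-lacking contrast per
assayed TF uses the same log-space exact test as the motif module.
Intensity-stratified retention (quantile bins within class, bootstrap CI
on the top-minus-bottom difference) checks that differential intensity
does not explain the losses, and `evo_ko_concordance()` contrasts matched
versus mismatched knockouts for clusters whose cross-species loss is
attributable to exactly one factor's motif.

## 9. Orchestration and reproducibility

`run_pipeline()` executes simulate → TFBR → share → decay → motif →
cluster → co-evolve → ancestry → knockout from one configuration (list or
YAML), writes per-stage outputs in the package's text formats, and ends
with a manifest carrying a canonicalized config hash (stable under key
reordering), the seed, and per-stage row counts and wall-clock.  Identical
seed and configuration give byte-identical stage outputs.  The package's
functions are the programmatic interface; the pipeline runner is the
single entry point an end-to-end user needs, and each stage is equally
callable on its own.

## 10. Problem sizes and limitations

The shipped tests run the generator at 5,000–30,000 loci (decay-rate
recovery averages 20 independent runs of 10,000 loci per divergence
point), sizes at which binomial error bounds are tight enough to make the
recovery claims meaningful while the whole suite stays interactive on a
single core.  Known limitations: orthology maps are the block-TSV dialect
(no chain/net parsing); projections keep only the largest-block portion;
indels in bound motifs are not modeled; the generator does not simulate
read-level biases, genome-quality differences between species, or
gain-of-binding processes by default; and reconstruction includes only the
mouse clade — the rat outgroup is used for divergence, not for ancestral
inference.
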