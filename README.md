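# tfbindevo

Comparative analysis of tissue-specific transcription-factor (TF) binding
across closely related species, for researchers studying the evolution of
gene regulation from multi-species ChIP-seq designs.  The package covers
the full analysis chain for a five-mouse-plus-rat liver study design
(CEBPA, HNF4A, FOXA1, with CTCF as control):

* **TFBR definition** — reproducible TF-bound regions as pooled peaks
  supported by both biological replicates ("Inter-pool").
* **Cross-species sharing** — projection of bound regions through block
  orthology maps, shared/unshared/unalignable calls.
* **Turnover-rate estimation** — anchored sharing decays with divergence
  time *t* as *e*^(−λt); λ is estimated by ordinary least squares of
  ln(sharing) on *t*.
* **Motif–SNV attribution** — PWM log-odds scanning on both strands, the
  above-threshold hit nearest the peak summit, SNVs inside its footprint,
  and the shared/unshared × SNV Fisher exact test computed by log-space
  hypergeometric summation (valid far below p = 10⁻¹⁵).
* **Combinatorial clusters** — single-linkage categorization of 1TF / 2TF
  / 3TF / multiplicity binding within a 300-bp summit window, cluster
  fates across species, and co-evolution of co-bound intensity changes
  (correlation of per-member Δlog₂ intensities).
* **Ancestral trajectories** — continuous Wagner (L1) parsimony on the
  fixed mouse phylogeny via the Farris interval algorithm (exact minimum
  of Σ|parent − child|), classification of each locus as conserved /
  progressive / random / undetermined, and a within-species permutation
  null for class enrichment.
* **Knockout destabilization** — retention of co-bound partner peaks after
  genetic deletion of one factor, by cluster class, with exact-test
  contrasts, intensity-stratified controls and evolution–knockout
  concordance.

Every stage is driven by a synthetic-data generator (`sim_config()`,
`simulate_*()`) with full ground truth, calibrated to the study design's
summary statistics, so each estimator has a parameter-recovery test.

## Worked example

Simulate binding-site turnover at λ = 0.12/MY for 10,000 anchor loci,
measure anchored sharing against each partner species, and re-fit the
decay constant:

```r
library(tfbindevo)

cfg <- sim_config(n_loci = 10000, seed = 42)
tv  <- simulate_turnover(cfg)
partners <- c("CAST", "SPRET", "CAROLI", "RAT")
sh <- do.call(rbind, lapply(partners, function(sp)
  sharing_fraction(tv$peaks$C57BL6J, tv$peaks[[sp]], tv$maps[[sp]],
                   divergence_my = cfg$divergence_times[[sp]])))
sh[, c("partner_species", "divergence_my", "n_shared", "fraction")]
#>   partner_species divergence_my n_shared fraction
#> 1            CAST             1     8879   0.8879
#> 2           SPRET             3     6997   0.6997
#> 3          CAROLI             6     4892   0.4892
#> 4             RAT            20      890   0.0890

fit_decay(data.frame(t = sh$divergence_my, fraction = sh$fraction))
#> decay_fit: lambda = 0.1212 /MY (se 0.0003), intercept = 0.0065, R^2 = 1.000, n = 4
```

Sharing falls to about half at the 6-MY (Caroli) distance, and the fitted
decay constant recovers the injected 0.12/MY.  Continuing with intensities
and ancestral reconstruction:

```r
it <- simulate_intensities(tv, cfg)
cor(it$rep1[, "C57BL6J"], it$rep2[, "C57BL6J"])^2
#> [1] 0.809        # replicate R^2, inside the 0.76-0.83 band

X <- normalize_log2(2^it$log2[, MOUSE_SPECIES])
prof <- ancestral_profiles(X, mouse_clade(build_study_phylogeny()))
round(prop.table(table(prof$class)), 3)
#>    conserved  progressive       random undetermined
#>        0.495        0.079        0.419        0.007
```

The recovered class fractions track the generator's regime mixture
(50% conserved / 5% progressive / 45% random); the small shifts come from
loci near the classification tolerance.  An end-to-end run of all nine
stages (simulate → TFBR → share → decay → motif → cluster → co-evolve →
ancestry → knockout) with per-stage output files and a manifest:

```r
run_pipeline(default_pipeline_config(outdir = "demo_run", seed = 1))
```

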