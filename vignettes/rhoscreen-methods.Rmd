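---
title: "Models and methods behind rhoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rhoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhoscreen)
```

# The experimental system

`rhoscreen` analyzes (and simulates) pooled shRNA screens of embryonic
skin morphogenesis.  A lentiviral library — 999 hairpins targeting 166
Rho GTPases and their regulators (20 GTPases, 77 GEFs, 66 GAPs, 3 GDIs,
at least 5 hairpins per gene) plus 20 scrambled controls — is injected
into the amniotic sac at E9.5, transducing the single-layered surface
ectoderm at MOI ≤ 1.  At E18.5 the epidermis and the dermal fraction
containing the hair follicles (HFs) are separated enzymatically; because
only surface epithelial progenitors are transduced, the integrated
hairpins sequenced from the dermal fraction report specifically on HF
cells.  Hairpins whose knockdown impairs HF morphogenesis are depleted
in the HF fraction relative to the starting library; hairpins whose
knockdown favors it are enriched.

# Coverage design

Each embryo carries ~120,000 surface progenitors at injection.  Only
~15% can be transduced while keeping MOI ≤ 1, and ~10% of transduced
founders end up contributing to HFs, so one embryo yields about
`120,000 × 0.10 × 0.15 = 1,800` transduced HF founders —
`hf_founders_per_embryo(120000, 0.10)` returns the 12,000 future HF
progenitors present at injection time.  For a 1,000-hairpin library at
a 100-fold founder coverage target,

```{r}
coverage_design(library_size = 1000, target_coverage = 100,
                progenitors_per_embryo = 120000,
                hf_founder_fraction = 0.10, transduction_rate = 0.15)
```

so 56 embryos suffice and the 60 actually pooled per replicate leave
headroom.  `min_embryos_for_coverage()` is the ceiling of
`library_size × coverage / founders_per_embryo` and is monotone in each
argument in the expected direction.

# The generative model of the simulator

The simulator reproduces the screen's statistical structure — it is the
ground-truth source for every power and error-control claim the test
suite makes.

Per embryo: the number of transduced founders is
Binomial(120,000, 0.15).  Each founder receives one hairpin uniformly at
random (MOI ≤ 1), commits to the HF fate with probability 0.10, and
founds a clone whose E18.5 size is negative-binomial with mean
40 × *e* and dispersion (size) parameter 2, where *e* is the gene's
multiplicative fitness effect in that founder's fraction (1 for neutral
genes and all scrambled controls).  The mean of 40 cells per founder is
the printed expansion estimate; the paper-scale data do not constrain
clone-size dispersion, so we chose a moderately overdispersed law
(size 2 gives a clone-size CV of ~0.7) once, as representative of real
clonal growth variability, and did not revisit it.

Per replicate, 60 embryos are pooled.  Because founder counts are
i.i.d. across embryos and a sum of negative binomials with common mean
scale is again negative binomial with summed size, `simulate_screen()`
pools founder counts first and draws one clone-total per
hairpin × fraction cell — distributionally identical to per-embryo
simulation and an order of magnitude faster.  Clone totals are drawn as
`qnbinom(runif(·))`, so coupling the seed across effect settings yields
an exactly monotone response to the effect size; the test suite uses
this coupling to verify monotonicity.

Sequencing: each sample's cell tallies (a uniform library for the t0
in vitro reference) are multiplied by per-hairpin gamma noise with mean
1 and shape 100 (CV ≈ 10%), then sampled to `reads_per_sample`
(default 10^6) reads by a multinomial draw.  The gamma factor models
amplification jackpotting across the 28 PCR cycles; its magnitude was
set to be consistent with the study's own observations that
pre-amplification and sequencing did not bias hairpin quantification
and that biological replicates correlate at Spearman R² ≥ 0.97.  The
printed "~4,000-fold" E18.5 representation figure is not derivable from
the other printed quantities, so the simulator reports its achieved
coverage (`attr(ct, "achieved_coverage")`, ~108 HF founders per hairpin
at defaults) rather than asserting it.

What the simulator does *not* model: spatial structure (placode
clustering, HF waves), differences in expansion between the EPI and HF
lineages (the printed estimate does not distinguish them; both use the
mean of 40), lineage trees, and dissection/separation errors.  Passing
tests therefore demonstrate the statistical machinery under the
screen's sampling design, not robustness to spatially structured
artifacts.

# Fold changes and hit calling

`normalize_log2fc()` converts counts to counts-per-million, adds a
prior of 0.5, and takes log2 ratios against the t0 sample.  CPM makes
the statistic exactly invariant to sequencing depth (a global
multiplicative factor on any sample's counts cancels identically); the
prior keeps E18.5 dropouts finite — a hairpin absent from the dermal
fraction is a biological depletion and must stay in the analysis,
whereas a hairpin with zero reads in *every* sample carries no
information and is discarded by `filter_zero()`.  Each sample is then
centered on the median raw log2 fold change of its 20 scrambled
controls (median, not mean, for robustness to outlier controls), which
pins the scrambled median at exactly zero.

`shrna_test()` tests each hairpin's replicate log2 fold changes with a
two-tailed t test and adjusts p values by Benjamini–Hochberg within
each fraction.  Two test structures are provided:

* `"vs_scr"` (default): a pooled-variance two-sample t test of the
  hairpin's replicates against the pooled replicate values of all
  scrambled controls in that fraction (60 reference values in a
  triplicate screen; a scrambled hairpin is compared with the other 19
  controls).
* `"one_sample"`: the hairpin's replicates against zero.

The default deserves a note, because the design was genuinely open.
With triplicates the one-sample test has 2 degrees of freedom, and its
two-sided p value at |t| = 17 is still ~0.003; the BH step-up at a 10%
FDR over 999 tests requires p ≤ 0.0001·k at rank k, which such p values
essentially never reach.  The one-sample reading therefore has
near-zero power at this screen's scale no matter how strong the
effect — it cannot have produced a 68-candidate screen.  Pooling the
scrambled controls restores ~61 degrees of freedom, gives genuine
4-fold effects vanishingly small p values, and matches the logic of
normalizing to the scrambled controls in the first place.  Both
variants remain available (`test_variant =` in `screen_analysis()`).

`call_gene_hits()` encodes the candidate rule: a gene is called in a
fraction when at least 2 of its hairpins (configurable) show a ≥ 2-fold
change in the same direction, each supporting hairpin is significant
(raw p < 0.05 **and** BH q < 0.10 — the conjunction is the stricter
reading of the two printed statements of the threshold), and no other
hairpin of the gene crosses 2-fold in the opposite direction.
`classify_candidates()` assigns Venn classes across fractions and flags
HF-specific candidates: genes called in the HF fraction whose gene-mean
|log2FC| in the epidermis stays below 1 (i.e. under 2-fold; "not
dramatically selected" is not quantified in print, so the threshold is
exposed as `epi_neutrality_threshold`).

Under the global null the full pipeline makes essentially no gene calls
(the acceptance suite measures 0% empirical FDR over 50 simulated
screens), and planted 4-fold HF depletions are recovered at ≥ 9 of 10
genes per seed.

# Competition assay

`simulate_competition()` models the two-color pilot: founders receive
the neutral GFP-scrambled or the RFP-test virus with equal probability,
clones expand as above (test effects applied to RFP only), and each
embryo reports `(final RFP/GFP) / (initial RFP/GFP)` per fraction.
A neutral test hairpin gives a mean ratio of 1; embryos with zero GFP
cells in a fraction are excluded with a warning.  `competition_ratio()`
computes the same normalization for measured flow-cytometry counts.

# Morphometrics

All morphometric inputs are measurements (angles, line profiles, label
masks); segmentation is upstream and out of scope, and synthetic
generators (`sim_cortical_profile()`, `sim_voronoi_mask()`,
`sim_adhesion_mask()`) provide test inputs with known truth.

*HF orientation*: angles are measured against the anterior–posterior
axis (0° = perfect A-P alignment) in (−180, 180]; histograms use
left-open bins so the circle tiles exactly, and distributions are
compared with the two-sample Kolmogorov–Smirnov test.  Follicles are
perpendicular when their growth axis lies within 15° of the skin
normal (the cutoff is not printed; 15° is our default, inclusive at
the boundary and configurable).

*Planar cell polarity*: a cell is polarized when its cortical CELSR1
profile shows two opposing domains.  Operationally: smooth the profile
circularly (~7.5° window), require the two strongest local maxima —
after non-maximum suppression at 60° so one noisy domain cannot count
twice — to exceed the profile median by 0.2 (normalized units) and to
sit 180° ± 30° apart.  All three constants are exposed.  The polarity
axis is the doubled-angle mean of the two refined peak directions,
reported in (−90, 90] with 0° meaning domains on the A-P axis; the
classification is rotation-covariant.  On noisy von-Mises double-peak
profiles the planted axis is recovered within a fraction of a degree.

*Profiles and shapes*: line-intensity profiles are rescaled to the unit
interval and averaged in 20 equal bins, which normalizes cells of
different sizes while preserving the overall mean exactly for equally
spaced samples.  Label masks yield per-cell pixel-count areas, field
density, and heights as projection extents.  Focal adhesions are
8-connected components of a thresholded mask, kept when their area is
at least 0.3 µm² — the bound is inclusive, following the printed size
range "0.3 ≤ ∞".

# BioID filter

`filter_interactome()` applies the replicate-presence rule: a protein
belongs to the bait's proximity interactome when detected (count > 0)
in at least 2 of the 3 bait replicates and in none of the control-bait
samples.  Both thresholds are arguments; output order (descending
summed counts, alphabetical ties) is fixed for determinism.  Because
"frequency" in an interactome cloud can mean spectral counts or
replicate counts, `interactome_frequencies()` reports both
normalizations.

# Numerical and scale choices

Simulated screens in the test and acceptance suites use the full
999-hairpin library at 10^6 reads per sample; 50 null screens plus a
20-seed recovery study run in well under a minute each on one core.
The per-hairpin t statistics are computed in closed form (vectorized)
rather than via 1,998 `t.test()` calls; the suite cross-checks them
against `stats::t.test` on fixtures.  The Mann–Whitney branch of
`normality_dispatch()` uses the exact null distribution for groups of
size ≤ 8 and the midrank normal approximation otherwise.  All
simulation entry points take a single seed from which any substreams
are derived, and equal seeds give byte-identical outputs.

# Known limitations

* The simulator's t0 sample is uniform; real libraries have dispersed
  representation, which inflates replicate rank correlations relative
  to our null simulations.
* Epidermal effects do not propagate into the HF lineage; in vivo, an
  early clonal-growth defect would also reduce HF representation.
  HF-specific classification on real data therefore deserves the
  epidermal-neutrality screen more than the simulations suggest.
* The one-mismatch rescue in `count_hairpins()` gives exact matches
  precedence and discards ambiguous (≥ 2 neighbor) segments rather than
  assigning them.
* Angle handling is planar; 3-D follicle axes enter only through
  `classify_follicle_growth()`.
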