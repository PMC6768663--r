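# rhoscreen

Design, simulation and analysis of in utero pooled shRNA morphogenesis
screens.

Pooled RNAi screens of embryonic skin follow lentivirally transduced
epidermal progenitors into the epidermal and hair-follicle (HF)
fractions at E18.5: hairpins whose target genes are needed for HF
morphogenesis are depleted among the integrated inserts sequenced from
the HF fraction, relative to their t0 library representation and to
scrambled (Scr) controls.  `rhoscreen` provides the full desk-side
toolchain for such screens, for the screen designer as much as for the
analyst:

* **Coverage/power design** — how many embryos per replicate are needed
  so every hairpin is carried by ≥ C transduced HF founders, given the
  per-embryo progenitor count, transduction rate and HF fate fraction.
* **Simulation with ground truth** — a clonal founder-expansion model
  (binomial transduction at MOI ≤ 1, Bernoulli HF fate, overdispersed
  clone growth with per-gene fraction-specific fitness effects, embryo
  pooling, gamma PCR noise, multinomial sequencing), plus the two-color
  GFP/RFP competition assay and a FASTQ emitter.
* **Quantification** — barcode demultiplexing, trimming each read to
  its 21-nt hairpin, exact or one-mismatch dictionary matching, and the
  zero-read filter.
* **Hit calling** — scrambled-normalized log2 fold changes versus t0
  (log2 CPM + 0.5, median-of-Scr centered), per-hairpin replicate
  t tests with Benjamini–Hochberg FDR control at 10%, and the gene
  rule: ≥ 2 hairpins at ≥ 2-fold in the same direction, each
  significant, none opposing — then Venn classification across
  fractions and HF-specific candidate flagging.
* **Companion quantifications** — the two-color competition ratio, the
  Shapiro–Wilk → t-test / Mann–Whitney / Kolmogorov–Smirnov decision
  tree, BioID replicate-presence interactome filtering, and
  planar-cell-polarity / morphometric measurements (HF orientation
  histograms, cortical-domain polarity calling, 20-bin intensity
  profiles, label-mask areas and focal-adhesion morphometry).

The statistical core, per hairpin *i*, fraction *f*, replicate *r*:

    log2FC_ifr = log2( (CPM_ifr + 0.5) / (CPM_i,t0 + 0.5) ) − median_Scr(...)

with gene-level calls requiring ≥ 2 supporting hairpins at
|log2FC| ≥ 1, raw p < 0.05 and BH q < 0.10 (two-sample pooled t versus
the scrambled replicate pool by default; see the methods vignette for
why), and no ≥ 2-fold opposing hairpin.

## Worked example

Simulate the reference screen (999 hairpins, 166 genes, 60 embryos ×
3 replicates) with ten genes planted as 4-fold HF-depleted, then call
hits:

```r
library(rhoscreen)

manifest <- synthesize_manifest(library_composition(), seed = 1)
planted  <- sprintf("Gef%02d", 1:10)
effects  <- effect_spec(planted, epi_effect = 1, hf_effect = 0.25)
counts   <- simulate_screen(sim_params(), manifest, effects, seed = 1)
fit      <- screen_analysis(counts, manifest)
fit
```

```
screen analysis: 999 hairpins tested, 166 genes
  candidates: 10 total (EPI-only 0, HF-only 10, both 0); 10 HF-specific
```

All ten planted genes — and nothing else — come back as HF-only,
HF-specific depleted candidates.  `summary(fit)` adds the replicate
Spearman R² and the candidate table; `coef(fit)` returns per-hairpin
mean log2 fold changes per fraction and `plot(fit)` the EPI-vs-HF
scatter.  The embryo-count arithmetic behind the design:

```r
coverage_design(library_size = 1000, target_coverage = 100,
                progenitors_per_embryo = 120000,
                hf_founder_fraction = 0.10, transduction_rate = 0.15)
```

```
coverage design: 1000 shRNAs at 100x coverage
  1800 transduced HF founders/embryo -> >= 56 embryos per replicate
```

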