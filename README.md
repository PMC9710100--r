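# lncarray

Differential lncRNA/mRNA microarray profiling for two-group designs:
quantile normalization, fold-change/P/FDR filtering, six-way positional
classification of lncRNAs, antisense and lincRNA–neighbor cis-pairing with
direction-concordance statistics, hypergeometric over-representation, and
2^−ΔΔCt qPCR validation — exercised end-to-end on a synthetic-data
generator with planted ground truth.

## The scientific problem

DBA/1 mice model audiogenic seizures and seizure-induced respiratory
arrest (a SUDEP model); C57BL/6 mice are resistant. Comparing brainstem
lncRNA and mRNA expression between the strains (n = 4 arrays per group)
asks which transcripts differ, how the differential lncRNAs sit relative
to coding genes, and whether cis-located lncRNA–mRNA pairs change in the
same direction. This package re-implements that complete analysis as
reusable, tested R functions, for anyone running a two-group array (or
array-like intensity) comparison with lncRNA annotation.

The core operations:

* **Quantile normalization** — every sample column is forced onto the
  common rank-mean distribution: sort each column ascending, average
  across columns at each rank, substitute, restore the input order.
* **Differential expression** — per transcript, FC = ratio of group means
  of normalized linear intensities (reported ≥ 1 with up/down direction),
  Welch t on log2 intensities, Benjamini–Hochberg FDR per RNA class.
  Primary filter FC ≥ 2 & P < 0.05; sensitivity filter FC ≥ 2 &
  FDR < 0.05.
* **Positional classification** — each lncRNA gets exactly one of
  sense_overlapping, intronic, natural_antisense, nonoverlapping_antisense,
  bidirectional (divergent 5′ ends < 1000 bp), intergenic.
* **Cis-pairing** — antisense lncRNA/sense mRNA pairs, and for each DE
  intergenic lincRNA the nearest DE coding neighbor upstream and
  downstream within 300 kb; concordance = fraction of pairs with equal
  direction (frac_up_up + frac_down_down).
* **Over-representation** — upper-tail hypergeometric
  P(X ≥ k | K, n, N) of a DE list against GMT gene sets over the measured
  universe, BH-corrected.
* **qPCR** — 2^−ΔΔCt with reference-gene (GAPDH) normalization and the
  control-group mean set to 1.

## Worked example

The `analysis/` directory is a numbered workflow over the package
(simulate → normalize/DE → classify/pair → enrich → qPCR → summarize),
writing its tables under `results/analysis/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_normalize_de.R
Rscript analysis/03_classify_pairs.R
```

which prints (seed 1, packaged default configuration):

```
simulated 2400 transcripts x 8 samples; 567 annotated transcripts
planted DE: 121 up, 297 down; planted pairs: 115 (79 concordant)
lncRNA: 2000 tested, 264 pass primary (74 up / 190 down), 258 pass sensitivity
coding: 400 tested, 159 pass primary (56 up / 103 down), 159 pass sensitivity
recovery of planted effects under the primary filter: 99.0%
antisense pairs: 10 rows over 10 distinct DE antisense lncRNAs
concordance over 115 pairs: 68.7% concordant (up/up 13.0%, down/down 55.7%; up/down 7.8%, down/up 23.5%)
planted pairs recovered: 115/115
```

Reading this: of 115 planted lincRNA–neighbor pairs every one is
recovered by the DE → classify → neighbor-search chain, and the recovered
direction split (68.7% concordant) reproduces the planted 0.685
concordant fraction; the 99% planted-effect recovery reflects quantile
normalization pinning a handful of extreme-tail effects (see the methods
vignette). The same stages are available as single calls —
`quantile_normalize()`, `de_test()`, `classify_all()`,
`antisense_pairs()`, `lincrna_neighbors()`, `concordance_summary()`,
`hypergeom_enrich()`, `ddct()` — and `run_pipeline("config.yaml")` runs
everything from one declarative file.

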