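---
title: "Methods: two-strain lncRNA/mRNA array profiling with lncarray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-strain lncRNA/mRNA array profiling with lncarray}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncarray)
```

## The analysis

`lncarray` re-implements, as a tested and reusable pipeline, a complete
bulk-microarray comparison of brainstem lncRNA and mRNA expression between
two inbred mouse strains — a seizure-susceptible DBA/1-like "treatment"
group and a C57BL/6-like control group, four animals per group. The
pipeline has seven computational stages:

1. quantile normalization of probe intensities;
2. two-group differential expression (DE) with a fold-change/P filter and
   an FDR-based sensitivity filter;
3. six-way positional classification of lncRNAs against coding
   transcripts;
4. cis-pairing: antisense lncRNA–mRNA pairs and intergenic
   lincRNA–nearest-neighbor pairs with direction-concordance statistics;
5. gene-set over-representation of the DE mRNA lists;
6. qPCR relative quantification by 2^−ΔΔCt and direction concordance with
   the array;
7. descriptive summaries (length/chromosome/category distributions,
   volcano coordinates, clustering orders).

Because the original raw arrays are not needed to exercise any of this
logic, the package ships a synthetic-data generator that plants known
ground truth for every stage; all tests and the acceptance script run
against it.

## Quantile normalization

`quantile_normalize()` implements the literal four-step procedure: sort
each sample column ascending, average across columns at each rank, replace
each value by its rank's mean, and restore the original row order. It
operates on raw linear intensities (the procedure sorts the original
values; the log2 transform is applied afterwards, for testing only).

Ties are not addressed by the four-step text; tied values within a column
receive the average of the rank-means of the positions they occupy, which
makes the output invariant to the arbitrary internal ordering of ties.
The unit tests check the procedure against an independently coded literal
transcription and against `limma::normalizeQuantiles(ties = TRUE)`.

One consequence worth knowing: quantile normalization assumes that most
transcripts are unchanged and that changes are roughly balanced. When a
planted effect sits at the extreme low- or high-intensity tail of a
column, its values are pinned to the shared tail rank-means and the
apparent fold change is compressed. This is a property of the method, not
of this implementation; it is why the planted-effect recovery criteria in
the tests are stated as ≥ 90% rather than 100%, and why the simulated
study keeps differential transcripts a minority of the array.

## Differential expression

For each transcript the fold change is the ratio of group arithmetic means
of normalized linear intensities, reported ≥ 1 with an up/down label
(treatment vs control; equal means tie-break to "up", a fixed and
documented convention). P values come from a Welch unequal-variance
two-sample t-test on log2 intensities — the source analysis does not name
its test, and Welch on log2 is the standard choice for single-channel
array data; the implementation is a vectorized row-wise Welch test,
cross-checked against `stats::t.test` in the unit tests. FDR is
Benjamini–Hochberg (`stats::p.adjust`); lncRNAs and mRNAs are corrected as
separate families by default because they are reported as separate result
sets (`fdr_family = "joint"` switches to one family — the original
correction scope is not recoverable from the published tables).

Two filter regimes are always computed:

* **primary** — fold change ≥ 2 and P < 0.05;
* **sensitivity** — fold change ≥ 2 and FDR < 0.05.

No moderated-variance (empirical Bayes) testing is used; with n = 4 per
group the Welch test is underpowered relative to limma-style moderation,
which is a deliberate fidelity choice, not an oversight.

## Positional classification

Coordinates are 0-based half-open internally; GTF I/O is 1-based
inclusive, BED12 0-based half-open (both via `rtracklayer`). Each lncRNA
is assigned exactly one of six categories by a precedence ladder, ordered
by strength of physical overlap (the source lists no tie-break; this
order mirrors its listing order):

1. **sense_overlapping** — same strand, exon–exon overlap;
2. **intronic** — same strand, no exon–exon overlap, lncRNA exon overlaps
   an intron;
3. **natural_antisense** — opposite strand, exon–exon overlap;
4. **nonoverlapping_antisense** — opposite strand, gene-body overlap
   without exon–exon overlap;
5. **bidirectional** — opposite strand, no overlap, divergent
   (head-to-head) 5′ ends separated by < 1000 bp;
6. **intergenic** — none of the above.

Interpretation choices, made once and flagged: "natural antisense"
requires exon-level overlap (keeping categories 3 and 4 disjoint);
"head-to-head within 1000 bp" means divergent transcription with the gap
measured between the two 5′ ends; "intergenic" is operationalized as "no
overlapping and no bidirectional coding partner" — proximity alone does
not disqualify, which is what feeds the < 300 kb lincRNA neighbor search.
Among multiple qualifying partners the largest overlap (or smallest 5′
gap) wins, ties broken by lexicographic transcript id.

A note on strand symmetry: the four overlap categories depend only on
*relative* strand and survive a global strand flip; head-to-head geometry
does not (flipping both strands turns divergent into convergent), so the
strand-flip property test exempts bidirectional assignments.

The classifier finds candidate partners with
`GenomicRanges::findOverlaps` and is verified, on randomized toy genomes,
against a brute-force checker that literally tests each definition on
integer base-position sets.

## Cis-pairing and concordance

Pairing is restricted to transcripts passing the primary filter, since the
published pair tables count *differentially expressed* antisense lncRNAs
and lincRNAs.

* **Antisense pairs**: lncRNAs in categories 3–4 paired with their
  classified partner; distance 0. A nonoverlapping-antisense lncRNA lying
  wholly inside one intron of its partner is labelled
  `intronic_antisense`, matching the published table's vocabulary.
* **lincRNA neighbors**: for each DE intergenic lncRNA, the nearest DE
  coding gene upstream *and* the nearest downstream within 300 kb each
  yield a pair (one lincRNA can contribute two pairs, as the published
  table shows). Distance is the gap between nearest transcript
  boundaries, not TSS-to-TSS — the published tables list neighbors on
  both sides, which is consistent with a boundary-gap search; the window
  is a parameter. Upstream/downstream is labelled from the lincRNA's
  perspective in its own strand orientation; the convention is recorded
  in the output.

`concordance_summary()` reports the four direction-category fractions
(computed as exact counts over the pair total, so they close to 1 exactly)
and the concordant fraction, which is by construction the up/up + down/down
sum — the identity that also holds in the published percentages
(12.9% + 55.6% = 68.5%).

## Over-representation

`hypergeom_enrich()` is a one-sided hypergeometric (Fisher exact upper
tail) of a gene list against named sets, conditioned on the measured
universe — all transcripts on the array, not the genome — with BH
correction across sets and enrichment score (k/n)/(K/N). The up- and
down-regulated lists are analyzed separately. The original study's
enrichment tool and statistic are unnamed, so the field-default statistic
is used and the published pathway identities are treated as illustrations,
never as test targets; no GO graph topology or live database retrieval is
attempted.

## qPCR quantification

`ddct()` implements 2^−ΔΔCt with an assumed amplification efficiency of
2: technical replicates are averaged per sample, ΔCt = Ct(gene) −
Ct(reference, GAPDH in the emulated design), and relative values are
2^−(ΔCt − mean control ΔCt), which pins the control-group mean to 1 — the
published reporting convention ("control set to 1"). Reference-gene
normalization cancels any per-sample global Ct shift, a property the
tests check explicitly. `concordance_with_array()` then compares qPCR
direction with array regulation per gene.

## The synthetic-data generator

`sim_config()` defaults are the emulated study conditions, chosen once:

| parameter | default | rationale |
|---|---|---|
| `n_samples_per_group` | 4 | the study design |
| `planted_log2fc` | 2 (linear 4) | comfortably above the FC ≥ 2 filter, well inside the published fold-change range (2–326) |
| `noise_sd` | 0.25 log2 units | typical residual SD for array replicates |
| `baseline_log2_mean` / `sd` | 8 / 1.5 | typical single-channel intensity scale |
| `concordant_fraction` | 0.685 | the published concordant fraction |
| `pair_direction_split` | 12.9 / 55.6 / 8.0 / 22.5 | the published four-way direction split |
| planted DE direction skew | 70% down | mirrors the published down-dominance |

Intensities are Gaussian on log2 and exponentiated (log-normal), matching
standard array noise models; the true intensity distribution of the
original arrays is not published, so this is a stand-in, not an
inference. Ct values are defined as offset − log2(abundance) + noise so
the ΔΔCt identity is exact at zero noise.

The toy genome places every planted structure in its own 2 Mb block:
features occupy ≲ 270 kb at the block start, so > 1.7 Mb separates
features of adjacent blocks — comfortably beyond the 300 kb neighbor
window and the 1000 bp promoter window, which keeps every planted
category and pair unambiguous. Far-intergenic plants (the `intergenic`
category count) have no coding gene within 300 kb and yield no pairs;
planted lincRNA–neighbor pairs are a separate knob (`n_linc_pairs`), each
with exactly one DE coding neighbor 20–250 kb away. Pair directions are
planted as exact counts (`round(concordant_fraction * n_linc_pairs)`
concordant), so the recovered concordant fraction is deterministic given
full recovery.

What the generator does **not** emulate: probe-level replicates, spatial
or dye effects, batch structure, multi-isoform loci (planted lncRNAs are
single-exon, classification is per transcript), or correlated noise
between cis-neighbors. Passing tests therefore demonstrate correctness of
the computational procedures under a clean planted-truth model, not
robustness to every artifact of real arrays.

## Problem sizes and numerical choices

The packaged default configuration simulates 400 coding + 2000 lncRNA
transcripts over 8 samples with 115 planted lincRNA pairs — large enough
that DE transcripts stay a minority (so normalization is well-behaved)
and small enough that the full pipeline completes in seconds. The
test-suite property checks use 200 replicate null simulations of 1000
transcripts for FDR control, 100 randomized toy genomes for the
classification oracle, and 50 random matrices for the normalization
oracle.

Numerical conventions: equality of normalized column distributions is
asserted to 1e-9; hypergeometric tail mass to 1e-12 against exhaustive
enumeration; fraction mappings close to 1 exactly because they are
computed from integer counts. Degenerate inputs are contracts, not
surprises: a single-sample matrix normalizes to itself, zero-variance
rows are dropped from clustering with a warning, a zero-noise DE row with
equal means gets P = 1 (and P = 0 when means differ), and empty pair or
gene lists raise explicit empty-input errors.

## Known limitations

* The published headline counts (897 DE lncRNAs / 438 mRNAs) depend on
  the original raw arrays and are not reproduced; the pipeline reproduces
  the *procedures* and the in-paper worked quantities (the concordance
  identity and the distinct antisense lncRNA count).
* Whether the original normalization ran on the linear or log scale, and
  whether FDR was corrected jointly or per RNA class, is not stated in
  the source; the literal linear reading and per-class correction are
  adopted and both are configurable.
* Classification is transcript-level; no collapsing to gene level.
* The concordance statistics are positional and direction-based only; no
  correlation-network coexpression is computed.
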