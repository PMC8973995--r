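---
title: "Methods: fragment typing, DE filtering, target scanning and network inference in trfnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fragment typing, DE filtering, target scanning and network inference in trfnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trfnet)
```

# Scope

trfnet re-implements, as a tested and reusable pipeline, the analysis style
used in small-RNA studies of tRNA-derived fragments (tRFs) and tRNA halves
(tiRNAs) in two-group cell-model designs — typically a stimulated vs
untreated comparison with three replicates per group. The stages are:
fragment classification of small-RNA reads against tRNA references,
CPM-normalised differential expression (DE) with class-specific fold-change
thresholds, miRanda-style target-site prediction on 3'UTRs, anti-correlated
sncRNA–mRNA network construction with hub ranking and transcription-factor
(TF) annotation, hypergeometric gene-set enrichment, and Livak 2^-ddCt qPCR
quantification. Because the raw data of such studies are rarely
re-analysable at desk scale, a synthetic-data generator with planted ground
truth stands in for them; every stage is validated against that truth.

# Fragment taxonomy and classification

Mature tRNAs are 70–90 nt and end in the post-transcriptionally added CCA.
Reads are aligned ungapped and full-length to the mature sequence and to the
precursor 3' trailer, then classified by position and length, first matching
rule winning:

1. trailer compartment, alignment starting at trailer position 0 → **tRF-1**
   (RNase-Z product beginning at the 3' flanking sequence, which carries a
   poly-U run);
2. mature, start 0, 16–28 nt → **tRF-5** (D-loop cleavage product);
3. mature, 3'-anchored, 16–28 nt → **tRF-3** (T-loop product retaining the
   CCA);
4. mature, start 0, 29–50 nt → **tiRNA-5** (5' half from anticodon-loop
   cleavage);
5. mature, 3'-anchored, 29–50 nt → **tiRNA-3** (3' half);
6. mature, strictly internal → **i-tRF**;
7. otherwise unclassified (this includes 14–15 nt and 51+ nt alignments, for
   which the taxonomy defines no class).

Design choices worth spelling out:

* **CCA slack.** "3'-anchored" means the alignment ends within `cca_slack`
  (default 1 nt) of the mature 3' end. The canonical 17-nt Thr-AGT tRF-3
  (`AUCCCAGCGGUGCCUCC`) itself ends in UCC, one base short of the terminal
  CCA, so a zero-slack rule would misclassify the best-characterised
  fragment of this class. The slack is applied symmetrically to both
  3'-anchored classes (tRF-3 and tiRNA-3) — 3'-trimming variability does not
  distinguish fragment lengths.
* **Anticodon-loop check.** The tiRNA definition implies cleavage in the
  anticodon loop, but loop coordinates require structure annotation that
  reference FASTA files usually lack. When `anticodon_start` metadata is
  present and `check_anticodon = TRUE`, tiRNA calls additionally require the
  cut site to fall in `[anticodon_start - 3, anticodon_start + 6)`; the check
  is off by default so that plain references remain usable. The synthetic
  generator always cuts its tiRNA reads inside the loop, so round-trip tests
  hold under either setting.
* **Alignment policy.** Fragments are by definition exact subsequences of
  their source tRNA, so the default allows zero mismatches (a flag allows
  more, served by Biostrings pattern matching). Multi-mapping reads resolve
  deterministically by (fewest mismatches, mature before trailer, smallest
  start, lexicographically smallest reference id).
* **Coordinates** are 0-based half-open everywhere; the mature sequence
  includes the CCA.

Classification is a pure function of (start, end, compartment, reference
length), which the tests exploit: permuting read order never changes a call,
and on noise-free simulated reads the confusion matrix is exactly diagonal.

# Differential expression

Columns are scaled to counts-per-million (each sample sums to 10^6), the
total-normalisation appropriate when features are short RNAs of comparable
length. Per feature, the fold change is `(mean treated + 1) / (mean control
+ 1)` — the unit pseudocount avoids division by zero and makes results
reproducible bit-for-bit — and the p-value is a two-sided pooled-variance t
test on `log2(x + 1)`.

The pooled (Student) test rather than Welch is a deliberate calibration
choice: at n = 3 per group the Welch–Satterthwaite degrees-of-freedom
approximation is markedly conservative (measured type-I ≈ 0.03 at nominal
0.05 on log-normal data), whereas the pooled test holds ≈ 0.047. Pooling
variance at tiny n is also the standard genomics practice. The type-I
property is asserted by simulation in the test suite: under a global null of
2000 features the fraction with p < 0.05 must lie within 0.05 ± 0.015.

Direction calls use the field's class-specific thresholds: mRNAs are `up` at
fold change ≥ 2.0 (or `down` at ≤ 0.5) with p < 0.05; tRF/tiRNAs and miRNAs
use a differential multiple of 1.2 (≥ 1.2 or ≤ 1/1.2), interpreted
symmetrically with the mRNA rule. No multiple-testing correction feeds the
direction call — the raw `p < 0.05` criterion is the convention these
vendor-style pipelines use — but Benjamini–Hochberg q-values are reported
when requested, so the orthodox quantity is always available.

**Composition effects.** CPM normalisation couples features: strongly
one-sided planted effects inflate one group's totals and shift every null
feature's fold change off 1. At the default study conditions (172 up / 34
down of 2000 mRNAs at the 2.0 threshold; 11/24 of 300 miRNAs and 4/16 of 150
tRFs at 1.2) the shift stays well inside the calling windows, so planted
designs are recovered exactly. Tests that freeze *exact* recovery of
one-sided sncRNA plants use a larger universe (600 miRNA / 300 tRF features)
and within-group CV 0.02, sizing the margin to many standard deviations by
construction rather than by seed luck. This is a real property of
total-normalised DE, not an artefact: heavily one-sided regulation moves the
apparent fold change of unregulated features.

# Target-site scanning

Candidate sncRNA binding sites on 3'UTRs are scored with a seed-weighted
local duplex alignment, the scheme popularised by miRanda: the sncRNA is
reversed (3'→5') and locally aligned to the UTR (5'→3'), scoring
complementarity rather than identity. Constants follow the published
miRanda-3.3a defaults and are fixed in `scan_params()`:

| constant | value |
|---|---|
| Watson–Crick match | +5 |
| G:U wobble | +2 |
| mismatch | −3 |
| gap open / extend | −9 / −4 |
| seed positions (from sncRNA 5' end) | 2–8 |
| seed scale | ×4 |
| score threshold | >140 (strict) |

The seed scale multiplies *every* score contribution at a seed position —
substitutions and gap penalties alike, as in miRanda. This matters: with
unscaled, cheaper gaps the scanner can bridge partial seed matches through
1–3 nt gaps and a 17-nt random query hits a random 200-nt UTR above 140 in
roughly one trial in six, destroying specificity. With scaled gaps the
shuffled-query null rate is ≤ 5 hits per 100 trials, which the test suite
asserts. A perfect 17-nt complement scores exactly 190 (7 seed positions ×
5 × 4 = 140 plus 10 positions × 5 = 50), so any planted perfect site of
length ≥ 16 clears the threshold.

All non-overlapping sites strictly above the threshold are reported
best-first: the dynamic program (affine-gap Smith–Waterman, implemented in
C++) is recomputed after masking each reported site's UTR columns, and score
ties resolve to the leftmost site (smallest end column, then smallest query
row). Scores are exact sums of small integer constants, so the tie tests on
doubles are safe. A plain-R re-implementation of the same DP serves as a
brute-force oracle in the tests; the two must agree exactly on random
sequence pairs.

Free-energy (ΔG) filtering, the second stage of miRanda, is deliberately
omitted — score-only selection at the 140 threshold is the published
criterion this pipeline mirrors. One consequence is honest and documented:
the fixed threshold was designed for ~22-nt miRNAs, and longer queries (40–50
nt tiRNA halves) accumulate chance hits at a much higher rate. Networks
built from tiRNA-half regulators are therefore denser than miRNA networks on
random background, which is why the synthetic pipeline plants its
known-answer hub among the miRNAs.

# Network construction

A predicted (sncRNA, mRNA) pair becomes a regulatory edge only when the DE
calls are anti-correlated — regulator up with target down, or regulator down
with target up; `ns` features never enter. The result is a bipartite graph
(igraph) whose nodes carry the feature type, DE p-value and fold change, TF
status (mRNA symbols found in a user-supplied TF list), and degree
recomputed from the edge set. Hubs are regulators ranked by degree
descending, then DE p-value ascending, then id — "highest degree and lowest
p-value", with no centrality variants. Two networks (miRNA–mRNA and
tRF/tiRNA–mRNA) can be merged by node id, with attribute conflicts rejected
rather than silently resolved, and exported as SIF and GraphML for
Cytoscape-style tools. The package ships a nine-symbol TF fixture covering
both six-TF sets used in the overlap tests.

# Gene-set enrichment

For a gene list of size n against a term of size K within a background of
size N, with overlap k, the p-value is the one-sided hypergeometric upper
tail P(X ≥ k). The default mode is the DAVID-style EASE variant, computed
with k − 1 in place of k, so singleton overlaps are never significant; mode
`"fisher"` gives the plain one-sided Fisher exact value and is verified
against `fisher.test` to 10^-12 in the tests. Gene symbols are normalised to
the rat (RGD) initial-capital convention before matching. Terms with zero
overlap are omitted; rows sort by p; the enrichment score is −log10(p); BH
q-values are reported but never filter (the `p < 0.05` convention again).
Gene sets and background are explicit inputs (GMT + symbol list) so results
are independent of any annotation-database version.

# qPCR quantification

The Livak method with amplification efficiency fixed at 2: per sample
ΔCt = Ct_target − Ct_reference; ΔΔCt subtracts the *arithmetic mean* ΔCt of
the calibrator group (the standard Livak formulation, rather than per-sample
pairing); RQ = 2^−ΔΔCt. By construction the geometric mean RQ of the
calibrator group is exactly 1, which the tests assert to 10^-12. Group
comparisons use a two-sided Student t test for two groups and one-way ANOVA
with Tukey HSD for more, matching the validation statistics such studies
report. Ct values must lie in (0, 45) with at least two samples per group.

# The synthetic-data generator

One integer seed governs everything; each operation derives its own sub-seed
deterministically, so outputs are byte-identical across runs and platforms.
The generator emulates:

* **References**: 70–88 nt mature tRNAs ending CCA, anticodon at the
  canonical offset (0-based 33), 30-nt trailers with a poly-U run in their
  first 25 nt. (Lengths are capped at 88 nt so that a 3' half cut in the
  anticodon loop stays within the 50-nt tiRNA window.)
* **Reads**: per-class draws obeying each class's positional rule exactly,
  with optional 3'-adapter suffixes for trimming tests.
* **Expression**: log-normal within-group noise (mean-preserving, CV
  configurable, default 0.05) around planted group means; planted-up
  features have treated/control mean ratio `effect_fold` (default 4),
  planted-down the reciprocal; default planted counts are 172/34 mRNAs,
  11/24 miRNAs, 4/16 tRF/tiRNAs — the Table-1-style design the pipeline is
  meant to recover.
* **UTRs**: i.i.d. uniform nucleotides (200 nt) with perfect
  reverse-complement sites overwritten at recorded coordinates in a
  configurable fraction of DE-mRNA UTRs; a designated hub sncRNA receives a
  configurable share of the plants.
* **Ct tables**: Gaussian Ct noise around fixed baselines with the true ΔΔCt
  added to the treated group's target Ct.

What it does **not** emulate — and hence what passing tests do not show
about real data: sequencing error and quality variation, RNA modifications
(m1A/m3C) that stall reverse transcription, secondary-structure-dependent
cleavage preferences, realistic UTR base composition and conservation,
library-size variation beyond what CPM removes, and any correlation
structure between features. The generator's purpose is planted-truth
validation of the pipeline's logic, not biological realism.

# Numerical choices and degenerate inputs

* Zero-variance expression groups: the t statistic is undefined; the p-value
  falls back to its limit (1 when the group means agree, 0 otherwise).
* All-zero expression columns are an error naming the sample, as is a
  missing reference Ct.
* Alignment, classification and hub ordering break all ties
  deterministically (documented orderings), so reruns are reproducible.
* The scanner validates alphabets strictly (ACGTU only, listing offenders)
  and rejects UTRs shorter than the query and queries outside 15–50 nt.
* Pipeline outputs are hashed (MD5) into `manifest.json`; the run log is
  excluded from hashing so wall-time lines do not break determinism
  comparisons.

# Problem sizes

The test suite and the acceptance script run, as the package's own choice of
desk-scale conditions: 20 tRNA references; 600 classified reads (100 per
class); 2000 mRNA / 300 miRNA / 150 tRF expression features in 3 vs 3
designs; 200-nt UTRs for the DE mRNAs; 100-trial null sweeps for the scanner;
and two full pipeline runs for the determinism check. A full simulated run
completes in well under a minute on one CPU.

# Known limitations

* The score-only site selection (no ΔG filter) over-calls sites for long
  queries; treat tiRNA-half edges as screening-level candidates.
* The DE model is a per-feature t test on normalised intensities; count
  models (negative binomial), batch correction and paired designs are out of
  scope.
* TF annotation is whatever list the user supplies; no regulon database is
  bundled beyond the small fixture used in tests.
* Enrichment reproduces the statistic, not any specific annotation
  database's term lists.
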