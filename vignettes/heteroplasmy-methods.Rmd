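---
title: "Quantifying mitochondrial RNA heteroplasmy in paired oocyte-cumulus samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial RNA heteroplasmy in paired oocyte-cumulus samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heteroplasmR)
```

## The problem

Mitochondrial transcripts within one individual are not uniform: a fraction
of reads at a position can carry a base different from the consensus, either
because the underlying mtDNA is heteroplasmic or because a
post-transcriptional modification (m1A and relatives) derails reverse
transcription and produces an apparent variant with no DNA change. In a
paired design — single oocytes and their surrounding bulk cumulus cells,
across young, adult and aged mice — comparing the *level* of such mtRNA
heteroplasmy between cell types and age groups is informative even when
absolute variant *incidence* is confounded by depth and expression
differences.

heteroplasmR implements that comparison end to end: quality-filtered pileup
from aligned reads, a transparent threshold caller, per-mouse recurrence and
maternal-origin classification, synonymy and region annotation on the mouse
mitochondrial genome, the paired oocyte-cumulus statistics, and a
synthetic-study generator that makes the whole pipeline testable without any
sequencing data.

## The heteroplasmy statistic and its filters

For a sample, position and alternate base, the mtRNA heteroplasmy level is

$$h = \frac{\text{variant read count}}{\text{sequencing depth at the position}}$$

where the depth is always the *quality-filtered* depth (bases surviving the
filters below). A variant is emitted when, at a position:

* quality-filtered depth >= 100 (inclusive),
* the alternate base's frequency >= 1% (inclusive),

with reads contributing only when mapping quality >= 20 and individual
bases only when base quality >= 30. These four thresholds are the analysis
defaults of `filter_config()` and are never hidden elsewhere. Only
single-nucleotide substitutions are modelled: indels and multi-nucleotide
events are outside scope by construction, and soft-clipped or inserted
bases contribute no counts (standard pileup semantics). Whether the
original depth filter was applied before or after base-quality filtering is
not knowable from the analysis description alone; this package uses the
quality-filtered depth throughout, in both the filter and the denominator
of $h$, and documents that as its single definition.

The "consensus" a variant deviates from defaults to the reference genome
base, which is reproducible; `consensus_from_tables()` offers a
majority-vote alternative across the study's samples for users who want
consensus to mean the empirical majority base.

## Study aggregation

**Recurrence.** Sequencing noise makes singleton observations unreliable,
so downstream analysis is restricted to variants detected (h >= 1%) in at
least two samples of the *same* mouse — both oocytes, both cumulus samples,
or one of each. Detection reuses the 1% calling floor: the description of
non-detection in oocytes as "below 1%" supports a single shared threshold.

**Maternal origin.** A recurrent variant found in more than one cumulus
sample of a mouse is classified maternal (somatic tissue carrying it implies
inheritance rather than a germline de-novo event). The strict criterion
(`maternal_min_cumulus = 2`) cannot be satisfied by a mouse with a single
complex, so the relaxed single-cumulus criterion is exposed as a
configuration option rather than silently chosen. Likewise, "more than one
cumulus sample" is read within-mouse; a study-wide reading would be a
different biological claim, and the within-mouse version is the default.

**Paired deltas.** For each complete complex, `delta = h_oocyte -
h_cumulus`, so a negative value means the cumulus cells carry more of the
variant — the predominant direction. Per-variant averages are provided both
including complexes where the variant was absent (Average A) and excluding
them (Average B), since the two conventions answer different questions
(study-wide burden vs level-when-present).

**Bins.** Levels are reported in three bins: below 10%, 10-50%, above 50%.
Boundary values 10% and 50% fall in the middle bin, since the top class is
defined as strictly "above 50%".

**Top variants.** The "most interesting variants" can be ranked by mean
level over detecting samples (`mean_h`) or by mean absolute paired change
(`mean_abs_delta`). The two rules select different sets in general, and
descriptions of such rankings commonly conflate them, so both are
implemented and neither is privileged.

## Synonymy annotation

The packaged gene map follows the standard mouse mitochondrial gene order
(two rRNAs, 22 tRNAs, 13 protein-coding genes, D-loop at 15,443-16,299 on a
16,299 bp reference). The bundled sequence is synthetic — generated with the
base composition of the mouse heavy strand, not the RefSeq chromosome — and
is clearly labelled as such; it supports all coordinate, strand and codon
logic, but not alignment of real reads. Users with the real reference
supply it through `load_annotation()`.

Coding changes are classified under the vertebrate mitochondrial genetic
code (NCBI translation table 2), in which ATA codes for Met and AGA/AGG are
stop codons, so classification under the standard code would be wrong at
exactly the positions this analysis cares about. Every codon is translated
by plain table lookup (no initiator-codon special-casing). Decisions where
the underlying analysis is silent:

* **Overlapping genes** (e.g. mt-Atp8/mt-Atp6, mt-Nd5/mt-Nd6): all hits are
  reported; the primary region class follows the fixed priority
  protein_coding > tRNA > rRNA > D_loop; a substitution is non-synonymous
  if it is non-synonymous in *any* overlapping frame — conservative and
  deterministic.
* **Incomplete stop codons** (genes whose terminal codon is completed by
  polyadenylation, here mt-Co3 and mt-Nd4): the trailing partial codon
  cannot be translated, so substitutions there are flagged with a warning
  and treated as non-coding rather than silently guessed.
* Stop gains and losses count as non-synonymous; the analysis only ever
  uses the binary split.

Correctness is checked exhaustively: for every coding position and every
alternate base, the per-codon classifier is compared against an independent
oracle that mutates the whole gene at the sequence level and translates
complete proteins.

## Statistics

* **One-way ANOVA** across the three age groups, on the pooled per-age
  vectors of call-level heteroplasmy values, separately per cell type (a
  per-sample-mean mode is available). The pairwise follow-ups are the three
  age pairs, corrected as one family.
* **Holm-Sidak step-down**: the i-th smallest of m p-values is adjusted to
  $1-(1-p_{(i)})^{m-i+1}$ with running-maximum monotonicity and clipping at
  1. This variant is not in `stats::p.adjust()` and is implemented
  directly, validated against a literal evaluation of the formula.
* **Paired t-tests** on oocyte vs cumulus levels of top-ranked variants,
  with the sample (n-1) standard deviation — the package uses n-1
  denominators everywhere, as every grouping here is a small sample.
* **Linear fit** of cumulus level on oocyte level over variants observed in
  both members of a complex, reporting slope, $R^2$ and the t-based slope
  p-value.
* **Sister CV**: per variant shared by >= 2 sister samples (same mouse and
  cell type), CV = sd/mean of the levels across all sisters; averaged per
  mouse and then per age group.
* **D-loop cumulative curves**: per age group and cell type, the number of
  D-loop variant observations at or above each threshold in (1%, 100%] — a
  non-increasing step function.

All distribution evaluations go through R's F and t distributions;
closed-form identities (two-group F equals the squared pooled t; $R^2$
equals the squared Pearson correlation) are asserted in the tests at 1e-10
and 1e-12.

## The synthetic study

`simulate_study()` generates the structure the analysis assumes, with
defaults chosen to mirror the study design: 3 age groups (3 weeks, 9 weeks,
12 months), 4 mice per group, 2 complexes per mouse (per-mouse overrides
reproduce designs with 1 or 3 complexes), each complex yielding one oocyte
and one cumulus sample — 48 samples in all.

* **Maternal variants**: Poisson(6) per mouse; positions uniform outside
  the artifact sites; alternate base uniform over the three non-reference
  bases; founder level from Beta(1.2, 12) truncated to [0.05, 0.95], so
  most planted variants sit below 10% with occasional high-level ones,
  while staying comfortably detectable at the default depths.
* **Segregation**: each sample's realized level is drawn from
  Beta$(c\,h_0,\; c\,(1-h_0))$ with concentration $c = 60$ — a standard
  tractable stand-in for bottleneck drift between germline and soma. It is
  generator machinery, not an inference model.
* **Cell-type asymmetry**: cumulus expected levels are scaled by 1.5
  (capped at 0.95), matching the observation that most variants run higher
  in cumulus cells; cumulus depth is 3x oocyte depth.
* **Modification artifacts**: fixed sites with cell-type-specific apparent
  rates, jittered per sample (Beta, concentration 200). Defaults place
  cumulus-elevated sites at 179, 729 (rRNA) and 14131 (tRNA-Glu, rate 0.23
  in cumulus vs essentially absent in oocytes) and an oocyte-elevated site
  at 233 (12S rRNA) — the directional pattern the paired analysis must
  recover. The rates are placeholders within descriptive ranges; no RT
  chemistry is modelled.
* **Counts**: depth per position is negative-binomial (size 20) around a
  per-feature-class mean (oocyte default 2,000-4,000); alternate counts are
  Binomial(depth, h); sequencing error (0.001/base) spreads uniformly over
  the three non-reference bases. At planted and artifact positions the
  planted signal replaces the error draw, so the truth table is exact.

RNG consumption order is fixed and documented in `?simulate_study`, making
every study byte-reproducible from its seed. `emit_alignments()` converts
any base-count table into SAM records (MAPQ 60, base quality 40) whose
pileup under default filters reproduces the table exactly, which is how the
SAM ingestion path is exercised without binary fixtures.

What the generator does *not* emulate: correlated error along reads,
alignment artifacts, expression-driven coverage profiles (coverage varies
only by feature class), library-size differences between sisters, or any
age effect (none is planted, so age-group tests should come back
non-significant on simulated data). Passing recovery tests therefore
demonstrates the pipeline's correctness on its own model assumptions, not
performance on real single-cell RNA-seq.

## Validation set-up and problem sizes

The test suite validates each module against independent oracles:
brute-force per-(position, base) calling on random tables, whole-gene
translation for synonymy (~34,000 substitutions over the packaged map),
sum-of-squares and normal-equations oracles for the statistics, and
determinism/round-trip properties for all serializations. The end-to-end
recovery check runs the full default study (48 samples, whole 16.3 kb
contig) and requires >= 99% recall and precision of planted variants,
>= 95% maternal-classification agreement, and >= 90% correct delta
direction at both artifact sites; these sizes keep the whole suite around a
minute on one core while leaving the binomial error on every checked
fraction far below the margins being asserted.

`scripts/acceptance.R` recomputes the same quantities from scratch on a
fresh simulated study for any seed and writes them as JSON.

## Known limitations

* The threshold caller is deliberately transparent: no strand-bias model,
  no base-quality recalibration, no genotype likelihoods. It implements
  the four stated thresholds and nothing else.
* Origin classification depends on the 2-cumulus criterion and fails open
  (`unclassified`) for mice with a single complex.
* The packaged reference sequence is synthetic; synonymy classes on it are
  internally consistent but not those of the real mouse chrM. All logic is
  reference-agnostic once a real FASTA and gene map are supplied.
* Presence/absence at the 1% floor is sharp: a variant at true 1.0% will be
  "absent" in roughly half of its samples by binomial noise. This mirrors
  the thresholded analysis being reproduced rather than attempting
  censoring-aware estimation.
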