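---
title: "Domain-centric mutation analysis: models, tests and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-centric mutation analysis: models, tests and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domspot)
library(dplyr)
```

`domspot` analyses somatic cancer mutations on the coordinate system of
protein domain families. This vignette explains the statistical models,
the parameters that matter, what the synthetic-data generator does and
does not emulate, and the design choices made where more than one
reasonable option existed.

## The domain-centric view

Protein domains recur across proteins as conserved structural and
functional units. A mutation at a given position of one family member is
expected to have consequences similar to a mutation at the *equivalent*
position — the same multiple-sequence-alignment (MSA) column — of
another member. Pooling a family's mutations on its alignment therefore
aggregates evidence that is invisible gene by gene: a position mutated
twice in each of ten kinases is unremarkable in any one gene and
striking in the family.

Two complementary questions are asked. *Which families* carry more
mutations than expected (enrichment), and *which positions within a
family* concentrate them (hotspots)? Both are asked separately for three
mutation classes — missense, truncating (nonsense and frameshift,
pooled because both abolish the downstream product), and in-frame
indels — and for three datasets: tumour-suppressor (TS) genes, oncogenes
(OG), and all genes. The class and dataset splits matter biologically:
tumour suppressors characteristically accumulate dispersed truncating
mutations (loss of function needs no precision), while oncogenes carry
missense mutations clustered at specific activating positions.

## Mutation classification and mapping

Protein-change strings are parsed with a strict grammar: `V600E`
(missense, two distinct standard residues), `E813*` (stop gain),
`Q1247fs*26` (frameshift, with or without the new-stop offset),
`E746_A750delELREA` / `F113del` (in-frame deletion), `K601insV`
(insertion), `V600delinsGG` (deletion–insertion). Anything else —
including synonymous strings and nucleotide-level notation — is kept as
`unclassified`, counted, and excluded downstream. Records whose stated
reference residue contradicts the proteome, or whose position lies
beyond the protein, are dropped with a message rather than raising an
error: bulk catalogues contain stale records, and one bad row should not
abort an analysis.

Coordinates are 1-based inclusive everywhere (protein residues, domain
boundaries, MSA columns), matching the mutation notation itself (V600E
is residue 600). A mutation maps to every domain instance whose interval
contains its first affected residue; multi-residue indels are anchored
at their first residue. A mutation under overlapping instances of
*different* families contributes to each family — the data would
otherwise be dropped silently — while same-family instances on one
protein may not overlap by construction. The MSA column of a mapped
mutation is the column of the `local_pos`-th non-gap character of its
instance's alignment row; a row that cannot supply it indicates an
inconsistent alignment/domain-table pair and is a hard error.

## The hotspot test

Within one family, dataset and class, let `n` be the total number of
mutations mapped anywhere in the family's alignment and `L` the number
of alignment columns. Under the null hypothesis every mutation lands on
each column with equal probability `p = 1/L`, so the count `k` at a
column is binomial and the evidence against the null is the upper tail

    P(X >= k) = sum_{i=k}^{n} C(n, i) p^i (1 - p)^(n - i),

computed through the survival form of the binomial CDF, which remains
accurate far into the tail (the test suite checks agreement with exact
rational arithmetic to 1e-12 relative error over all `n <= 60`,
`k <= n`, `p` in {1/10, 1/50, 1/200}). Columns are the test unit because
they are the only coordinate shared by all family members; `p = 1/L` is
uniform over columns rather than residues for the same reason.

Only columns with at least `min_count = 2` same-class mutations are
reported ("recorded" hotspots) — a singleton cannot be recurrent.

**Multiple testing.** The Bonferroni denominator `m` counts *every
column of every family* whose class total reaches `min_count` in the
dataset run, not merely the columns that happened to pass the count
filter. The distinction is material: the screen is applied to all
columns, so all of them are implicit tests. Correcting only over the
columns that passed would, under a sparse null (say 10 mutations on 100
columns), leave a lone two-mutation column with `m = 1` and an
unconditional p-value of 0.004 — "significant" in roughly a third of
null families. With `m` counting all columns of analysable families the
procedure is conservative, as the type-I simulations in the test suite
confirm. A per-family correction scope (`correction = "family"`,
`m = L`) is available when families are to be judged in isolation, and
`m_total` can be set explicitly.

Families whose class total is below `min_count` contribute neither tests
nor columns to `m`: they cannot produce a reportable hotspot.

## The enrichment test

"Mutational frequency" is operationalised as mutations per
residue-opportunity. A family's *exposure* is the summed length of its
instances times the number of tumour samples — one number that jointly
normalises for domain frequency (how many instances exist), domain
length, and cohort size. Each tested family yields a 2×2 table

    [ observed,    exposure - observed    ]
    [ background,  bg exposure - background ]

tested with Pearson's chi-square (1 df, no continuity correction). Two
background modes exist: a dedicated background set (e.g. 450 families
unrelated to cancer) pooled into a single background row, and a
genome-wide mode in which each family is tested against all other
families pooled. Bonferroni `m` is the number of families tested per
class; a family is flagged *enriched* only when its corrected p-value is
below alpha **and** its rate exceeds the background rate, so depleted
families are never flagged by the two-sided statistic.

A caveat the user should know: the chi-square approximation is accurate
at Bonferroni-corrected tail quantiles only when expected counts are
adequate (tens, not single digits). With very rare classes —
in-frame indels especially — expected family counts of 1–10 make the
far-tail approximation mildly liberal, and isolated low-count families
can reach nominal significance on two or three observed mutations.
Degenerate tables (a zero marginal) return statistic 0 and p-value 1
with a message rather than an error.

## Comparative analysis

Significant hotspots of the TS, OG and genome runs are intersected at
two resolutions: shared families and shared (family, column) positions.
The seven exclusive regions of the three-set Venn are reported with
explicit member lists; counts always sum to the union. "Co-located"
means *identical* (family, column, class) — no tolerance window, since
alignment columns are already the equivalence classes of positions.
Co-location of an unlabelled protein's genome-run hotspot with an OG
hotspot marks a putative gain-of-function candidate, with a TS hotspot a
putative loss; a column matching both is reported as ambiguous, never
silently resolved.

## Gene classification

The 20:20 rule labels a gene TS when at least 20% of its classified
mutations are truncating, and OG when at least 20% of its missense
mutations recur at a single protein position (the denominator is the
gene's missense count, and the position is a protein residue, not an MSA
column). Genes satisfying both are `both`, neither `neither`.

The domain-composition classifier asks whether TS and OG genes are
separable from their domain content alone. Features are instance counts
per family (counts rather than presence flags — the stronger default,
with a `binary` switch); the learner is pluggable, defaulting to a
linear soft-margin SVM; evaluation is stratified 10-fold
cross-validation with the pooled held-out AUC computed by the
Mann–Whitney rank formulation (ties count one half; the rank AUC equals
the trapezoidal ROC integral, which the tests verify). Genes labelled
both TS and OG are excluded from training and can be scored afterwards;
scores are calibrated to [0, 1] by rank against the training scores, and
decision labels use two cuts (TS at ≥ 0.78, OG at ≤ 1 − 0.83).

One property of cross-validated AUC worth knowing: because all folds
share most of their training data, a learner fitted to label noise gives
held-out scores that are correlated across genes, so the null
distribution of the pooled CV-AUC is noticeably wider (sd ≈ 0.06 at 200
genes) than the iid Mann–Whitney null (sd ≈ 0.04). Null-calibration
checks in the test suite therefore use a label-blind scorer for the
tight band, and the fitted learner for a centring check that would catch
train-on-test leakage (a leaking harness memorises permuted labels and
pushes the AUC far above one half).

## The synthetic-data generator

The generator emulates the full input bundle with known ground truth:

- **Families.** Each family is grown from a random ancestor sequence;
  every instance applies per-residue substitutions (probability 0.15)
  and occasionally one short deletion and/or insertion (probabilities
  0.08 and 0.05, length ≤ 3), so the *true alignment is known by
  construction* — insertion blocks get their own columns, deletions
  become gaps. Hotspot recovery can therefore be tested on the true
  alignment (a pure statistics test), with the built-in aligner as a
  separate, measurable error source rather than a silent one.
- **Proteome.** 24 tested families and 450 background families
  (defaults), instances embedded in host proteins between random linkers
  of 10–30 residues. Tested-family instances live on 100 labelled genes
  (15 TS, 15 OG, 70 other); the first third of tested families
  preferentially lands on OG genes and the second third on TS genes
  (4:1 weighting), giving the domain-composition classifier a
  recoverable but imperfect signal. Background instances live on
  dedicated unlabelled proteins.
- **Mutations.** Background mutations are Poisson-scattered uniformly
  per residue at class rates 5e-5 (missense), 1e-5 (truncation), 2e-6
  (indel) per residue per sample over 200 samples — sized so a typical
  tested family accrues a handful of background missense events, the
  regime in which both tests operate in practice. TS genes carry 6× the
  truncation rate, OG genes 2× missense and 0.5× truncation, matching
  the characteristic spectra of the two classes. Planted enriched
  families get a 10× class rate; planted hotspots redirect an `excess`
  fraction of a family's class mutations to the residue aligned with one
  chosen column, optionally restricted to hosts of one gene class. The
  hotspot families' rate multipliers (20 for the OG missense plant, 25
  for the TS truncation plant, 10 for the unrestricted plant) are power
  choices: they give each planted family a class total large enough that
  recovery is essentially certain, the sparse truncation class needing
  the largest boost.
- **Strings.** Change strings are emitted in the same grammar the parser
  accepts, with reference residues taken from the simulated proteome;
  `stale_ref_fraction` deliberately corrupts a fraction of references to
  exercise the drop-and-log path.

What the generator does **not** emulate: trinucleotide signature biases,
cancer-type-specific spectra, copy-number and fusion events, correlated
mutation rates along the genome, alignment uncertainty in real Pfam
alignments, and the reconciliation of catalogue transcript sequences
with the reference proteome (inputs are assumed pre-reconciled). Passing tests on synthetic data therefore
demonstrate that the statistical machinery is correct and well
calibrated under its stated null, not that real catalogues satisfy that
null.

## Numerical and design notes

- All probabilities are computed in survival-function form; results are
  written with p-values in scientific notation and round-trip through
  the TSV writers to 12 significant digits.
- The built-in progressive aligner (identity-distance guide tree by
  average linkage, profile–profile Needleman–Wunsch on expected BLOSUM62
  scores, linear gap penalty 6) guarantees only a *valid* alignment —
  rows ungap exactly to their inputs — not agreement with any external
  program; `method = "external"` shells out to `mafft` when fidelity to
  a production aligner matters. Ties in the dynamic program resolve
  deterministically (diagonal, then up, then left).
- Deduplication: a mutation recurring in the same sample is counted
  every time it appears — the catalogue row is the unit of evidence and
  collapsing would require assumptions about the upstream pipeline.
- All randomness in a simulated dataset flows from the single seed in
  its spec; `run_all()` output directories are byte-identical across
  runs with the same seed. Problem sizes throughout (the 474-family
  default study, 500-family null ensembles, 200-replicate power checks)
  were chosen to make each property measurable at desk scale with
  comfortable margins.

## Known limitations

- The chi-square enrichment test inherits Pearson's small-count
  behaviour (see above); an exact or mid-p alternative is a possible
  extension for the indel class.
- Hotspot power depends on family-wide `n`; positions in rarely mutated
  families are untestable in principle at `min_count = 2`.
- The binomial null treats columns as exchangeable; real alignments have
  column-specific mutability (CpG content, conservation) that the model
  ignores, so real-data hotspot p-values are best read as ranking scores
  subject to biological follow-up.
- Rank calibration of classifier scores is monotone but coarse for genes
  scoring inside a dense cluster of training scores; the probability
  cuts (0.78/0.83) are conventions, not calibrated probabilities.
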