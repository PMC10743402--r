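---
title: "ConStruct: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ConStruct: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ConStructOTOF)
```

## The problem and the model

Otoferlin (the *OTOF* gene product, long isoform, 1979 residues) drives
Ca²⁺-triggered vesicle release at the inner-hair-cell ribbon synapse;
missense variants that disable it cause auditory neuropathy spectrum
disorder. Because this is a single, structurally well-characterised
protein, a gene-specific classifier can exploit *where* a substitution
falls — which C2 domain, which disordered region, how conserved the site
is — rather than relying only on generic substitution features.

ConStruct encodes each single amino-acid variant as nine predictors
(position, exon number, BLOSUM80 substitution score, C2-domain code,
disordered-region code, composition-bias flag, coiled-coil flag, and two
phyloP conservation values) and fits a random forest. The forest is a
bagged ensemble of decision trees with random feature subsetting — an
appropriate learner here because the predictors mix ordered, categorical
and binary scales, interactions (e.g. "conserved *and* inside a C2
domain") carry most of the signal, and no distributional form is assumed.

The model's core assumptions, made explicit:

* pathogenicity is learnable from protein-level context plus site
  conservation; the nucleotide-level change enters only through the phyloP
  values supplied with each variant;
* the domain/region interval structure of the long isoform is correct and
  fixed; variants are interpreted against it in 1-based, closed
  coordinates;
* training labels (pathogenic/benign) are clinically established and
  treated as ground truth.

## Cross-validation design

Accuracy is estimated by five-fold cross-validation with a
**position-ordered cyclic fold assignment**: variants are sorted by
position (ties broken by reference then alternate residue, so the
assignment does not depend on input row order) and fold labels 1..5
assigned cyclically. Every fold therefore samples the entire protein; a
random or contiguous split would let one fold be dominated by a single
domain and make fold metrics incomparable. With 270 variants the rule
forces five folds of exactly 54.

Out-of-fold probabilities are pooled before computing confusion counts and
AUC (counts then sum to *n*, and fold-level class imbalance does not
distort the summary); per-fold reports are also returned. Fold-averaged
AUC was the plausible alternative; pooling was chosen because the pooled
counts are what a confusion table over all 270 variants reproduces.

A variant is called pathogenic when its probability strictly exceeds the
threshold. The default confusion threshold is 0.5; the strict inequality
matters only at threshold values that coincide with attainable vote
fractions, and it matches how the reporting-threshold analysis below is
phrased ("higher than 0.85").

## Tunable parameters

| parameter | default | why |
|---|---|---|
| `ntree` | 500 | vote fractions stable to ~0.02; cheap at n = 270 |
| `mtry` | ⌊√9⌋ = 3 | standard random-forest default for classification |
| `nodesize` | 1 | fully grown trees; bagging controls variance |
| `seed` | 17 | fixed so identical data give identical models |
| CV threshold | 0.5 | symmetric default; the sweep explores alternatives |
| consensus threshold | 0.85 | high-confidence regime where false positives are a small share of positive calls |

All are recorded in the fitted object's metadata. The reporting threshold
should be chosen from `class_score_distribution()` /`threshold_report()`
output on the user's own cross-validation run, not taken on faith.

## Evaluation conventions

Sensitivity is TP/(TP+FN) and specificity TN/(TN+FP) — the standard
definitions, applied consistently; balanced accuracy is their mean and is
invariant to swapping the two per-class rates. A metric whose denominator
class is empty is reported as `NA`, never 0. AUC is the rank-based
(Mann–Whitney) statistic: the probability a random pathogenic variant
outscores a random benign one, ties counted half — identical to the
exhaustive pairwise count, which the tests verify on small fixtures.
Distribution summaries use quartiles by linear interpolation
(`quantile(type = 7)`) and Tukey fences at 1.5 and 3 IQR with *strict*
inequalities, so a value exactly on a fence is not an outlier; these
conventions are fixed so summaries are reproducible across runs.

## Consensus VUS prioritization

A VUS is nominated as probably pathogenic when (1) its ConStruct
probability strictly exceeds the consensus threshold and (2) all required
methods call it pathogenic. The default required panel is the eight
accurate dbNSFP-derived predictors (MetaLR, MetaSVM, MutationAssessor,
PolyPhen-2 HDIV, PROVEAN, SIFT 4G, MutPred, LIST-S2) plus SAV-Pred; the
mean rank-score panel is those nine plus ConStruct, ten in all. Both
panels are configurable: the division between the "required" eight and
SAV-Pred, and the exact membership of the ten-method rank panel, are
interpretive choices, so they are arguments rather than constants. A
missing call blocks selection (absence of evidence is not a benign call),
and raising the threshold can only shrink the selection. Output is sorted
by mean rank score, descending, ties broken by position then residues —
a stable, reproducible ordering.

Rank scores are consumed as given when a dbNSFP-style extract provides
them; `rank_scores_from_raw()` is an explicitly local approximation
(rank/N within the supplied column, mean ranks for ties) for when they are
absent — it cannot reproduce genome-wide dbNSFP rank scores and is
documented as such.

## Annotation data and their provenance

The packaged config carries the seven C2-domain intervals (1–98, 236–357,
400–531, 944–1069, 1115–1242, 1464–1593, 1714–1865; codes 1–7 in that
order) and four disordered-region intervals (128–171, 642–694, 1299–1324,
1343–1405). The C-terminal transmembrane segment has no published
interval in this coordinate list and is deliberately *not* a coded domain.
The composition-bias layer, the coiled-coil layer and the 46-interval
exon partition are **synthetic placeholders** (the partition is simply 46
near-equal blocks of 1..1979): the real coordinates are curated database
content that is not bundled. The config marks these layers in its
`synthetic_layers` field, every user-facing doc repeats the warning, and
no test depends on the placeholder coordinates. Supplying a corrected
config JSON replaces any layer.

The substitution matrix is the verbatim NCBI BLOSUM80 file (matblas build,
1/3-bit units). Off-diagonal BLOSUM80 scores are frequently negative;
disruptive substitutions score negative and conservative ones positive,
which is exactly the contrast the classifier uses.

## What the synthetic generator does and does not emulate

`simulate_training_set()` draws 93 pathogenic and 177 benign variants (the
composition of the curated set this package targets) with the documented
class-conditional tendencies: pathogenic variants fall inside C2 domains
2–7 with probability 0.8 (and therefore in higher-numbered exons), carry
substitutions sampled with weight ∝ exp(−0.6 · BLOSUM80) so their scores
skew negative, and have phyloP100 ~ N(6, 1.5) and phyloP30 ~ N(0.6, 0.3);
benign variants are uniform over the sequence with weight ∝
exp(+0.6 · BLOSUM80) and conservation centred at 0. Positions are sampled
without replacement so no duplicate variants arise. `simulate_vus_set()`
draws 1302 VUS, 16 of which are planted with an unambiguous pathogenic
profile (domain membership certain, phyloP100 ~ N(7, 0.8), strongly
negative substitutions); per-method scores come from a shared latent
pathogenicity plus per-method noise (sd 0.5), so method concordance is
tunable, and calls derive from each method's cutoff.

These distributional values are invented defaults — the real data motivate
only the *direction* of each tendency — and they produce deliberately
well-separated classes. Passing the recovery checks (pooled balanced
accuracy ≥ 0.9, planted positives recovered by the consensus screen)
demonstrates that the pipeline is wired correctly end to end: encoding
preserves the signal, folds never leak training variants, the consensus
logic composes. It does **not** demonstrate the accuracy attainable on
real curated variants, where classes overlap, labels are imperfect, and
conservation correlates with structure in ways the generator ignores
(no real otoferlin residue identities, no allele-frequency structure, no
dbSNP identifiers beyond format).

## Numerical choices and degenerate inputs

* Seeding: every stochastic step takes an explicit integer seed; the VUS
  generator offsets its seed by a fixed constant so training and VUS draws
  are decoupled but jointly reproducible; cross-validation seeds fold *f*
  with `seed + f − 1`. Two identical runs are byte-identical.
* Problem sizes: the shipped tests run the full 270/1302 default
  composition; the 20-seed recovery study uses the default 500-tree
  forest, chosen because a full run completes in well under a minute at
  these sizes.
* Degenerate inputs fail loudly: single-class training sets, missing
  phyloP values, duplicate variants, all-missing score columns,
  out-of-range positions and non-partitioning exon maps are all errors,
  not silent repairs.
* `k = n` cross-validation (leave-one-out) is permitted; `k` larger than
  `n` is not.

## Known limitations

* Protein-level only: no VCF/genomic coordinates, no HGVS cDNA parsing, no
  liftover, no synonymous variants.
* The packaged exon map, composition-bias and coiled-coil layers are
  placeholders (see above); domain/region coordinates are fixed to the
  published list and revising them requires a new config.
* Compared predictors are consumed as score columns; none are
  re-implemented, so their calls are only as good as the extract supplied.
* The classifier interface is random-forest only; alternative learners
  would slot in behind `construct_fit()` but are not provided.
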