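# ConStructOTOF

Protein-centric pathogenicity classification of OTOF missense variants.

Auditory neuropathy spectrum disorder (ANSD) is a hereditary sensorineural
hearing loss most often caused by missense variants in *OTOF*, the gene
encoding otoferlin — the Ca²⁺ sensor for synaptic vesicle release at inner
hair cell ribbon synapses. General-purpose pathogenicity predictors are of
uneven accuracy on this one protein, and a large share of the known *OTOF*
missense variants remain variants of uncertain significance (VUS). This
package is for clinical genetics and bioinformatics groups interpreting
targeted *OTOF* sequencing: it implements the **ConStruct** approach — a
gene-specific classifier built from **con**servation and protein
**struct**ure features — together with the evaluation and VUS-prioritization
machinery around it.

## The model

Each single amino-acid variant (SAV) at residue position *p*, replacing
residue *r* with *a*, is encoded as nine predictors:

| predictor | value |
|---|---|
| position | *p* ∈ 1..1979 (otoferlin long isoform) |
| exon number | coding exon containing the variant, 1..46 |
| substitution score | BLOSUM80(*r*, *a*) |
| functional domain | C2-domain code 1..7, or 0 outside |
| region | intrinsically disordered region code 1..4, or 0 |
| composition bias | 1 if inside a low-complexity stretch |
| coiled coil | 1 if inside the coiled coil |
| phyloP100 | conservation, 100-vertebrate alignment |
| phyloP 30-primates | conservation, 30-primate alignment |

A random forest is trained on labelled pathogenic/benign SAVs and validated
by **position-ordered five-fold cross-validation**: variants are sorted
along the protein sequence and fold labels 1..5 assigned cyclically, so
every fold spans the whole protein and no fold is a contiguous (locally
correlated) block. Pooled out-of-fold confusion counts give sensitivity
TP/(TP+FN), specificity TN/(TN+FP), balanced accuracy
(sensitivity+specificity)/2, accuracy, and rank-based AUC. Class-conditional
score distributions (Tukey box statistics) support choosing a
high-confidence reporting threshold, and a consensus rule — ConStruct
probability above a threshold **and** a unanimous pathogenic call from a
panel of established predictors — nominates probable pathogenic variants
among VUS, ranked by mean rank score across methods.

## Worked example

```r
library(ConStructOTOF)
map <- otoferlin_annotation()   # packaged domain/region/exon intervals
mat <- blosum80()               # packaged NCBI BLOSUM80

# encode one variant (the nine predictors)
encode_variant(1504, "L", "P", phylop100 = 7.5, phylop30 = 0.6,
               map = map, matrix = mat)
#>   position exon_number blosum_score domain_code region_code comp_bias
#> 1     1504          35           -5           6           0         0
#>   coiled_coil phylop100 phylop30
#> 1           0       7.5      0.6

# a synthetic training set with the class structure of curated OTOF data
training <- simulate_training_set(simulation_config(seed = 42), map, mat)
cv <- construct_cv(training, map, mat, seed = 42)
cv
#> ConStruct 5-fold cross-validation (position-ordered), n = 270
#>   pooled: TP 92  TN 176  FP 1  FN 1  (threshold 0.50)
#>   sensitivity 0.989  specificity 0.994  BA 0.992  accuracy 0.993  AUC 1.000

# metrics straight from confusion counts
metrics_from_counts(76, 162, 15, 17)
#> TP 76  TN 162  FP 15  FN 17
#> sensitivity 0.817  specificity 0.915  BA 0.866  accuracy 0.881
```

Leu1504Pro sits in C2 domain 6 with a strongly negative BLOSUM80 score and
high vertebrate conservation — the profile the model associates with
pathogenicity. (The exon number shown comes from the packaged placeholder
exon partition; supply a config with the real protein-coordinate exon map
for clinical use — see `?otoferlin_annotation`.) The cross-validation block reports pooled out-of-fold
counts; on the default synthetic set the classes are well separated by
construction, so balanced accuracy is near 1.

A command-line front end over the same functions is installed as
`exec/construct.R` (subcommands `simulate`, `encode`, `train`, `cv`,
`predict`, `evaluate`, `prioritize`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("exec","construct.R",package="ConStructOTOF"))')" \
    evaluate --counts 76,162,15,17 --out metrics.json
```

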