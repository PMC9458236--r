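# ensplif

Post-processing for receptor-ensemble docking campaigns: per-residue
protein–ligand interaction fingerprints (PLIF), ensemble-aggregated
**ensPLIF** fraction descriptors, and a prior-weighted CART classifier with
the retrospective-screening statistics used to validate structure-based
virtual screening (SBVS) protocols.

## Who this is for

Computational medicinal chemists running retrospective or prospective
virtual screens in which every compound is docked repeatedly — against
several receptor conformations (e.g. clustered MD snapshots), with several
independent replicates, keeping several binding modes per run — and who want
to classify compounds by their *interaction pattern* rather than by docking
score alone. The worked examples target acetylcholinesterase (AChE) with
actives and decoys in the DUD-E style, but nothing is enzyme-specific.

## The method

**PLIF.** For one receptor/pose pair and an ordered binding-site residue
list, each residue gets a 7-bit block: (1) apolar contact, (2) aromatic
face-to-face, (3) aromatic edge-to-face, (4) H-bond with the residue as
donor, (5) H-bond with the residue as acceptor, (6) ionic with the residue
as cation, (7) ionic with the residue as anion. All detectors are geometric
(distance and angle cutoffs, configurable via `geometry_params()`). The
`nobb` option restricts detection to side-chain atoms. Bit *N* of the
concatenated string is descriptor *N*: for residue position *p* and
interaction ordinal *o*,

    N = (p − 1) × 7 + o.

With the packaged 57-residue AChE consensus binding-site list
(`ache_consensus_residues()`), the fingerprint has 399 bits; e.g. bit 240 is
(Trp279, aromatic face-to-face).

**ensPLIF.** A compound docked to `R` receptors × `r` replicates × `m` modes
yields `R·r·m` poses (2 × 3 × 5 = 30 in the reference protocol). Descriptor
`V[i]` is the fraction of those poses in which bit *i* is set. The analysis
table has columns `y` (1 active / 0 decoy), `name`, `dg` (mean over runs of
each run's best docking score, kcal/mol), then `V1..Vn`.

**Classification.** A binary CART fitted on the `V` columns with class
priors `(π_inactive, π_active)` altering both the Gini impurity,
`p(j|t) ∝ π_j · n_j(t)/N_j`, and the leaf labelling — the standard device
for rare-active screens (prevalence ≈ 1.7 %). `grid_search_priors()` scans
the prior, selecting the best balanced accuracy subject to an F1 floor;
`validate_tree()` runs the overfitting (stratified CV), descriptor
cross-correlation, and chance-correlation (y-scrambling) checks.

**Statistics.** `metrics()` reports sensitivity, specificity, precision,
F1 = 2TP/(2TP+FP+FN), BA = (sensitivity+specificity)/2, and the enrichment
factor defined as the positive likelihood ratio,

    EF = [TP/(TP+FN)] / [FP/(FP+TN)],

which is the definition consistent with the published AChE protocol
comparisons (not precision over prevalence). `scan_cutoff()` scans a
docking-score cutoff for maximum F1; `select_replication()` picks the
smallest replicate count within tolerance of the best F1.

## Worked example

```r
library(ensplif)

## a planted complex: ammonium against Asp, benzene stacked on Phe
cx <- make_complex(list(
  list(residue = "ASP", type = "ionic_protein_anion",   distance = 3.0),
  list(residue = "PHE", type = "aromatic_face_to_face", distance = 3.6)),
  seed = 7)
fp <- compute_plif(cx$receptor, cx$ligand, cx$residues, nobb = TRUE)
fp
#> <plif_bits: 2 residues, 14 bits, 4 set (5,7,8,9)>
describe_bit(set_bits(fp), cx$residues)
#>   index residue                   type
#> 1     5    Asp1 hbond_protein_acceptor
#> 2     7    Asp1    ionic_protein_anion
#> 3     8    Phe2                 apolar
#> 4     9    Phe2  aromatic_face_to_face
```

The ammonium plants the residue-anion ionic bit (7) and, being an N–H
donor 3 Å from a carboxylate O, also a legitimate H-bond (bit 5); the
stacked benzene gives both the face-to-face (9) and the apolar contact (8)
of the second block.

```r
## published upgraded-protocol confusion matrix -> its statistics
metrics(confusion_matrix(TP = 214, FN = 239, TN = 25886, FP = 364))
#> <screen_metrics EF=34.068 F1=0.415 BA=0.729 sens=0.472 spec=0.986 prec=0.370>

## prior search on a synthetic screen with a planted interaction rule
tab <- make_table(n_active = 60, n_decoy = 940, n_vars = 12,
                  rule = list(list(var = "V5", threshold = 0.4, dir = ">=")),
                  bit_noise = 0.15, seed = 11)
gs <- grid_search_priors(tab, prior_grid = seq(0.05, 0.5, 0.05),
                         f1_floor = 0.1)
gs$metrics
#> <screen_metrics EF=63.872 F1=0.841 BA=0.935 sens=0.883 spec=0.986 prec=0.803>
tree_rules(gs$tree)[3]
#> [1] "Key #3: V5 >= 0.3"
```

The planted rule (`V5 >= 0.4` marks actives) is recovered as the dominant
"key"; EF, F1 and BA quantify the resulting screen.

A command-line wrapper over the same functions ships as
`system.file("scripts", "ensplif_cli.R", package = "ensplif")` with
subcommands `bindsite`, `plif`, `ensplif`, `eval` and `tree`.

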