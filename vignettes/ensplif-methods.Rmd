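---
title: "Interaction-fingerprint screening with ensPLIF: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction-fingerprint screening with ensPLIF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensplif)
```

## The problem

Docking-score rankings are noisy classifiers of bioactivity. When a
compound is docked many times — against several receptor conformations,
with independent replicates, keeping several binding modes — the *pattern*
of protein–ligand contacts across all those poses carries information a
single score does not. This package implements that post-processing chain:
per-pose interaction fingerprints (PLIF), their aggregation into ensemble
fractions (ensPLIF), and a prior-weighted decision tree that turns the
fractions into an active/inactive call, together with the retrospective
statistics used to compare screening protocols.

## The fingerprint model

For an ordered binding-site residue list of length $R$, a pose maps to a
$7R$-bit string, seven interaction classes per residue in a fixed order:
apolar, aromatic face-to-face, aromatic edge-to-face, H-bond
(residue donor), H-bond (residue acceptor), ionic (residue cation), ionic
(residue anion). The order is load-bearing: descriptor $N$ of the
downstream table is bit $N = (p-1)\cdot 7 + o$ for residue position $p$
and class ordinal $o$. The packaged acetylcholinesterase consensus list
(`ache_consensus_residues()`, 57 residues, so 399 bits) pins this
numbering to the published decision-tree variables: position 4 is Asp72,
hence its apolar bit is 22 and its anion bit 28; position 23 is Ser122,
hence its donor bit 158; and so on for all eleven published descriptors.
The assignment of ordinals within a block is fixed by requiring all eleven
to land on their printed indices simultaneously; that system of
constraints admits exactly the order above.

One textual discrepancy is resolved deliberately: the published results
prose names "Ser112" where the descriptor table says Ser122. Ser112 is
absent from the consensus list and index 158 is arithmetically consistent
only with Ser122, so Ser122 is used throughout.

### Geometric detectors and their parameters

All thresholds live in `geometry_params()` and are logged into output
headers; the defaults follow the classical residue-based
interaction-fingerprint scheme from which this family of tools descends:

| parameter | default | meaning |
|---|---|---|
| `apolar_cutoff` | 4.5 Å | max apolar-atom pair distance |
| `aromatic_centroid_cutoff` | 4.0 Å | max ring-centroid distance |
| `f2f_max_plane_angle` | 30° | plane angle separating face-to-face from edge-to-face |
| `hbond_da_cutoff` | 3.5 Å | max donor–acceptor heavy-atom distance |
| `hbond_min_dha_angle` | 135° | min D–H···A angle when the polar H exists |
| `ionic_cutoff` | 4.0 Å | max inter-group atom distance for salt bridges |

When a donor's polar hydrogen is absent from the structure the angle test
is skipped and the H-bond is accepted on distance alone; this is the more
permissive reading and is stated here because the original tools do not
document their behaviour for H-less inputs.

With `nobb = TRUE` the receptor is restricted to side-chain atoms *before*
any perception, so backbone-only contacts can never set a bit and the
side-chain fingerprint is always a bitwise subset of the all-atom one.
Glycine then contributes nothing — its block is structurally all-zero —
which is accepted behaviour of the side-chain-only convention.

### Chemical perception

Protein residues are perceived from atom-name templates for the 20
canonical amino acids: Phe/Tyr/Trp/His ring definitions, Asp/Glu
carboxylates (always anionic), Lys/Arg (always cationic), Ser/Thr/Tyr
hydroxyls as both donor and acceptor, and apolar side-chain C/S atoms
without O/N neighbours. These conventions assume a structure prepared at
physiological pH. Histidine follows its hydrogen records: the protonated
ring nitrogen donates, the other accepts, and only a doubly protonated
imidazolium counts as cationic; with no ring hydrogens present the
NE2-protonated tautomer is assumed.

Ligands carry no reliable typing in docking output, so they are perceived
from geometry and partial charges: bonds from the file when present (MOL2)
or inferred by covalent radii ($d \le r_i + r_j + 0.45$ Å); rings as the
smallest cycles of the heavy-atom graph, aromatic when all members are
C/N/O/S with at most three heavy neighbours and the ring is planar within
a 7.5° mean out-of-plane deviation; donors are N/O bearing hydrogen;
acceptors are N/O that are not positively charged; cations are quaternary
N or atoms at charge $\ge +0.30$ e; anions are terminal-oxygen pairs of
carboxylate/phosphate/sulfate groups or single O at charge $\le -0.30$ e;
halogens count as apolar contact partners (the scheme has no halogen-bond
class). These rules approximate the SMARTS-based typing of the original
fingerprinting tools; they are isolated in one module precisely so they
can be swapped without touching detection.

## ensPLIF aggregation

For each bit, the descriptor is the fraction of aggregated poses showing
it: $V_i = k_i/m$. The reference protocol aggregates all poses of
2 receptors × 3 replicates × 5 modes, so every $V_i$ has denominator 30 —
a structure the published per-compound descriptor values display
consistently, which is why all-pose aggregation (rather than best-pose
selection) is implemented. When a docking-score cutoff is applied first,
the denominator becomes the number of retained poses, keeping $V$ a
well-defined frequency; a compound retaining no poses gets an all-zero
descriptor row (flagged in the table attributes) with `dg` kept at its
pre-filter value. Whether the original campaign filtered poses or gated
whole compounds at −8.7 kcal/mol is not decidable from the published text,
so both routes exist (`filter_poses_by_score()` pose-level,
`classify_by_score()` compound-level).

`dg` is the mean over runs of each run's best score, in kcal/mol. It is
invariant to mode order, and deliberately *not* recomputed after pose
filtering.

## The prior-weighted tree

`fit_plif_tree()` is greedy binary recursive partitioning with Gini
impurity on prior-adjusted class proportions
$p(j\mid t) \propto \pi_j\, n_j(t)/N_j$, candidate splits at midpoints
between consecutive observed values, node classes by prior-weighted
majority, and weakest-link cost-complexity pruning at
$\alpha = \mathrm{cp} \cdot R(\mathrm{root})$. Defaults mirror the
classical CART/rpart settings: `min_split = 20`, `min_leaf = 7`,
`cp = 0.01`, `max_depth = 30`, and priors equal to the empirical class
frequencies unless set — under frequency priors the fit reduces exactly to
plain Gini CART, which is verified in the tests against an exhaustive
split-enumeration oracle and against an independent CART implementation.
Ties between splits break deterministically toward the lower column index
and threshold; there are no surrogate splits and no missing-value handling
because descriptor tables are complete by construction.

The prior convention is `(inactive, active)` in sorted label order, so the
published optimum "0.9:0.1" is `c(0.9, 0.1)`: prior mass 0.1 on actives
still up-weights them roughly six-fold against a 1.7 % prevalence. Because
the opposite reading cannot be excluded from the text alone, the default
grid in `grid_search_priors()` covers both orderings
(active prior 0.05–0.95). Selection maximises training balanced accuracy
subject to a training-F1 floor (the published selection used an F1 floor
of 0.413; whether that floor was train or cross-validated F1 is unstated,
and training F1 is the default here), with ties broken toward the less
extreme prior.

### Validity checks

`validate_tree()` bundles three checks. Overfitting: stratified $k$-fold
cross-validation, flagged when training BA exceeds CV BA by more than 0.1.
Cross-correlation: Pearson $|r|$ among the tree's split variables, flagged
above 0.8. Chance correlation: y-scrambling — refit after label
permutation — flagged when the real training BA fails to exceed the 95th
percentile of the scrambled distribution. Note that in-sample BA of a
flexible tree on scrambled labels sits *above* 0.5 whenever the priors
up-weight the minority class; that optimism is expected and is exactly why
the chance-correlation criterion compares against the scrambled
distribution rather than against 0.5. Under frequency priors the scrambled
null does centre on 0.5, which the tests assert. All stochastic steps
(fold assignment, permutations) consume one seeded generator recorded in
the report.

## What the synthetic fixtures emulate

The package tests itself without external data through three generators,
all byte-deterministic under a seed.

`make_complex()` builds planted-interaction complexes: single idealized
residues (geometries from a packaged template file of textbook residue
geometry, `inst/extdata/residue_templates.pdb`) placed 30 Å apart, with
small charged/aromatic/polar ligand probes positioned at stated distances
and plane angles. This suffices to exercise every detector with positive
and negative controls bracketing each threshold, but it does not emulate
real binding sites: no clashes, no solvent, no conformational strain, no
correlated contacts between neighbouring residues. Passing the fingerprint
property tests therefore demonstrates detector correctness, not docking
realism.

`make_vina_output()` writes multi-model PDBQT with `REMARK VINA RESULT`
lines, scores sorted ascending within each run. The default score model —
actives $N(-9.5, 0.5)$, decoys $N(-7.5, 0.7)$ kcal/mol — was chosen once
so that a cutoff near −8.7 kcal/mol separates the classes imperfectly, the
regime in which a cutoff scan is actually informative.

`make_table()` emulates the analysis table directly: descriptors are
binomial fractions $k/30$, actives obey a planted threshold rule with a
configurable per-condition disobedience rate, and the default class sizes
(453 actives, 26250 decoys) reproduce the benchmark prevalence of
0.017. Tests that do not need that scale use smaller tables (tens to a
few thousand rows), a deliberate choice documented per test; the fitting
code is the same at every size.

## Numerical choices and degenerate inputs

Plane fitting uses the SVD of centred ring coordinates and refuses
collinear input; normals are unit length with arbitrary sign, and every
consumer uses angles folded to [0°, 90°]. Distances compare against
cutoffs with a $10^{-12}$ slack so boundary fixtures behave predictably.
The score-cutoff convention is *at or below* (`dg <= cutoff` is a
positive call). Readers keep the first alternate location with a warning,
preserve file atom order, never renumber residues, and treat residue
identity as (chain, number, insertion code) with `ResnameNumber` display
names. Empty selections, single-class tables, zero-atom molecules and
mixed-length bitstrings are errors, not silent results.

## Known limitations

The box rule in `compute_box()` (padded bounding box of the selected
residues, centred on the reference-ligand centroid) is an explicit
approximation of the external "bind"-style box definition; it only feeds
docking configuration and never enters fingerprint math, but its
dimensions should not be expected to reproduce any published box. The
ligand-typing rules are geometric approximations of SMARTS-based typing.
Seven interaction classes mean no halogen bonds, water bridges or metal
coordination. Tree-structure equivalence with any published tree figure is
not claimed — published thresholds are unavailable — only variable-set
and operating-point behaviour are checked, on synthetic emulations. The
docking-dependent published numbers (the replication F1 series, the full
retrospective screen) require external docking software and are inputs
here, not outputs.
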