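---
title: "Structure-based prediction of Asn/Asp degradation hotspots: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based prediction of Asn/Asp degradation hotspots: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fvhotspots)
```

## The problem

Asparagine deamidation and aspartate isomerization are among the most
common chemical degradation routes of therapeutic antibodies. Both
proceed through a cyclic succinimide intermediate formed when the
backbone nitrogen of the *following* residue attacks the Asn/Asp
side-chain carbonyl. Whether a given Asn/Asp actually degrades depends
far more on its structural context than on sequence alone: sequence-only
motif rules (NG, DG, ...) over-predict heavily because most motif
residues sit in rigid, protected environments.

`fvhotspots` predicts degradation *hotspots* — residues with
substantial modification under accelerated-stability stress — in
antibody variable (Fv) regions from an ensemble of structure models
(typically the five top-ranked loop-refinement solutions of a homology
model). The package covers the full pipeline: PDB ensemble I/O, CDR
annotation, extraction of twenty structural descriptors, hard-coded
published decision trees for Asp and Asn, ensemble aggregation into
residue-level calls with probabilities, a sequence-motif baseline, and
a retraining toolkit (class-weighted lookahead recursive partitioning
with grouped Monte Carlo cross-validation).

## The descriptor set

For every non-terminal Asn and Asp in every ensemble member, one row of
descriptors is extracted (`extract_descriptors()`), one row per
(residue, model):

* **Leaving-group environment** — `hb_sidechain`: hydrogen-bond count of
  the side-chain head group (Asp OD1/OD2, Asn ND2); `pka`: side-chain
  pKa through a pluggable provider interface (absent by default; the
  published analysis found pKa irrelevant for classification, so no
  internal estimator is shipped).
* **Nucleophile accessibility** — `succ_N_sasa` (Å²) and `succ_N_hbonds`
  of the successor's backbone nitrogen.
* **Transition-state geometry** — `dist_cg_n1`: Cγ(n)–N(n+1) distance
  (Å); `chi1`; `cgonc`: the dihedral over Cγ, the side-chain carbonyl
  oxygen (OD1), N(n+1) and the backbone carbonyl carbon of n;
  `res_sasa` (Å²); `phi`/`psi` (degrees, (−180, 180]).
* **Successor size** — the fully-exposed solvent-accessible surface area
  of the successor amino-acid type, from a fixed 20-entry lookup
  (`successor_size_table()`, Gly 23.13 Å² ... Trp 229.62 Å²).
* **Conformational flexibility** — `rmsd`: per-residue Cα RMSD across
  the ensemble about the ensemble-mean position (Å), after a
  least-squares superposition fitted on *framework* Cα atoms only, so
  that loop variability is not absorbed by the fit. For a single-model
  ensemble the value is 0 by construction. The superposition reference
  and whether CDRs join the fit are configurable
  (`superpose_ensemble()`).
* **Secondary-structure context** — `sec_struct` (helix/sheet/turn/coil)
  from a Kabsch–Sander-style hydrogen-bond-energy assignment (below);
  `next_diff_ss_n` / `next_diff_ss_c`: residue distance to the next
  different secondary-structure class in each direction;
  `pos_in_coil`: margin/center/n.a.; `bend`: Cα(n−1)–Cα(n+1) distance.
* **Location** — `fab_location` 1–14 (framework/CDR segments walked
  heavy then light chain; even codes are CDRs) and `cdr_loop` 0–3.

### Numerical choices

* **SASA** is Shrake–Rupley with probe 1.4 Å, Bondi-type van der Waals
  radii and 960 deterministic spiral points per atom (configurable).
  An unknown element falls back to 1.70 Å with a warning. The
  implementation is verified against the closed form for an isolated
  atom and a grid-integration oracle for two-sphere overlaps (≤ 2 %).
* **Hydrogen bonds** use a heavy-atom criterion: donor–acceptor
  distance ≤ 3.5 Å and an angle ≥ 120° at the donor between its closest
  bonded heavy atom, the donor, and the acceptor (amide hydrogens are
  not required in the input). Counts are per head group: an Asp side
  chain sums over OD1 and OD2. Both parameters are exposed in
  `hbond_criterion()`.
* **Secondary structure** places amide hydrogens geometrically
  (N–H anti-parallel to the preceding C=O), scores N–H···O=C pairs with
  the classical electrostatic energy term (cut-off −0.5 kcal/mol), and
  derives helices from consecutive n-turns (n = 3, 4, 5), sheets from
  parallel/antiparallel bridge patterns (isolated bridges included) and
  turns from unpaired n-turns; everything else is coil, as is any
  residue with an incomplete backbone (with a warning). On ideal helix
  and two-strand antiparallel fixtures the assignment agrees with a
  reference DSSP implementation.
* **Position in coil**: "margin" when the nearest different
  secondary-structure class is one or two residues away on either
  side. The published Boolean rules leave distances of exactly 3–4
  unlabelled; this implementation labels every non-margin coil residue
  "center", which affects reporting only — no shipped classifier splits
  on this field. When no different class occurs before the chain end,
  the distance extends to one past the terminus and an `open_*` flag is
  set (a terminus is treated as a change of environment).
* **Dihedrals** use the atan2 formulation with the IUPAC sign
  convention; degenerate geometry returns `NA` rather than a number.
* **CGONC atom mapping**: the named atoms are read as Cγ, the
  side-chain carbonyl oxygen OD1, the successor backbone nitrogen, and
  the backbone carbonyl carbon of the residue itself; the mapping is
  noted here because the printed definition is ambiguous about which
  "O" and "C" are meant.

## The published classifiers

`published_asp_tree()` and `published_asn_tree()` hard-code the
published decision trees. Two split thresholds are not printed and are
shipped as named constants with their admissible intervals: the Asp
large-successor cut (must fall between Asp 110.21 and Pro 111.53 Å²;
set to 110.9, which reproduces the narrated {Gly, Ala, Ser, Cys, Asp}
small-successor set exactly) and the Asn big-successor cut (between Asn
113.19 and Val 124.24 Å²; set to 118.7). Interval boundaries follow the
narration: "between 0.145 and 0.485" is implemented left-open
(`rmsd <= 0.145` branches to the inflexible side), and the
secondary-structure-distance splits treat an exact distance of 3 as the
non-class-2 branch on both trees (the narration is contradictory at the
boundary; the choice is documented per node).

Leaf probabilities are the residue-count purities of the printed leaf
compositions (Asp class 1: 5 hotspots vs 2 non-hotspots → 5/7; class 2:
3/3; class 3: 2/3; Asn class 1: 3/3; class 2: 6/10; class 3: 4/6);
leaves without a printed composition carry 1.0. Member probabilities
always lie in [0.5, 1] for the majority class.

A residue is called a hotspot when **at least one** ensemble member
lands on a hotspot leaf (`aggregate_ensemble()`); the quantitative
output is the mean ± SD of the members' hotspot probabilities, so the
report distinguishes a 1-of-5 call from a 5-of-5 call.

The sequence baseline (`sequence_baseline()`) calls every CDR Asn/Asp
followed by G/S/T (Asn) or G/S/T/D/H (Asp) a hotspot; NN is detected by
the nine-motif scanner (`motif_scan()`) but is deliberately not part of
the baseline motif set, matching the published comparison.

## CDR annotation

Combined Kabat+Chothia CDR limits are accepted explicitly
(`cdr_ranges()`, or a four-column text file for the command-line
workflow) and always take precedence. `auto_cdr_ranges()` offers a
light-weight anchor-motif detection (first/last conserved Cys, the
conserved Trp, the WGxG/FGxG J-segment motifs and classical spacing
rules) rather than a full numbering-scheme alignment: antibody
renumbering is a large dependency that contributes nothing to the
method itself, and the exact union intervals used in the original
analysis are not printed, so the limits are user-facing configuration
with documented defaults. Detection failures are loud and name the
missing anchor.

## The retraining toolkit

`train_tree()` grows a binary tree over numeric and categorical
descriptors by weighted Gini reduction with inverse-class-frequency
weights by default (the datasets of interest are 2.7–5.5 % hotspots).
Categorical features order their levels by weighted hotspot fraction
and scan prefix subsets, which is optimal for a binary outcome.

**Lookahead.** At each node the top `lookahead_alternatives` (default
7) candidate splits are compared by the total leaf impurity of a greedy
expansion `lookahead_depth` (default 4) levels deep. Deep greedy
rollouts on noisy data are nearly tied for any reasonable first split,
so the lookahead arbitrates only among candidates whose immediate
impurity lies within 5 % (of the node impurity) of the best candidate;
a clearly superior immediate split stands. This keeps the lookahead's
purpose — resolving genuinely ambiguous split choices by their
downstream consequences — without letting rollout noise overrule a
dominant split.

**Pruning.** Cost-complexity (weakest-link) pruning on the weighted
misclassification risk produces the standard nested sequence;
`pruning_level` selects the n-th tree in that sequence (1 = unpruned),
which is how a discrete "pruning level" dial is interpreted here.

**Cross-validation.** `monte_carlo_cv()` samples a train fraction
(default 75 %) of *groups* — the 5-member ensembles stay together — for
`n_repeats` (default 40) repeats, applies the at-least-one-member rule
on the held-out groups and reports residue-level confusion counts,
their means, and the ROC point of the averaged counts. Confusion counts
are at residue level because the aggregation rule is defined per
residue. `tidy()`, `glance()` and `autoplot()` expose the repeat table,
the summary row and a ROC-style plot.

## Synthetic data

The generators exist so that every pipeline stage can be exercised with
inputs whose ground truth is known by construction; they are not
intended to mimic real antibody structures in detail.

* `build_peptide()` constructs toy polypeptides from internal
  coordinates with canonical (Engh–Huber-like) bond lengths and angles;
  realized φ/ψ/χ₁ reproduce the targets to well under 0.5°. Only
  backbone + Cβ atoms are built, plus the full Asp/Asn head group, so
  every descriptor is computable. A short extended stub serves as the
  second chain, placed far from the first.
* `build_ensemble_with_jitter()` replicates the base model and adds
  isotropic Gaussian jitter (`jitter_sd`, Å) to designated loop
  residues only — the framework stays identical across members, so the
  framework-fitted superposition is exact and the expected per-residue
  RMSD has the closed form σ·√3·√(1 − 1/m). The shipped end-to-end
  fixture uses σ = 0.45 Å with m = 5, giving an expected RMSD ≈ 0.70 Å,
  comfortably above the very-high-flexibility cut of the Asp tree, so
  the planted Asp-Gly site exercises hotspot class 1.
* `build_sheet_model()` pairs two ideal extended strands antiparallel
  by a rigid placement refined against the canonical cross-strand
  H-bond ladder.
* `simulate_labelled_dataset()` draws descriptor tables from documented
  per-field distributions (a 65 % rigid / 35 % flexible RMSD mixture —
  rigid |N(0.04, 0.04)|, flexible Gamma(2, scale 0.25) Å; a successor
  pool enriched in small residues as in CDR-like sequence context;
  secondary-structure distances 1 + Poisson(1.6); bimodal φ/ψ; Gamma
  surface areas), grouped into 5-member ensembles that share group-level
  values while per-member fields (dihedrals, surface areas, distances)
  vary slightly. Labels come from applying a rule tree with the
  at-least-one rule, optionally flipped with a noise probability; a
  requested class fraction is met exactly (before noise) by rejection
  sampling. The distributions were chosen once so that conformational
  flexibility is the dominant discriminator, mirroring its role in the
  published trees; parameter-recovery tests train on 400 groups (2000
  vectors) with 5 % label noise over 10 seeds and check the recovered
  first split as a cross-seed property (all first splits on `rmsd`, the
  median threshold within ±0.05 Å of the planted 0.145 Å cut) because a
  5 % label flip can legitimately drag an individual seed's optimal
  boundary.

What passing these tests shows — and does not show. They demonstrate
that the descriptor extraction is numerically correct on geometries
with known answers, that the published rules are encoded faithfully,
and that the trainer can recover planted rule structure under noise at
the published class imbalance. They do not validate predictive accuracy
on real antibodies: the original mass-spectrometry dataset is
proprietary, real homology-model ensembles have correlated, non-Gaussian
loop variability, and real CDR conformations are not ideal-geometry
peptides.

## Known limitations

* No full antibody numbering (Kabat/Chothia/IMGT) — anchor heuristics
  or explicit ranges only.
* pKa is interface-only; connect an external PROPKA-compatible tool if
  needed.
* The H-bond criterion and the DSSP-letter collapse
  (H/G/I → helix, E/B → sheet, T → turn) are fixed conventions; the
  software originally used for these steps in the published analysis is
  closed, so exact agreement at class boundaries is not guaranteed.
* Ensemble RMSD is computed against the ensemble-mean position (not
  pairwise-averaged); this is the documented, configurable choice.
* Problem sizes in the shipped tests (peptides of 20 residues, ensembles
  of 5, simulated datasets of up to 2000 rows, 10 recovery seeds) were
  chosen as the smallest sizes at which each property is stable.
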