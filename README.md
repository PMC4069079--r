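# fvhotspots

Structure-based prediction of asparagine deamidation and aspartate
isomerization hotspots in antibody variable (Fv) regions.

## Why

Asn and Asp residues degrade through a cyclic succinimide intermediate:
the backbone nitrogen of the *next* residue attacks the side-chain
carbonyl, ultimately yielding iso-aspartate/aspartate mixtures. In the
CDRs of a therapeutic antibody this can destroy binding and potency.
Sequence motifs (NG, DG, NS, ...) flag candidate sites but over-predict
drastically — most motif residues are structurally protected. This
package implements a structural predictor: from an ensemble of Fv
structure models (typically the five top loop-refinement solutions of a
homology model) it extracts twenty descriptors per Asn/Asp per model —
solvent accessibility, backbone/side-chain dihedrals (φ, ψ, χ₁),
hydrogen bonds, secondary-structure context, per-residue ensemble Cα
RMSD (conformational flexibility), successor size, CDR location — and
applies published decision trees for Asp and Asn.

The core decision rules: an Asp is a hotspot only if it is flexible
(ensemble RMSD > 0.145 Å) *and* followed by a small residue
(Gly/Ala/Ser/Cys/Asp), with three hotspot classes distinguished by very
high flexibility (RMSD > 0.485 Å), a nearby C-terminal
secondary-structure change, or an Asp-Gly motif. An Asn is a hotspot
only if its successor is small (≤ Asn-sized) and the residue is not
rigid (RMSD > 0.01 Å), with classes driven by CDR-loop-1 location,
φ < −75.2°, or high exposure (SASA > 89.4 Å²). A residue is called a
hotspot if **at least one** ensemble member is classified as one; the
report carries mean ± SD of the member hotspot probabilities.

A retraining toolkit (class-weighted recursive partitioning with
lookahead and cost-complexity pruning, grouped Monte Carlo
cross-validation, ROC bookkeeping) supports rebuilding the classifier
on your own labelled descriptor data.

## Worked example

Build a small synthetic five-model ensemble whose heavy-chain "CDR"
(ordinals 8–12) contains an Asp-Gly site with planted loop flexibility,
then predict:

```r
library(fvhotspots)

rec <- peptide_recipe("AKTSVPTASDGYSLTVSSAK", phi = -120, psi = 130,
  jitter_sd = 0.45, loop_ordinals = 8:12, n_models = 5, seed = 42)
ens <- build_ensemble_with_jitter(rec)
ranges <- cdr_ranges(heavy = list(c(8L, 12L), NULL, NULL),
  light = list(NULL, NULL, NULL))
pred <- predict_hotspots(ens, ranges)
dplyr::filter(pred, call == "hotspot")
#> # A tibble: 1 × 15
#>   chain_role ordinal aa    succ_aa motif cdr_loop call    hotspot_class p_mean
#>   <chr>        <int> <chr> <chr>   <chr>    <int> <chr>           <int>  <dbl>
#> 1 H                9 D     G       DG           1 hotspot             1  0.714
```

The planted Asp (ordinal 9, DG motif) is the only hotspot call: its
ensemble RMSD (≈ 0.7 Å from the 0.45 Å loop jitter) exceeds the
very-high-flexibility cut, so all five members land on hotspot class 1,
whose probability is 5/7 ≈ 0.714 (the published leaf composition).
Re-running with a single model gives RMSD 0 everywhere and zero hotspot
calls — flexibility is the gatekeeper in both trees.

Real structures enter through `read_fv_model("model.pdb", "H", "L")`
and `build_fv_ensemble()`; `extract_descriptors()` returns the full
descriptor tibble (one row per residue × model) for inspection or
export with `write_descriptors()`. Retraining:

```r
d  <- simulate_labelled_dataset(400, rule_tree = published_asp_tree(),
  noise = 0.05, seed = 1)
tr <- train_tree(d)                 # lookahead 4 / 7 alternatives / pruning level 4
cv <- monte_carlo_cv(d, n_repeats = 40, seed = 1)
glance(cv)                          # mean TP/FN/FP/TN, TPR/FPR
autoplot(cv)                        # ROC-style repeat plot
```

A command-line wrapper (`inst/cli/fvhotspots.R`) exposes `predict`,
`describe`, `train` and `scan` subcommands over PDB/FASTA/CSV inputs
with TSV + JSON reports.

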