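---
title: "Methods: temporal multi-omics integration, network reconstruction and controllability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal multi-omics integration, network reconstruction and controllability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emtomics)
```

# Scope

`emtomics` implements the computational core of a temporally resolved
multi-omics analysis of epithelial–mesenchymal transition (EMT):
cells induced with TGF-β are profiled at ten timepoints (an untreated
control, 4 h, then a daily grid out to day 12) in three biological
replicates across many molecular layers — transcriptome (MRNA),
whole-cell (WCP), nuclear (NUC), membrane (MEM), secreted (SEC) and
glycosylated (GLYCO) proteomes, phosphoproteome (PHOS), metabolome
(METABOL) and others. The package covers six analysis stages plus a
synthetic-data generator with planted ground truth:

1. preprocessing and two-step time-course differential selection,
2. cross-layer topology via RV matrix correlations and a PC-style skeleton,
3. regulatory gene classes (Class I / II-A / II-B) and kinase activity,
4. ligand–receptor (L-R) crosstalk detection and cluster scoring,
5. rooted prize-collecting Steiner forests (PCSF) with cumulative
   temporal prizes,
6. structural controllability by maximum matching.

# Preprocessing

Layers arrive as log2 intensity matrices (features × 30 samples).
`preprocess_omics()` applies, in order:

* **Valid-value filter.** Features observed in fewer than 70% of
  samples (`min_valid_fraction = 0.70`) are dropped. Features left
  with no observations are dropped, never imputed.
* **Imputation.** Either local least squares — each incomplete
  feature is regressed on its `k = 10` most-correlated complete
  features over the observed samples and missing entries take the
  fitted values — or the half-minimum rule for
  below-limit-of-detection missingness: half the feature's observed
  minimum on the linear scale, i.e. the observed log2 minimum minus 1.
  When fewer than `k` complete features exist, LLS falls back to
  half-minimum with a warning.
* **Quantile normalization** across samples (via `limma`).
* **Zero-centering per replicate block**: each feature's mean within
  one replicate's ten samples is subtracted. Each replicate is one
  isobaric-labeling batch, so this removes block-level batch offsets
  from the balanced design without touching within-block temporal
  contrasts.
* **Replicate outlier rule** (intended for metabolite-style layers,
  off by default): within each feature/timepoint triplet, replicate
  values at least one SD from the triplet mean are masked and
  re-imputed. With three replicates this rule is aggressive by
  construction; it is provided as the field-standard convention and
  left optional.

Fold changes (`log2fc_profile()`) are differences of replicate-mean
log2 intensities against the control, i.e. log2 ratios of geometric
means — a T−1 vector per feature with the control fixed at 0.

# Two-step differential selection

`select_differential()` re-implements the two-step time-course
regression *criteria* (not a port of any specific tool) for a
single-series design:

* **Step 1.** Per feature, ordinary least squares of intensity on
  polynomial time, with time coded on the uniform index grid
  0..T−1. The full model is tested against intercept-only with an
  F-test and p-values are adjusted by Benjamini–Hochberg *within the
  layer*. A perfectly flat feature (zero model and residual variance)
  is assigned p = 1 by convention.
* **Step 2.** For features passing the step-1 FDR gate, backward
  elimination removes polynomial terms whose t-test exceeds the
  per-term level; the coefficient of determination r² of the retained
  model is recorded. Features failing step 1 are never selected, so
  step 2 is not computed for them.
* **Selection.** adj. p ≤ 0.05, r² ≥ 0.6 and max |log2FC| ≥ 1
  (all three configurable).

Design choices: the polynomial degree defaults to 3 — enough to track
one or two switch-like transitions across ten points without
overfitting (degree must satisfy T ≥ degree + 2). Time is coded on
the index grid rather than calendar hours because the sampling is
nonuniform (4 h then daily) while all stage logic downstream operates
on indices; the coding is a documented argument, not a hidden
constant.

# Layer topology

Each preprocessed layer X (samples × features, feature-mean centered)
is summarized by its configuration matrix S = XXᵀ; centering is a
deliberate deviation from the uncentered textbook formula because
uncentered cross-products are dominated by feature means
(`center = FALSE` restores the exact formula). Matrix correlation
between layers i, j is the RV coefficient

RV(Sᵢ, Sⱼ) = vec(Sᵢ)ᵀvec(Sⱼ) / √(vec(Sᵢ)ᵀvec(Sᵢ) · vec(Sⱼ)ᵀvec(Sⱼ)),

which is 1 on identical configurations, invariant to orthogonal
feature-space transforms and to feature duplication, and lies in
[0, 1] for PSD inputs. Partial RV applies the recursive
partial-correlation formula to the RV matrix, recursing over the
conditioning set in sorted order; conditioning sets are capped at
size 2 (ample for ≤ 10 layers). `topology_skeleton()` runs only the
*skeleton* phase of the PC algorithm — edge orientation is
deliberately not implemented, as the collider machinery would be out
of proportion to the summary reported here. The skeleton is monotone
in ε at conditioning order 0; this is not guaranteed at higher
orders and is tested only at order 0.

Additional per-gene couplings: `per_timepoint_r2()` (adjusted R² of
cross-layer log2FC regressions per timepoint) and
`pairwise_gene_pcc()` (per-gene Pearson correlation of the two
(T−1)-long profiles; zero-variance profiles are flagged NA and
excluded downstream with a count).

# Regulatory classes and kinase activity

`assign_class()` encodes the class rule on cross-layer profile
correlations for genes quantified in ≥ 2 proteomic layers:

* **Class II-B** — any layer pair with r ≤ −0.4 (anticorrelated).
  This test runs *first*: one strong anticorrelation is biologically
  decisive (active post-translational divergence), so a gene is never
  Class I just because its other pairs agree.
* **Class I** — all pairs r ≥ 0.4 (consistent, translation-coupled
  regulation).
* **Class II-A** — everything else (uncorrelated).

`class_persistence()` reports the fraction of shared genes keeping
their label between two classifications; under independent uniform
relabeling over three classes the expectation is 1/3, which the test
suite verifies by simulation. `concordance_fraction()` counts
differential genes in a subcellular layer whose correlation with a
reference layer (e.g. WCP) stays below r = 0.1 — regulation invisible
to whole-cell measurements; genes whose reference profile does not
move (NA correlation) count as discordant.

`kinase_activity()` adopts the standard KSEA mean-enrichment form

z = (mean(substrate log2FC) − mean(all regulated log2FC)) · √m / sd(all),

computed per timepoint over kinases with m ≥ 3 mapped substrate
sites; the background is the full regulated-site set (the common
published convention — with a large regulated set the substrate
contribution to the background is negligible). No specific formula is
canonical in the literature for this scoring, so the choice is
exposed rather than hard-coded into interpretation. Absolute scores
are summed into the ternary EMT stage bins E = {t1, t2} (4 h, day 1),
E/M = {t3–t5} (days 2–4) and M = {t6–t9} (days 5–12). Location shifts
of all fold changes cancel by construction.

# Ligand–receptor crosstalk

`find_regulated_lr()` searches a configurable L-R database (a small
synthetic one ships with the generator; real analyses supply e.g. a
FANTOM5-derived table) with ligands restricted to SEC and receptors
to MEM/GLYCO, both confidently measured (adj. p < 0.01). The combined
fold change C = L + R is computed per timepoint against the control;
|C| ≥ 1 at any timepoint marks the pair regulated, the sign giving
direction. When a receptor is quantified in both membrane layers the
smaller p-value wins (ties break by layer name, deterministically).
Whether regulated pairs must additionally be codirectional
(sign(L) = sign(R)) is ambiguous as a convention; a `codirectional`
flag enforces it and defaults to off. `score_cluster_crosstalk()`
scores sender → receiver communication as the product of the
cluster-mean ligand and receptor expressions over all ordered cluster
pairs, and `lr_cooccurrence_pcc()` is a generic cohort-level
co-expression check.

# Prize-collecting Steiner forests

The scaffold is a directed typed interactome (seven interaction
types). Edge weights follow the reciprocal-outdegree rule
w(e) = 1/k_out(x) for e = (x, y), costs c(e) = 1 − w(e); outdegree is
counted on the deduplicated simple digraph so weights out of a node
sum to 1, and parallel typed edges share their pair's weight.
Self-loops are removed. `merge_causal_edges()` unions an externally
estimated signed edge list into the scaffold and recomputes all
weights; opposite-sign duplicates are kept and flagged.

Prizes are binary and cumulative: a node is prized at t when the
maximum |log2FC| over all its measurements (phosphosites and
multi-layer values collapse to the parent gene node) strictly
exceeded 1 at any timepoint up to t. Once prized, always prized —
forests at later timepoints therefore build on earlier ones. Uniform
unit prizes avoid both the ambiguity of choosing among per-timepoint
fold changes and the over-representation of extreme movers.

`solve_pcsf()` minimizes

f(F) = Σ_{v∉V_F} (β·p(v) − μ·k(v)) + Σ_{e∈E_F} c(e) + ω·κ

over forests whose nodes are reachable from the designated receptor
roots (TGFBR1/TGFBR2 by default) along selected directed edges within
hop depth D (root = depth 0). The per-tree charge ω·κ is encoded by a
dummy node with cost-ω edges to the roots. Defaults β = 10, ω = 5,
μ = 0, D = 5, constant across timepoints so that differences among
the per-timepoint forests reflect the data, not parameter drift.
μ charges the *total scaffold degree* of included nodes; it is inert
at the default 0 but implemented and tested at μ > 0.

Two solvers are provided:

* **Exact** — exhaustive enumeration of per-node parent assignments
  with structural pruning, written in C++. Guaranteed optimal;
  refuses instances whose assignment space exceeds an internal cap
  (intended for graphs up to roughly 20 candidate edges). The
  validation suite checks it against an independent edge-subset
  enumeration oracle.
* **Heuristic** — deterministic best-margin-path accretion:
  repeatedly attach the prized node whose depth-feasible directed
  path from the current forest (or from a root, paying ω) has the
  best margin (path cost minus recovered penalties), ties broken
  lexicographically by node id. Paths are found on the depth-layered
  state DAG two ways per step — plain minimum-cost, and
  prize-discounted (edge relaxation c(e) − β·p(target), exact on the
  DAG despite negative weights) so that paths scooping up several
  prized nodes at once are visible; margins are always recomputed
  from the actual path, so discounting steers the search but never
  the accounting. Because greedy accretion can overpay ω by opening
  a tree per root, can break first-attachment ties badly, and can
  spend depth budget that later attachments need, the accretion runs
  as a small deterministic portfolio — every non-empty root subset ×
  every tied-best first attachment × both path strategies — and the
  best resulting forest wins. No randomness anywhere. Reported
  objectives are recomputed by `forest_objective()`, which
  independently validates the forest certificate (unique parents,
  |E| = |V| − κ, rooted reachability, depth bound).

Directionality is an interpretive choice: trees are rooted at the
TGF-β receptors, so the default requires directed reachability; an
`undirected` relaxation exists for cross-checks against generic
undirected PCST solvers. How ties among equally optimal forests were
broken in any particular historical analysis is unknowable;
determinism here (fewest edges, then enumeration order) is a
repository convention.

# Structural controllability

`bipartite_mapping()` maps the directed network to a bipartite graph
(out-copies vs in-copies; each directed edge x→y becomes (x⁺, y⁻)).
A maximum matching (Hopcroft–Karp-class algorithm via `igraph`)
yields the minimum driver count N_D = max(N − |M|, 1); unmatched
in-copies are the driver witnesses. The floor of 1 reflects that a
perfectly matched network still needs one external input; the witness
set is non-unique and only N_D and the classes are contract-stable.
`classify_nodes()` removes each node in turn and compares N′_D with
N_D: indispensable (> — a controller), dispensable (<), neutral (=).
Which network to analyze is a pipeline convention: `run_all()` uses
the union of all per-timepoint forests.

# The synthetic-data generator

`simulate_multiomics()` emulates the study design: 10 timepoints × 3
replicates, partially overlapping feature sets drawn from a shared
gene universe, latent programs with switch-like transitions at
indices 3 and 6 of the grid (the E→E/M and E/M→M boundaries),
additive Gaussian noise on the log2 scale (the normalization space of
the real data), per-replicate batch offsets removed by
zero-centering, uniform missingness, and optional left-censoring for
metabolite-style layers. Planted structure:

* differential features carry program step profiles with amplitudes
  2 and −1.5 (well above the |log2FC| = 1 operating threshold);
* Class I genes share one profile across their layers; Class II-B
  genes have it sign-flipped in one designated layer; Class II-A
  genes receive *exactly orthogonal* per-layer profiles
  (Gram–Schmidt) — independent random profiles over nine timepoints
  would breach the ±0.4 class window by chance alone about a quarter
  of the time, which would make zero-noise recovery ill-posed;
* ligand/receptor genes (`LIG*` in SEC, `REC*` split over MEM and
  GLYCO) implement the planted regulated pairs, receptors at 75% of
  the ligand amplitude;
* phosphosites either track their parent WCP protein or carry
  independent site-level regulation (default half each).

`simulate_interactome()` plants a signaling cascade below the first
root with activation times increasing along the cascade; background
edges never point into the cascade or the roots, so at the default
β the activated cascade prefix is provably the unique optimal forest
— giving the solver a planted network answer, not just planted
prizes. `simulate_cluster_expression()` plants elevated sender-ligand
and receiver-receptor cluster means.

Per-feature noise magnitudes are free parameters of the generator:
the defaults (noise 0.25, batch 0.2 log2 units) are plausible for
TMT-style proteomics but are deliberately documented as
uncalibrated — nothing in the package claims they reproduce any real
dataset's variance structure. The generator also does not emulate
raw spectra, reads, single-cell counts, feature-dependent
missingness, or correlated noise across features; passing tests
demonstrate algorithmic correctness on known ground truth, not
robustness to every pathology of real data.

# Validation problem sizes

The test and acceptance suites run at desk scale by choice: 100
random PCSF instances of up to 12 nodes / 20 edges against the exact
solver; 500 random digraphs of up to 8 nodes against brute-force
matching enumeration; 200 null simulations of 1000 flat features and
200 power simulations of a planted amplitude-2 switch at noise 0.25;
zero-noise recovery runs on the default layer configuration with a
12-node scaffold. Headline numbers from the original biological
study (thousands of regulated features, a 115k-edge interactome)
require the full deposited datasets and versioned external databases
and are out of scope here; the package validates the *procedures* on
recoverable ground truth instead.

# Numerical conventions

* Flat features: p := 1 (never selected); zero-variance profiles:
  PCC := NA, excluded with a count.
* RV on a zero configuration matrix is an error, not 0; partial RV
  with |r| = 1 in a denominator is a "degenerate conditioning" error.
* Strict inequality (|log2FC| > 1) in the prize rule: a fold change
  of exactly 1.0 is not prized.
* Objective ties in the exact PCSF solver break toward fewer edges,
  then enumeration order; all accounting is validated to 1e−9.
* Gene identity collapsing: phosphosite ids `GENE_S123` map to their
  parent gene; miRNA and metabolite ids keep `MIR:`/`MET:` prefixes
  to avoid namespace collisions.
* Seeds: `run_all()` derives per-stage child seeds from the global
  seed by stable string hashing (always below 2³¹), so stages are
  individually reproducible.
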