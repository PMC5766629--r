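---
title: "Target prioritization and NMR discrimination: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target prioritization and NMR discrimination: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`netmet` implements the computational chain used in network-pharmacology
studies of multi-component preparations — here the Kushen alkaloid
injection studied against hepatocellular carcinoma — from PPI topology
through target ranking and pathway over-representation to an ¹H-NMR
metabolomics discrimination workflow. This vignette explains the models,
the tunable parameters, and the places where the design was genuinely open.

## PPI topology

Networks are simple and undirected: self-loops are dropped and duplicate or
reversed-duplicate interactions collapse to one edge, the same cleaning a
Cytoscape import applies to a STRING export. Distances are unweighted hop
counts; no confidence weighting is supported (deliberately — the upstream
study used none).

Two per-node parameters drive everything downstream:

* **average shortest path length** $X_i$ — the mean distance from a node to
  the *other* nodes of its own connected component. Restricting to the
  component is an assumption: published tables contain rows with
  $X_i = 1.00$, which is impossible in a connected 432-node network and
  only arises when a node's small component is averaged on its own.
  Isolated nodes have no defined value and are reported as missing.
* **betweenness centrality** $X_j$ — Brandes betweenness normalized by
  $2/((N-1)(N-2))$ with $N$ the node's component size, so values lie in
  $[0,1]$ (a star center scores exactly 1). This matches the
  NetworkAnalyzer convention under which published values reach 0.80000.
  Components with $N \le 2$ score 0.

Both conventions are validated in the test suite against an exhaustive
BFS/path-counting oracle on random graphs with up to 25 nodes.

## The R prioritization statistic

Candidate targets are ranked by an equal-weight min–max combination of the
two topology axes:

$$R = \tfrac12\,\frac{X_i - \min X_i}{\max X_i - \min X_i}
    + \tfrac12\,\frac{1/X_j - \min(1/X_j)}{\max(1/X_j) - \min(1/X_j)}$$

Smaller $R$ is more central, hence more interesting; the record attaining
both the minimum path length and the maximum betweenness scores exactly 0.
Three details are implementation decisions:

* $1/X_j$ is undefined at 0, so betweenness is clamped below at `xj_floor`
  (default $10^{-5}$, the smallest betweenness in the packaged target
  table). The clamp preserves ordering without infinities.
* The min/max cohort is exactly the record set passed in — for the packaged
  table, the 48 mapped targets, not the surrounding 432-protein network.
  This choice reproduces the printed scores for the verifiable rows.
* Ties rank by larger betweenness, then accession, for determinism.

The packaged table (`load_target_table()`) transcribes the published
48-target topology table. Its printed R column is reproducible to
±0.0005 from the printed, rounded $X_i$/$X_j$ for ten verifiable rows
(QDPR, GABRE, REG1A, CA2, C1R, CASP3, NOS2, MYC, ARG1, ASS1); several
other rows (ALDH2, SERPINC1, CA1, MMP2) are *not* consistent with their
own printed inputs — most plausibly the original ranking used unrounded
topology values. The package recomputes and documents, it does not
"correct": tests assert only the verifiable rows, and the printed column
is kept as `r_printed` for comparison.

## Over-representation and pathway impact

Gene-set enrichment is a one-sided hypergeometric tail,
$p = P[X \ge k]$, over an annotation-restricted universe: by default the
union of all genes annotated in the supplied GMT, not a genome. Query
genes outside the universe are dropped with a message. The multiple-testing
column is Benjamini–Hochberg — the original table labels its column FDR
without naming a method, so BH is an assumption, stated here. The reporting
cutoff is the nominal $p \le 0.001$ convention. Exact p-values from any
particular annotation release are not reproducible without that release;
only the procedure is tested (against exhaustive enumeration of draws on
small universes).

Pathway impact follows the MetPA idea: the impact of a matched metabolite
set on a pathway graph is the matched share of total (relative) betweenness
centrality, in $[0,1]$. Matching only leaf metabolites of a pathway gives
impact 0 even when many are matched — that is the intended topology
weighting, not a defect.

## The ¹H-NMR workflow

**Binning.** Spectra are segmented into left-closed 0.01-ppm buckets over
$\delta$ 0.50–9.00 (850 raw bins); buckets intersecting the residual-water
window $\delta$ 4.5–5.0 are dropped *before* normalization (800 retained),
so water never distorts row sums. Left-closed half-open intervals are a
convention choice; the boundary treatment is tolerant to floating-point
wobble at shared edges.

**Normalization.** Each retained-bin row is scaled to sum to 1
(total-intensity normalization). A consequence worth remembering when
reading fold changes: constant-sum data are compositional. If treatment
raises total signal, every unchanged metabolite appears slightly "down"
(closure). The packaged default panel shows this clearly — a planted
11-fold glucose increase appears as ~4-fold after closure. Fold changes
from row-normalized bins are relative, not absolute, statements.

**PLS-DA.** NIPALS PLS1 on the 0/1-coded, centered class vector. With a
univariate response the weight step is closed-form per component, so there
is no convergence loop to fail. Column scaling defaults to unit variance
(the SIMCA convention); `pareto` and `center` are available and matter (see
below). $Q^2 = 1 - \mathrm{PRESS}/\mathrm{SS}$ comes from 7-fold
venetian-blind cross-validation (folds interleave samples in order), with
centering and scaling re-estimated inside each training fold. `n_comp =
"auto"` adds components while each raises $Q^2$ by more than 0.01.

**Permutation validation.** Class labels are shuffled uniformly (the
accidental re-draw of the original labeling is not excluded) `n_perm = 200`
times; the model is *valid* when every permuted $R^2Y$ **and** $Q^2$ falls
strictly below the original. Two practical consequences, both visible in
the test suite:

* At 6 + 6 samples the label space holds only $\binom{12}{6} = 924$
  assignments, so 200 uniform shuffles re-draw the original labeling with
  probability ≈ 0.2; a re-draw ties the statistics exactly and fails the
  strict check regardless of effect size. Validity checks in this package
  are therefore run at 10 samples per group, where the label space is
  ≈ 1.8 × 10⁵ and the issue vanishes.
* With 800 bins and a dozen samples, a single permuted component can reach
  $R^2Y \approx 1$ (the cross-product matrix of hundreds of scaled noise
  bins is nearly isotropic), so the $R^2$ clause is intrinsically tighter
  than the $Q^2$ clause in wide matrices.

**Scaling choice.** On these synthetic spectra most retained bins contain
no resonance at all. Unit-variance scaling inflates every such noise bin to
the same scale as the peaks, and the weight vector spends most of its norm
on noise — cross-validated predictions shrink toward the class mean even
with enormous planted effects. Pareto or center scaling keeps the signal
bins dominant, which is why the end-to-end checks fit with `pareto` —
the same reasoning that makes Pareto scaling the common practice for
binned NMR data. Real spectra are less sparse, so unit variance behaves
better there than in this synthetic setting; the default stays `uv` for
fidelity to common software defaults, and the choice is exposed.

**OPLS-DA.** One predictive component after `n_orth` orthogonal-signal
components are removed (Trygg-style OSC). The predictive score correlates
with class at least as strongly as the first PLS score on the same data.
S-plot statistics are the covariance and correlation of each scaled
variable with the predictive score; VIP for the predictive component is
$\sqrt{p}\,|w_j|$, so the mean square of VIP is 1 for every model (a tested
invariant, as for PLS-DA's multi-component VIP).

**Differential calling.** Per metabolite, assigned-bin intensities are
summed, groups compared by a two-sided Student t-test (Welch behind a
flag), and a metabolite is called when its best assigned-bin VIP reaches
1.0 and $p < 0.05$. Fold change is reported as a magnitude ≥ 1 plus an
up/down direction, the convention of published differential-metabolite
tables. Because the VIP and t statistics are computed from the same data
they are strongly dependent; the VIP gate trims little from the nominal 5%
null call rate, so expect false calls near $\alpha$ per tested metabolite.

## Synthetic data: what it emulates, what it does not

`gen_ppi` plants hub targets of prescribed degree on a preferential-
attachment or uniform background; the designed centrality order is the
degree order, and the highest-degree hub wins the R-ranking in ≥ 90% of
replicates (tested). `gen_spectra` evaluates unit-height Lorentzians
(HWHM 0.002 ppm, the solution-NMR line shape) on a 0.001-ppm grid, scales
by group concentrations, adds i.i.d. Gaussian noise and floors at zero.
The default panel mirrors the published cell-compartment effect pattern:
16 metabolites at literature chemical shifts with the published fold
magnitudes as treated/control ratios (the β-glucose anomeric resonance
falls inside the water window, so its ring resonances are used instead).

The generator deliberately omits J-coupling fine structure, chemical-shift
drift and misalignment, baseline artefacts, inter-sample biological
covariance, and peak overlap crowding. Passing tests therefore demonstrate
the correctness and statistical behavior of the *procedure* on data with
known structure — they do not certify performance on real spectra, where
alignment and overlap dominate the error budget. Likewise the published
model statistics ($R^2X$ 0.632/0.741, $Q^2$ 0.979/0.993 for cell/medium)
depend on undeposited raw spectra and are context, not reproduction
targets.

## Problem sizes and numerical conventions

Simulation-based checks use 12–24 samples, 50–800 variables, 50-replicate
recovery experiments and 100-replicate validity experiments with 50–200
permutations — sizes chosen so every distributional claim rests on enough
replicates while a full run of the suite stays in the minutes range.
Numerical conventions: degenerate min–max axes contribute 0 to R;
zero-variance columns are centered but not scaled; Q² folds never leave a
single class in training (an error if requested); bin/exclusion boundary
comparisons use a 10⁻⁹ tolerance; the recovery experiment plants
offsetting up/down effect pairs so constant-sum closure does not leak
class signal into unchanged metabolites.

## Known limitations

* The BH step-up is not idempotent; re-adjusting an adjusted vector is a
  user error the package does not try to detect.
* The R statistic is cohort-relative: adding or removing one target changes
  every score. That is inherent to min–max scaling and is why the packaged
  table is scored as a fixed 48-row cohort.
* `pathway_impact` requires the matched metabolites to be nodes of the
  pathway graph; name harmonization between assignment tables and pathway
  graphs is the caller's responsibility.
* Compositional (row-normalized) fold changes understate or even invert
  weak changes when strong changes dominate total intensity; interpret
  directions of small-magnitude calls with care.
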