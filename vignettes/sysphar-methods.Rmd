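---
title: "Methods: dose-response modeling, enrichment, connectivity, chemical similarity, and causal network inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-response modeling, enrichment, connectivity, chemical similarity, and causal network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`sysphar` implements a systems-pharmacology workflow for characterizing the
mode of action of a compound from concentration-series omics data. This
vignette documents the models, the tunable parameters, the synthetic-data
world used for validation, and the numerical and design choices made where
the design was genuinely open.

## 1. Concentration-response linear model

For each feature (gene, protein, phosphoprotein) measured on a log2 scale,
`fit_dose_response()` fits by ordinary least squares

$$ y = \beta_0 + \beta_1 \cdot c + \beta_2 \cdot \mathrm{cell} + \varepsilon,$$

where $c$ is the treatment concentration in native micromolar units (no
rescaling, so $\beta_1$ is in log2 expression units per µM) and
$\mathrm{cell}$ is a set of cell-system indicator covariates, included when
`adjust_for_cell_system = TRUE` (the "core gene", cell-system-independent
model) and omitted for per-cell-system fits. Two-sided p-values for
$\beta_1$ come from the t distribution with the residual degrees of freedom;
the false discovery rate is controlled with the Benjamini–Hochberg step-up
(`bh_adjust()`, computed jointly over all features). `compute_srp()` provides
the complementary pairwise view: one treatment concentration against its
vehicle control, by equal-variance two-sample t-test per feature.

Deliberate choices:

* **Plain OLS, not moderated statistics.** Empirical-Bayes variance
  moderation (as in `limma`) changes the t-statistics in ways that depend on
  unpublished shrinkage parameters; the plain linear model is the declared
  contract here, and moderation is an extension point.
* **Zero-residual fits.** A feature lying exactly on a non-flat line has no
  finite t-statistic. It receives $p = 0$ and a `degenerate` flag rather
  than an infinite statistic; `rank_genes()` then places such features
  beyond the finite extremes on the side of their slope sign, ordered by
  $|\beta_1|$, keeping the ranking total while marking unreliability. A
  feature that is exactly constant gets $\beta_1 = 0,\ t = 0,\ p = 1$.
  "Exactly" is judged at relative tolerance $10^{-12}$.
* **Missing values** are dropped per feature; a feature without at least one
  residual degree of freedom gets `NA` statistics and the flag.

## 2. Gene set enrichment (weighted Kolmogorov–Smirnov)

Genes are ranked by decreasing $\beta_1$-associated t-statistic
(`rank_genes()`, ties broken lexicographically by gene id for platform
determinism). `enrichment_score()` walks the list with the standard weighted
KS running sum: increment $|s_i|^\alpha / \sum_{hits}|s|^\alpha$ at set
members, decrement $1/(N - |S|)$ elsewhere; the enrichment score is the
maximum-magnitude deviation. Two documented numerical rules:

* **Tie rule.** When the positive and negative extremes tie in magnitude
  (within $10^{-9}$ relative — which also absorbs floating-point
  accumulation differences between implementations), the positive extreme is
  taken. Without this rule, independently coded implementations can disagree
  on exact ties purely through summation order.
* **All-zero hit weights** (possible with $\alpha > 0$ on degenerate
  rankings) fall back to equal weights.

`gsea()` uses a *gene-permutation* null: for each set size, `n_permutations`
random same-size gene subsets are scored (the null depends only on size, so
equal-size sets share one pool). This choice — rather than phenotype
permutation — reflects that the ranking derives from a fitted model
coefficient, not from exchangeable sample labels. NES is ES divided by the
mean |null ES| of the same sign; nominal p-values are one-sided within the
sign class with a +1 pseudocount (never exactly zero); FDR follows the
sign-stratified ratio method over the pooled null NES. Defaults:
$\alpha = 1$, `min_size = 5`, `max_size = 500`, `n_permutations >= 100`.

One consequence worth knowing: on *noiseless* synthetic data the ranking is
degenerate (responders at artificial extreme scores, everything else at 0),
and with $\alpha = 1$ any set containing a single responder saturates near
$ES = 1$. For planted-truth checks at zero noise the package's tests
therefore use $\alpha = 0$ (the classic unweighted statistic), where only
the order matters; with realistic noise the default $\alpha = 1$ behaves as
usual.

## 3. Signature connectivity with an empirical null

`run_connectivity()` compares a query differential signature (the per-gene
t-statistics of the combined linear model) against a perturbagen signature
library restricted to the common gene universe (`match_genes()`, in library
gene order). Each library signature is scored by Spearman correlation
(Pearson on average ranks); scores are collapsed to the best condition per
perturbagen (`collapse_best()`, lexicographic tie-break).

Significance is calibrated empirically: `empirical_null()` runs random
signatures — uniform permutations of the actual query values, preserving its
marginal distribution (configurable to Gaussian draws) — through the *same*
scoring-and-collapsing pipeline and pools all best-per-perturbagen
correlations into a single null distribution. The default of 100 random
signatures mirrors standard practice for this analysis. The one-sided
empirical p-value is $(1 + \#\{pool \ge \rho\}) / (1 + |pool|)$ with
retention at $p \le 0.001$; the +1 pseudocount means retention at that
threshold requires a pool of at least 999 values (the package warns
otherwise). The null is pooled across perturbagens rather than
per-perturbagen, keeping the pool large; anticorrelated hits are reported
but not significance-tested.

## 4. Chemical similarity fingerprints

`parse_smiles()` reads a deliberately scoped SMILES dialect: organic-subset
and bracket atoms with charge, ring closures, branches, explicit bond
orders, aromatic lowercase notation. Aromaticity is taken exactly as written
(no perception — this removes a large under-specified subsystem), and
stereochemistry and isotopes are rejected.

Three 512-bit binary fingerprints are provided:

* **PathFp** — every simple path of up to 7 atoms, serialized as atom
  symbols (lowercase aromatic, charge suffixed) joined by bond symbols
  `- = # :`, reading direction chosen lexicographically;
* **SphereFp** — for every atom and radius 1–5 bonds, the induced
  neighborhood subgraph serialized canonically (node-count prefix, node
  attributes in canonical order, sorted edge list; the central atom is
  marked). Canonical ordering comes from iterative neighborhood refinement
  on (symbol, degree) colors with individualization backtracking, so the
  encoding is invariant under graph isomorphism. The node-count prefix is
  part of the serialization because without it two elementary neighborhoods
  (e.g. a bare carbon and a C–C pair) happened to collide under the hash;
* **FragFP** — dictionary lookup: bit $i$ is set iff dictionary fragment
  $i$ occurs among the molecule's path/sphere strings. The proprietary
  512-fragment dictionary of the original descriptor is not public, so a
  shipped open dictionary (~100 short path fragments generated
  deterministically from prototype molecules in
  `default_fragment_dictionary()`) replaces it; bit-compatibility with the
  original software is explicitly a non-goal.

Hashed fingerprints use FNV-1a (64-bit) on the canonical fragment string,
modulo 512 — deterministic and platform-independent; golden bit positions
are frozen in the test suite. `tanimoto()` is $|a \wedge b| / |a \vee b|$
with the both-empty convention of 1.0; `similarity_matrix()` produces the
heat-map-ready distance table of a panel against a reference molecule.

## 5. TF activity and causal network inference

`tf_activity()` scores each transcription factor as the weighted,
mode-adjusted mean of its regulon targets' t-statistics,
$\mathrm{raw} = \sum w \cdot \mathrm{mode} \cdot t / \sum w$, with a
gene-label permutation z-score. The top K (default 10 — a pragmatic cap to
keep the network visualizable) by $|z|$ are selected.

`build_ilp()` encodes the causal question as an integer program over a
signed directed prior knowledge network: node states in $\{-1, 0, +1\}$, a
non-perturbation node may hold a non-zero state only if some incoming edge
carries a consistent signal from a non-zero source, used edges must form a
DAG rooted at the perturbation, and the objective is

$$\sum_{T \in TFs} w_T\,[\sigma(T) \ne \hat\sigma(T)] \; + \;
  \beta\,\#\{\sigma \ne 0\}.$$

Defaults: $w_T = |z_T|$ from `tf_activity()`, $\beta = 0.1 \cdot \bar w$
(both configurable; $\beta > 0$ is required — with $\beta = 0$ optimal
solutions are not sparse and the 0–100 aggregation loses meaning). The
perturbation node always carries its fixed sign and then counts toward the
node penalty; sign `"free"` solves both fixings and keeps the better
objective (ties keep both solution sets).

**Solver.** No external MILP backend is assumed. The propagation + acyclicity
constraints are equivalent to: every non-zero node is reachable from the
perturbation through sign-consistent edges within the non-zero set. The
solver first reduces domains with signed-reachability arguments on the
doubled graph (a state that cannot be reached, or that can never propagate
to a measured TF in its measured sign, costs $\beta$ without benefit and is
excluded from optima), then runs depth-first branch-and-bound with cost
pruning, enumerating *all* optimal assignments up to `enumerate_cap`
(default 100). This is exact for the desk-scale networks the package
targets (a guard rejects more than ~24 undetermined nodes). The test suite
checks the solver against exhaustive state enumeration.

`aggregate_solutions()` reports per node
$100 (n_{up} - n_{down}) / n_{solutions}$, a *signed* variant of the usual
0–100 activation value (the unsigned magnitude is also emitted for parity
with that convention); an edge is included if used in at least one optimal
solution, annotated with its use frequency, where a used edge is a
sign-consistent edge between non-zero nodes on a perturbation-to-TF path.

## 6. The synthetic world

`sim_config()` fixes the stated experimental design: concentrations 0, 100,
200, 300, 400 µM with a vehicle control in every cell system, four cell
systems, three replicates per condition, log2-scale values. Defaults chosen
once and documented:

* responder slopes uniform in 0.002–0.008 log2 units/µM (0.8–3.2 log2 fold
  change at the 400 µM top dose — the magnitude range of strongly responding
  oxidative-stress genes);
* residual noise SD 0.25 log2 units (typical microarray replicate scatter);
* baselines $\beta_0$ drawn once per gene × cell system (uniform 4–12), so
  the cell-system covariate genuinely matters;
* replicates default 3 (a typical in-vitro omics design).

A single global seed expands into per-component child seeds through the
documented integer hash in `child_seed()`, so stages can be regenerated
independently and runs are bit-identical under a fixed seed.

Planted structure: `gen_gene_sets()` draws ≥80% of planted-set members from
sign-concordant responders; `gen_signature_library()` builds mimic
signatures by blending the query's standardized ranks with independent
noise, calibrating the mixing weight by bisection until the achieved
Spearman correlation is within 0.01 of target (a rank-blend targets the rank
statistic directly); `gen_pkn()` plants a signed spine from the perturbation
node to a junction with TFs attached, TF signs equal to the sign product
along their path, and wires distractor edges only *away from* planted-path
and TF nodes — making the planted path the unique optimum, so an exact
solver must recover it with all node values at ±100. Because the spine
always connects the perturbation, the generator cannot produce a
disconnected perturbation node. Regulon modes are set to the TF's sign so
that positively responding target genes give the TF a concordant activity
score.

**What a green test does and does not establish.** The synthetic world has
i.i.d. Gaussian noise, linear responses, independent library signatures and
a uniquely identifiable planted path. Real data violate all of these
(correlated genes, saturating dose-response, batch structure, redundant
network paths); green tests certify the *algorithms* — estimator
correctness, calibration of the empirical nulls, exact optimization — not
robustness to those violations.

## 7. Pipeline and reproducibility

`run_pipeline()` executes simulate → dose → {gsea, connect} → network (chem
independent) from one configuration, each stage reading only the declared
TSV/GMT/SIF/JSON files of its predecessors, and writes a manifest with the
package version, all child seeds and per-file MD5 checksums. The
configuration file format is JSON (`read_pipeline_config()`, versioned
schema, flags override file values); JSON was chosen over YAML because the
target environment ships no YAML parser and the schema needs nothing YAML
adds. `pipeline_demo()` is the one-command synthetic end-to-end run; running
it twice with the same seed produces byte-identical outputs.

## 8. Known limitations

* The linear model ignores saturation; strongly sigmoidal responses will
  under-report slopes.
* GSEA FDR uses the pooled-null ratio method; with very few sets the
  estimate is coarse.
* The connectivity null treats genes as exchangeable under permutation;
  correlated query structure is not preserved.
* The ILP solver is exact but exponential in the worst case; it targets
  reduced, desk-scale networks, not genome-scale prior knowledge networks.
* FragFP uses an open replacement dictionary; distances are not comparable
  with those from the original proprietary dictionary, and numerical
  equality with published heatmaps is out of reach by design.
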