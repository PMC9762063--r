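---
title: "Learning pathways of intervention influence on physical activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning pathways of intervention influence on physical activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

E-health interventions change physical activity (PA) by influencing
socio-cognitive determinants — self-efficacy, attitude, intention, habit,
planning, commitment, social concepts — which in turn change behaviour.
Classical mediation analyses test one path at a time; `pabn` instead learns
the whole dependency structure as a temporal hybrid Bayesian network from
integrated longitudinal trial data, stabilises it by bootstrap, and distills
the subgraph of directed paths from the intervention indicator to the PA
outcomes at 6 months (short-term, T2) and 12 months (long-term, T3).

Because participant-level data of this kind are not publicly deposited, the
package ships a synthetic-cohort generator that reproduces the *statistical
shape* of such an integrated database — the variable inventory, the
per-study measurement availability that creates block missingness on
integration, and intervention effects propagating through determinants —
with a known ground-truth network, so every stage of the workflow is
testable end to end.

## Model class

The model is a conditional-Gaussian (CG) Bayesian network over the measured
variables:

* discrete nodes (gender, education, the intervention indicator) are
  multinomial, with a conditional probability table per configuration of
  their discrete parents;
* continuous nodes (concept scales, minutes/week of PA, age) are Gaussian,
  with an intercept, one linear coefficient per continuous parent and a
  noise variance, all per configuration of their discrete parents;
* a continuous node can never parent a discrete node — this keeps the joint
  likelihood tractable and is the standard CG restriction.

Structures are restricted by four rule families, each decidable per arc:

1. **temporal** — no arc may point into an earlier measurement wave
   (T0 &lt; T1 &lt; T2 &lt; T3);
2. **type** — no continuous parent of a discrete node;
3. **role** — demographics accept only other demographics as parents;
   baseline (T0) measurements accept only demographics and other baseline
   measurements; the intervention indicator accepts only demographics and
   baseline measurements (in the hybrid class its admissible parents are
   thus the *discrete* demographics — the type rule excludes the continuous
   ones);
4. no self-loops; acyclicity is enforced by the search and is automatic
   across waves by rule 1.

These restrictions remove obviously non-causal orientations, so most arc
directions in the learned model are forced by design rather than by the
data.

## Structure learning

Scoring uses the BIC in the convention *maximized log-likelihood −
(k/2)·ln n*, higher is better, with maximum-likelihood (unsmoothed)
estimates. The score decomposes over nodes, so the greedy search caches one
local score per (node, parent set). Free parameters per discrete node are
(r−1)·q and per continuous node (p+2)·q, where r is the level count, p the
continuous-parent count and q the discrete-parent configuration count; the
penalty is applied locally, which is equivalent to a global penalty because
the counts add.

`hill_climb()` starts from the empty graph and repeatedly applies the best
strictly-improving single-arc move (add, delete, reverse) among the
constraint-admissible, acyclicity-preserving candidates, stopping at a
local optimum. Ties are broken lexicographically by (child, parent, move
type), so runs are deterministic; a seed is consumed only by optional
random restarts (default 0 — robustness comes from bootstrap averaging,
not restarts). A minimal improvement of 1e−6 guards against floating-point
move cycles. On a 5-node tiered fixture the greedy optimum coincides with
the exhaustively enumerated global optimum (verified in the test suite).

### Missing data: structural EM with expected sufficient statistics

The integrated table has two missingness layers: deterministic design
blocks (a study never measured a concept at a wave) and record-level MCAR.
`structural_em()` alternates:

* **E-step** — complete the data under the current model. For each record,
  discrete configurations compatible with its observed discrete cells are
  enumerated (feasible: at most gender × education × intervention = 12);
  conditional on each configuration the continuous block is jointly
  Gaussian, so missing continuous cells have an exact conditional mean and
  covariance given the observed ones.
* **M-step** — hill-climb and refit parameters on the completed data.

The default E-step is *soft*: the conditional means fill the table, and the
per-record conditional covariances are carried into every Gaussian local
score and parameter fit through corrected cross-moment matrices
(`E[xxᵀ] = m mᵀ + C`). This matters. Plain conditional-mean completion
(available as `estep = "hard"`) gives imputed mediators shrunken variance,
so they fail to screen their ancestors, and the search then adds spurious
chain-skipping arcs (e.g. a T1 variable pointing straight at its
grandchild's T3 wave); at 20% extra MCAR on the 14-node experimental truth
this costs a median of ~5 extra arcs relative to the complete-data result,
while the soft E-step costs ~0. A stochastic (draw) completion was also
evaluated and is worse than either: single-draw noise destabilises the
stopping rule. Missing *discrete* cells are completed by posterior mode in
both flavours.

Iteration starts from the empty-graph model (marginal means/modes, with
marginal variances as the initial covariance correction) and stops when the
completed-data BIC improves by less than `score_tol` (default 1e−4) or
after `max_iter` cycles (default 25). A step that would lower the score
terminates the loop with the previous model kept, so the reported score
trajectory is non-decreasing by construction. Every variable must be
observed in at least `min_obs_frac` of records (default 5%) — below that a
local model rests on too few cases to be worth reporting.

## Stability: bootstrap, SHD diagnostics, averaging

`bootstrap_confidence()` resamples records with replacement to the original
size, relearns per resample, and reports the fraction of resampled models
containing each *directed* arc. Confidence is direction-specific because
the tier system forces most orientations; counting adjacencies would blur
exactly the directional claims the fragment makes. Resampling is stratified
by study of origin: the integrated table is heterogeneous by design, and an
unstratified resample can lose a small study's design block entirely. (This
stratification is a package choice; an unstratified bootstrap is obtained
by passing `strata = NULL`.)

`select_n_boot()` diagnoses how many resamples are enough: it draws the
largest candidate count once, forms the threshold-averaged structure from
each nested prefix, and returns the smallest candidate whose averaged
structure is identical (structural Hamming distance 0) to the next one.
`shd()` counts arc insertions, deletions and reversals, a reversal costing
one.

`average_network()` keeps the arcs whose confidence meets the threshold —
**inclusive**, so 0.60 survives a 60% threshold, reading "at least 60%"
literally. Thresholding a tally of DAGs can in principle leave a directed
cycle within a wave; the repair removes the lowest-confidence arc of each
cycle until acyclic and logs every removal.

## The fragment and its annotation

`extract_fragment()` first drops arcs below the display stability threshold
and then keeps exactly the arcs lying on at least one directed path from
the intervention node to any PA target. In a DAG, an arc u→v lies on such a
path iff u is reachable from the source and some target is reachable from
v, so the extraction is two reachability sweeps; the test suite proves it
equal to exhaustive simple-path enumeration on random tiered DAGs.
Extraction is idempotent and monotone in the threshold. A consequence worth
knowing: a determinant adjacent to an outcome only by an *outgoing* arc
from the outcome falls outside the fragment — direction, not proximity,
decides membership.

Each fragment arc carries two annotations:

* **stability band** (drawn as line thickness): 1–4 at cut-offs 0.7, 0.8,
  0.9 of bootstrap confidence;
* **MI band** (drawn as 1–3 asterisks): jackknife bias-corrected mutual
  information between the endpoint columns, banded at the 33% and 67%
  quantiles *of the fragment's own arcs* — relative banding, with the
  realized cut-off values and the MI min/max reported alongside the graph
  so bands remain interpretable across models. A value exactly on a
  cut-off goes to the higher band (a deterministic choice; the boundary
  case is measure-zero in practice).

`jackknife_mi()` computes the plug-in estimate appropriate to the type pair
— Gaussian MI −½ln(1−r²) for continuous–continuous, pooled-minus-
conditional Gaussian entropies for discrete–continuous, the contingency
plug-in for discrete–discrete — on pairwise complete cases (pair-level
deletion maximises usable records per arc; listwise deletion would discard
most of a block-missing table), then applies the leave-one-out jackknife
correction n·Î − (n−1)·mean(Î₋ᵢ), floored at 0. All leave-one-out values
are computed by O(n) downdating of sufficient statistics, not by n refits.
It requires at least 10 complete pairs and positive variance; Gaussian
entropies use a 1e−12 variance floor so a degenerate level cannot produce
an infinite estimate.

## The synthetic generator

`build_default_truth()` encodes: demographics (age in years, uncategorised;
binary gender; 3-level education), the binary intervention indicator,
eleven determinant concepts measured on 1–5 scales (intention on 1–10) at
the waves where any of the five studies measured them, and a minutes/week
PA outcome at all four waves. The five study designs carry the per-study
availability masks and the studies' relative sizes (scaled by a factor,
default 0.2, for desk runtimes); integration of the per-study blocks
creates the characteristic ~30% design missingness, and an extra MCAR layer
(default 5%) models residual nonresponse. One alignment choice deserves
note: the extracted measurement table does not always make explicit which
waves a three-wave concept occupies; concepts are left-aligned to T0–T2
except habit, which is placed at T0, T2, T3 — the only assignment
consistent with habit's documented role at both later waves.

Ground-truth effects are specified on a standardized scale (autoregressive
0.55, cross-concept 0.30–0.40, intervention shifts 0.2–0.5 SD) and
converted to raw coefficients; residual variances are set so marginal SDs
stay near their nominal values down the chains (floored at 0.45 SD).
Determinant scales are clipped to their range after sampling and PA is
truncated at 0; the clipping touches ~1–2% of values, a mild non-Gaussian
contamination the learner tolerates. Intervention assignment uses the
pooled allocation probability of the five trials (0.737) rather than
per-study allocation.

What the generator does **not** emulate: the real studies' observed means
and covariances (no public moments exist to calibrate against), MNAR or
dropout mechanisms, item-level psychometrics, floor/ceiling response
styles, or within-study clustering. Passing tests therefore demonstrate
that the *machinery* recovers known structure under the stated conditions —
not that any substantive finding about PA determinants transfers to real
cohorts.

`build_compact_truth()` is the experimental workhorse: 14 nodes
(intervention; attitude, self-efficacy, intention, habit over T1–T3 where
kept; PA at T1–T3), 20 arcs, moderate effects, one full-availability study,
20% MCAR option. Structure-recovery, EM-degradation, bootstrap and replay
experiments in the tests and the acceptance script run on it at n = 2000;
the analysis scripts run the full 47-variable inventory at 15% of the
nominal study sizes (~900 records) with 30 bootstrap resamples and
EM capped at 2 cycles per resample — sizes chosen to keep a complete
desk run in minutes while leaving every qualitative behaviour visible.

## Numerical and degenerate-input choices

* Local Gaussian fits use QR least squares on complete data and
  normal-equation solves on expected moments; a rank-deficient or
  zero-variance local model scores −Inf, so the search simply never adopts
  it.
* CPTs are fitted with a Laplace pseudo-count of 1 (configurable to 0) so
  EM never meets a zero probability; *scoring* always uses the unsmoothed
  ML frequencies.
* Conditioning on observed continuous blocks falls back to a pseudoinverse
  when a covariance block is singular (deterministic test fixtures with
  zero noise); a record whose evidence has zero density under every
  configuration falls back to the model marginals.
* `impute_record()` on a fully observed record is the identity; on a fully
  missing one it returns marginal means/modes.
* All randomness descends from one root seed through a deterministic
  mixing function (`derive_seed()`), so stages and individual bootstrap
  replicates are independently reproducible and all derived seeds stay
  within 32-bit range.

## Known limitations

* Greedy search finds local optima; with informative tiers and moderate
  effects this matches the global optimum on small fixtures, but no
  guarantee exists at 47 nodes.
* Arc confidence is computed per directed arc, not per equivalence class;
  within-wave arcs whose direction the data cannot identify can split
  their confidence across the two orientations and both may fall below
  threshold.
* The bootstrap quantifies sampling stability given the observed cohort;
  a fluke association *in* the cohort is stably recovered, not averaged
  away — separating those requires replicate cohorts, which only a
  simulation setting provides.
* Linear-Gaussian locals cannot represent interactions among continuous
  parents or nonlinear dose-response; the CG class excludes discrete
  children of continuous parents by construction.
* At stratum sizes of a few hundred with 90%-missing design blocks, some
  variables fall below any sensible minimum-observation floor and their
  local models are effectively marginal.
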