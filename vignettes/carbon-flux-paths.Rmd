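---
title: "Expression-guided carbon flux paths: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-guided carbon flux paths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icfp)
```

## The problem

A metabolic pathway proposed for a phenotype should satisfy two demands that
classical graph path finding ignores. First, mass balance: a path that
consumes a cofactor or throws off a by-product only "works" if other
reactions in the network can regenerate or drain those species at steady
state. Second, evidence: among the many balanced routes between two
metabolites, the ones whose enzymes are actually expressed under the studied
condition are the interesting ones. This package couples the two: paths are
found over *carbon-exchange arcs* (substrate→product pairs within a reaction
between which carbon atoms really move, so currency metabolites such as ATP
or NADH never act as shortcuts), every candidate must admit a steady-state
flux pattern, and the ranking is driven by expression data — including the
expression state of the *off-path* reactions recruited for balancing.

## The path model

Let $C$ be the metabolites (internal set $I$, external set $E$, growth
medium $E_m \subseteq E$), $R$ the reactions after each reversible reaction
is split into an irreversible forward/backward pair, $S_{cr}$ the
stoichiometric coefficients and $d_{ijr} = 1$ where reaction $r$ transfers
carbon from $i$ to $j$. Binary $u_{ij}$ selects arcs of the path, binary
$z_r$ marks active reactions, continuous $v_r \ge 0$ are fluxes. For a query
$\alpha \to \beta$ the constraints are:

* degree constraints: exactly one arc leaves $\alpha$ and one enters
  $\beta$; no arc enters $\alpha$ or leaves $\beta$; in-degree equals
  out-degree at every other metabolite, and in-degree is at most one
  everywhere (a simple path; applying the revisit bound to $\alpha$ too is
  vacuous and harmless);
* $\sum_r S_{cr} v_r = 0$ for $c \in I$ and $\ge 0$ for
  $c \in E \setminus E_m$; medium metabolites carry no balance constraint
  at all (free uptake and excretion);
* $z_r \le v_r \le N z_r$: an active reaction runs at flux at least 1 and
  at most the cap $N$;
* $z_\lambda + z_\mu \le 1$ for each split reversible pair;
* $u_{ij} \le \sum_{r:\,d_{ijr}=1} z_r$: every path arc is witnessed by an
  active reaction. Variables $u_{ij}$ are only created for ordered pairs
  backed by at least one carbon arc (the support constraint would force all
  others to zero; pruning them shrinks the model with no semantic change),
  and self-pairs $i = j$ are excluded.

$\alpha$ and $\beta$ keep their ordinary class-based balance constraints;
they get no special exemption.

## Three-stage ranking and enumeration

Given a partition of $R$ into highly (H), medium/invariant (M) and lowly
(L) expressed sets, the solve is lexicographic:

1. minimise $V_1 = \sum_{r \in L} v_r$;
2. minimise $V_2 = \sum_{r \in M} v_r$ subject to the stage-1 optimum;
3. minimise the arc count subject to both.

A single weighted objective would need weight ratios on the order of the
flux cap and is numerically fragile; three sequential solves avoid that.
Stage optima are carried forward as inequality caps
$\sum v \le \mathrm{round}(V^\*) (1+\varepsilon) + \varepsilon$ rather than
the equalities of the formal statement: the staged sum can never fall below
its optimum, so the inequality preserves the lexicographic semantics while
tolerating round-off. $\varepsilon$ is kept at $10^{-12}$ (`stage_tol`)
because any cap slack $s$ can be converted into an objective bias of up to
$N s$ through the big-M coupling — with a loose $10^{-6}$ slack and
$N = 1000$ the later stages would be biased by $\sim 10^{-3} \cdot s/\varepsilon$
in the worst case, which is visible against the reference implementation.
If a stage is infeasible under a cap (possible through round-off only), it
is retried once with a tenfold looser cap before erroring.

The $k$-th solution is obtained by adding, for every accepted solution, the
cut $\sum_{(i,j) \in \text{arcs}} u_{ij} \le |\text{arcs}| - 1$ and
re-running all three stages; cuts accumulate over the whole enumeration, so
solutions are pairwise distinct and their $(V_1, V_2, \text{length})$
tuples are lexicographically non-decreasing. Ties between solutions with
identical tuples are genuine ambiguity: their relative order is
solver-dependent and deliberately unspecified. Enumeration stops early with
a message when the solution space is exhausted.

A classification with neither H nor L reactions carries no expression
signal. The solver then reduces to the plain carbon-flux-path problem —
length minimisation only — and reports $V_1 = V_2 = 0$. Minimising
$\sum_{r \in M} v_r$ when $M = R$ would instead impose a flux-parsimony
criterion that the expression-free method does not have.

After stage 3 the binaries are fixed and one more linear program picks,
among the flux patterns realising that solution, the one with minimum total
flux. This does not touch the staged objectives; it only removes the
arbitrariness of the flux vertex that a pure length minimisation happens to
return (which can otherwise park irrelevant fluxes at the cap $N$).

## Classifying reactions from expression data

The series route mirrors a growth-rate compendium analysis:

1. series are log2-transformed exactly once (raw intensities must be
   positive) and restricted to genes that appear in the network's GPR
   rules;
2. features with fewer than `min_measurements = 4` non-missing values are
   declared invariant without testing — a two- or three-point series cannot
   support a trend test with meaningful residual degrees of freedom;
3. each remaining series is fit by ordinary least squares of log2
   expression on the condition value (the condition labels are the
   covariate; with equally spaced conditions an index covariate gives the
   same calls). The tested effect is the fitted change across the full
   condition range, $\hat\Delta = \text{slope} \times \text{range}$,
   because the fold-change threshold refers to the change between the
   first and last condition. The p-value for the composite null
   $|\Delta| \le \tau$, $\tau = \log_2 T$, is the sum of two shifted tails,
   $p = P(t_d > (|\hat\Delta|-\tau)/se) + P(t_d > (|\hat\Delta|+\tau)/se)$,
   capped at 1 — the same form as limma's `treat` statistic. Under a point
   null this approaches 1; at the boundary $|\Delta| = \tau$ it is at least
   1/2. Degenerate series get conventions rather than errors: zero
   condition variance → sign 0, $p = 1$; zero residual variance → the
   limiting step test ($p = 0$ if $|\hat\Delta| > \tau$, else 1);
4. per-feature variance moderation (shrinkage toward the pooled residual
   variance with `prior_df` extra degrees of freedom, default 4) is
   available but off by default: the default path is reproducible from the
   stated formula alone, while the moderated path approximates — not
   replicates — empirical-Bayes machinery;
5. gene- and protein-level calls are merged per gene locus with the protein
   call taken wholesale (p-value *and* sign) where present, since protein
   abundance sits closer to metabolic phenotype; features with neither
   measurement are non-differential by construction;
6. the merged p-values are FDR-corrected (Benjamini–Hochberg by default; a
   Grenander/ECDF tail-area estimator with a tail-based null-proportion
   estimate is selectable via `fdr_method = "grenander"`), and features
   with $q$ strictly below `fdr_cut = 0.2` are called up or down by the
   sign of the regression slope.

The fold-change route thresholds per-gene log2 fold changes at
`fc_cutoff = 0.5850` ($= \log_2 1.5$ to four decimals).

Either way, gene states are propagated to reactions through the GPR rules
under ternary logic — up $= +1$, invariant $= 0$, down $= -1$, AND = min
(a complex is only as available as its scarcest subunit), OR = max (one
expressed isoenzyme suffices) — and a reaction is H, M or L as its rule
evaluates to $+1$, $0$ or $-1$. Reactions without a rule, and genes without
data, evaluate to 0: absence of evidence never pushes a reaction out of M.
Both members of a split reversible pair share one rule and hence one state.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `fold_threshold` (T) | 1.5 | fold change tested against (ratio scale) |
| `fdr_cut` | 0.2 | strict upper bound on q for a differential call |
| `fc_cutoff` | 0.5850 | log2 threshold of the fold-change route |
| `min_measurements` | 4 | minimum non-missing points per tested series |
| `prior_df` | 4 | prior degrees of freedom if moderation is enabled |
| `big_m` (N) | 1000 | flux cap linking v and z; a warning fires if any optimal flux comes within 1% of it (the flux scenario may be truncated — raise N) |
| `flux_floor` | 1 | minimum flux of an active reaction (the model's unit) |
| `stage_tol` | 1e-12 | relative slack when carrying a stage optimum forward |
| `k` | 1 | number of ranked paths to enumerate |

## The built-in solver

No linear- or integer-programming library is a dependency: the package
carries a dense two-phase primal simplex and a depth-first branch-and-bound
over the binary variables (most-fractional branching, nearest-integer child
first, incumbent pruning, no MIP gap — optimality is proven by exhausting
the tree). Numerical behaviour on big-M models is the main design concern,
and several standard safeguards are built in:

* power-of-two row and column equilibration (exact in binary floating
  point) before solving;
* periodic refactorisation of the tableau from the original data, with
  optimality/unboundedness verdicts only ever accepted on freshly
  refactorised numbers;
* a Harris-style two-pass ratio test biased toward large pivot elements;
* an exact fallback that refactorises after every pivot and applies the
  classical lexicographic leaving-row rule (cycling-free), plus a
  deterministic right-hand-side perturbation as a last resort, with the
  optimal basis snapped back to the true right-hand side; marginal
  infeasibility verdicts (phase-1 optima just above tolerance, as arise at
  branch-and-bound nodes whose fixings barely exceed a stage cap) are
  accepted only when independent perturbed runs agree on them;
* dual-simplex repair of small primal infeasibilities left by the fast
  pass, and a final "polish" solve of the winning integer configuration so
  reported objective values are exact to solver precision.

The brute-force reference (`brute_force_icfp()`) enumerates every simple
path over the carbon-arc graph explicitly (guarded to networks of at most
12 metabolites), solves the two flux stages for each path with its arcs
fixed — off-path reactions stay free for balancing — and sorts by
$(V_1, V_2, \text{length})$. Its per-path stage problems keep $z$ integral:
relaxing the activity indicators would understate $V_1$ and $V_2$ whenever
an optimal balancing would use a flux below the floor. Model construction
is independent of the incremental path model; only the low-level solver
kernel is shared. The test suite demands exact tuple agreement between the
two routes on batches of random networks.

## What the generators emulate — and what they do not

`random_network()` plants a chain of unit conversions from a medium source
to an external target (so at least one balanceable path always exists, by
construction and verified at generation), then adds random reactions with
coefficients in $\{-2,-1,1,2\}$, sign-consistent carbon arcs, optional
reversibility and random GPR rules. `synthetic_expression()` draws linear
log2 trends (total change $\pm$`effect_log2` across the condition range,
default $2\log_2 1.5$ over 8 conditions) with i.i.d. Gaussian noise
(sd 0.25 by default), and flags a random 30% of features with an additional
protein series to exercise the merging rule. The defaults are the study
conditions used throughout the checks: 500 features of which 20% are
differential, sizes at which a laptop run finishes in seconds.

Real expression data are not i.i.d. Gaussian around clean linear trends:
probe effects, batch structure, heteroskedasticity and correlated genes are
all absent here, and real networks have far more reactions per metabolite
than the generator's. Passing tests on these inputs demonstrate that the
algorithms do what their definitions say — not that the statistical
pipeline has any particular power on a given real data set.

On that point, a caution worth stating: under the default synthetic
conditions the threshold regression leaves a planted effect only about two
residual-t units beyond the tested threshold, and its null p-values are
far from uniform (they concentrate near 1). Estimators that assume a
uniform null — Benjamini–Hochberg, and tail-area estimators generally —
are then very conservative: they essentially never call a null feature
(realised false-discovery proportions near zero) but recover well under
half of the planted effects. Users who need more power at a tolerated FDR
should increase the number of conditions or replicates rather than loosen
`fdr_cut`.

## Degenerate inputs and edge behaviour

* source with no outgoing carbon arc, target with none incoming, or a
  target unreachable over the arc graph → a typed `icfp_no_path` error
  before any solve;
* queries whose path space is smaller than `k` → a shorter result list,
  an exhaustion message and `exhausted = TRUE` on the fit;
* paths that cannot be balanced are simply never returned (the reference
  implementation drops them; the solver's constraints exclude them);
* every solution is re-verified against the full constraint set
  (`check_solution()`, tolerance $10^{-6}$ on continuous constraints) —
  the solver and verifier are separate code paths;
* duplicate carbon-arc triples are deduplicated; triples violating the
  substrate/product sign convention are rejected with the offending triple
  named.

## Problem sizes used in the checks

The bundled verification batches use networks of 6–10 metabolites and 8–14
reactions (50 networks for solver-vs-reference agreement, 20 for the
expression-free reduction) and expression sets of 500 features over 8
conditions (20 replicates, plus 50 null replicates). These sizes keep a
full run in the minutes range while covering reversibility, multi-substrate
reactions and all three classification states; the enumeration guard of the
reference implementation (12 metabolites) is the binding constraint on
network size.

## Known limitations

* Carbon-exchange arcs are an *input*: the package does not compute atom
  mappings, and without arc annotations there is no model.
* No thermodynamic constraints, flux-variability analysis or biomass
  machinery — the flux patterns returned are feasibility certificates for
  a path, not predictions of a flux distribution.
* Genome-scale enumeration is possible in principle (the model size grows
  with the arc count) but the built-in solver is designed and tested at
  desk scale; large reconstructions would want a commercial solver behind
  the same model, and exact replication of a published path list would
  additionally require the original solver's tie-breaking.
* The SBML reader covers the Level-3 fbc subset (species, stoichiometry,
  reversibility, gene-product associations, legacy GENE_ASSOCIATION
  notes); the tabular dialect is the authoritative format, carbon arcs
  always come from the TSV side table.
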