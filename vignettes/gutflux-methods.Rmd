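---
title: "Methods: constraint-based strain analysis with gutflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraint-based strain analysis with gutflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutflux)
```

# The modeling problem

gutflux analyses *Escherichia coli* strains of the human gut at two
levels. At the sequence level, it decides which strains a metagenomic
sample contains, from read alignments against reference genomes. At the
metabolic level, it derives a strain-specific genome-scale metabolic
model from a pan-genome network and predicts phenotypes — growth rates
on different carbon sources, flux ranges, flux couplings — with
constraint-based methods.

The central object is a stoichiometric model: metabolites, reactions
with flux bounds (mmol gDW⁻¹ h⁻¹), gene–protein–reaction (GPR) boolean
rules, and a biomass pseudo-reaction whose flux is the specific growth
rate (h⁻¹). Flux balance analysis (FBA) solves

$$\max_v\; c^\top v \quad \text{s.t.}\quad S v = 0,\; lb \le v \le ub,$$

the steady-state mass-balance linear program. Exchange reactions follow
the convention negative flux = uptake, positive = secretion, stated once
here and used everywhere.

# The LP engine

No linear-programming package is part of this package's dependency
footprint; the LP solver is its own bounded-variable two-phase primal
simplex (C++, dense arithmetic), which is also the node solver for the
iMAT mixed-integer program. Design points:

* reduced-cost tolerance 1e-9, pivot tolerance 1e-8, phase-I
  feasibility tolerance 1e-7 (scaled by |b|);
* Dantzig pricing with a switch to Bland's rule after a run of
  degenerate pivots (anti-cycling);
* the basis inverse is refactorized every 100 pivots;
* lower bounds must be finite (all models here bound fluxes at ±1000,
  the COBRA convention, when a file omits bounds); upper bounds may be
  `Inf` (used by internal slack variables).

The engine is validated two ways: against brute-force
polytope-vertex enumeration on networks small enough to enumerate
(≤ 8 reactions; the acceptance suite runs 100 random topologies and the
largest observed deviation is ~1e-13), and against the closed-form
optima of the toy generators.

Reported FBA results are checked a posteriori: an "optimal" flux vector
must satisfy |S v|∞ ≤ 1e-6 and bounds to 1e-9, otherwise the result is
flagged. Infeasible and unbounded statuses are propagated as statuses,
never silently mapped to zero.

# Flux variability, robustness, degeneracy

FVA fixes the objective at a fraction f of its optimum (default f = 1,
exposed as `objective_fraction`) and minimizes/maximizes each flux in
turn. A hair of slack (1e-9) is left on the objective constraint so the
optimal face is not cut off by round-off. Directions are classified
as forward (min ≥ 0, max > 0), reverse (max ≤ 0, min < 0),
bidirectional (min < 0 < max) or blocked (|v| < 1e-9 at both ends).

FBA optima of genome-scale models are usually degenerate. The package
therefore never asserts on individual coordinates of one optimal vertex
in its tests: claims are made about the objective, about FVA-certified
ranges, or about quantities forced by stoichiometry. For the same
reason the diet-stress comparison (below) can optionally be run on
FVA-midpoint fluxes (`--robust-fluxes` semantics) instead of a single
FBA vertex.

# Flux sampling

`sample_fluxes()` draws near-uniform points from the flux polytope with
an artificial-centering hit-and-run chain: directions are differences
between a random warmup point and the running center of mass of all
accepted points, which keeps every step inside the null space of S
without an explicit null-space basis. Warmup points are optimal
vertices of LPs with standard-normal random objectives
(2 × n_reactions of them by default); thinning is 100 steps per
retained sample. One integer seed drives both warmup and chain, and the
contract is bit-identical output for identical seeds. Proposals with a
degenerate direction count as zero-length steps, so chains terminate
even on polytopes that collapse to a point.

Growth is *not* constrained during sampling by default — the object of
study is the whole solution space; `at_optimum = f` optionally adds
c'v ≥ f·opt. Sample counts and thinning are stated in the acceptance
script (5,000 × 100 on the ~55-reaction core fixture); marginal
uniformity is only asserted on a box case with a closed-form uniform
marginal (Kolmogorov–Smirnov, p > 0.01 at n = 5000), which is what a
hit-and-run chain can honestly promise at this scale.

# Context-specific extraction: GIMME and iMAT

Both extraction methods consume per-reaction evidence obtained by
pushing gene scores through the GPR rules (AND = min, OR = max; empty
GPR ⇒ evidence ∞, the reaction is unconditional; genes missing from a
profile score 0, logged not fatal, because pan-genome profiles may omit
genes).

**GIMME** (LP): minimize Σ (threshold − evidence)·|v| over
below-threshold reactions subject to mass balance, bounds, and
c'v ≥ growth_fraction · optimum (default 0.9). |v| is linearized with
one auxiliary variable per penalized reaction. A penalized reaction is
removed when its flux can be zero without degrading either the penalty
optimum (to 1e-6) or the growth guarantee; candidates are examined in
lexicographic id order, making the removal set deterministic under
alternate LP optima. Penalized reactions that must carry flux are kept
and flagged as evidence/flux inconsistencies.

**iMAT** (MILP): maximize the count of high-evidence reactions active
at |v| ≥ ε (ε = 1.0 by default) plus low-evidence reactions with zero
flux, with binary indicators linked to fluxes by big-M constraints,
solved by depth-first branch and bound over the LP relaxation. Two
implementation choices matter:

* before building the MILP, every flux bound is tightened by FVA under
  the growth constraint. This is what makes the relaxation bound sharp
  enough to prune — with the raw ±1000 bounds the big-M constraints are
  vacuous and branch and bound degenerates to enumeration;
* the spec of the growth guarantee lives inside the MILP (not only as a
  post-check), so every returned model satisfies it by construction.
  The signature therefore carries a `growth_fraction` argument
  defaulting to GIMME's 0.9.

Among alternate optimal removal sets iMAT returns the first incumbent
of a deterministic depth-first search (branching on the most fractional
indicator, activity branch first). A lexicographic secondary objective
was considered and rejected: encoding it with weights 2^-rank is
numerically unusable beyond ~40 binaries, and re-solving per candidate
(as GIMME does) would multiply MILP solves. On binary profiles the two
algorithms agree exactly — the acceptance suite asserts identical
reaction sets and exact planted-truth recovery over 20 seeded
pan-models.

Removal semantics everywhere: reactions are deleted, then orphan
metabolites (appearing in no remaining reaction) are dropped. That
definition is also what "model-specific metabolites" means in
`compare_models()` (union minus intersection across models).

# Strain profiling

Reads (BLAST outfmt-6 tables, or SAM through Rsamtools) are filtered at
99% identity, and multi-mapping queries are dropped entirely — a read
must align to a single position; bitscore ties are *not* rescued, the
conservative reading. Coordinates are 1-based inclusive on ingestion
(BLAST convention); interval unions use IRanges.

"10-fold coverage" is interpreted as mean depth (Σ aligned bases ÷
genome length), not breadth: the criterion is stated alongside average
genome sizes, which is a depth reading. Breadth (fraction of positions
covered ≥ 1×) is computed and reported as well, and both thresholds are
boundary-inclusive (depth exactly 10.0 is present; a gene covered for
exactly 80% of its length by one scaffold is covered). Gene coverage
follows the single-scaffold rule — the covered fraction is the maximum
over individual scaffolds, never a sum across scaffolds.

Enrichment of covered genes is a one-sided Fisher exact test computed
as the upper hypergeometric tail in log space (`phyper(log.p = TRUE)`),
so p-values far below double-precision underflow are still reported via
log10. The acceptance suite checks every 2×2 table with margins up to
30 against term-by-term enumeration from binomial coefficients.

# Diet response

Growth is simulated per condition by opening exactly one carbon
exchange at the stated uptake (9 mmol gDW⁻¹ h⁻¹ for the four-source
comparison), closing every other carbon exchange, and setting oxygen to
−18 (aerobic) or 0 (anaerobic). Conditions whose LP is infeasible
(typically: maintenance ATP cannot be paid) are reported as zero growth
with the status flagged, not dropped.

A reaction is diet-stressed between conditions x and y when
|flux_x| > 1.1·|flux_y| or |flux_x| < 0.9·|flux_y|. The ratio form is
undefined at flux_y = 0, so the implemented closure is: zero→nonzero
and nonzero→zero are stressed, zero→zero is not, and a sign flip
(reaction reversing direction) is stressed — a reversal is more than a
10% change under any reading. The criterion is applied to magnitudes
and is scale-free (multiplying both vectors by c > 0 changes nothing),
which the suite asserts as a property. Stressed genes are the union of
GPR leaves over stressed reactions.

# The synthetic generators and what they do (not) show

**Toy networks** (`make_toy_model`) — chain, parallel, diamond, cycle —
carry closed-form optima (chain: min of capacities; parallel: capped
sum of branch capacities; diamond: sum of per-arm bottlenecks; cycle: a
chain plus an off-path reversible 2-cycle that FVA must classify
bidirectional). Capacities are drawn U[2, 20] under a seed.

**The core fixture** (`make_core_fixture`) is a hand-curated,
deterministic ~55-reaction E. coli-style central-carbon network:
glycolysis/gluconeogenesis, pentose-phosphate pathway, TCA cycle with
glyoxylate shunt, fermentation to acetate/ethanol/lactate, lumped
oxidative phosphorylation (P/O 2 for NADH, 1 for FADH₂), PTS glucose
uptake, exchanges for glucose/acetate/ethanol/succinate/lactate/O₂/
CO₂/phosphate, non-growth ATP maintenance as a lower bound of
8.39 mmol gDW⁻¹ h⁻¹ on ATPM (the iAF1260 value), and growth-associated
ATP (45 mmol per gDW) inside the biomass stoichiometry. It is
hand-curated rather than random because scenario analyses need stable
reaction ids matching field abbreviations (ACS, PTAr, ACKr, PGK, PGL,
GND, RPI). Deliberate simplifications: one lumped NAD(H) pool standing
in for NADH/NADPH, no protons or water, no nitrogen, and formulas only
on exchange metabolites (used for carbon-source classification). Its
qualitative behavior mirrors the real organism — glucose the best of
the four sources at equal uptake, anaerobic growth positive but far
below aerobic, acetate useless anaerobically, oxidative-PPP flux
anticorrelated with ribose-5-phosphate isomerase flux in sampling — but
its absolute growth rates are fixture properties, not predictions for
any real strain, and nothing genome-scale (membrane lipids, cofactor
biosynthesis, transport energetics) is represented.

**Pan-genome models** (`make_pan_with_strains`) add accessory reactions
to the core fixture, each gated by its own gene: either duplicates of
existing irreversible reactions (isozyme-like bypasses) or peripheral
byproduct-secretion branches. Accessories are growth-dispensable *by
construction*, so the pan optimum equals every strain optimum and the
GIMME/iMAT equivalence property is well-posed. This also bounds what
the passing tests show: they validate the extraction machinery on
networks where the planted truth is recoverable, not the harder
biological case where a missing gene removes an essential reaction
(that case is exercised separately and yields a kept-but-flagged
inconsistency).

**Alignment tables** (`planted_cohort` + `make_alignments`) tile
100-bp reads around a reference so realized depth equals planted depth
exactly and breadth saturates at depth ≥ 1; each strain is present in
exactly round(prevalence × n) samples. Read identity is a per-strain
constant with optional Gaussian jitter defaulting to 0 — the boundary
properties (depth exactly 10.0, identity exactly 99.0) are only
well-defined for clonal identities, and threshold behavior, not error
modeling, is what these fixtures test. No sequence-level simulation is
attempted.

# Problem sizes and numerical choices

The default validation workloads are: 100 random toys for the LP
oracle; full FVA (110 LPs) on the core fixture; 5,000 samples ×
thinning 100; 20 seeded pan-models for extraction; all 2×2 tables with
margins ≤ 30 for the Fisher check. These sizes were chosen as the
smallest at which each property is sharp (exact couplings, exact
recovery, boundary inclusiveness) while keeping a full run in minutes
on one core.

Tolerances: mass-balance residual 1e-6 (reporting), bound slack 1e-9,
blocked-flux 1e-9, GIMME optimality slack 1e-6, iMAT integrality 1e-6.
Ties in the simplex ratio test break toward the largest pivot magnitude
(stability) except under Bland's rule (lowest index, termination).

# Known limitations

* The simplex is dense; it is sized for desk-scale networks (hundreds
  of reactions), not for genome-scale models with tens of thousands.
* iMAT's branch and bound has a node budget (default 5,000) and errors
  beyond it rather than returning a suboptimal set silently.
* SBML support is the constraint-based subset (L2-notes and L3-fbc
  read; L3-fbc write); kinetic laws, events and unit systems are out of
  scope.
* Sampling uniformity is asserted only where a closed form exists; on
  general polytopes the chain is the de-facto-standard heuristic, not a
  certified uniform sampler.
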