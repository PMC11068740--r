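---
title: "Designing function-specific minimal microbial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing function-specific minimal microbial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minicom)
```

## The problem

Gut microbial communities digest dietary fibre and ferment it to short-chain
fatty acids (SCFA: acetate, butyrate, propionate), but not every member of a
community contributes to that function.  A *minimal microbiome* is a smallest
subset of the species that still achieves a stated fraction of the full
community's growth rate and SCFA production.  Finding one identifies the
keystone species for the function (typically the fibre degraders and the SCFA
producers) and is useful for designing defined consortia, e.g. as an
alternative to faecal transplants.

`minicom` computes minimal microbiomes from per-species genome-scale
metabolic models (GSMMs) with a three-step constraint-based procedure.

## The community model

Members are merged compartment-wise.  Every internal metabolite and reaction
of member $k$ is suffixed `_org<k>`; each member exchange reaction is rewired
to transfer its metabolite between the member and a shared pool compartment
(`[u]`), and one community-level exchange reaction per pooled metabolite
connects the pool to the environment.  Writing $v^k_j$ for the flux of
reaction $j$ in member $k$ (mmol/gDW-h), the pool mass balance makes the
community exchange flux of each metabolite the sum of the member exchange
fluxes — this single constraint is what permits cross-feeding.  Positive
exchange flux is secretion, negative is uptake (the COBRA convention).

A *diet* is a table of bounds on the community exchange reactions; uptake
availability is a negative lower bound.  Under the default `closed` policy
every exchange not listed in the diet gets lower bound 0 (the environment
supplies nothing), which matches how curated diet tables are meant to be
applied.  Diet entries never touch non-exchange reactions.

**Coupling.**  Maximising the summed biomass could otherwise let a
zero-growth member carry arbitrary flux.  Every non-biomass reaction of
member $k$ is therefore coupled to its biomass flux,
$\pm v^k_j - c\, v^{k,\mathrm{bio}} \le u$, applied in both flux directions so
reversible reactions cannot escape the coupling.  The constants are not part
of the mathematical formulation proper; we default to $c = 400$,
$u = 0.01$ mmol/gDW-h, the convention established for AGORA-style community
models, and expose both (as well as a flag restricting coupling to internal
reactions only).

## The three steps

1. **Joint FBA.**  Maximise $\sum_k v^{k,\mathrm{bio}}$ subject to mass
   balance, bounds, and coupling.  This yields the community growth rate and
   the per-species rates $\theta^k$.
2. **Growth-constrained SCFA maximisation (FVA step).**  Maximise the
   weighted SCFA exchange sum
   $w_{ac} v_{ac} + w_{bu} v_{bu} + w_{pr} v_{pr}$ subject to the same
   constraints plus $v^{k,\mathrm{bio}} \ge \texttt{gr\_opt\_frac}\cdot\theta^k$
   for every member.  Constraint 1 uses the full weight triple (default
   1:1:1); Constraints 2–4 are the acetate-, butyrate- and propionate-only
   versions.  The optimum $\vartheta_{\mathrm{SCFA}}$ is the community's
   attainable production at near-optimal growth.  Because lowering
   `gr_opt_frac` only relaxes the feasible set, $\vartheta$ is non-increasing
   in it — sub-optimal growth yields more SCFA, a well-known trade-off.
3. **Membership MILP.**  Introduce a binary $X^k$ per species and minimise
   $\sum_k X^k$ (the $L_1$-norm of the membership vector) subject to the
   community constraints, membership gating, and the retention thresholds
   $v_{\mathrm{SCFA}} \ge \texttt{scfa\_frac}\cdot\vartheta_{\mathrm{SCFA}}$
   and a growth threshold (below).  For communities too large for a direct
   MILP, a *sequential deletion* pre-pass walks a (seeded random or
   user-given) species sequence, tentatively deleting each species — zeroing
   all its flux bounds — and keeping the deletion iff the reduced community
   still meets both thresholds (one growth LP and one SCFA LP per test).
   Passes repeat until the community reaches `milp_size` or a pass deletes
   nothing.  The result depends on the sequence, so the driver runs several
   independently seeded iterations and deduplicates the solutions; integer
   cuts ($\sum_{k \in S} X^k \le |S| - 1$) optionally enumerate alternative
   minimal supports.

### Design choices in the MILP

Two points of the printed formulation admit more than one reading; both are
implemented and the choices are exposed:

* **Growth threshold.**  A literal per-species bound
  $v^{k,\mathrm{bio}} \ge \texttt{gr\_frac}\cdot\theta^k$ contradicts
  $X^k = 0 \Rightarrow v^{k,\mathrm{bio}} = 0$ whenever $\theta^k > 0$.  The
  default mode `community` requires
  $\sum_k v^{k,\mathrm{bio}} \ge \texttt{gr\_frac}\cdot\sum_k\theta^k$, which
  reproduces the arithmetic of reported minimal-community growth rates
  (80% of the community total); mode `per_species` gates the bound by
  membership, $v^{k,\mathrm{bio}} \ge \texttt{gr\_frac}\cdot\theta^k X^k$,
  which stays linear because $\theta^k$ is a constant.
* **Exclusion gating.**  Gating only the biomass bounds leaves an excluded
  member able to carry up to $u$ flux per reaction through the coupling
  slack.  By default *all* bounds of member $k$ are gated,
  $LB^k_j X^k \le v^k_j \le UB^k_j X^k$, making exclusion exactly equivalent
  to deletion (and to the oracle's subset semantics); `gate =
  "coupling_only"` reproduces the literal formulation.

Unbounded flux domains are honoured up to the standard $\pm 1000$ mmol/gDW-h
COBRA bounds: true infinities would break the $X$-gating products, so
$\pm 1000$ is the operational infinity.

Thresholds are compared with a $10^{-9}$ slack to avoid boundary flapping;
LP/MILP feasibility and integrality tolerances are $10^{-6}$.  When both
thresholds are zero the empty community is optimal; it is reported (with a
warning) rather than silently promoted to a singleton.

## Solver

No linear-programming package is available in this R installation, so the
package ships its own dense bounded-variable two-phase primal simplex
(compiled; Dantzig pricing with a Bland's-rule fallback, product-form basis
updates with periodic refactorisation, and a true-residual recheck before any
"feasible"/"optimal" verdict) plus a branch-and-bound layer for the binary
membership variables that exploits the integrality of cardinality objectives
when bounding.  Community problems here are small (tens to a few hundred
rows), well inside what a dense simplex handles in microseconds to
milliseconds.  A second backend that shells out to SciPy's HiGHS is included
purely for cross-checking; the test suite asserts agreement of the two
backends to $10^{-6}$ relative on both community-derived and random LPs.

## The synthetic communities and what they do (not) show

`make_toy_community()` builds small cross-feeding chains with analytically
known structure: a *degrader* converts fibre to a monomer plus biomass, SCFA
*producers* convert the monomer to one SCFA plus biomass, *freeloaders* grow
on the monomer without producing, and *cross-feeders* condense monomer with
acetate into butyrate.  The diet supplies only fibre (5 mmol/gDW-h by
default), so all downstream metabolites move through the shared pool.  All
yields are small integers or halves, so every LP optimum is an exact
rational and expected values in the tests are exact.  Named fixtures
(`toy_3`, `toy_5_redundant`, `toy_9_demo`) provide a unique-support case, an
interchangeable-producer case, and a 9-member demonstration community with
four butyrate producers of decreasing yield among five non-producers.
`random_toy()` draws seeded random role mixes (always at least one degrader
and one producer) for property testing.

`brute_force_minimal()` is the independent oracle: it enumerates every
nonempty subset of up to 12 members, re-assembles the constraint system
densely with its own code path (no shared constraint builder with the
workflow), and tests the same two-LP feasibility semantics.  Agreement
between the MILP and the oracle is therefore evidence of correctness, not a
tautology.  The test suite checks this agreement on twenty random toys
(3–8 members) for all four constraint ids over a grid of retention
fractions, along with feasibility certificates (residuals of returned flux
vectors against an independent dense re-assembly), monotonicity of the
minimal cardinality in both retention fractions, monotonicity of
$\vartheta_{\mathrm{SCFA}}$ in `gr_opt_frac`, reduction soundness, exact
enumeration on the redundant fixtures, and byte-identical determinism under
a fixed seed.  Those problem sizes keep the whole suite around a minute on
one CPU while exercising every subset of each community.

What the toys do *not* emulate: genome-scale network redundancy (thousands
of internal routes), realistic biomass compositions, thermodynamic or
regulatory constraints, and diets with dozens of carbon sources.  Passing
tests certify the algorithmic machinery — model merging, coupling, the three
steps, gating, enumeration — not the biological fidelity of any particular
GSMM collection; results on real communities inherit the assumptions of the
input reconstructions and of FBA itself (steady state, growth-maximising
behaviour, unconstrained cross-feeding unless bounded).

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `gr_opt_frac` | 0.99 | per-species growth floor (fraction of $\theta^k$) during the SCFA maximisation |
| `gr_frac` | 0.8 | growth retention threshold of the minimal community |
| `scfa_frac` | 0.8 | SCFA retention threshold |
| `constraint` | 1 | 1 = weighted SCFA sum, 2/3/4 = acetate/butyrate/propionate |
| `weights` | 1:1:1 | $(w_{ac}, w_{bu}, w_{pr})$, used by constraint 1 |
| coupling `c`, `u` | 400, 0.01 | biomass coupling coefficient and slack |
| `milp_size` | 8 | deletion stops once this size is reached |
| `iterations` | 1 | independently seeded deletion/MILP rounds |

Negative SCFA exchange fluxes (uptake of an SCFA supplied by the diet or by
another member) are allowed in the weighted objective by design: weighted
optima can legitimately trade uptake of one SCFA for production of another,
and forbidding it would silently change the reported optima.

## Known limitations

* The formulation is abundance-free: biomass fluxes are summed without
  abundance weighting, and no dynamic or spatial structure is modelled.
* Enumeration by integer cuts is complete only for the supports it is asked
  for; with `same_cardinality_only = TRUE` it stops at the first larger
  optimum and does not claim to list feasible non-minimal communities.
* The sequential pre-pass can delete every member of some minimal supports;
  the MILP cardinality after reduction is then larger than the full-MILP
  optimum.  This is inherent to sequence-dependent reduction; multiple
  iterations with different seeds mitigate it.
* The built-in simplex is dense; genome-scale communities with tens of
  thousands of reactions would need a sparse LP backend (the backend
  interface accepts one).
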