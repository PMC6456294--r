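---
title: "Modeling substrate competition in a promiscuous dimeric dinucleotide cyclase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling substrate competition in a promiscuous dimeric dinucleotide cyclase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gacakin)
```

## The scientific problem

Hypr GGDEF enzymes such as GacA are homodimeric cyclases that accept both
ATP and GTP, one NTP per half-active site, and so can synthesize three
cyclic dinucleotides: cdiG (two GTP), cdiA (two ATP) and 3′,3′-cGAMP (one
of each). In vivo these enzymes behave almost exclusively as cGAMP
synthases, yet in vitro they look promiscuous. This package implements
the kinetic model that resolves that tension: product choice is set by
the competition of the two substrates for the two sites, and modest
differences in conditional binding constants — amplified by cellular
substrate ratios and, possibly, asymmetric activation — suffice to make
cGAMP the dominant output.

## The reaction network

The model tracks 14 species (`cyclase_species()`): the free active dimer
`E`; four single-bound states `EnG`, `EGn`, `EnA`, `EAn`, where `n` marks
the empty half-site (the two half-sites are treated as equivalent but kept
as distinct species — lumping them would rescale the macroscopic constants
by a factor of 2); four double-bound states `EGG`, `EGA`, `EAG`, `EAA`
(first letter = pocket 1); the three products; and free `A`, `G`.

Every binding step shares one on-rate constant, k~on~ = 1 µM⁻¹s⁻¹, an
explicitly arbitrary convention: all k~cat~ values are ≪ 1 s⁻¹, so binding
equilibrates much faster than catalysis and only the dissociation
constants matter (a test verifies that a ten-fold change of k~on~ moves
endpoint product fractions by < 10⁻³). Off-rates are k~off~ = k~on~·K for
the six dissociation constants (K~1A~, K~2A~, K~1G~, K~2G~, K~A|G~,
K~G|A~). Catalysis converts each double-bound state directly into free
enzyme plus product (rate constants k~cat,cdiG~, k~cat,cGAMP~,
k~cat,cdiA~): formation of the linear intermediate is assumed
rate-determining, so no intermediate species are modeled. Total enzyme is
constant — activation/dimerization equilibria are outside the model.

Two packaged presets (`gaca_params()`) carry the published wild-type
constants: the cooperative set (343, 53, 39, 20, 71, 10 µM; k~cat~ 0.03
s⁻¹) and the non-cooperative reference (80, 80, 25, 25, 80, 25 µM; 0.04
s⁻¹).

Importantly, the cooperative constants **violate thermodynamic cycle
closure**: K~1G~·K~A|G~ = 2769 ≠ K~1A~·K~G|A~ = 3430 µM². The
implementation deliberately does not enforce detailed balance — the
fitted model does not satisfy it, and imposing it would change the
predictions. A consequence discussed below is a small concentration-
dependent cycle flux in the binding network.

## Integration modes and numerics

`simulate_timecourse()` integrates the network in either of two modes:

* **stiff** (default): `lsoda` via deSolve with a compiled C right-hand
  side, rtol 10⁻⁸ / atol 10⁻¹⁰ for simulation (10⁻⁶/10⁻⁹ inside the
  grid-search objective, where only endpoint fractions at the
  percentage-point scale matter). The network is stiff: pseudo-first-order
  binding rates reach ~400 s⁻¹ at 100 µM substrates against catalytic
  rates of 0.03 s⁻¹.
* **euler**: the classic fixed-step linear update
  x(t+Δt) = x(t) + Δt·dx/dt on a 1 s reporting grid. A literal 1 s
  explicit step is unstable at these rates, so the integrator sub-steps
  automatically: the effective step is bounded so that no species can
  lose more than 10% (the `safety` fraction) of itself in a single
  update, which simultaneously guarantees stability and non-negativity.
  If an interval would need more than `max_substeps` sub-steps the solver
  errors out rather than clipping. The two modes agree on endpoint
  product fractions to < 10⁻⁴ (tested).

Trajectories satisfy the three conservation laws (enzyme; adenine and
guanine totals in depletion mode) with relative drift < 10⁻⁶; tiny
solver-level negative values (below 100·atol) are zeroed, anything larger
is an error.

Default conditions mirror the laboratory setup: one-hour time course,
1 s reporting, depletion mode. The enzyme concentration is **not**
published for the simulations; the package defaults to E₀ = 1 µM.
Note that depletion-mode endpoint ratios genuinely depend on E₀ (it sets
what fraction of the pool is consumed in an hour, and substrate depletion
skews ratios over time); what is E₀-invariant — exactly, by linearity —
is the clamped-substrate flux fraction, and that is the invariance the
test suite asserts.

## The exact steady-state solver

With substrates clamped (`homeostasis = TRUE`, d[A]/dt = d[G]/dt = 0) the
nine enzyme-species balance equations are linear, and
`steady_state_ratios()` solves them exactly: the Jacobian columns are
assembled by evaluating the (linear) derivative at unit basis states, the
redundant free-enzyme row is replaced by the conservation constraint
ΣE = E₀, and the system is solved directly. Synthesis fluxes are
k~cat~-weighted occupancies; their normalized fractions are the in vivo
product-ratio prediction. Long-horizon clamped integration converges to
this solution (< 10⁻³ per fraction, tested), which makes the two routes
independent cross-checks.

A useful approximate oracle is the rapid-equilibrium binding polynomial,
with flux weights G²/(K~1G~K~2G~), A·G·(1/(K~1G~K~A|G~) +
1/(K~1A~K~G|A~)) and A²/(K~1A~K~2A~). It is exact only under detailed
balance; with the fitted constants the exact solve deviates from it by up
to ~0.005 per fraction. For the same reason the flux fractions are *not*
exactly homogeneous in (A, G): scaling both substrates ten-fold moves
fractions by up to ~0.01 even with catalysis scaled down 100-fold,
because the detailed-balance-violating cycle carries a
concentration-dependent circulating flux. Tests assert these properties
at 0.01 absolute tolerance accordingly.

## Fitting

**Single substrates.** With one substrate the scheme collapses to the
closed form v = k~cat~E₀S²/(K₁K₂ + 2K₂S + S²) (the 2 counts the two
single-bound states). `fit_single_substrate()` minimizes squared error on
the log-parameter scale from a deterministic 4×4 grid of K starting
values (log-spaced over the observed concentration range) — no
randomness, no dependence on a lucky start. The fit raises an
identifiability flag when the design does not bracket the fitted curve's
half-saturation point S₅₀ = K₂ + √(K₂² + K₁K₂): saturating-only data
constrain k~cat~ but not the binding constants. Noise-free
self-consistency recovery of both preset triples is within 1% (tested).

**Heterodimeric constants.** K~A|G~ and K~G|A~ are not observable from
single-substrate assays; they are estimated by simulating the
depletion-mode endpoint fractions at each dataset condition and scoring
the summed squared differences to the observed fractions **in percentage
points** (×100). The percentage scale was chosen so that error magnitudes
are commensurate with the published model-error values, which are only
explicable on that scale; the metric label records the convention.
`fit_heterodimer()` evaluates the full Cartesian grid — default 1–100 µM
on both axes in 1 µM steps, exactly 10,000 combinations, matching the
published procedure; 0 is excluded since a zero dissociation constant is
unphysical. The argmin is reported with deterministic lexicographic
tie-breaking (smallest (K~A|G~, K~G|A~)), and a tie flag. On noise-free
self-generated data the surface minimum is exactly zero at the generating
parameters; the full-grid recovery of (71, 10) µM is an acceptance test.

The published model-error numbers themselves (443 and 4118) cannot be
recomputed here because the underlying experimental product-ratio table
is distributed only as supplementary source data; the package replaces
that check with the self-consistency recoveries above.

## Forward predictions

`homeostasis_scan()` evaluates the steady-state solver across ATP:GTP
ratios at fixed G (default 100 µM), marking the physiological reference
r = 3 (cellular ATP typically exceeds GTP ≥ 3-fold; the scanned range
[1, 10] represents that physiological neighborhood — the exact range is a
package choice, not a published number). With the cooperative constants,
cGAMP is the single most abundant product at every ratio from 2 to 10
and a strict majority for moderate ATP excess (r ≈ 3–8); toward r = 10
cdiA catches up (cGAMP fraction 0.48 at r = 10). The scans default to
the exact solver; `method = "integrate"` switches to finite-horizon
clamped integration for cross-checking.

`asymmetric_scan()` repeats the scan with k~cat,cGAMP~ multiplied by a
fold factor, modeling receiver-domain activation that accelerates the
heterodimeric reaction preferentially; fold = 1 reproduces the plain scan
bit-for-bit. At fold 9 and r = 4 the cGAMP flux share is 91.8%, i.e. the
enzyme becomes >90% selective. `delta_delta_G()` converts a fold
asymmetry into the equivalent activation-energy difference R·T·ln(fold)
(R = 1.987×10⁻³ kcal mol⁻¹K⁻¹), defaulting to T = 301.15 K — the 28 °C
enzymatic assay temperature, a documented, overridable choice since the
temperature used for the published conversion is not stated. Nine-fold
costs 1.31 kcal/mol.

## Motif classification

`classify_sequences()` implements the GGDEF signature classification on
an alignment: the five signature columns and the two selectivity
positions (Watson–Crick-face position 348 and cross-dimer stacking
position 304, in GmGacA numbering; a per-alignment offset accommodates
shifted numberings such as GsGacA's 347/303) are located by
`signature_columns()` via gap-aware mapping from a named reference
sequence. A sequence is called active when its motif matches
`[G/A/S]G[D/E]E[F/Y]` — the permissive first position, the invariant
general-base glutamate at position 4 — with one structural override: the
combination of Ser/Thr at position 348 with a central Glu is inactive
(the "Goldilocks" spacing constraint: the short Ser side chain and the
longer Glu cannot both reach the substrate), whereas the flexible Asp at
348 tolerates either central residue. The shorter 4-position pattern that
omits the general-base column is also evaluated, and records where the
two patterns disagree are flagged (`pattern_discrepancy`) rather than
silently merged. Any gap at a signature column makes the record
unclassifiable — never imputed. `motif_summary()` cross-tabulates the
selectivity class against the central residue and counts Arg at the
cross-dimer position; database-snapshot-dependent percentages from the
original large-scale survey are intentionally not reproduced — the tool
computes the same statistics on whatever alignment it is given.

## Synthetic data

The generators stand in for the study's measured tables, which are not
redistributable:

* `sim_product_ratio_data()` emulates the product-ratio measurements:
  ATP fractions {10, 25, 50, 75, 90}% of a 200 µM total pool (the
  published experiments used ~100 µM of each NTP; the exact mixes are not
  printed, so this design is a declared default), one-hour depletion
  endpoints, additive Gaussian replicate noise of sd 2 percentage points
  with renormalization, 3 replicates — the simplest model consistent with
  "average of independent technical replicates (n = 3)"; the true
  replicate scatter is unknown, so sd = 2 is a declared default, not an
  estimate.
* `sim_initial_rate_data()` emulates the pyrophosphate-detection assay:
  zero plus a log-spaced grid from 1 µM to 10 mM, noise in rate units,
  negative draws floored at zero and flagged.
* `sim_alignment()` builds labeled toy alignments (canonical Asp-348/Arg
  sequences, Hypr Ser/Thr-348/Tyr sequences that never carry a central
  Glu, and a gapped unclassifiable class) with exact largest-remainder
  family counts (a multinomial mode exists behind a flag).

Every generator is seed-deterministic, restores the global RNG state, and
records its seed, version and generating truth. What passing tests on
these fixtures demonstrate is *self-consistency and correctness of the
computational chain* — recovery of known parameters, zero-mismatch
classification — not agreement with any real measurement: the generators
share the simulator's idealizations (no systematic errors, no
concentration-dependent noise, no misassigned peaks, perfectly aligned
sequences).

## Problem sizes and determinism

Default analysis sizes are desk-scale by design: the full grid search is
10,000 cells × 5 conditions ≈ 50,000 endpoint integrations (about a
minute with the compiled right-hand side), scans and steady-state solves
are instantaneous, and the test suite's end-to-end checks use the same
sizes as the analyses they verify. The model contains no stochastic
terms, so identical inputs give identical outputs; the only randomness
anywhere is the seeded noise in the generators, and `run_pipeline()`
stamps every artifact with the seed and a config hash.

## Known limitations

* No product inhibition: the allosteric I-site feedback by cdiG that the
  enzyme family exhibits is not part of this kinetic scheme.
* No enzyme inactivation, thermal or pH dependence over the time course.
* The activation-asymmetry scan is a scenario analysis — the model does
  not describe *how* receiver-domain activation would produce the
  k~cat~ asymmetry.
* Depletion-mode endpoint ratios depend on E₀ and total pool size;
  comparisons to experiments require matching those, and the published
  values for the simulated enzyme concentration are not available.
* The motif classifier reads alignment columns; severely misaligned
  sequences will be classified by whatever occupies the signature
  columns. Column mapping via a user-named reference is the contract.
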