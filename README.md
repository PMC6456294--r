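# gacakin

Kinetic modeling of promiscuous homodimeric dinucleotide cyclases.

Bacterial GGDEF-domain cyclases work as homodimers with one NTP site per
monomer. Canonical diguanylate cyclases condense two GTP into cyclic
di-GMP; the Hypr ("hybrid promiscuous") subclass, typified by the
*Geobacter* enzyme GacA, accepts both ATP and GTP and can therefore make
three products — cyclic di-GMP (cdiG), cyclic di-AMP (cdiA) and the mixed
messenger 3′,3′-cGAMP. Which product dominates is a quantitative question
about substrate competition across the two half-active sites. `gacakin`
implements the mass-action model of that competition, the estimation of
its binding constants from data, and the forward predictions that explain
how such an enzyme can behave as a dedicated cGAMP synthase inside a cell.

## The model

Fourteen species evolve under mass-action kinetics: free dimer E; the
single-bound states E·N·[ ] and E·[ ]·N (equivalent half-sites, kept as
distinct species); the double-bound states E·GG, E·AA, E·AG, E·GA; the
three cyclic dinucleotide products; and free ATP and GTP. Binding steps
are governed by dissociation constants

* K<sub>1A</sub>, K<sub>1G</sub> — first binding event for each substrate,
* K<sub>2A</sub>, K<sub>2G</sub> — second binding event, same substrate,
* K<sub>A|G</sub>, K<sub>G|A</sub> — second binding event, *different*
  substrate (e.g. K<sub>G|A</sub> is GTP binding when ATP is already
  bound),

with a common on-rate k<sub>on</sub> = 1 µM⁻¹s⁻¹ (binding is never
rate-limiting; k<sub>off</sub> = k<sub>on</sub>·K). Each doubly-bound
state converts to its product with rate constant k<sub>cat</sub>,
regenerating free enzyme; intermediate formation is rate-determining, so
no linear intermediates appear. The difference between K<sub>2G</sub> and
K<sub>G|A</sub> ("selective cooperativity") is what biases the enzyme
toward the mixed product: for the fitted wild-type constants
K<sub>2G</sub>/K<sub>G|A</sub> = 2, i.e. GTP binds the ATP-loaded enzyme
twice as tightly as the GTP-loaded one.

The package provides:

* `simulate_timecourse()` — stiff (`deSolve::lsoda`, compiled
  right-hand side) or sub-stepped explicit-Euler integration, in closed
  "depletion" mode (in vitro) or substrate-clamped "homeostasis" mode
  (in vivo); `product_ratios()` for endpoint fractions.
* `steady_state_ratios()` — exact linear solve of the 9-state enzyme
  balance at clamped substrates: steady-state occupancies, synthesis
  fluxes and flux fractions.
* `fit_single_substrate()` — cooperative single-substrate rate law
  v = k<sub>cat</sub>E₀S² / (K₁K₂ + 2K₂S + S²) fitted by deterministic
  multi-start least squares.
* `fit_heterodimer()` — exhaustive grid search (default 1–100 µM × 1 µM
  step, 10,000 cells) for (K<sub>A|G</sub>, K<sub>G|A</sub>) against
  product-ratio data, scored as summed squared differences in percentage
  points.
* `homeostasis_scan()`, `asymmetric_scan()`, `delta_delta_G()` — forward
  predictions across ATP:GTP ratios, including asymmetric activation of
  the heterodimeric k<sub>cat</sub>.
* `classify_sequences()` and friends — GGDEF signature-motif
  classification (`[G/A/S]G[D/E]E[F/Y]` with the Goldilocks Ser/Thr ×
  central-Glu exclusion) on aligned FASTA/Stockholm input.
* `sim_product_ratio_data()`, `sim_initial_rate_data()`,
  `sim_alignment()` — seeded synthetic-data generators with recorded
  ground truth.

## Worked example

```r
library(gacakin)
p <- gaca_params("cooperative")   # published WT fitted constants

# One-hour closed reaction, 100 uM each NTP:
product_ratios(simulate_timecourse(p, reaction_conditions(A0 = 100, G0 = 100)))
#> Product ratios: cdiG 0.4706 | cGAMP 0.4527 | cdiA 0.0767

# Clamped (cellular) substrate ratios:
homeostasis_scan(p, ratios = c(1, 3, 10))[, c(1, 4:6)]
#>   ratio fraction_cdiG fraction_cGAMP fraction_cdiA
#> 1     1    0.62449805      0.3464831    0.02901885
#> 2     3    0.32205744      0.5382387    0.13970388
#> 3    10    0.08574619      0.4803731    0.43388067

# Nine-fold asymmetric activation of the heterodimeric kcat, 4:1 ATP:GTP:
p9 <- p; p9["kcat_cGAMP"] <- 9 * p[["kcat_cdiG"]]
steady_state_ratios(p9, A = 400, G = 100)
#> Clamped-substrate steady state (A = 400 uM, G = 100 uM, E0 = 1 uM)
#> Product ratios: cdiG 0.0458 | cGAMP 0.9181 | cdiA 0.0361
#>   synthesis fluxes (uM/s): cdiG 6.364e-03, cGAMP 1.276e-01, cdiA 5.022e-03

delta_delta_G(9)        # activation-energy cost of that asymmetry
#> [1] 1.314786           # kcal/mol at 301.15 K

# Recover the heterodimeric constants from (here: noise-free synthetic) data:
d   <- sim_product_ratio_data(p, noise_sd = 0, replicates = 1)
fit <- fit_heterodimer(d, p, KAG_grid = 66:76, KGA_grid = 5:15)
fit
#> Heterodimeric-constant grid search: 121 error evaluations
#>   argmin: K_A|G = 71 uM, K_G|A = 10 uM (error 0)
#>   metric: sum of squared residuals (percentage points^2)
```

At equal substrate concentrations the enzyme is nearly an even
cdiG/cGAMP producer, but at the cellular regime (ATP three-fold or more
over GTP) cGAMP is the single most abundant product, and a nine-fold
activation asymmetry — worth only ~1.3 kcal/mol — makes the enzyme >90%
selective for cGAMP.

`run_pipeline(outdir)` chains the whole analysis (synthetic data →
single-substrate fits → grid search → prediction scans → energy report)
with a seed and config hash stamped into every output.

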