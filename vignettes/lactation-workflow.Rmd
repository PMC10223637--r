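---
title: "Predicting medicine exposure through human milk: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting medicine exposure through human milk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkPBPK)
```

## The problem

More than half of postpartum women take medicines while breastfeeding, yet
for most medicines there is no quantitative information on how much drug the
infant ingests via milk. Clinical lactation studies are rare, so a *bottom-up*
prediction — from the molecule's physicochemical properties alone, with no
milk measurements — is the only option at an early stage. `milkPBPK`
implements such a workflow: a semi-mechanistic model of bidirectional
drug transfer between plasma and milk, coupled to a reduced compartmental
maternal pharmacokinetic (PK) model, from which milk-to-plasma ratios and
infant dose metrics are computed.

## The transfer model

Drug exchanges between maternal plasma and a fixed-volume milk compartment
(0.5 L, the volume at which the transfer regressions were calibrated) in both
directions, driven by the *unbound* concentrations:

$$\frac{dN_{milk}}{dt} = C_{plasma}\, f_{u,plasma}\, CL_{sec}
  \qquad
  \frac{dN_{plasma}}{dt} \mathrel{+}= C_{milk}\, f_{u,milk,total}\, CL_{re}$$

The two clearances are predicted from molecular descriptors:

$$\log_{10} CL_{sec} = -3.912 - 0.015\,PSA + 3.367\log_{10} MW - 0.164\,LogD_{7.4}$$
$$\log_{10} CL_{re} = 2.793 + 0.179\,LogP - 0.132\,HBD$$

with $PSA$ the polar surface area (Å²), $MW$ the molecular weight (g/mol),
$HBD$ the hydrogen-bond donor count, and $LogD_{pH}$ the octanol:buffer
distribution coefficient, computed by Henderson–Hasselbalch from $LogP$ and
the pKa set ($LogD = LogP + \log_{10} f_{neutral}$; per-group neutral
fractions multiply for polyprotic molecules and zwitterions). Plasma pH 7.4
drives secretion; milk pH 7.2 drives partitioning into milk lipid.

Binding in milk combines protein binding and lipid partitioning:

$$f_{u,skim} = \frac{f_{u,plasma}^{0.448}}{(6.94\times 10^{-4})^{0.448} + f_{u,plasma}^{0.448}}
\qquad
f_{u,milk,total} = \frac{1}{0.955/f_{u,skim} + 0.045\,P_{milk}}$$
$$\log_{10} P_{milk} = -0.88 + 1.29\,LogD_{7.2}$$

where 0.955/0.045 are the aqueous/lipid volume fractions of mature milk.
$f_{u,milk,total}$ is deliberately **not capped at 1**: weakly bound drugs can
slightly exceed 1 (levetiracetam ≈ 1.006) and reproducing published
milk-to-plasma ratios requires the uncapped value.

At periodic steady state the secreted and reabsorbed amounts over a dosing
interval balance, giving the closed form

$$M/P = \frac{AUC_{milk}}{AUC_{plasma}}
      = \frac{f_{u,plasma}\, CL_{sec}}{f_{u,milk,total}\, CL_{re}}$$

independent of the maternal disposition model, dose and route (linearity
assumed). This identity is the package's central internal oracle: the ODE
simulation and the closed form are independent code paths and the test suite
requires them to agree within 1% across randomized drugs and PK parameter
sets.

## The maternal model

The full whole-body physiology behind the original workflow is not
re-implemented; maternal disposition is a reduced linear compartmental model
(1–3 compartments, first-order absorption with optional lag, linear
clearance) whose parameters are user inputs. The lactation-specific
structure — the 0.5 L milk compartment connected *directly* to plasma, with
reuptake as the only milk efflux (no nursing removal) — is preserved
exactly. Breast tissue (volume 1.0 L, specific blood flow 27.0 mL/min/100 g,
vascular/interstitial/intracellular fractions 0.14/0.10/0.76, hematocrit
0.47 — the last not stated in the source physiology and set to the standard
adult reference) is carried as metadata and can optionally be included as a
perfusion-limited distribution compartment; it never intercepts the milk
exchange.

## Numerical approach

Between dose events the system is linear with constant coefficients, so the
engine does not use a numerical ODE stepper at all. It propagates the state
**exactly** through each inter-event segment via the eigendecomposition of
the rate matrix (variation of constants in the eigenbasis, with
series-stabilized $\varphi$-functions for near-zero eigenvalues), restarting
at every dose discontinuity; a matrix-exponential fallback (Van Loan block
form) covers defective systems. Consequences:

* solver tolerances do not exist; trajectories are exact to rounding,
* mass balance holds to machine precision (tested at 0.01%, observed ~1e-15),
* dose linearity is exact, and
* the only discretization error is the trapezoidal AUC on the output grid
  (default 200 points per dosing interval; refinement changes interval AUCs
  by far less than 0.1%).

Two steady-state routes are provided. `simulate_to_steady_state()` iterates
dosing cycles until the plasma **and** milk interval AUCs change by < 0.1%
(the milk check is a deliberate strengthening: with weak reuptake coupling,
milk approaches its periodic state more slowly than plasma), capped at 200
cycles with an explicit non-convergence flag. `steady_state_interval()`
solves the periodic fixed point $x_0 = (I - e^{A\tau})^{-1} c$ directly —
necessary for strongly milk-trapped compounds (LogD$_{7.2}$ near 6 implies
$P_{milk} \sim 10^7$ and a milk-depot half-life of months, far beyond any
realistic dosing horizon).

## Infant dose metrics

With milk intake 0.150 L/kg/day and a reference maternal weight of 60.3 kg:

* $DID = C_{milk} \times 0.150$ (mg/kg/day), using the interval-average
  concentration for $DID_{ave}$ and the peak for $DID_{max}$;
* $RID = 100 \times DID / (\text{daily maternal dose}/60.3)$ (%);
* $RID_{therapeutic} = 100 \times DID / \text{pediatric therapeutic dose}$ (%).

Model-evaluation statistics (fold error $10^{|\log_{10}(pred/obs)|}$, its
geometric mean, and the conventional two-fold acceptance flag) are provided
for comparing predictions against observations.

## Population variability

The population module draws individuals log-normally with median equal to
the nominal parameter value. By default only the milk volume varies
(geometric SD 1.16, the single variance component stated for the reference
three-months-postpartum population of n = 1000); the `gsd_map` is generic so
users can add variability on CL, V, ka, etc. — no further default GSDs are
invented. Percentile bands (5/50/95) use type-7 quantile interpolation,
fixed for cross-run comparability, and runs are bit-reproducible under a
fixed seed. Milk-volume variability widens the milk bands while leaving
plasma nearly untouched (the feedback runs only through the small reuptake
flux) — mirroring the structure, not a fitted covariate model.

## Packaged medicines and input provenance

Ten physicochemically diverse medicines ship as fixtures (amoxicillin,
caffeine, cetirizine, levetiracetam, metformin, nevirapine, sertraline,
tenofovir, valproic acid, zidovudine) with their published molecular
descriptors, published secretion/reuptake clearances and published
steady-state M/P predictions. Three provenance classes are tagged per block:
`published` (reference tables), `backcalculated`, and `user`.

Two honest caveats are encoded rather than hidden:

* The published **secretion** clearances are mostly *not* reproducible from
  the tabulated LogP/pKa via Henderson–Hasselbalch — the original analysis
  used unpublished measured LogD values. Each fixture therefore also stores
  *back-calculated effective* inputs (the LogD$_{7.4}$, and for cetirizine,
  sertraline and tenofovir also the LogP, that exactly reproduce the
  published clearances), selectable with `load_fixture_drug(name,
  effective = TRUE)`. The package asserts neither set is "correct".
* The maternal PK parameters attached to the fixtures are
  literature-plausible placeholders (`user`), because the source whole-body
  models are not published. Every quantitative agreement the package claims
  against published values (clearances, M/P ratios, dose percentages) is
  independent of them.

## What the synthetic-data generator emulates — and what a green test does not establish

`generate_synthetic_drugs()` samples molecular descriptors uniformly over
MW 100–600 g/mol, LogP −3–6, HBD 0–6, PSA 10–200 Å², $f_{u,plasma}$
0.01–1, with neutral/acid/base/zwitterion ionization drawn uniformly and pKa
in 2–12. This spans the chemical space of small-molecule medicines for
property-based testing (monotonicity, mass balance, oracle equivalence). It
emulates *descriptor diversity only*: generated "drugs" need not be
synthesizable, and passing tests establish internal mathematical consistency
of the implementation — not predictive accuracy against clinical lactation
data, which for this model family is known to over-predict milk exposure for
some actively transported or atypically partitioned compounds (published
examples: nevirapine, tenofovir; both over-predicted, neither
under-predicted — conservative from an infant-safety perspective).
Concentration-time overlays against clinical observations require the
unpublished maternal models and digitized observed data and are explicitly
out of scope.

## Degenerate inputs and tie-breaks

* pKa outside (0, 14) warns but never silently rejects.
* A fully protein-bound drug in skimmed milk ($f_{u,skim} = 0$) is not
  representable; `compute_fu_milk_total()` signals invalid input.
* Zero transfer clearances are tolerated by the parameter container (the
  milk compartment decouples and stays empty, with M/P undefined) so that
  structural tests can exercise the decoupled system; regression-derived
  clearances are powers of ten and always positive.
* Dose events landing exactly on output times are applied first; reported
  trajectories are right-continuous at dose times (an IV bolus peak is the
  post-dose value).
* Oral dosing without an absorption rate constant is an error, not a guess.

## Known limitations

* Passive transfer only: no transporter-mediated secretion/reuptake terms.
* Linear kinetics only; no enterohepatic recirculation, no metabolites, no
  drug metabolism in milk.
* Fixed three-months-postpartum physiology; no colostrum-to-mature-milk
  composition trajectory, and the model should not be extrapolated to the
  very early postpartum period.
* No infant disposition model: DID/RID quantify ingestion, not infant
  systemic exposure.
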