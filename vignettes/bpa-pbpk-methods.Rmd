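---
title: "Methods: PBPK models of bisphenol A across species and life stages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PBPK models of bisphenol A across species and life stages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpapbpk)
```

# The problem

Bisphenol A (BPA) is conjugated — predominantly glucuronidated — so
efficiently in the liver and the gut wall that the unconjugated (receptor
active) compound reaches systemic circulation at well under a percent of an
oral dose. The package implements flow-limited physiologically based
pharmacokinetic (PBPK) models of deuterated BPA and its total conjugates
(BPA-c) for the adult rat, adult monkey and adult human, derives immature
life stages (postnatal-day rats and monkeys, newborn humans) by allometric
and maturation scaling, and reproduces the disposition features that
distinguish the species: enterohepatic recirculation of conjugates in the
rat, renal reabsorption of conjugates in the monkey, and neither in the
human.

All internal computation uses amounts in nmol, volumes in L, time in h and
concentrations in nmol/L; micrograms appear only at the dosing and
reporting boundaries, converted through the molecular weight of the parent
(234.33 g/mol for the deuterated compound in rat and monkey sets,
228.29 g/mol for the human sets) or of the glucuronide. Blood and serum are
treated as equivalent (blood:serum ratio 1), recorded as an assumption.

# Model structure

## Parent compound

Each tissue is a well-stirred compartment with flow-limited uptake,

$$\frac{dA_t}{dt} = Q_t\left(C_{art} - \frac{A_t/V_t}{P_t}\right),$$

with explicit venous and arterial blood pools rather than an algebraic
venous-equilibration expression. The two formulations agree in the
flow-limited regime; the explicit form makes an i.v. bolus an exact state
jump and lets the mass balance close to solver precision. The lumped
inventory is venous blood, arterial blood, liver, fat, richly perfused and
slowly perfused tissue, plus the gastrointestinal states below. A
consequence of the explicit blood pool worth knowing: the serum curve after
an i.v. bolus starts at dose/venous volume and decays through a very fast
venous-mixing transient, and that transient carries a real share of the
i.v. AUC; the output grid is geometrically refined after every dose so the
trapezoid AUC and the ODE-integrated AUC state agree within 0.1% anyway.

Hepatic conjugation is Michaelis–Menten in the rat, with the whole-liver
Vmax expressed as an IVIVE product (in vitro velocity x microsomal protein
per g liver x liver mass, `ivive_vmax()`), and first order in monkey and
human, in both cases driven by the liver venous concentration. At the
packaged 100 ug/kg dose the liver operates far below Km, so AUC is
dose-proportional to well under 2%.

## Gut and first pass

Oral doses pass stomach to gut lumen to enterocyte with first-order rate
constants. In the enterocyte the parent either escapes to portal blood
(`k_portal_transfer`) or is conjugated. The rat uses a single composite
constant that lumps conjugation with immediate basolateral export of the
conjugate, so the conjugated flux appears directly in the systemic
conjugate pool; monkey and human form an explicit enterocyte-conjugate
pool that effluxes first order to systemic blood. This presystemic loss,
not hepatic extraction alone, is what produces the observed sub-percent
oral bioavailability of unconjugated BPA at low doses.

## Conjugate disposition and the rat enterohepatic loop

Systemic conjugates use one compartment (monkey, human) or three (rat).
In the rat a fixed fraction (0.993) of hepatically formed conjugate is
excreted into bile directly — the packaged value keeps the systemic bypass
below the reported 1% — and a Michaelis–Menten biliary transporter
(MRP2-like) acts on the central conjugate pool, so conjugate that reached
circulation (from the gut wall or from reconjugation) recirculates as
well; both are needed for the cumulative fecal excretion to accumulate
while urinary recovery stays in the 6–8% window. Bile passes through three
first-order transit compartments to the terminal intestine, where
bacterial deconjugation liberates parent. The deconjugation flux is
partitioned at rate level — the split is exact at every instant — into 90%
reconjugation (back to the systemic conjugate pool through the
enterocyte), reabsorption to portal blood as parent, and fecal excretion
of parent; undeconjugated conjugate leaves in feces first order.

The loop constants are constrained jointly by a flux budget. Writing
$D$ for the cumulative deconjugation per unit dose, $f_{fec}$ for the
fecal-parent fraction of the split and $\varphi_b$ for the biliary share
of central-conjugate elimination, the asymptotic recoveries are
$F_{feces}^{parent} = f_{fec} D$,
$F_{urine} \approx (1-\varphi_b)\, (0.9\,D)$ and the remainder leaves as
fecal conjugate. Because 90% of every deconjugated molecule re-enters the
loop, hitting 46–49% fecal parent forces $D \gtrsim 5$ — each molecule
cycles several times — and the urinary window then pins
$\varphi_b \approx 0.99$. The packaged values
($f_{reabsorbed} = 0.0175$, $f_{fec} = 0.0825$, $D \approx 5.7$) were
derived from this algebra and verified by simulation; at 96 h the
accounting horizon (an assumption, the collection window of the cited
radiolabel studies not being stated) the loop has converged to within a
fraction of a percent of its asymptote.

Monkey conjugates are filtered at a urinary clearance with a
capacity-limited (Michaelis–Menten) reabsorption flux capped at
filtration, returned to the central pool. At high concentration the
reabsorption saturates, so net urinary clearance rises with concentration;
at low concentration it retains most of the filtrate, which is what
prolongs the conjugate terminal phase. A small first-order fecal clearance
of circulating conjugate stands in for the minimal biliary route and
produces the sub-3% fecal recovery; it is an addition to the minimal
structure, tagged as calibrated in the provenance map. Renal reabsorption
is removed for humans.

## Ontogeny and cross-species extrapolation

Derived life stages scale volumes with body weight (exponent 1), flows and
Vmax-type capacities with the 0.75 power, and first-order rate constants
with the −0.25 power (so first-order capacities, k x V, also scale with
the 0.75 power); the maturation fractions of the packaged ontogeny tables
then multiply hepatic conjugation, gut-wall conjugation and biliary export
(MRP2). Fractions are stored relative to the adult, which makes scaling
compositional. The hepatic fractions encode fold-differences in capacity
of up to 282 at postnatal day 3 in the rat and 8.1–14.9 across infant
monkeys; the rat gut matures late (fractions 0.05–0.4 before weaning)
while the infant monkey gut is already about half active, the ordering —
though not the magnitude, which is a calibration choice — being what
produces the strong rat age gradient and the flat monkey profile in the
steady-state panel.

The newborn human set is produced at load time by replacing the PND5
monkey set's physiology with newborn-human values and rescaling the
first-order constants by the body-weight ratio to the −0.25 power. At
periodic steady state the daily-average serum parent concentration obeys
the well-stirred identity $C_{avg} = f_{gut}\,A/(24\,CL_{int})$ (with
$f_{gut}$ the enterocyte escape fraction and $A$ the daily dose), which
the simulated panel reproduces to four digits; the PND5 monkey gut
fraction (0.5346) was fixed with this identity against the newborn
steady-state prediction and then frozen.

# Numerical choices

* Stiff integration with `deSolve::lsoda`, rtol 1e-8, atol 1e-10 nmol.
  Hepatic extraction is fast relative to perfusion, so the system is
  genuinely stiff (eigenvalues beyond 1000/h in the rat).
* Doses are state jumps applied through solver events (i.v. to venous
  blood, oral to stomach); a dose at time zero is folded into the initial
  state so the reported value at t = 0 is post-bolus.
* The output grid always contains every dose time, the instant 2 h after
  the first dose (used by the fat partitioning experiment), and a
  geometric refinement (80 points from 1e-4 h to 0.5 h) after each dose.
* An independent fixed-step classical Runge–Kutta integrator
  (`simulate_fixed_step`) serves as the oracle; at dt = 2e-4 h it is
  within the stability region of the stiffest packaged model and agrees
  with the stiff solver to better than 0.1% on all outputs.
* The mass-balance residual is reported at every output time as
  |administered − (in body + excreted)| / dose; packaged scenarios close
  to ~1e-14.
* Steady state under repeated daily dosing is declared on the first day
  whose AUC differs from the previous day's by less than 0.1% (error if
  not reached by day 14). Cmax refines the grid maximum by local quadratic
  interpolation.
* Negative-concentration protection: Michaelis–Menten and clearance terms
  clamp their concentration argument at zero; solver tolerances keep any
  transient undershoot below 1e-6 of the dose.

# Calibration and sensitivity

The original models were fitted visually; here calibration is explicit
bounded least squares (Levenberg–Marquardt, log10-transformed parameters).
Time-course targets contribute log-scale residuals at the observation
times, with censored points excluded; reported ranges enter as hinge
losses that vanish anywhere inside the range, so a range is never
over-fitted to its midpoint. The procedure is deterministic given the
starting point; the seed argument only stamps provenance.

Local sensitivity uses central differences at 1% relative perturbation,
reported as (dM/M)/(dp/p). Perturbing cardiac output co-scales all tissue
flows so the perturbed set still conserves flow. Two structural results
are worth stating because they are easy to get wrong: for *oral* dosing
the steady-state parent AUC is nearly invariant to cardiac output — the
well-stirred liver cancels the flow dependence of bioavailability against
that of clearance — while for *i.v.* dosing the coefficient is strongly
negative, as expected for flow-limited hepatic clearance. The most
sensitive parameters for oral parent exposure in the monkey are the
hepatic first-order constant and the gut-wall conjugation/transfer
constants, matching the qualitative ranking reported for these models.

# Synthetic data and what passing tests show

`generate_series()` samples a simulated observable at design times
(default sparse PK design 0.25–96 h), multiplies by mean-one lognormal
noise with a given CV, and censors below a limit of detection;
`recovery_suite()` runs generate-then-refit cycles (20 replicates at 5%
noise in the packaged experiment; horizons of 24 h keep each fit to a few
seconds) and flags parameters whose normalized sensitivity on the observed
curve is below 0.01 as non-identifiable — the biliary Km, for example, is
not identifiable from low-dose serum data because the transporter never
approaches saturation there.

The generator shares the model's structure by construction, so recovery
experiments demonstrate identifiability and optimizer correctness, not
model adequacy: lognormal measurement error, no inter-animal variability,
no sampling-time error, no assay drift. Agreement with the packaged
windows likewise shows that the model family can satisfy the reported
constraints simultaneously, not that every packaged constant is uniquely
determined — the provenance tags distinguish paper-cited values from
calibrated and assumed ones parameter by parameter.

# Known limitations

* Total conjugates only; the glucuronide/sulfate split is out of scope.
* Flow-limited tissues without plasma-protein binding; the fat:serum ratio
  at 2 h therefore reflects both the partition coefficient and the local
  slope of the serum curve, and sits slightly above the coefficient while
  serum is still falling.
* The EHR loop uses deliberately non-physiological lumped constants (as
  the source models did); transit and deconjugation rates are identifiable
  only jointly.
* Discrete life stages; no continuous growth, no pregnancy/fetal model,
  no mouse parameter set.
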