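---
title: "Model and methods: whole-body PBPK with dissolution-driven oral absorption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nanopbpk` couples three models: a whole-body perfusion-limited
pharmacokinetic (PBPK) core, a compartmental absorption and transit
description of the gut in which oral input is produced by particle
dissolution (together, a physiologically based biopharmaceutics model,
PBBM), and an in vitro USP II dissolution simulator used both forward (to
predict a dissolution profile from a particle size distribution) and
inverse (to back-calculate a *product* particle size distribution, P-PSD,
from an observed profile). This vignette records the model equations, the
parameter conventions, the one-time calibrations frozen into the packaged
tables, and the limitations a user should know about.

## Whole-body disposition

Each of 13 tissues (lung, adipose, muscle, liver, spleen, heart, brain,
kidney, skin, reproductive organs, red and yellow marrow, rest-of-body) is
perfusion-limited:

$$V_t \frac{dC_t}{dt} = Q_t\left(C_{b,art} - \frac{C_t\,B\!:\!P}{K_{p,t}}\right)$$

with tissue:plasma partition coefficients $K_p$ taken as *inputs* (the
packaged efavirenz values are literature-method estimates per species), the
blood-to-plasma ratio $B\!:\!P$ handling red-cell partitioning (no explicit
erythrocyte compartment), the lung perfused in series at full cardiac
output, and venous/arterial blood pools closing the loop. Reported plasma
concentration is venous blood divided by $B\!:\!P$, in ng/mL.

Hepatic metabolism is Michaelis-Menten per enzyme,
$v = V_{max} C_d/(K_m + C_d)$, with whole-organ $V_{max}$ (mg/s) and $K_m$
(mg/L). The driving concentration $C_d$ is not uniquely determined by a
perfusion-limited model, and the convention used by commercial tools is not
published; it is therefore isolated in one switchable function
(`hepatic_driver_concentration()`). The packaged default is the unbound
liver tissue concentration, $C_d = f_{up} C_{liver}$. The alternative
unbound-plasma convention ($f_{up} C_{liver}/K_p$) caps the attainable
hepatic plasma clearance at $f_{up}\,CL_{int} \approx 1.9$ L/h in the rat
parameter set, which no physiologic hepatic blood flow can reconcile with
the reported i.v. exposure; the default convention reproduces it at a
hepatic flow inside the literature range (see *Calibrations*). Renal
elimination follows $f_{up} \cdot GFR$ on arterial plasma by default, with
an explicit-value override.

The solver is stiff-capable (`deSolve`: `lsoda` for the systemic model,
sparse-Jacobian `lsodes` for the coupled oral model), absolute tolerance
1e-9 mg and relative 1e-7, output on a fixed grid with a finer early
segment. Mass balance (body + gut + excreted + metabolised = dose) is
audited on every run and stays within 0.1% (typically ~1e-8).

## Oral absorption (the PBBM)

The gut is a 9-compartment chain (stomach, duodenum, two jejunum and three
ileum segments, caecum, ascending colon) with first-order transit at
1/transit-time. Suspensions empty the stomach with a 0.1 h transit time,
the standard immediate-release suspension convention; tablets use the
fasted default (0.25 h).

Solid drug is carried as a binned particle size distribution. Each bin in
each compartment dissolves by the Wang-Flanagan (Noyes-Whitney) law for a
shrinking sphere,

$$\frac{dm}{dt} = -\frac{3 D m}{\rho r h}(C_s - C), \qquad h = \min(r, 30\,\mu m),$$

with the particle radius recovered from the bin's mass and (conserved)
particle number; the number advects with transit, which factorises exactly
as bin-count times a shared transit-occupancy tracer. The 30 um
diffusion-layer cap is the standard in vivo convention: below it $h = r$,
which is the mechanism by which small particles gain disproportionate
rate. Two numerical smoothings keep the right-hand side differentiable: a
0.1 um regulariser in the depletion limit (the $m^{1/3}$ radius law has
unbounded slope at zero) and a steep smooth version of the nano-effect
threshold switch. Both bias rates by under 1% for micron-sized particles.

Luminal solubility per compartment is the pH-adjusted aqueous solubility
(Henderson-Hasselbalch; flat across GI pH for a pKa-10.2 weak acid) plus a
bile-salt solubilisation increment interpolated through the packaged
fasted- and fed-state biorelevant points, so those two printed solubilities
are reproduced exactly at their nominal bile concentrations (3 and 15 mM).
The drug's fitted solubilisation ratio acts as a dimensionless multiplier
on this increment relative to its reference value, which is what the
sensitivity analysis sweeps. When the nano effect is enabled, particles at
or below 1 um radius receive a flat solubility multiplier (1.381 in the
packaged record); the Ostwald-Freundlich mode exists to examine the
physical plausibility of that scalar (with the packaged interfacial
tension it predicts a ~4% enhancement at 100 nm, i.e. the flat factor is an
effective, not a curvature-thermodynamic, parameter).

Absorption is passive: flux = $P_{eff} \cdot (SA/V) \cdot ASF \cdot$
dissolved amount, per absorptive compartment (stomach excluded, colon at
reduced surface scale). Absorbed drug passes one enterocyte pool with
saturable gut metabolism (gut-sited enzymes, driven by total enterocyte
concentration) and is delivered to the liver as portal inflow, so hepatic
first pass is intrinsic to the disposition model. The per-species
absorption scale factor ASF is a packaged stand-in for the commercial
surface-area dialect; see *Calibrations*.

## In vitro USP II model and P-PSD inversion

The vessel is a single well-stirred compartment (900 mL); saturation
solubility is `sol_aq + kaff * surfactant`. Three in vitro-specific
transport conventions differ from the GI model, all documented here
because the 50 rpm powder test is hydrodynamically unlike the intestinal
surface:

* boundary layer $h = r$ with no cap (quiescent Sherwood-2 limit);
* micelle-facilitated diffusion: the solubilised fraction diffuses at the
  micelle's Stokes-Einstein diffusivity (packaged micelle radius 1.26 nm),
  with a transport efficiency of 0.70 reflecting finite micelle-drug
  equilibration across the boundary layer;
* coning: dense particles settle into the stagnant cone under the paddle,
  losing exposed surface as $1/(1 + (r/60\,\mu m)^2)$.

The efficiency and coning radius are the in vitro model's two calibrated
constants: they were set once so that the simulator, driven by the
case-study's reported P-PSDs, reproduces the reported dissolution
efficiency of both formulations (raw material ~53%, nanocrystals ~90%,
with >85% at 15 min for the nanocrystals), and then frozen. Without them a
plain free-drug Wang-Flanagan rate overpredicts both (raw DE ~75%): the
printed mean/SD summaries of a P-PSD under-determine the per-bin fractions
the source tool actually fits, so some transport resistance must be
carried by the in vitro rate model itself.

`fit_ppsd()` inverts the simulator by bounded Nelder-Mead least squares on
(log mean radius, log SD) with multi-start (default 3 starts spread over a
decade), reporting AFE/AAFE/RMSE of the fitted profile. On noise-free
self-generated profiles it recovers the generating moments to three
figures; at 1% multiplicative noise the mean radius returns within ~2%.

## PSD discretisation

`expand_psd()` assumes the mass-weighted radius distribution is log-normal
parameterised by its arithmetic mean and SD, cut into equal-probability
mass bins with conditional-mean representative radii. Conditional means
preserve the arithmetic mean exactly but lose within-bin variance (~14% of
the SD for the raw material's CV~1 distribution at 8 bins), so a log-space
power correction $r \to C r^b$ is solved (one-dimensional root find) to
restore the SD exactly while holding the mean; radii stay positive and
log-normally shaped. Discretised mean and SD therefore match the inputs to
machine precision, which the round-trip tests assert at 2%.

## Validation statistics

Fold error FE = predicted/observed per point; AFE = $10^{\mathrm{mean}(\log_{10} FE)}$;
AAFE = $10^{\mathrm{mean}|\log_{10} FE|}$. The acceptance rule is the
conventional two-fold criterion: all FE in [0.2, 2] and AFE, AAFE < 2. NCA
uses Cmax/tmax lookup, linear-up/log-down trapezoids, and a 3-point
terminal log-linear fit for $\lambda_z$ (user-overridable); AUC to infinity
adds $C_{last}/\lambda_z$ and is flagged absent when the tail is not
log-linear decreasing. Both conventions (profile-level FE over
concentration-time points, and parameter-level FE over NCA summaries) are
available, as the two are used for different tables in practice.

## Population simulation

Virtual subjects multiply parameters by independent unit-mean log-normal
deviates: 30% CV on enzyme Vmax, 20% on GI transit times and tissue blood
flows, 15% on tissue volumes and permeability, 0% on solubility by
default. These CVs are a documented stand-in for proprietary
population-physiology generators (whose covariate equations are not
public), chosen to produce prediction bands of the magnitude reported for
small-rodent PK studies; they are fully user-configurable and carry no
claim of demographic realism. Cardiac output is recomputed as the sum of
perturbed tissue flows, preserving the flow-balance invariant. Bands are
pointwise (not simultaneous) percentiles on a 150-point grid. The default
design (n = 7 subjects, 10 repeats) matches the case study.

Because the case study's observed animal data exist only as figures, all
"observed" datasets in the package are generated from the model itself
plus multiplicative residual noise (`make_observed_pk()`). Coverage
checks are therefore *self*-coverage: they verify the variability model
and band construction, not agreement with external animals. This is
stated here once and applies to every downstream test.

## One-time calibrations (frozen)

Four packaged constants were calibrated once against the case study's
reported outputs and then frozen; none is adjusted at run time.

1. **Depot-fat volumes.** Tissue volumes are not reported; standard
   species tables are packaged, but with the reported partition
   coefficients (adipose Kp 69.6 in rat) literature fat volumes
   overshoot the reported steady-state distribution volumes. The adipose
   fraction is therefore solved so `steady_state_vd()` returns the
   reported Vss (1.672 L rat, 746.6 L human). The resulting rat fat
   volume (~0.3% of body weight) is lean even for a young laboratory rat;
   this is the price of taking the printed Kp column at face value.
2. **Rat hepatic blood flow** (27.4% of cardiac output, ~82 mL/min/kg,
   upper literature range) from the reported i.v. 2 mg/kg AUC.
3. **Absorption scale factors** (rat 40, human 2.0) from the reported
   oral nanocrystal exposures. The rat value is large: with the packaged
   clearance convention the reported i.v. clearance implies a hepatic
   extraction near 0.88, and the reported oral Cmax is then only
   reachable in a fast-absorption regime in which a concentrated portal
   bolus partially saturates first-pass metabolism. The simulated rat
   tmax is accordingly earlier (~0.1 h) than reported (~0.67 h) — an
   accepted trade-off, since exposure magnitude, not peak time, is the
   quantity the rat model is asked to reproduce. The human value needs no
   such regime (hepatic extraction ~1%) and lands Cmax, AUC and tmax
   simultaneously.
4. **In vitro micelle efficiency and coning radius** (0.70, 60 um), as
   described above.

## Problem sizes and determinism

The shipped tests run the full rat population design (70 subjects), a
192-hour human simulation, reduced sensitivity grids (5-7 points per
parameter versus 25 in the full design), and single P-PSD inversions;
the full 25-point grids are a one-line change (`psa_config(n_tests = 25)`).
Every stochastic step takes an explicit seed and is bit-reproducible under
it.

## Known limitations

* Tissues are perfusion-limited; no transporters, lymphatics,
  enterohepatic recycling, or metabolite kinetics.
* The hepatic driving-concentration convention is an assumption; switching
  it rescales clearance and first-pass extraction jointly.
* No precipitation (the drug is non-ionisable across GI pH) and no
  fed-state simulation.
* The in vitro hydrodynamic constants are calibrated to one compound in
  one apparatus configuration; treat them as apparatus parameters, not
  drug properties.
* Population CVs are stand-ins; covariate-driven physiology (age, sex,
  genotype) is out of scope.
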