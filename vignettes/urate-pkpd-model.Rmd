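---
title: "A physiological PK/PD model of uricosuric urate lowering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A physiological PK/PD model of uricosuric urate lowering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uricosim)
```

## The problem

A uricosuric drug lowers serum urate (SUA) by blocking tubular reabsorption
of filtered urate, so that more of the glomerular load is excreted. Given
only phase-1 data — plasma drug concentrations, interval urine collections
and serum urate time courses from single-ascending-dose (SAD) cohorts —
we want a model that predicts the full SUA–time profile under repeated
dosing. `uricosim` implements that workflow for dotinurad-like agents: an
oral one-compartment PK model, a one-pool physiological urate disposition
model with an Emax drug effect on renal clearance, the estimation cascade
that identifies every parameter from SAD-style data, and a conservative
forward simulator.

## The drug model

Plasma kinetics are the classic one-compartment, first-order absorption
form. After a dose $D$ at time 0,

$$C_p(t) = \frac{D}{V/F}\,\frac{K_a}{K_a - K_e}\left(e^{-K_e t} - e^{-K_a t}\right),$$

and repeated doses superpose. The parameterisation is deliberately the
apparent oral triplet ($V/F$, $K_a$, $K_e$); the reference estimates for
dotinurad in fasted healthy men are $V/F$ = 10585 mL, $K_a$ = 0.770 /h,
$K_e$ = 0.0795 /h (`reference_pk_params()`), giving $t_{1/2} \approx 8.7$ h
and CL/F $\approx$ 0.84 L/h. One fasted parameter set serves all regimens:
the observed food effect on exposure is small (fed/fasted geometric mean
ratio of $C_\mathrm{max}$ about 0.84) and fed profiles are well predicted by
fasted parameters, so no lag time or fed-state model is carried.

`fit_pk()` performs least squares on the linear concentration scale
(optionally two-pass $1/\hat y^2$ weighting — the estimation objective used
on the original data is not recorded, so the plain objective is the
default). The absorption/elimination flip-flop ambiguity is removed
structurally: the optimizer works in $(V/F, K_e, \Delta k)$ with
$K_a = K_e + \Delta k$, $\Delta k > 0$. Starting values come from curve
stripping ($K_e$ from the terminal log-linear slope, $K_a = 3/T_\mathrm{max}$,
$V/F$ from $D/(\mathrm{AUC}\cdot K_e)$).

`nca()` is the model-free companion: trapezoidal AUC, $\lambda_z$ by
log-linear regression on the last three positive post-peak points extended
backwards while the adjusted $R^2$ improves (the selection rule is not
stated in the source material; this is the common automatic rule), ties in
$T_\mathrm{max}$ broken to the earliest time, and a flagged linear
interpolation when the 24 h sample is absent.

One identity worth spelling out because it is easy to get wrong: for
once-daily oral dosing the accumulation ratio of daily AUC is
$\mathrm{AUC}_{0\text{-}\infty}/\mathrm{AUC}_{0\text{-}24}$ (steady-state
daily AUC equals the single-dose total AUC). The familiar
$1/(1-e^{-K_e\tau})$ form is the IV-bolus special case; with these
parameters the bolus form gives 1.174 while the oral model gives 1.198,
which is what the test suite asserts (and which sits inside the observed
1.18–1.22 range).

## The urate model

Urate is treated as one well-mixed pool of volume $V_{d,UA}$, produced at a
constant rate ("synthesis", diet plus endogenous turnover) and cleared by
two parallel routes:

* renal: filtration at GFR followed by fractional reabsorption $f_{reabs}$,
  so $CL_{R,UA} = GFR(1 - f_{reabs})$ at baseline;
* non-renal (gut): constant clearance $CL_{Gut,UA}$.

The drug relieves reabsorption through a saturable effect of the total
plasma concentration,

$$CL_{R,UA}(C_p) = GFR - f_{reabs}\,GFR\left(1 - \frac{E_{max} C_p}{EC_{50} + C_p}\right),$$

which is monotone and concave in $C_p$ and rises from the baseline
clearance to $GFR(1 - f_{reabs}(1 - E_{max}))$. The drug is assumed not to
touch GFR, $CL_{Gut,UA}$, $V_{d,UA}$ or synthesis.

Two closures anchor the baseline: renal and non-renal excretion split 2:1
($CL_{Gut,UA} = CL_{R,UA}/2$), and the pre-dose state is a steady state, so
synthesis equals total clearance times baseline SUA. `urate_physiology()`
enforces both, which is what makes a placebo simulation exactly flat — the
natural consistency check for the whole machine. Note a subtlety: the three
healthy-volunteer baseline means (SUA 5.71 mg/dL, urinary urate
575 mg/day, $CL_{R,UA}$ 7.10 mL/min) are mutually inconsistent by about
2% ($CL_{R,UA}\times\mathrm{SUA} \approx 584$ mg/day), as sample means of
ratios tend to be. The simulator closes the balance through SUA and
clearance; `derive_baseline()` reproduces the flux arithmetic
($X_{f} = X_u/2$, synthesis $= 1.5\,X_u$) exactly as defined.

### The estimation cascade

Each parameter has its own estimator, run in order by `run_pipeline()`:

1. **Baselines** from pre-dose data: SUA at time 0, 24 h urinary urate,
   $CL_{R,UA} = X_u/\mathrm{AUEC}$ (`clearance_from_excretion()`, with AUEC
   the area under the SUA curve — the exposure denominator).
2. **$V_{d,UA}$** by delta mass balance (`estimate_vd_ua()`): the extra
   urate excreted over the first 24 h (urinary increase plus the signed
   change in gut excretion) divided by the SUA drop. Applied to output of
   the conservative simulator this returns the generating volume to machine
   precision — it is literally the discrete conservation identity
   rearranged. The reference value is 16.0 L (0.27 L/kg at 60 kg).
3. **$f_{reabs}$** from placebo subjects (`estimate_freabs()`):
   $1 - CL_{R,UA}/GFR$, with GFR taken as creatinine clearance normalised
   to 1.73 m² body surface area when creatinine data exist, otherwise
   implied from a known baseline pair via `implied_gfr()`. Reference:
   0.943, implying GFR $\approx$ 124.6 mL/min.
4. **$E_{max}, EC_{50}$** (`interval_means()` + `fit_emax()`): per dosed
   subject, mean $C_p$ and mean $CL_{R,UA}$ over the 0–6, 6–12, 12–24 and
   24–48 h windows; the effect is back-calculated by inverting the
   clearance relation, clipped to $[0,1)$ with a warning when noise pushes
   it outside (the inversion is not specified in the source; this is the
   algebraic rearrangement), and the simple Emax curve is fitted by
   bounded least squares. Reference: $E_{max}$ = 0.51, $EC_{50}$ =
   196 ng/mL (547 nmol/L total; 3.8 nmol/L free at 99.3% protein binding).

A caveat the test suite quantifies rather than hides: the interval-mean
regression in step 4 is intrinsically approximate even on noise-free data,
because the effect is concave in $C_p$ — the mean effect over a window where
$C_p$ swings widely is smaller than the effect at the mean $C_p$, which
drags $EC_{50}$ upward (and $E_{max}$ slightly up with it) relative to the
generating values. On zero-noise synthetic data the pipeline recovers PK
parameters, $f_{reabs}$ and $V_{d,UA}$ essentially exactly, while the Emax
stage lands within roughly 10% on $E_{max}$ and 25% on $EC_{50}$; the
pipeline test asserts those characterised bands. When the Emax fit is given
effect points evaluated at exact concentrations (no window averaging), the
recovery is exact — that distinction is why the parameter-recovery
experiments in the acceptance script use the direct fit.

## The simulator

`simulate_sua()` integrates the pool with an explicit conservative update
at `dt` = 1 h by default, mirroring an hourly clearance re-evaluation:
per step, $C_p$ is the *exact analytic mean* of the one-compartment curve
over the step (excretion is an integral quantity, so a point sample would
bias it), clearance comes from the Emax relation, excreted amounts are
$X_u = CL_{R,UA}\cdot \mathrm{SUA}\cdot dt$ and
$X_f = CL_{Gut,UA}\cdot \mathrm{SUA}\cdot dt$ with start-of-step SUA, and
the pool update books every milligram: the residual of
$\Delta\mathrm{pool} = \mathrm{synthesis}\cdot T - \sum X_u - \sum X_f$
is below $10^{-8}$ mg on every simulation in the suite. Simulations start
24 h before the first dose so the baseline interval is part of the output.

The start-of-step scheme is first order; the suite verifies the Richardson
ratio of about 2 when halving `dt`. Because the first day's SUA transient
is fast (the effective urate turnover rate roughly quadruples at the 5 mg
exposure), the hourly explicit scheme carries a few percent of
discretisation error there; a `sua_at = "midpoint"` option provides a
half-step predictor whose halving error stays under 0.5% if trajectories
on a tight tolerance are needed. The default remains the start-of-step
reading because it is the update rule the original hourly procedure
describes. Two independent oracles guard the integrator:
`steady_state_sua()` (the closed-form equilibrium under a clamped
concentration, approached within 0.1% in the long run) and
`mass_balance_residual()`.

`predict_mad()` packages the multiple-dose scenario: once-daily dosing,
sampling at the multiple-ascending-dose blood schedule, tidy output for
overlay on observed data. With the reference parameters, 5 mg once daily
keeps the predicted SUA below 3 mg/dL throughout days 5–7.

## The synthetic study generator

No individual-level clinical data accompany the source material, so
`generate_sad()`/`generate_mad()` fabricate cohorts with the statistical
structure the estimators assume: 6 active + 3 placebo subjects per cohort
(SAD doses 0.5–20 mg; MAD 2 and 5 mg once daily for 7 days), the exact
blood and urine schedules of those designs, lognormal between-subject
variability around the reference values (dispersions taken from the printed
summary statistics where available, 20% otherwise; weight 60 ± 10% kg
truncated to 50–80 kg, BSA by Du Bois at a fixed 1.70 m height), residual
lognormal noise (10% plasma, 5% SUA/urine — declared synthetic defaults,
not inferred quantities), and a 1 ng/mL plasma quantitation floor emitted
as 0 with a below-limit flag. Identical configuration and seed regenerate a
dataset byte for byte.

What the generator does *not* emulate — and what passing recovery tests
therefore cannot certify about real data: circadian variation in GFR and
urate synthesis, dropout and sampling-time jitter, assay-specific error
structure, correlation between PK and physiology parameters within a
subject, and any departure of real urate handling from the one-pool, 2:1,
constant-synthesis idealisation.

## Numerical and design choices

* **Units.** Time h; drug amounts ng (mg doses converted once); volumes mL;
  drug concentrations ng/mL; SUA stored mg/dL and converted to mg/mL only
  inside mass-balance arithmetic; clearances stored mL/min and converted to
  mL/h inside the integrator. Every factor lives in one file.
* **Sign conventions.** The delta mass balance requires a positive SUA
  drop; inconsistent signs raise rather than silently negate.
* **Bounds.** $E_{max}$ is constrained to $(0, 1]$; an estimate at the
  bound raises a saturation warning. Starting values pinned at a bound are
  nudged inward, since Levenberg–Marquardt cannot leave an active bound.
* **Degenerate inputs.** $K_a = K_e$ is rejected (the coincident-rate limit
  is out of scope); a negative pool aborts with a physical-inconsistency
  error; windows without urine or SUA coverage raise missing-interval
  errors.
* **Problem sizes.** The test suite and acceptance script run on the study
  designs themselves (54 SAD / 27 MAD subjects, 1 h simulation grids over
  48–240 h, a few thousand subjects for distribution checks) and complete
  in well under a minute.

## Limitations

The model is a deliberately small idealisation: one urate pool, constant
synthesis, no transporter-level mechanism, no renal secretion, no
solubility or crystallisation physics, total (not free) plasma
concentration as the effect driver, and point simulation without
uncertainty propagation. The estimation cascade reproduces the published
procedure, including its window-averaging approximation, rather than a
statistically optimal joint fit — extending it to a mixed-effects or
simultaneous PK/PD estimator would be the natural next step.
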