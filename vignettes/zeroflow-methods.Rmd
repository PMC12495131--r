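---
title: "Zero-flow pressure after cardiac arrest: model, controller, and comparison pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zero-flow pressure after cardiac arrest: model, controller, and comparison pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`zeroflow` studies a deceptively simple question: if the heart is stopped,
what pressure does the circulation settle to, and is that number — the
mean circulatory filling pressure (MCFP) — a stable property of the
circulation at all? The package provides the three ingredients needed to
answer it on a desk: a closed-loop cardiovascular simulator with autonomic
reflex control, a synthetic generator of pig-like arrest recordings
anchored to experimental group summaries, and the signal-processing and
statistics chain that compares them. This vignette documents the science
and the numerical choices; the function reference documents the API.

## The circulation as a 21-compartment RC network

The model is a lumped-parameter ("Windkessel") network in the classical
electrical analogy: 21 compartments arranged in a closed loop with
branching systemic beds (head/arms, kidneys, splanchnic organs, legs),
a right and left heart of two chambers each, and a pulmonary circuit.
Compartment 0 is the aortic arch (the arterial afferent site of the
baroreflex) and compartment 15 the right atrium (the venous afferent
site). Each passive compartment obeys

$$P_i = \frac{V_i - V_{0,i}}{C_i} + P_{ext,i},$$

with compliance $C_i$ (mL/mmHg), unstressed volume $V_{0,i}$ (the volume
at zero transmural pressure) and an external pressure that equals the
intrathoracic pressure for thoracic compartments. The four cardiac
chambers use a time-varying elastance, $P = E(t)\,(V - V_0) + P_{ext}$,
where $E(t)$ rises from the diastolic floor $E_{min}$ to the systolic
peak $E_{max}$ and back as a raised-half-sine (Hann) pulse over the
systolic fraction of each beat; systolic duration scales with the square
root of cycle length ($T_s = 0.3\sqrt{T}$ s), a standard convention in
this model family. Flow on each connection is $Q = \Delta P / R$, with
ideal diodes on the four cardiac valves and on the microvascular
(arteriolar) edges — the latter representing the Starling-resistor
behaviour of arterioles and distal venous valves that block retrograde
flow from veins into arteries. Volume is conserved exactly by
construction; simulations track total volume and abort on non-finite or
negative compartment volumes.

Parameter provenance: the experimental report this design follows prints
no compartment table, and its cited open-source ancestor could not be
bundled here; `inst/extdata/model_human.yaml` is therefore a
representative healthy-adult parameter set assembled from the field's
published summary values (total systemic arterial compliance ≈ 2 mL/mmHg,
venous ≈ 92 mL/mmHg, regional bed resistances of 3–5 mmHg·s/mL, total
blood volume 5 L, unstressed volume ≈ 3.8 L). At baseline it produces
MAP ≈ 95 mmHg, CVP ≈ 2–3 mmHg, CO ≈ 5.5 L/min, pulse pressure ≈ 34 mmHg
and an MCFP of 8.7 mmHg — all within textbook ranges.

## Arrest, and what "elastance to zero" means

Circulatory arrest is modelled as instantaneous at $t = 0$: heart rate,
respiratory rate and cardiac *activation* are set to zero and the
intrathoracic pressure is held at 0 (the experimental protocol
disconnected the ventilator before arrest). Two modelling decisions here
deserve justification:

**Arrest elastance.** Removing activation leaves each chamber at an
"arrest elastance", a config knob (`arrest_elastance`) defaulting to the
chamber's diastolic $E_{min}$. Taking the phrase "elastance to zero"
literally (a near-zero floor such as $10^{-3}$ mmHg/mL) would make each
arrested chamber a 1000 mL/mmHg reservoir; the four chambers would then
swallow essentially the entire stressed volume and drag the whole
zero-flow equilibrium below 1 mmHg — incompatible with any observed
plateau of 9–16 mmHg. Reading it as "activation to zero" keeps the
chambers as passive reservoirs with their diastolic stiffness, which is
also what an arrested ventricle physically is. The analytic MCFP
(`mcfp()`) uses $1/E_{arrest}$ as each chamber's compliance either way,
so the equilibrium oracle stays consistent with whatever the knob is set
to.

**Valves after arrest** (`valve_mode_post_arrest`). Three modes exist.
`"open"` ignores all valves after arrest — the MCFP idealization of free
redistribution, used by the equilibrium-oracle tests. `"diode"` keeps all
one-way valves one-way. The default, `"sealed_cardiac"`, additionally
closes the cardiac valves: in a linear diode network any open forward
path through the arrested heart lets a venous pressure peak seep into the
arteries (veins → right heart → lungs → left heart → aorta), so a
sustained venous-over-arterial gradient — the experiment's signature
observation — would be impossible. The observed persistence of that
gradient for ten minutes is itself the evidence that no effective
conduit exists across the arrested heart; the sealed mode encodes that as
structure. With reflexes off the choice is immaterial for the measured
channels: arterial and venous pressure equilibrate through the
microcirculation within ~30 s either way.

There is no nonlinear collapse law: compartments may carry pressures
below their external pressure. This is a known limitation of the linear
model class.

## The reflex controller

Short-term pressure regulation is a discrete-time controller ticking at
the signal sampling rate (200 Hz — the only rate stated anywhere in the
experimental chain), in four stages per tick:

1. **Afferent smoothing** — running means over 250 samples (1.25 s) of
   aortic-arch pressure, aortic pulse pressure, and right-atrial
   pressure.
2. **Error and saturation** — subtraction of the set points (95 / 35 /
   3 mmHg) and arctangent saturation $\varphi(e) = \frac{2L}{\pi}
   \arctan\!\frac{\pi e}{2L}$, which has unit slope at zero and is
   strictly bounded by $L$: 18 for the arterial baroreflex (ABR), 5 for
   the cardiopulmonary reflex (CPR). The exact normalization of the
   saturation is not fixed by its verbal description; this form was
   chosen for its unit small-signal gain and hard asymptote.
3. **Arc dynamics** — convolution of each scaled error with a unit-area
   triangular impulse response (delay / peak / end per arc), so a
   constant input passes through with gain one.
4. **Static gains** — each arc output scales onto its effectors: heart
   rate (additive, bpm), contractility (fractional on $E_{max}$),
   microvascular resistance (fractional), and venous unstressed volume
   (additive mL, distributed over the venous compartments in proportion
   to their unstressed volumes). Positive (hypertensive) errors lower
   heart rate, contractility and resistance and raise unstressed volume —
   standard negative feedback. Effectors are clamped (HR ≥ 0, scales
   ≥ 0.1).

During arrest the controller keeps running in the
ventricular-fibrillation scenarios (with pulse pressure fed as zero), and
is pinned at base in the pentobarbital scenarios. With all gains zero the
simulation is bit-identical to one without a controller, which the test
suite asserts literally.

**Kernel and gain constants.** The construct (unit-area kernels, per-arc
gains) is prescribed; the constants are not published. The fast
parasympathetic heart-rate arc (support 1 s) and slow sympathetic arcs
(delay 2 s, support 30–40 s) follow the conventional timescales of this
controller family. The two venous-tone arcs are the package's calibrated
elements: an ABR-driven venoconstriction arc (delay 10 s, peak 170 s, end
290 s, 42 mL per unit scaled error at human scale) and a CPR-driven
relaxation arc (delay 300 s, peak 480 s, end 620 s, 169 mL/unit). They
were set — once, against the anchor-constrained reference curves — so
that the reflex-enabled arrest reproduces the observed time course: a
venous pressure climbing from its 30-s crossing value to a peak near
300 s (ABR arc fully recruited, error saturated) and relaxing toward a
plateau by 600 s (CPR arc responding to the sustained venous
hypertension). These long time constants exceed classical baroreflex
kernels and should be read as lumped stand-ins for the slower
venous-tone and volume-receptor dynamics the four-arc structure must
express to match the data. All constants live in the YAML configs and are
user-overridable.

With the human defaults the closed loop settles to a periodic orbit with
mean aortic pressure within a few mmHg of the 95-mmHg set point (the test
suite asserts ±10).

## Scenarios and the zero-flow equilibrium oracle

The four study scenarios cross volume status (euvolemia, or hypovolemia
as a 20 % blood-volume reduction applied as a proportional scaling of all
compartment volumes before stabilization) with reflex activity (on =
VF-like, off = pentobarbital-like). Determinism is exact: the integrator
is fixed-step with no random elements, so identical configurations give
bit-identical traces.

The simulator's primary quantitative oracle is analytic: with reflexes
off, valves open and external pressures zero, every compartment must
relax to

$$P_{eq} = \mathrm{MCFP} = \frac{V_{total} - \sum_i V_{0,i}}{\sum_i C_{eff,i}},
\qquad C_{eff,i} = \begin{cases} C_i & \text{passive} \\ 1/E_{arrest,i} & \text{cardiac,} \end{cases}$$

strictly increasing in total volume and decreasing in any unstressed
volume. The acceptance tests verify plateau = closed form to 0.1 mmHg for
randomized parameter sets in both volume states (horizon 1800 s, because
the slowest redistribution time constant of the default network is
~2 min and the plateau criterion is tight).

## The synthetic pig cohort

Real recordings are replaced by a generator anchored to the experimental
group summary table (`anchor_table()`): mean ± SD of CO, MAP and CVP for
the three groups at T0 = −20 s, T1 = 30 s, T2 = 300 s, T3 = 600 s. Each
group-mean curve is: constant at the baseline anchor until arrest; an
exponential transition (τ = 5 s, renormalized to hit the T1 anchor
exactly) over 0–30 s, consistent with the reported ~30-s equilibration;
and monotone cubic smoothstep segments between T1, T2 and T3 (zero slope
at the anchors, hence strictly monotone rise to the peak and fall to the
plateau, without inventing any values beyond the printed anchors). CO
drops to zero instantaneously at arrest — flow ceases at once. A
pulsatile carrier at the baseline heart rate (100 bpm; arterial
peak-to-peak 30 mmHg, so systolic−diastolic ≈ 30 mmHg around the MAP
anchor) runs before arrest purely so the 0.5 Hz filter has realistic work
to do; it is a synthetic convention, not data.

Per-animal traces add (i) one offset draw per channel, correlated across
channels (ρ = 0.8; hemodynamic variables co-vary across animals) and
scaled by the *local* interpolated SD curve, so the cohort dispersion
matches the table at every analysis time; and (ii) band-limited Gaussian
noise (2 mmHg raw SD shaped below 5 Hz). Every animal derives its own RNG
substream from the cohort seed, so cohorts are reproducible and animals
independent. Default group sizes are 7 pentobarbital animals and the 7 VF
animals split 4 euvolemic / 3 hypovolemic (14 total, the study size);
all sizes are configurable.

What passing tests on this cohort do and do not show: anchor round-trips
verify the *processing chain* (filter, extraction, statistics) exactly,
because the generator is anchor-exact by construction; they do not
validate the generator against raw experimental waveforms, whose
beat-to-beat morphology, artifacts and non-Gaussian dispersion the
generator does not attempt to emulate.

## Processing chain

`lowpass_mean()` applies the third-order Butterworth (0.5 Hz cut-off)
forward and backward — zero phase, squared magnitude response, so a 2-Hz
component is attenuated by $1/(1+(2/0.5)^6) \approx 1/4097$, which the
tests check against the closed form to 1 %. Edges use odd
(anti-symmetric) reflection padding over six filter time constants;
residual boundary transients are confined to a few time constants at the
record ends, well away from any analysis time. Re-filtering a filtered
mean signal is a no-op to < 0.1 mmHg in the interior; note that this
near-idempotence holds for signals without energy near the cut-off (the
mean curves), since forward-backward filtering is not a spectral
projection.

`extract_timepoints()` averages ±1 s around each nominal analysis time
("approximately" is in the times' definition; the window damps residual
ripple). `normalized_rmse()` divides the RMSE over the 0–600 s
post-arrest window by the reference range over that window and reports
percent; range normalization was chosen (over mean normalization) because
the < 5 % agreement convention is meaningful for range-scaled error.
Window and denominator are arguments. If traces do not cover the window
the comparison clips to the overlap and flags it.

`group_statistics()` runs the prespecified contrasts — within-group
change over T1–T3 (one-way repeated-measures ANOVA), group × time
interaction versus the pentobarbital group and over all groups (mixed
two-way ANOVA, interaction tested within subjects), the paired CVP-vs-MAP
test at 600 s, and Shapiro–Wilk normality screens — delegating the test
mathematics to `stats::aov`, `stats::t.test` and `stats::shapiro.test`
(two-sided p-values, within-subject error terms). No multiplicity
correction is applied beyond the per-contrast α = 0.05, matching the
original analysis. The type-I calibration test uses null cohorts with
*time-constant* between-animal dispersion, under which the covariance is
compound-symmetric and the ANOVA F exact; the study cohort's
anchor-tracking dispersion (SD varying over time) deliberately violates
sphericity the way real data do, and is used for effect detection, not
for calibration.

## Pig calibration

`derive_pig_config()` documents the derivation of the packaged
`model_pig.yaml`: allometric scaling of the human default to a 41.5-kg
animal (volumes and compliances by the blood-volume ratio, resistances
inversely, so pressures and time constants are preserved), pig rates
(HR 100, RR 20 /min), set points moved to the pig operating point, then a
damped fixed-point loop of short baseline simulations adjusting total
volume (→ CVP 11 mmHg), microvascular resistance (→ MAP 53 mmHg) and a
contractility scale (→ CO 3 L/min, the depressed pump function of
anesthetized piglets), with the pulse-pressure set point tracking the
measured baseline pulse pressure and the starting pressures rebalanced
each iteration so the controller warm-start sees near-zero afferent
errors. The packaged config reproduces the target baseline to ~1 %.

## Model fidelity, honestly stated

With the pig-calibrated config, the reflex-enabled arrest tracks the
VF-euvolemic reference with a mean range-normalized RMSE of **5.7 %**
over 0–600 s (CVP 3.8 %, MAP 7.6 %); disabling the reflexes degrades this
to **22.8 %** — a factor of four, reproducing the qualitative claim that
reflex activity is required for fidelity. The MAP channel cannot reach
the < 5 % convention in this model class, for a structural reason worth
stating: once the arterial pressure falls below the venous side, the
arteriolar diodes close and — with no conduit through the arrested
heart — the trapped arterial volume has no efflux path, so simulated MAP
is pinned near its crossing value (~15 mmHg). The experimental MAP
instead declines further (≈ 18 → 11 mmHg between 300 and 600 s), a
late drift attributed to ischemic loss of arterial wall tone — a
mechanism this model family deliberately omits (no ischemia, no
pharmacology; reflex inactivation is the only representation of
pentobarbital). The acceptance machinery therefore reports the measured
error as-is and additionally asserts the robust ordering property
(reflex-on error several-fold below reflex-off).

## Numerical choices

* Integrator: fixed-step explicit Euler at `dt` = 0.5 ms. The stiffest
  nodes (aortic segments) have time constants of 0.8–1.3 ms, so 1 ms
  would sit at the edge of the stability region; 0.5 ms keeps a ≥ 2.8×
  margin. A step-halving test on the three-compartment reduction, and an
  independent stiff-ODE reference solution (`deSolve::lsoda`), bound the
  discretization error below 0.1 mmHg.
* Controller tick 5 ms (200 Hz); slow arcs are decimated to 10–20 Hz with
  their kernels discretized at that rate and renormalized to unit sum, so
  steady-state gain is exactly one regardless of rate.
* Ring-buffer warm-starts: afferent windows and kernel histories are
  padded with their first observation, so a simulation started at its
  operating point has no controller transient.
* Baseline settling is checked (arterial drift over the last 20 s before
  arrest < 2 mmHg) and failure raises an error advising parameter review.
* Problem sizes in the shipped tests: single traces at 200 Hz over
  [−60, 615] s; equilibrium-oracle runs to 1800 s; cohort property checks
  at n = 50 (100 Hz) and n = 200 (time-point fast path); statistics
  calibration with 200 Monte-Carlo replicates. These sizes make the full
  suite a desk-scale computation while keeping every estimate's
  uncertainty far below its test tolerance.

## Known limitations

Linear compliances (no pressure–volume curvature, no collapse at negative
transmural pressure); no ischemic or pharmacological vascular effects; no
microcirculatory flow after arrest; atria and ventricles share one
activation shape; the reflex constants beyond the published set points,
limits and window are calibrated, not measured; and the synthetic cohort
is anchor-faithful but not waveform-faithful. Within those bounds, the
package reproduces the study's central result: zero-flow pressure is not
one number — it depends on the arrest mechanism through the autonomic
reflexes.
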