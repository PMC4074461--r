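---
title: "Methods: COP reconstruction, sway metrics, and reliability statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: COP reconstruction, sway metrics, and reliability statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(swayboard)
```

## The measurement problem

Standing balance is commonly quantified by the wander of the center of
pressure (COP) — the point of application of the resultant vertical
ground-reaction force — during quiet stance. Laboratory force platforms are
the reference instrument; consumer four-load-cell balance boards are a
cheap, portable alternative, but a board-based system is only clinically
usable if its scores are *reliable* (stable across raters and days) and
*valid* (in agreement with the platform). `swayboard` implements the full
chain: signal reconstruction, preprocessing, sway outcomes, and the
agreement statistics, plus a simulator that stands in for the human study so
every stage can be verified against known ground truth.

## COP reconstruction

A board reports four corner loads f_tl, f_tr, f_bl, f_br (top/bottom ×
left/right, toe edge up). The COP follows from a moment balance about the
board center:

$$x = \frac{W}{2}\,\frac{(f_{tr}+f_{br})-(f_{tl}+f_{bl})}{F},\qquad
  y = \frac{D}{2}\,\frac{(f_{tl}+f_{tr})-(f_{bl}+f_{br})}{F},\qquad
  F=\textstyle\sum f$$

with W = 45 cm (medio-lateral) and D = 26.5 cm (antero-posterior) by
default. Two conventions had to be fixed because board firmware specifies
neither: the **long axis is medio-lateral** (positive right; y positive
toward the toes), and the **force unit is arbitrary** — the quotient makes
the COP invariant to uniform scaling, so newtons and kg-equivalents give
identical trajectories. Both are stated in `?board_geometry`.

Division by F makes near-unloaded samples (step-on/step-off) explode.
Samples with F below 5% of the trial's median load (`min_load_fraction`,
tunable) are flagged invalid: interior ones are linearly interpolated from
valid neighbours, leading/trailing runs are dropped. A trial with no valid
sample raises an unrecoverable-signal error.

For simulation the package also needs the inverse map. Among the
one-parameter family of four-force decompositions consistent with a given
(x, y, F), `forces_from_cop()` uses bilinear corner weights
$(1\pm u)(1\pm v)/4$ with $u = x/(W/2)$, $v = y/(D/2)$ — non-negative
everywhere on the board and exactly invertible. The round-trip
reconstruction error is at machine precision (the test suite bounds it at
1e-9 cm).

## Preprocessing

Board timestamps arrive with transmission jitter, and Butterworth designs
assume uniform sampling, so the pipeline order is fixed: reconstruct →
resample → filter. `resample_uniform()` interpolates linearly onto a uniform
grid spanning the original time range (50 Hz default). Whether the original
clinical software filtered forces before or coordinates after COP
reconstruction is not documented anywhere; this package filters the COP
coordinates, and that ordering is deliberately not configurable.

`lowpass_filter()` applies a Butterworth low-pass (default 4th order, 12 Hz
at 50 Hz — the conventional board parameters) in one of two modes:

* **zero_phase** (default): forward-backward application of the same
  design. Posturography pipelines conventionally avoid phase lag; the price
  is a squared magnitude response, so the amplitude ratio at the cut-off is
  1/2 rather than 1/√2.
* **causal**: a literal single forward pass (amplitude 1/√2 at the
  cut-off), for conformance with a plain "4th-order filter" reading.

Edge handling: in zero-phase mode the signal is padded on each side by odd
reflection about its endpoints (3 × order samples) before filtering and
trimmed afterwards; both modes also subtract the first sample before
filtering and add it back, i.e. start the filter in steady state at the
initial value. Together these make the DC gain exactly 1 in floating point
and keep startup transients out of 10 s one-leg trials; trajectories
shorter than the 3 × order warm-up are rejected rather than silently
filtered.

## Sway metrics and aggregation

Path length is the polyline length
$PL=\sum_i\sqrt{\Delta x_i^2+\Delta y_i^2}$ (cm); average velocity is
$VA = PL/T$ with $T=(N-1)/f_s$ the elapsed recorded duration (cm/s), so
$VA \cdot T \equiv PL$ by construction. Published board tables are *not*
internally consistent with this identity (their printed VA runs ≈6% above
PL/T across tasks; trimming or an alternative denominator would explain it,
but the cause is unrecoverable), so the clean kinematic definition is
adopted and no numeric check ties VA to PL through published values. No
start/end trimming is applied by default, since the measurement protocol
never mentions any.

The protocol value for one (subject, task, session) condition is the
arithmetic mean of the three repetitions (`summarize_trials()`); trials that
fail preprocessing are dropped from the mean with a logged, machine-readable
reason rather than failing the condition — mirroring clinical practice with
unusable trials.

## Reliability statistics

For each session pair (inter-rater A1–B, intra-rater A1–A2, device validity
A1–A3) and each task × metric cell, the ratings form an n-subjects × 2
matrix analyzed under the two-way crossed ANOVA model.

**ICC.** Published board studies rarely state which ICC form they used.
This package defaults to **two-way, absolute agreement, single measures —
ICC(2,1)** — because absolute agreement is the question actually asked of
raters and devices, and it is the form consistent with SEM and Bland-Altman,
which both penalize systematic offsets. The consistency form ICC(3,1) is
computed and reported alongside (conventional for intra-rater
repeatability); both definitions and single/average units are selectable in
`icc_twoway()`. Confidence intervals use the F-distribution constructions of
the McGraw–Wong conventions, with Satterthwaite degrees of freedom for the
agreement form; average-measure bounds are the Spearman–Brown transform of
the single-measure bounds (exact for the consistency form). The
point-estimate algebra is cross-checked in the tests against brute-force
ANOVA mean squares from `aov()`, and the CI construction is validated by
coverage simulation (95% nominal, checked at n = 20, k = 2 over 500
replicate studies).

Degenerate inputs: a matrix with zero total variance has no defined ICC and
raises an explicit error; identical columns with subject variance give
exactly 1 with a collapsed CI.

**Banding.** ICC ≥ 0.80 "high", 0.60–0.79 "moderate", below 0.60 "low".
The conventional phrasing leaves [0.79, 0.80) ambiguous; band edges here are
half-open at the lower bound (0.80 is high, 0.60 moderate).

**SEM.** $SEM = SD\sqrt{1-ICC}\cdot\sqrt{n_{repeats}}$. The SD entering the
formula is the pooled SD of the two compared conditions,
$\sqrt{(SD_a^2+SD_b^2)/2}$ — published SEM columns cannot be reproduced from
any printed SD, so the choice is documented here rather than inferred. The
repeated-measures multiplier is exposed but defaults to 1: the analyzed
values are already means of three trials, and the correction should not be
applied silently. ICC estimates slightly outside [0, 1] are clamped with a
warning (negative estimates occur legitimately in small samples).

**Differences and agreement.** The difference column is b − a (second
condition minus first); the significance marks are `*` p < 0.05 and `**`
p < 0.01 from a two-sided paired t-test — published tables leave their
asterisks undefined, so this is a documented assumption, not a reproduction.
Bland-Altman limits of agreement are bias ± 1.96·SD of the differences (the
normal 95% multiplier; no small-sample t correction), with the (mean,
difference) pairs returned for plotting via `plot()`.

## The simulator: what it emulates, and what it does not

**Trajectory level.** Quiet-stance COP wander is generated as a discrete
Ornstein-Uhlenbeck process per axis,
$x_{t+1} = x_t - \theta x_t \Delta t + \sigma\sqrt{\Delta t}\,\varepsilon_t$
— mean-reverting, stationary, concentrated at low frequencies, and visually
plausible, unlike white noise. Defaults θ = 1 s⁻¹, σ = 0.4 cm·s^(−1/2)
give stationary sway of a few millimetres and raw path lengths of the order
of tens of cm over 10–30 s. When a target path length is set, the
trajectory is rescaled about its mean — path length is homogeneous of
degree 1 under such scaling, so the calibration is exact. When the study
generator materializes raw recordings it calibrates against the *filtered*
path length; the filter is linear with unit DC gain, so the scaling
commutes with it and the raw-route/table-route agreement is exact up to
floating point (the test suite enforces a conservative 2% bound).

**Study level.** Trial values follow the variance-components model
$y_{ijk} = \mu_i + r_j + e_{ijk}$: subject true scores
$\mu_i \sim N(\mu_{task}, \sigma_s^2)$, session (rater/day) effects
$r_j \sim N(0, \sigma_r^2)$ drawn per (task, session), trial error
$e_{ijk} \sim N(0, \sigma_e^2)$, floored at zero. The platform session
instead applies a fixed affine device response $b + s\mu_i$ (default
s = 0.9, b = 0: reference platforms read systematically lower on this class
of board comparison). The implied per-trial board-board agreement ICC is
$\sigma_s^2/(\sigma_s^2+\sigma_r^2+\sigma_e^2)$. Defaults — 20 subjects,
four tasks with mean PL 36/40/44/81 cm (30/30/10/10 s), three trials,
sessions A1/B/A2/A3, σ_s = 7, σ_r = 1.5, σ_e = 3 cm — put simulated scores
and ICCs in the range reported for healthy adults (PL roughly 35–85 cm,
ICC ≈ 0.7–0.92) without claiming to reproduce any particular published
table. With these defaults the zero-floor truncation probability is
negligible (far below 1e-6), so it introduces no measurable bias; recovery
tests run in regimes where it is irrelevant.

What the generator does **not** emulate: fatigue and learning across
sessions, non-normal and heteroscedastic subject distributions, spectral
differences between tasks, sensor quantization and drift, or any
biomechanical (inverted-pendulum) structure. Passing recovery tests
therefore show the *statistics* are correct under the stated model, not
that a physical board meets any reliability level.

## Problem sizes and numerical checks

The validation suite uses: ICC-vs-oracle equivalence on random small-integer
matrices up to 8 × 4 (tolerance 1e-10); estimator recovery over 200
replicate two-session studies at n = 500 with true ICC 0.85 (mean within
±0.02); CI coverage over 500 studies at n = 20 (95% ± 3 points);
Bland-Altman LOA coverage at n = 10⁴ normal differences (95% ± 1 point);
filter gain checks at the cut-off against the analytic Butterworth
magnitude (±0.01); a 1001-point circle for path length (0.1%); and
machine-precision round-trips for COP ↔ forces. These sizes make the whole
suite run in seconds while leaving Monte-Carlo noise well inside each
tolerance.

## Known limitations

* Only PL and VA are computed — no sway area, RMS amplitude, or
  frequency-domain outcomes.
* The ICC confidence intervals are the classical F-based approximations;
  exact coverage degrades for very small n or ICC near the boundaries.
* The ~6% VA/PL inconsistency and the unreproducible SEM column observed in
  published board tables are documented, deliberately unresolved
  discrepancies: this package's definitions are self-consistent instead.
* No live acquisition: recordings enter as CSV; Bluetooth/HID capture and
  per-cell calibration are out of scope.
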