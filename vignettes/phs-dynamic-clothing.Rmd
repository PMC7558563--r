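---
title: "Predicted Heat Strain with dynamic clothing corrections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicted Heat Strain with dynamic clothing corrections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phsdyn)
```

## The model

The Predicted Heat Strain (PHS) model, specified by ISO 7933, is a rational
heat-balance model of a clothed, working person. Each minute it balances the
metabolic rate against respiratory heat losses, dry heat exchange
(convection and radiation through the clothing) and evaporation of sweat,
and converts the residual storage into a rise of core and rectal
temperature. Sweating is driven by the required evaporation, filtered with a
10-minute time constant and capped by the maximum sweat rate; evaporation is
capped by the maximum skin wettedness (0.85 for unacclimatized subjects) and
by the vapour-pressure gradient across the clothing. Two safety limits stop
an exposure: a rectal temperature of 38 °C (`dlim_tre`) and a cumulative
water loss of 5 % of body mass (`dlim_loss95`; 7.5 % for the median-subject
limit, 3 % when drinking is restricted). `phs_simulate()` implements the
standard's published program structure: initial rectal and core temperature
36.8 °C, skin 34.1 °C, zero initial sweat rate, a 3-minute skin-temperature
time constant, and the clothed/nude skin-temperature regressions
interpolated between 0.2 and 0.6 clo.

Clothing enters through four quantities: the static total insulation
$I_{tot} = I_{cl} + I_a/f_{cl}$ (with boundary-air-layer insulation
$I_a = 0.716$ clo and clothing area factor $f_{cl} = 1 + 0.3\,I_{cl}$), its
dynamic counterpart $I_{tot,dyn}$, the dynamic boundary layer $I_{a,dyn}$,
and the dynamic total evaporative resistance $R_{t,dyn}$. Wind and body
movement pump air through clothing and erode its insulation; the package
implements three published correction algorithms behind one interface,
`dynamic_clothing()`:

* **ISO 7933** — exponential regressions in the relative air velocity
  $v_{ar}$ and walking speed $v_w$ for normal clothing, applied to every
  category; below 0.6 clo the total factor is interpolated between the
  boundary-layer and the clothing factor in proportion to $I_{cl}/0.6$.
* **ISO 9920** — per-category dispatch: revised normal-clothing regressions
  referenced to still air at $v_{ar} = 0.15$ m/s; a cold-weather formula
  (above 1.4 clo) that also involves the shell's air permeability
  $p_r^{0.144}$; and, below 0.6 clo, an interpolation between the dynamic
  boundary layer and the corrected ("dressed") total insulation.
* **Lu** — a single regression correcting the total insulation of light
  clothing, valid for $0.15 \le v_{ar} \le 5.2$ m/s.

The clothing-only dynamic insulation is recovered as
$I_{cl,dyn} = I_{tot,dyn} - I_{a,dyn}/f_{cl}$, mirroring the structure of
$I_{tot}$. For the moisture path, ISO 7933 performs a double correction —
the permeability index is scaled by
$Corr_E = 2.6\,C^2 - 6.5\,C + 4.9$ of the total factor $C$ (capped at 0.9)
and the resistance recovered through the Lewis relation
$R_{t,dyn} = I_{tot,dyn}/(i_{mt,dyn} \cdot 16.7)$ with $I_{tot,dyn}$ in SI
units — while ISO 9920 multiplies the static total evaporative resistance
by the single factor $1.2\,C^2 - 0.5\,C + 0.3$. All insulation algebra is
done in clo; SI conversion (1 clo = 0.155 m²·K/W) happens only at the Lewis
relation and inside the heat balance.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `icl` | clo | — | basic clothing insulation; also classifies the ensemble (LC < 0.6 ≤ NC ≤ 1.4 < SC) |
| `rt_static` | m²·kPa/W | — | static total evaporative resistance, the ISO 9920 correction's input |
| `imt` | — | — | static moisture permeability index, the ISO 7933 correction's input |
| `pr` | L/m²·s | 1 | air permeability of cold-weather shells; 1 makes $p_r^{0.144}=1$, a deliberately conservative tight-shell default when unmeasured |
| `met` | W/m² | — | metabolic rate; also drives the estimated walking speed $0.0052\,(Met-58)$, capped at 0.7 m/s |
| `vw_measured` | m/s | `NULL` | measured walking speed; when absent the estimate above is used and the relative velocity stays at the air velocity |
| `duration` | min | 70 | simulation horizon; duration limits not reached are reported as the horizon |
| subject | — | 80 kg, 1.78 m, unacclimatized, drinking | chamber-study convention; acclimatization raises the sweat cap by 25 % and wettedness to 1 |

Category boundaries sit exactly at 0.6 and 1.4 clo and are assigned to NC;
the packaged ensembles span 0.48–2.01 clo, so only the conventions matter,
not the tie itself.

## Kinematics conventions

The correction formulas take the relative air velocity and the walking
speed separately. Three conventions are built in:

* *Estimated walking* (`use_measured_vw = FALSE`): $v_w$ from the metabolic
  rate, $v_{ar} = v_a$ — walking that is undefined in direction does not add
  to the air stream.
* *Measured walking, max rule* (`use_measured_vw = TRUE, vw_mode = "max"`,
  the default): omni-directional movement, $v_{ar} = \max(v_a, v_w)$,
  capped at 3 m/s.
* *Measured walking, corrections only* (`vw_mode = "air"`): the measured
  speed feeds the clothing formulas but $v_{ar}$ stays at $v_a$.

The default follows the omni-directional convention of the PHS program.
Which convention a given chamber study used is often unreported, and for
treadmill work the physically faithful relative velocity is genuinely
ambiguous (a walker on a treadmill does not move through the room air);
the switch exists so both readings can be compared. The comparison grids
(`comparison_grid()`) treat their tabulated "air speed" directly as
$v_{ar}$, since the regressions are expressed in that variable.

Inputs outside an algorithm's stated validity range — notably a measured
1.25 m/s against ISO 9920's 1.2 m/s walking-speed bound, and the 0.33 m/s
chamber air velocity against the cold-weather formula's 0.4 m/s floor — are
clamped to the nearest bound, flagged in the `clamped` field and logged.
Raw regression values above 1 (possible for the ISO 7933 factors near still
air and for permeable shells) are capped at 1 when the dynamic state is
assembled: movement never adds insulation.

## Numerical choices

* Clothing-surface temperature and the core-temperature/weighting pair are
  solved by damped fixed-point iteration to 0.001 °C (at most 30 steps),
  matching the published program.
* The dynamic permeability index is capped at 0.9.
* Duration limits are whole minutes at the first crossing; identical inputs
  give bit-identical trajectories (the model is deterministic).
* Degenerate inputs fail early: saturated air, sub-resting metabolic rate,
  Lu outside light clothing, a missing `pr` for the cold-weather formula.
  A non-finite state aborts with the offending minute.

## The scenario registry and run matrix

`table5_scenarios()` packages nine treadmill chamber exposures — one light
(0.48 clo), six normal (0.63–1.11 clo at 20–40 °C) and two cold-weather
(2.01 clo at 30/40 °C) conditions, all at 0.33 m/s air velocity, 1.25 m/s
treadmill speed, 70 min — with unacclimatized male subjects (80 kg/1.78 m;
77 kg/1.76 m for the light ensemble). Mean radiant temperature is set equal
to air temperature (climate chamber, no radiant source), posture standing,
external work zero. `phs_run_matrix()` crosses the registry with the
applicable algorithms (Lu only below 0.6 clo) and both walking-speed input
modes: 38 rows. Within this horizon dehydration never limits the exposure
(the sweat-rate cap keeps 70-min losses under about 1 kg, far from the 4-kg
5 % limit), so the maximum allowable time is governed by the rectal limit.

## Evaluation and the synthetic-observation generator

`rmsd_bias()` compares an observed with a predicted series after dropping a
10-minute burn-in (the initial-state transient), with the sign convention
measured − predicted. A fit is acceptable when the rmsd is below the
standard deviation of the observed data; by default that threshold is the
SD of the observed series after burn-in, and a replicate-subject
measurement SD can be supplied instead.

Real observed series are cohort means of chamber measurements, with
reported between-subject SDs of roughly 0.19–0.41 °C for rectal
temperature. `synth_observed()` emulates that structure as a model
trajectory plus stationary AR(1) Gaussian noise with marginal SD `sd`,
lag-1 autocorrelation 0.8 by default (minute-wise physiological series are
smooth), an optional systematic offset, and isotonic clipping for
cumulative water loss. What it does *not* emulate: inter-subject
variability in the underlying physiology, drift in metabolic rate, or any
model-structure error — so a passing evaluation on synthetic data shows the
metric plumbing and its calibration are sound, not that the model is
accurate for real cohorts. With noise at the largest realistic SD
(0.41 °C) on a 70-minute trajectory, the acceptance rule recovers the
generating model in about 95 % of 200 replicates, and with iid noise the
rmsd estimates the noise SD within 3 % at 10⁴ samples; both figures are
recomputed in the test suite at exactly those problem sizes.

## Known limitations

* The cold-weather ISO 9920 correction needs the shell's air permeability;
  when it is unreported the conservative `pr = 1` default makes those
  absolute results indicative only (their orderings and monotonicities are
  what the tests assert).
* Whether a "measured walking speed" study also raised the relative air
  velocity or only fed the clothing formulas is frequently unknowable; the
  two conventions can differ by several minutes in a duration limit whose
  trajectory crosses 38 °C shallowly.
* Only the unacclimatized/acclimatized branches of the standard are
  implemented; no posture-specific area factors, no wind-direction-resolved
  corrections, and no multi-node physiology beyond the PHS two-compartment
  structure.
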