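---
title: "Simulating script-driven perfusion culture: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating script-driven perfusion culture: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioreactr)
```

`bioreactr` re-creates, entirely in software, an automated perfusion
bioreactor for adherent cell culture: a syringe pump, a flow selector, six
culture wells, a fresh-media reservoir, a waste line carrying a non-contact
pH sensor, and the scripting language that drives them. This vignette is
the package's account of the models underneath — what is physically
grounded, what is a modelling choice, and where the boundaries of the
simulation lie.

## The protocol language

Protocols are plain text, one command per line, nine opcodes:

| Command | Value        | Effect |
|---------|--------------|--------|
| `Loop`  | count        | arm the repeat counter |
| `Vol`   | mL           | set the syringe transfer volume |
| `Goto`  | line number  | jump while the repeat counter is positive |
| `Wait`  | hh:mm:ss     | delay |
| `Dir`   | `F` or `B`   | pump direction (Forward = dispense, Backward = withdraw) |
| `Ch`    | channel id   | select the flow channel |
| `Stir`  | channel id   | toggle that well's stirrer |
| `Start` | —            | run the pump with the current Vol/Dir/Ch registers |
| `Msgbox`| text         | log a message |

Two semantics were genuinely open and are resolved here as package
conventions:

* **Loop/Goto pairing.** The command table alone does not say whether
  `Loop` repeats the whole script or a block, nor how `Goto` interacts with
  it. The convention chosen is the minimal one that makes "repeat a
  media-refresh cycle *k* times" expressible: `Loop n` arms a single counter
  with *n*−1 remaining passes; a `Goto` executed with a positive counter
  decrements it and jumps, and falls through once the counter is drained.
  The block between `Loop`'s successor and the `Goto` therefore runs exactly
  *n* times. There is one loop register — nesting is unsupported, and the
  validator warns when a second `Loop` arms before the previous counter can
  have drained.
* **`Msgbox` never blocks.** On interactive control software a message box
  waits for the operator; a headless protocol runner cannot. Messages are
  logged to the event trace and execution continues, which keeps unattended
  48-h protocols runnable.

Comments (`#`) and blank lines are accepted for maintainable protocol
files even though the original language has no comment syntax; the
formatter drops them, and `parse_script(format_script(s))` reproduces `s`'s
commands exactly (a property the suite checks on randomly generated
scripts). `Stir` is a toggle with all stirrers initially off. A `Wait`
advances the simulated clock instantly; interpreting it as wall-clock time
is a backend concern, not the interpreter's. A `max_steps` budget
(default 100,000 instructions) turns any runaway jump cycle into an error
rather than a hang, so every execution provably terminates one way or the
other.

The interpreter is additionally pinned, trace-for-trace, to an independent
brute-force reference evaluator (a plain line walk with an explicit jump
table, kept in the test helpers) over 1,000 randomly generated scripts per
suite run.

## Hardware models

**Syringe pump.** A transfer of $v$ mL at rate $\rho$ mL/min takes
$60 v/\rho$ seconds. The default syringe capacity is 10 mL (the standard
disposable syringe the physical pump houses); `steps_per_ml` (default 800,
typical of a NEMA17 + leadscrew drive) converts volumes to motor steps and
is configuration, not measurement — the real drive geometry is not
published. The default flow rate of 2 mL/min is likewise a configured
value. The calibration procedure is gravimetric: run at several set rates
for one minute each, weigh the dispensed water (1.000 g/mL), and fit
dispensed mass on set rate by ordinary least squares (`stats::lm`); an
accurate pump gives slope ≈ 1 g·min/mL and intercept ≈ 0.

**Selector.** Modelled as a single exclusive position: selecting a channel
closes all others. The physical device uses three servos whose internal
plumbing is not described, so no per-servo kinematics are modelled; the
channel table records servo index/angle placeholders only.

**Direction convention.** `B` withdraws from the selected channel into the
syringe, `F` dispenses from the syringe into it, matching a pump that
"fills or drains". Withdrawing from the waste line or dispensing into the
fresh-media reservoir is rejected; so are syringe overfill, dispensing more
than the syringe holds, and overdrawing a well. Across any sequence of
transfers the total liquid volume (wells + syringe + reservoir + waste) is
conserved; the suite drives 10,000 random pump operations against that
ledger.

## Colorimetric pH sensing

Phenol red shifts yellow → pink over pH ≈ 6.8–8.2. Rising pH deepens the
red form, which absorbs green light, so green intensity transmitted through
media in the tubing falls linearly with pH over that window. The shipped
default calibration is the reference line for DMEM,

$$G = -57.7\,\mathrm{pH} + 1032,$$

valid over pH 6.90–7.83 (the span of the calibration levels, n = 3
replicates per level). Intensity units are treated as arbitrary linear
counts since the detector's ADC depth is unspecified; an optional 10-bit
quantisation mode exists, off by default.

The forward sensor model used in simulation adds Gaussian noise to the
counts, default sd 2. The published calibration reports replicate means
but no dispersion, so the noise level is a package choice: 2 counts ≈
0.035 pH units of read noise, small against the ±0.2 pH band of interest
but large enough that calibration refits exercise real regression error.
Readings whose implied pH falls more than 0.1 outside the calibrated range
are *flagged*, never errors: the sensor sits passively on the waste line,
and a bad reading must not abort a culture.

## The culture digital twin

No growth or acidification kinetics are published for this system — only
the emergent behaviour (pH held at 7.4 ± 0.2 under 2 mL/6 h refresh;
enhanced proliferation versus an unrefreshed control). The twin is
therefore the package's own model, deliberately the simplest mechanism that
produces that behaviour:

$$\frac{dN}{dt} = r\,f(\mathrm{pH})\,N\left(1 - \frac{N}{K}\right),
\qquad \frac{dA}{dt} = qN, \qquad
\mathrm{pH} = \mathrm{pH}_{\mathrm{fresh}} - \frac{A}{\beta V}$$

with $f = 1$ within `ph_tolerance` of `ph_optimum`, declining linearly to 0
at a deviation of 1 pH unit. A partial media exchange of $v$ mL from a
well-mixed volume $V$ scales $A$ by $(V-v)/V$ and adds acid-free fresh
media; adherent cells are never removed by an exchange. The linear buffer
(pH deficit proportional to acid per mL) replaces full bicarbonate
equilibria — adequate over the narrow 6.9–7.8 window of interest and
analytically invertible; $\beta$ is in arbitrary acid-equivalent units.

Defaults, with units and rationale:

| parameter | default | meaning |
|---|---|---|
| `r_per_h` | 0.035 /h | fibroblast doubling ≈ 20 h at optimum |
| `K_cells` | 1.2×10⁶ | confluent 6-well monolayer |
| `q` | 6×10⁻⁷ /cell/h | acid production (calibrated, see below) |
| `beta` | 3.0 eq·mL⁻¹·pH⁻¹ | linear buffer capacity (arbitrary units) |
| `fresh_ph` | 7.5 | bicarbonate-buffered DMEM under incubator CO₂ |
| `ph_optimum`, `ph_tolerance` | 7.4, 0.2 | the fibroblast culture band |

These are **calibrated to qualitative outcomes, not fitted to data**: with
the standard initial conditions (7×10⁴ cells, 5 mL) the defaults make a
2 mL/6 h refresh hold all logged pH within 7.4 ± 0.2 over 48 h with mean
near 7.4, while an unrefreshed well drifts below 7.2 within 48–72 h and its
growth stalls. `q` and `fresh_ph` were chosen together, once, by direct
simulation of those two scenarios before the test suite was written. A
fresh-media pH as high as 7.6 was rejected: the first refresh cycle
disposes media that is still nearly fresh, so its logged pH necessarily
sits close to `fresh_ph`, and with sensor noise a 7.6 starting point places
early readings on the band edge. 7.5 keeps the whole noise-free logged
trajectory in ≈ [7.35, 7.48], comfortably inside the band from both sides,
and is physically sensible for CO₂-equilibrated media.

The twin is deterministic; all stochasticity lives in the sensor noise, so
a run is reproducible from its seed alone and pH/band statistics vary only
through the sensor model.

**What the twin does not emulate.** No CO₂/bicarbonate chemistry, oxygen
or nutrient limitation (acid load is the only feedback), lactate-specific
metabolism, contamination dynamics, well-to-well variability, evaporation,
or cell detachment. Passing tests therefore show the *control software*
behaves correctly against a plausible culture, not that these kinetics
describe any particular cell line quantitatively.

## Numerical choices

* **Integration**: explicit Euler, sub-stepped at ≤ 0.1 h. The dynamics are
  smooth and slow on that scale; the suite checks that halving the step
  changes the 48-h pH endpoint by far less than 0.005 pH.
* **Sampling grid**: trajectory times are rounded to 10⁻⁹ h so the sampling
  grid and exchange-event times collide exactly rather than by floating
  tolerance; exchange rows record the post-exchange state.
* **Parameter recovery**: `fit_culture_kinetics()` refits (r, q) by
  Nelder–Mead least squares on log cell count + pH, started away from the
  truth (×1.35, ×0.7); on a noise-free 48-h trajectory it returns the
  generating values within 1%, a self-consistency check that the trajectory
  actually identifies both rates.
* **Degenerate inputs**: single-level calibration designs and out-of-window
  pH levels are errors; a fully drained well (volume 0) is legal and inert;
  zero-volume exchanges are identities; drained loop counters make `Goto`
  fall through rather than trap.
* **Problem sizes** in the suite — 1,000 random scripts for the oracle
  equivalence, 10,000 random pump operations for the conservation ledger,
  48–72 h twin horizons at 0.1 h resolution — run in well under two minutes
  and were chosen as the smallest sizes at which the properties are
  convincingly exercised.

## The refresh controller

`build_refresh_script()` emits, per well per cycle: drain (`Ch well / Dir B
/ Vol v / Start`), dispose to waste through the sensor line, draw fresh,
refill — then one `Wait` per cycle, the whole body wrapped in `Loop/Goto`.
Wells are serviced in fixed ascending order (the original ordering is
unstated). Because sensing happens on the disposal transfer, each pH
reading reflects the well as it was at the start of that refresh — the log
lags the well state by one transfer, by construction. The simulated clock
advances during `Wait`s and pump transfers only (event-driven time);
register commands are instantaneous, and a 48-h protocol therefore
simulates 51.2 h once the 192 one-minute transfers are counted.

The controller is open loop: refresh timing comes from the script, never
from the pH readings. That matches the physical system; closed-loop
pH-triggered refresh would be future work.

## Known limitations

* The interpreter has no variables, arithmetic or conditionals — the
  command set is deliberately closed.
* One loop register; protocols needing nested repetition must be unrolled.
* The pump model has no acceleration profile, backlash or dead volume; the
  selector has no per-servo plumbing.
* The sensor model is a scalar green channel; no RGB imaging or LED drive
  electronics.
* Twin kinetics are qualitative (above); absolute cell counts from the twin
  should not be read as predictions.
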