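---
title: "Modelling FRC metabolism as a qualitative network: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling FRC metabolism as a qualitative network: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qnflux)
```

## The formalism

`qnflux` implements qualitative networks (QNs), the executable-model
formalism popularised by the BioModelAnalyzer. A QN is a finite, discrete
dynamical system:

* each node $i$ holds an integer level $v_i \in [lo_i, hi_i]$; most nodes
  use the range $[0,4]$, on which 2 is read as normal
  activity/concentration, 0–1 as low and 3–4 as high;
* each node has a *target function* $T_i$, an arithmetic expression over
  node levels (constants, `+ - * /`, `ceil`, `floor`, and n-ary `avg`,
  `min`, `max`);
* the update is synchronous and bounded: with all targets evaluated on the
  current state,
  $$v_i' = \mathrm{clamp}_{[lo_i,hi_i]}\bigl(v_i + \mathrm{sign}(T_i(v) - v_i)\bigr).$$

So a node drifts one level per step toward the value of its target
function, regardless of how far away that value is. The state space is
finite, hence every trajectory ends in a fixed point or a cycle;
`simulate_qn()` detects the terminal by exact state hashing with
first-occurrence indices, and `find_attractors()` enumerates the entire
successor map on small models, which is used throughout the test suite as
the ground-truth oracle (exactness was preferred over cycle-finding
cleverness — the models involved are tiny).

Numerical choices, stated once:

* the target comparison uses the raw real value of the expression with
  strict inequalities; $T_i$ is never rounded before comparison, which
  keeps half-integer targets from behaving asymmetrically;
* clamping is applied *after* the $\pm 1$ move, never to the target value,
  so the one-step-motion contract stays primitive;
* `avg()` of an empty operand list is 0, and a node with no incoming edges
  defaults to holding its value — environment and drug nodes therefore
  stay constant unless a protocol or condition forces them;
* the default target of a wired node is
  `avg(activators) - avg(inhibitors)`;
* no asynchronous or stochastic update scheme is offered: the semantics
  modelled here are synchronous by construction.

## The reference metabolic network

`frc_reference_model()` encodes fibroblastic reticular cell (FRC) central
carbon metabolism as 21 nodes: lactate/proton import, glycolysis, the
pyruvate–acetyl-CoA junction with an acetylcarnitine shunt, TCA flux,
NADH, the electron transport chain (ETC) with proton-gradient
back-pressure, ATP synthase, an uncoupling node, an OCR readout on
$[0,10]$, a $[0,100]$ assay clock, and three 0/1 drug switches. The
topology and every target function are a literature-based reconstruction —
the formalism fixes only their grammar — and the model ships as readable
documents (`inst/extdata/models/frc_metabolism.qn` and an equivalent
BMA-dialect JSON), so an externally supplied model file can be loaded with
`read_bma_model()` and run through the identical protocol.

The mechanistically load-bearing choices:

* **Proton-coupled lactate import.** MCT1 is induced by extracellular
  lactate and gates import (`Int_Lactate = avg(MCT1, Ext_Lactate)`).
  Intracellular protons `H_in` (high level = low pH; the scale is
  concentration, not pH, to avoid inverted-axis confusion) follow the
  *extracellular proton load*, not the lactate flux: the co-transported
  proton only acidifies the cytosol when the outside is acidic. Given that
  conditions are encoded purely as clamps on `Ext_Lactate`/`Ext_Protons`,
  any target for `H_in` must map (2,2), (4,4), (4,2), (2,4) to
  2, 4, 2, 4 respectively; the minimal such map is `H_in <- Ext_Protons`,
  and that is what the model uses.
* **Acid inhibition.** `Glycolysis = 4 - H_in` and
  `TCA_flux = min(AcetylCoA, 5 - H_in, 2)`. The constant 2 is the
  ADP-limited normal flux: extra substrate does not push basal respiration
  above normal, it spills over into the shunt
  (`Acetylcarnitine = AcetylCoA - TCA_flux + 2`). This is what makes
  sodium lactate OCR-neutral while still accumulating acetylcarnitine.
* **Respiratory control.** `ProtonGradient = 2*ETC + 2 - 2*ATP_Synthase -
  3*Uncoupling` and `ETC = min(NADH + Uncoupling, 5 - ProtonGradient +
  Uncoupling) * (1 - RotAA)`. The coefficients were chosen so that the
  coupled pair has integer fixed points in each assay phase (basal
  ETC 2 / gradient 2; post-oligomycin ETC 1 / gradient 4) rather than the
  period-4 orbit that a unit-gain feedback produces. `OCR =
  ceil(5 * ETC / 2)` scales chain activity to the 0–10 readout; the `ceil`
  keeps the OCR target integral for odd ETC levels, so settled basal OCR
  is a genuine fixed level, which the condition comparisons then compare
  *exactly*.
* **Drugs are switches, not dynamics.** `Oligomycin`, `FCCP`, `RotAA` are
  0/1 nodes with no incoming edges, set only by the protocol; oligomycin
  forces ATP synthase off (`2 * (1 - Oligomycin)`), FCCP drives membrane
  proton permeability to its maximum (`Uncoupling = 4 * FCCP`), and
  rotenone + antimycin A gate the whole chain to zero.
* **No Hif1α node.** The transcription-factor arm is deliberately absent:
  the modelled effect runs through intracellular pH, not Hif1α signalling.

## Conditions and the stress test

Conditions are clamps on the two environment nodes
(`frc_condition()`): control (2,2), lactic acid (4,4), sodium lactate
(4,2) — the salt delivers lactate at neutral pH — and a protons-only
condition (2,4). The baseline state puts every interior node at its range
midpoint (level 2 on the default scale, OCR at 5) and the model is
*pre-equilibrated* to a fixed point under the clamps, with the counter
held at 0, before the assay starts: basal OCR is then a settled property
of the treatment, mirroring the baseline reads of a real extracellular
flux assay. If the clamped dynamics cycled instead of settling this would
be an error, not a silent average; on this model all four conditions
settle within ~10 steps.

`run_stress_test()` advances the counter one unit (one nominal minute) per
step from 0 to 100 and forces each drug switch when the counter reaches
its event time; injections are irreversible within a run, as in a sealed
assay plate. The default timings 20/50/80 are the package's own choice of
a standard three-injection schedule on a ~100-minute assay; they are fully
configurable (`stress_protocol()`, `read_protocol()`), and the prediction
verdicts are invariant to shifting all events (tested at +5).

`compute_metrics()` uses a settling lag $L$ (default 5 counter units,
excluded after each injection, mirroring mix/wait cycles and giving the
discrete dynamics time to propagate): basal is the mean OCR over
$[L, t_{oligo})$, the post-oligomycin plateau the mean over
$[t_{oligo}+L, t_{FCCP})$, maximal the maximum over
$[t_{FCCP}, t_{rot})$, non-mitochondrial the mean over
$[t_{rot}+L, 100]$; ATP-linked = basal − plateau and spare = maximal −
basal, exactly. The prediction verdicts in `compare_conditions()` do not
use the window means: they compare the *settled integer* basal OCR levels,
because in a deterministic integer-valued model the honest comparison is
exact equality/inequality, not a tolerance on an average.

The three directional predictions the model reproduces, each an exact
integer comparison of settled basal OCR: lactic acid lowers basal OCR
below control (5 → 3 on the shipped model); intracellular protons alone
reproduce the drop (5 → 3); sodium lactate leaves basal OCR exactly at
control. A counterfactual clamp (`clamp = c(H_in = 2)` under lactic acid)
restores the control value, demonstrating that the modelled effect flows
entirely through intracellular acidification.

## Synthetic data

`make_fixture()` generates small networks with analytically known
behaviour — a constant-driven chain, a mutual-inhibition toggle, a relay,
a negative-feedback oscillator, and seeded sparse random networks whose
ranges are constrained to keep state spaces below $10^5$ so the exhaustive
oracle always applies. Fixtures are self-certifying: each `expected` block
is re-derived at test time by `find_attractors()` and by an independent
single-state recursive interpreter kept in the test helpers. Two fixtures
deserve a note: with pure default targets, "A activates B, B inhibits A"
*converges* (to (0,0)) rather than oscillating, and a linear toggle
(`4 - other`) has the whole anti-diagonal as fixed points; both fixtures
therefore use the steeper explicit targets `4 - 2*other`, which give a
genuine 5-cycle and exactly the two saturated toggle states plus one
symmetric period-2 cycle — all verified by enumeration.

`make_synthetic_trace()` builds piecewise-constant OCR traces at four
phase levels, adds optional Gaussian noise, then rounds and clamps to
integer levels, because the QN world is integer-valued; continuous values
exist only inside this module. Noiseless traces are recovered exactly by
`compute_metrics()`; under noise the basal estimate is unbiased (checked
at 50 replicates, noise SD up to 0.5). What the synthetic traces do *not*
emulate: injection-port artefacts, well-to-well variance, drift, and
protein normalisation of real instrument exports — so passing these tests
says the metric arithmetic is right, not that the package understands real
Seahorse files.

## Problem sizes and limitations

All simulations here are desk-scale by design: the reference model settles
in ~10 steps, a stress test is 100 steps over 21 nodes, and the oracle
tests enumerate random networks of 2–5 nodes (state spaces of 25 to a few
thousand; the enumeration limit defaults to $2\times 10^6$ states and
refuses larger models explicitly). The model is qualitative throughout: it
makes no quantitative kinetic claims, OCR levels are unitless ranks, and
the magnitude of the lactic-acid drop (2 levels on a 0–10 scale) is a
property of this reconstruction, not a calibrated prediction. ECAR, redox
balance, and gene-expression consequences of FRC activation are outside
the executable model.
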