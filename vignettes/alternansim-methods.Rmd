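---
title: "Methods: alternans mapping and border-zone fiber simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alternans mapping and border-zone fiber simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(alternansim)
```

## Scope

`alternansim` implements two connected workflows around cardiac alternans —
the beat-to-beat alternation of calcium transient amplitude and action
potential duration (APD) that precedes ventricular fibrillation:

1. an **optical-mapping analysis pipeline** that quantifies per-pixel
   calcium (or APD) alternans from dual-channel fluorescence movies,
   together with a **synthetic movie generator** that produces such movies
   with known ground truth, and
2. a **one-dimensional monodomain fiber simulation** of an infarct border
   zone (BZ) embedded in non-infarcted myocardium (NZ), with graded
   beta-adrenergic stimulation and S1–S2 protocols probing conduction block
   and premature-ventricular-complex (PVC) propagation.

## The alternans statistic

For one pixel, let `A` be the mean amplitude of even-indexed beats and `B`
of odd-indexed beats (0-based, anchored to the first recorded stimulus;
durations replace amplitudes for APD/CaTD alternans). The normalized
alternans magnitude is

$$\mathrm{NAM} = \frac{|A - B|}{A + B},$$

and the signed variant $(A-B)/(A+B)$ carries the phase. Amplitudes are
measured as the window peak minus the pre-upstroke baseline (the minimum of
the 10 ms preceding the stimulus), which makes the statistic invariant to
multiplicative gain and additive offset — essential for fluorescence data,
whose absolute counts are arbitrary. With an odd number of beats the last
beat is dropped so both parity series have equal length. Since the parity
anchor is a convention, the sign of the phase map is only meaningful
relative to it; parity inversion negates `signed` everywhere and leaves NAM
unchanged.

### Pipeline defaults

The analysis (`alternans_map()`) applies, in order: per-pixel linear
detrending, a 3×3 spatial mean filter, and a 3-frame temporal moving
average; all three are configurable and can be disabled. A pixel is valid
when its mean beat amplitude exceeds `valid_k = 5` times a robust per-pixel
noise estimate (1.4826 · median |first difference| / √2); weak-signal
pixels, such as scar, fail this rule. Nodal lines — the zero-level curves of
the signed map that separate regions alternating in opposite phase — are
extracted as linearly interpolated zero crossings between 4-adjacent valid
pixels of opposite sign, restricted to edges whose 3×3 neighborhood reaches
NAM ≥ 0.05; the floor suppresses spurious contours where nothing alternates.

Two numerical caveats are worth knowing. First, linear detrending of a
*periodic, drift-free* signal is slightly biased by the partial first/last
beats and perturbs recovered NAM at the 10⁻⁴ level; on drifting real data it
is a clear win, and the exactness tests disable it. Second, at short cycle
lengths the calcium transient does not fully recover between beats, so the
measured amplitude mixes in a small fraction of the previous tail and NAM is
mildly overestimated; with the default template this bias is ≪ 0.01 at
bcl ≥ 100 ms.

## The synthetic movie generator

The generator defines the study conditions for every pipeline test. Its
defaults mirror an epicardial alternans-mapping protocol: a pacing ladder of
140, 130, 120, 110, 100, 95, 90, 85, 80 ms basic cycle length (bcl), 10 s of
pacing per step with the final second recorded, a 32×32 pixel grid over a
7×7 mm field of view at 1 kHz, and three repeats per condition
(control, norepinephrine, norepinephrine + metoprolol).

Each pixel's calcium trace is a train of template transients — a
raised-cosine upstroke (default time-to-peak 12 ms) and exponential decay
(default τ = 25 ms; BZ pixels use a 1.25× longer decay, emulating the
prolonged CaTD90 of border-zone tissue) on a baseline of 100 counts with
amplitude 100. Even-indexed beats have amplitude $a(1+s)$ and odd beats
$a(1-s)$, where $s$ is the pixel's signed alternans magnitude, so the true
NAM is exactly $|s|$. Noise is zero-mean Gaussian per pixel and frame with
SD expressed as a fraction of the beat amplitude (default 5%), under an
explicit seed; regeneration with the same seed is bit-identical. An optional
voltage channel carries square-ish action potentials whose duration
alternates in phase with the calcium amplitude, reflecting the tight
coupling between calcium and APD alternans.

What the generator does *not* emulate: optics (dye spectra, photobleaching,
motion artifact), conduction (beats are simultaneous across the field), and
any emergent tissue dynamics — discordant patterns are prescribed through
the field's nodal geometry, not produced by a reaction–diffusion substrate.
Pipeline tests passing on these movies therefore validate the *estimator*,
not the biology of real recordings.

Movies are written as one multi-page 16-bit TIFF per channel plus a JSON
sidecar (metadata, quantization scale, optional ground truth). 16 bits match
the EMCCD cameras such data come from; quantization is explicit, so
write → read → write is bit-exact.

## The myocyte model

The supplementary ionic model behind the original fiber study is not
reproduced here; the package ships a phenomenological myocyte built to
satisfy the same qualitative physiology. It couples:

- a **Mitchell–Schaeffer-type excitable membrane** in a normalized voltage
  $u$ (mapped as $V_m = -85 + 125u$ mV) with a single recovery gate $h$:
  $\dot u = h u^2(1-u)/\tau_{in} - u/\tau_{out} + I_{Ca\to V} + I_{stim} + D\nabla^2 u$,
  with $\tau_{open}$/$\tau_{close}$ controlling recovery and plateau
  inactivation;
- a **two-compartment calcium-cycling subsystem**: cytosolic calcium $c$,
  an uptake (SERCA) pool and a release pool refilled from it with time
  constant $\tau_{tr}$. At each regenerative upstroke the release pool
  empties by a steeply load-dependent fraction
  $f_{max}\, j^{\gamma} / (j^{\gamma} + K^{\gamma})$; released calcium
  enters the cytosol over $\tau_{rel}$ and is reclaimed by SERCA in
  competition with sarcolemmal extrusion;
- a **calcium→voltage coupling** through a low-pass filtered calcium
  variable $c_w$ (τ = 120 ms, standing for the slowly equilibrating,
  NCX-weighted calcium the membrane integrates), acting as an inward
  plateau current $g_{cv}(c_w - c_0)\,u^2(1-u)$. The $u^2$ gating confines
  the current to the plateau; an ungated variant produced delayed
  afterdepolarizations at high gain.

**Why alternans is rate-dependent here.** The beat-to-beat release map is
destabilized by the steep load–release relation, but only when the release
pool cannot refill between beats: the refill factor $e^{-\mathrm{bcl}/\tau_{tr}}$
multiplies the map slope. With the BZ values ($\gamma = 30$,
$\tau_{tr} = 200$ ms) the fixed point is unstable at bcl 300 ms and stable
at 400 ms; the NZ values ($\gamma = 20$, $\tau_{tr} = 120$ ms) are stable
throughout the tested range. Calcium alternans drives APD alternans through
the coupling current — the same causal direction inferred from the
experiments the model descends from.

**Phenotypes.** The BZ cell differs from NZ by depressed SERCA (v_up × 0.5,
prolonging the calcium transient), steeper release restitution, slower
release-pool refill, a mild plateau prolongation (τ_close × 1.02) and slower
post-repolarization recovery of excitability (τ_open × 1.12, giving the
longer BZ effective refractory period).

**Beta-adrenergic stimulation** (`bar_level` ∈ [0, 1]) acts on two axes.
It applies small direct rate effects to every cell (SERCA stimulation,
faster release, 3% shorter τ_close, 4% faster τ_open — the modest APD and
refractory-period shortening seen under norepinephrine). And it *restores
the BZ remodeling*: every BZ factor is scaled by $(1 - \mathrm{bar})$, so at
full stimulation a BZ cell behaves like an NZ cell. This design choice is
anchored in the PVC-vulnerability table the simulation reproduces, where the
fully stimulated BZ fiber and the plain NZ fiber are nearly
indistinguishable (180 vs 181 ms), and in the biochemistry: the remodeling
axis is calcium handling, which PKA phosphorylation of phospholamban, RyR
and ICaL directly compensates.

**Integration.** Forward Euler with explicit diffusion, dt = 0.02 ms,
dx = 0.0125 cm and D = 3.3 × 10⁻³ cm²/ms (set for a conduction velocity
near 0.05 cm/ms; the explicit-stability bound dt < dx²/2D is respected).
Cells are initialized in a paced-like diastolic state (h = 0.6): from
pristine rest the first action potential is long enough to push a cable at
bcl 300 ms into a self-sustaining 2:1 rhythm before any steady state is
reached. Trajectories are bit-deterministic; halving dt changes APD90 by
< 0.5 ms.

APD90 is measured from the activation upstroke (−40 mV crossing) to 90%
repolarization of the peak-to-rest amplitude with linear interpolation. The
single-cell ERP is the shortest S1–S2 interval whose S2 produces an action
potential reaching 80% of the steady S1 amplitude, scanned at 1 ms.

## Fiber protocols

The standard cable has 240 cells with BZ at cells 81–160, S1 delivered to
the 8 leftmost cells (0.8 ms⁻¹ for 2 ms; a weaker drive loses 1:1 capture at
bcl 300 ms). After pre-pacing, spatially heterogeneous APD alternans is
confined to the BZ segment with tails decaying into the NZ over roughly one
electrotonic space constant (~12 cells); the distal NZ (e.g. cell 220)
alternates by < 1 ms. Under full beta-adrenergic stimulation alternans is
abolished everywhere and APD90 shortens in both zones.

The package's shipped protocols use 200 pre-pacing beats: the recorded APD
profile is identical at 150 and 300 beats, so the pattern is converged; the
harness accepts any depth.

**S2 protocols.** A premature stimulus (1.75× the S1 amplitude, as premature
stimuli are conventionally stronger) is delivered to a 10-cell segment —
about one space constant; a 5-cell source cannot ignite partially recovered
tissue at any coupling interval (CI). CI is measured from the S1 stimulus
time of the preceding beat. During alternans the S2 must follow a specific
beat: `apply_s2()` reads the parity of the recorded final beat pair at the
BZ center and continues the S1 rhythm for one or two beats so that the S2
follows the long-APD beat (conduction-block protocol; segment of proximal NZ
adjacent to the BZ) or the short-APD beat (PVC protocol; segment centered in
the BZ).

**Outcome classification** is sentinel-based: cells 5 in from each fiber
end. Both sentinels activated after the S2 → `FULL_PROPAGATION`; exactly
one → `BZ_BLOCK` (the wave escapes on one side but fails to traverse the
tissue on the other); neither → `NO_PROPAGATION`. A marginal local ignition
that dies within a few cells of the source counts as no propagation — the
earlier cell-counting rule mislabeled passive electrotonic spread next to a
stimulated-but-refractory segment. Activation itself requires a regenerative
upstroke: the cell must first be diastolic (< −60 mV) and subsequently
exceed −10 mV, which passive bumps next to a stimulated segment never do.

**Known limitation — ordering of outcomes.** Scanning CI at 1 ms, the
control fiber shows `NO_PROPAGATION`, then a 1–2 ms sliver of
`FULL_PROPAGATION`, then the `BZ_BLOCK` band, then full propagation. The
sliver is real model behavior: at the lowest igniting CIs the S2 wave crawls
slowly enough that the border zone recovers before the wavefront arrives,
while brisker waves at slightly longer CIs reach it earlier and block. The
soft threshold of the Mitchell–Schaeffer membrane widens this crawl regime
relative to sodium-upstroke ionic models; we report the outcome sequence as
measured and flag the non-monotonicity (`ordered = FALSE`) rather than
smoothing it away.

**What the standard configuration shows** (values from this package's own
protocols, reproduced by `scripts/acceptance.R`): a conduction-block window
exists in the control fiber and is absent under full beta-adrenergic
stimulation, where the scan collapses to a sharp no-propagation →
full-propagation transition at a shorter CI; and the five-fiber PVC
comparison reproduces all three experimental orderings — the
alternans-shortened beat makes the BZ fiber at bcl 300 more vulnerable than
the NZ-only fiber (A < B), baseline BZ refractoriness exceeds NZ at bcl 400
(C > D), and suppressing alternans removes the advantage (E > A). The
*absolute* coupling intervals are properties of the phenomenological
parameterization and are not calibrated to the reference ionic model's
printed values.

## Design decisions taken where the ground was open

- **Parity anchor**: the first recorded stimulus defines "even"; phase maps
  are documented as sign-symmetric.
- **Recording-level NAM** is the mean over valid pixels (whether the
  original analysis used a different aggregate is unspecified).
- **CaTD onset** is the stimulus time, since pacing times are known; a
  10%-of-peak crossing is the documented alternative.
- **Repeat averaging** is the arithmetic mean of the three repeats'
  summaries; with fewer repeats the available ones are averaged with a
  warning.
- **HDF5 container**: omitted — no HDF5 R binding is available in the
  supported environment; the TIFF + JSON dialect is complete and
  round-trip exact.
- **Fallback vs reference model**: all numerical claims in the tests are
  made for the shipped phenomenological model; the reference ionic model's
  printed coupling intervals are kept in the acceptance suite as the
  calibration target they are, and fail against the fallback by design.

## Problem sizes

The test suite and the acceptance script use: 1000 random traces for the
estimator oracle; 32×32 × 1000-frame movies (one bcl per check); 150-beat
single-cell runs; the 240-cell cable with 200 pre-pacing beats; and 1 ms CI
grids over 190–250 ms. These sizes were chosen as the smallest at which
every quantity is converged (pre-pacing) or fully determined (scans).
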