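---
title: "Nutation kinematics: model, measurement chain, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nutation kinematics: model, measurement chain, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutkin)
```

## The kinematic model

`nutkin` models a growing, nutating plant organ — a compound-leaf rachis —
as a planar beam of width $W = 2R$ whose midline geometry is described by
arclength $s$ (from the clamped base), local angle $\theta$, and signed
curvature $C$. Three ingredients drive the dynamics.

**Mean elongation.** The relative elemental growth rate of the midline is a
time-independent sigmoid of the distance $s'$ from the apex,
$$\dot E(s') = \frac{\dot E_{\max}}{2}
  \Big(1 - \tanh\frac{s' - L_{gz}}{\lambda}\Big),$$
describing an apical growth zone of constant length $L_{gz}$ that is
advected with the apex as the organ elongates.

**Differential elongation.** The two lateral faces elongate at
$\dot E \pm \delta\dot E / 2$, with
$$\delta\dot E(s', t) = \delta E_{\max}\,
  \mathrm{sech}^2\Big(\frac{s' - s_{bz}}{L_{bz}}\Big)
  \sin\frac{2\pi t}{T},$$
a unit-peak envelope centred by default at $s_{bz} = L_{gz}$: differential
growth peaks where the mean rate drops, which is what the time-averaged
profiles of the measurement chain recover. The $\mathrm{sech}^2$ envelope
is, up to normalization, the derivative of the $\tanh$ sigmoid, so the two
profiles are a consistent pair.

**Curvature dynamics.** For a thin beam the face arclength elements are
$\mathrm{d}s\,(1 \pm C W / 2)$, so
$\delta\dot E = \tfrac{d}{dt}\, 2\,\mathrm{artanh}(C W / 2)$ and
$$\partial_t C = \frac{\delta\dot E}{W}
  \Big(1 - \big(\tfrac{CW}{2}\big)^2\Big),$$
the leading order $\delta\dot E / W$ with a second-order correction in
$CW$. Curvature advection is neglected (the nutation period is much shorter
than the growth time scale), there is no elasticity, gravity, or internal
oscillator: the model is purely kinematic. Integration is explicit Euler
with $\mathrm{d}t = T/500$ by default; the convergence test in the suite
shows the final apex position changes by $<0.1\%$ when the step is halved.

### Initial state

Integrating $\partial_t C \propto \sin(2\pi t / T)$ from a straight start
leaves a constant curvature offset equal to the oscillation amplitude, so
the organ would oscillate about a bent mean — contrary to the observed
nutation about a rectilinear state. `simulate_rachis(init = "steady")`
(the default) therefore starts on the steady zero-mean cycle,
$C(s, 0) = -\delta E_{\max}\, g(s')\, T / (2\pi W)$; `init = "straight"`
is kept for the zero-curvature contracts.

### Closed-form apex amplitude and the order-of-magnitude relation

Integrating the curvature rate over one period and along the organ, the
apex angular amplitude of the simulated model is, at small amplitude,
$$A_{\mathrm{exact}} = \frac{\delta E_{\max} T}{2\pi}\cdot
  \frac{2 L_{bz}}{W}
  = \frac{\delta E_{\max}\, T\, L_{bz}}{2\pi R},$$
(the sine integrates to $T/2\pi$, the envelope to $2L_{bz}$). The
order-of-magnitude chain used to invert a measured amplitude —
differential growth over one period, divided by $R$, integrated over
$L_{bz}$ — drops the $2\pi$ and the factor 2:
$\delta E_{\max} \approx A R / (T L_{bz})$. `amplitude_relation()` exposes
the dimensionless prefactor explicitly (default 1, the order-of-magnitude
reading; $2\pi$ for quantitative round trips against the simulation). With
$A = 25^\circ$, $R = 1.5$ mm, $T = 2.5$ h, $L_{bz} = 15$ mm the default
inversion gives $\delta E_{\max} \approx 0.0174\ \mathrm{h^{-1}}$, which is
also the package's default amplitude.

### Contractions

A face contracts where $\dot E(s') < \delta E_{\max}\, g(s') / 2$ at some
phase. With $s_{bz} = L_{gz}$ the required amplitude at apex distance $s'$
is $\dot E_{\max} / (1 + \tanh((s' - L_{gz})/\lambda))$: inside the growth
zone it is at least $\dot E_{\max}$ (attained exactly at the growth-zone
edge), and in the basal tails it decreases toward $\dot E_{\max}/2$ while
both rates vanish exponentially. $\delta E_{\max} > \dot E_{\max}$ is
therefore a sufficient condition everywhere; the exact threshold depends on
the spatial profiles chosen. `contraction_test()` reports the minimum face
rate (the margin) and its location over the whole organ; tests pin the
growth-zone threshold to $\dot E_{\max}$ and the full-organ brute-force
threshold to $\dot E_{\max}/2$.

## Camera projection and apparent elongation

The bending plane is horizontal: a top view sees the true planar midline, a
side view sees its orthogonal projection, where each material segment
foreshortens by $|\cos\theta|$. The apparent elongation rate of a segment is
$\tfrac{d}{dt}\log(\text{projected length})$, which decomposes exactly into
a material term ($\tfrac{d}{dt}\log$ of the face arclength, oscillating at
the nutation period $T$ where differential growth acts) and a geometric
term $\tfrac{d}{dt}\log|\cos\theta|$. For nutation symmetric about the
straight state the geometric term is an even function of $\theta$ and
oscillates at $T/2$, with the largest amplitude where the angular excursion
is largest — apically. This is the origin of the two-mode structure in the
wavelet kymographs: dominant period $T/2$ at the apical end, $T$ basally,
a 2:1 ratio, with the handover between the apex and the bending-zone
centre.

## Synthetic data

`make_node_tracks()`, `render_frames()` and `make_kymograph_dataset()`
generate everything the measurement chain consumes, with the simulation as
ground truth:

* node tracks emulate the fluorescent node markers: material points
  advected by growth, Gaussian positional jitter (default 0.05 mm),
  per-frame dropout (default 2%) emulating marker fading and occlusion, at
  the 2.5-min top-view cadence; the projected apex point is tracked with
  the same noise so the chain can measure apex distances;
* frames emulate the speckle-textured organ: smoothed uniform noise defined
  in material coordinates (so features are advected and their contrast is
  diluted where tissue stretches), drawn as a band of width $W$ with
  additive sensor noise, at the 1-min side-view cadence;
* kymograph bundles sample the true curvature and elongation fields on
  stated grids with independent Gaussian noise. One master seed fans out to
  independent per-product substreams.

What the generator does *not* emulate: leaflets and their occlusions beyond
the dropout model, perspective or lens distortion, flash lighting,
out-of-plane (3D) components of nutation, and the slow amplitude
modulations of real nutation. Passing tests therefore demonstrate that the
measurement chain is correct and well-calibrated on data obeying the model
assumptions, not that those assumptions hold for any particular organ.

## Measurement chain: numerical choices

* **Midline**: Otsu threshold, transverse median per longitudinal bin along
  the cloud's principal axis, moving-median smoothing (window 9 bins),
  pixel centres at index $-0.5$. Degenerate (empty) masks raise detection
  errors rather than returning guesses.
* **Curvature**: Taubin's algebraic circle fit on a 10-mm sliding window
  (low bias on short arcs; `pracma::circlefit` serves as an independent
  oracle in the tests), sign from the tangent-to-centre cross product
  (left bending positive). Collinear windows give 0, not an error.
* **Node tracking**: when the detection count is conserved, matching by
  rank order along the organ (the conservation + ordering rules; this
  forbids swaps); otherwise greedy nearest-neighbour under a displacement
  bound with gap closing; frames violating the rules are flagged for
  manual correction, never guessed.
* **Segment elongation**: $d\log d/dt$ of inter-node distances by centred
  differences; positions are chord sums accumulated from the tracked apex
  (gap-filled in time so a dropout does not shift the chain). The 3×3
  mean + median smoothing pair is applied to displayed kymographs but not
  before apex-frame time averaging, which does its own denoising — spatial
  smoothing across 20-mm segments would smear the sigmoid transition.
* **Image correlation**: 1D normalized cross-correlation of band-averaged
  intensity profiles with parabolic sub-pixel refinement, followed by a
  stretch-compensated second pass (the window is re-matched after warping
  by the first-pass local strain, removing the rigid-shift distortion
  bias); strain by local linear regression over 5 window centres. A `lag`
  of several frames trades time resolution for signal-to-noise, since the
  sub-pixel error is independent of the lag. Exact matches short-circuit
  the sub-pixel step so zero motion yields exactly zero.
* **Envelope**: magnitude of the FFT-based analytic signal of the
  mean-removed series, lightly smoothed; edges are unreliable within
  roughly one period of the record ends.
* **Apex-frame profiles**: samples are rebinned by apex distance with
  10-mm bins. A 30-mm bin (the inter-node scale) was considered and
  rejected: the sigmoid transition ($\lambda = 15$ mm) is barely
  identifiable at that resolution, and because segment midpoints sweep
  through fine bins as the apex advances, 10-mm bins remain well populated.

## Wavelet analysis

The continuous wavelet transform uses the second-order complex-Gaussian
(`cgau2`) mother wavelet in its analytic form
$\psi(x) = (4x^2 - 3 + 4ix)\, e^{-ix - x^2} / \sqrt{5\sqrt{2\pi}}$, whose
amplitude spectrum peaks at $(1 + \sqrt{17})/2$ rad per unit $x$, i.e. a
centre frequency of $\approx 0.40768$ cycles. Scales map to periods through
this centre frequency. Coefficients are computed by direct FFT convolution
with **L1 normalization** ($1/a$): under the centre-frequency mapping this
makes a pure tone's energy peak exactly at the tone's period, matching the
convention of the standard commercial CWT implementation emulated here
(under $1/\sqrt{a}$ the tone argmax is biased high by $\approx 9\%$ for
this wavelet). Two consequences are documented and tested: white noise
acquires a deterministic $1/a$ energy tilt (its raw argmax pins at the
shortest analyzed period and is a boundary artifact, not a mode), and
energies of different scales are comparable only through the stated
convention. Energy is $|C(a,b)|^2$, aggregated per position by the mean
outside the cone of influence (two scales per record edge), normalized per
position to unit maximum (a global-maximum option is provided). The
dominant period per position is the argmax refined by log-period parabolic
interpolation; modes are counted as dominant-period plateaus — chains of
occupied period-grid indices at most one step apart — each covering at
least 10% of positions, so a slowly drifting ridge is one mode and an
isolated handover point is none. The period grid is logarithmic with 32
voices per octave on $[4\,\mathrm{d}t,\ n\,\mathrm{d}t/4]$ (the
record-length side gets a 10% grace since the cone of influence already
flags those cells).

## Fitting

`fit_mean_profile()` fits the sigmoid by weighted Levenberg–Marquardt least
squares (bin counts as weights) with bootstrap-over-bins confidence
intervals (200 resamples, recorded seed); profiles that do not decay
within the window raise an error instead of returning a silent boundary
estimate. `fit_differential_profile()` fixes the envelope shape to the
normalized derivative of the fitted sigmoid and estimates only the
amplitude. `fit_wavelet_kymograph()` minimizes the Frobenius distance
between per-position-normalized energy maps of observation and simulation
(simulate → project → apparent rate → energy map) over the requested free
parameters, by coarse grid search then Brent (one parameter) or
Nelder–Mead refinement; all other parameters are fixed, mirroring a
protocol where period and geometry are measured before fitting. A flat
objective across the grid is reported as unidentifiable, with no estimate.

## Problem sizes

The package's own test and demonstration conditions are: organ of 250 mm
with 151 material markers, five nutation periods (12.5 h) at
$\mathrm{d}t = T/500$, kymographs at the 2.5-min camera cadence, 12 node
markers, and 20-seed recovery studies; rendered side views use 0.25 mm/px.
These sizes keep every study on a laptop scale while leaving all estimators
deep inside their asymptotic regimes.

## Known limitations

* Planar kinematics only: real circumnutation has out-of-plane components;
  the side view of the model is degenerate (a straight band) by design.
* The default $\delta E_{\max}$ (from the order-of-magnitude inversion at
  $25^\circ$) yields a simulated apex amplitude of about $4^\circ$; the
  exact-prefactor inversion reproduces $25^\circ$. Both relations are
  exposed; which is appropriate depends on whether a order-of-magnitude
  estimate or a quantitative round trip is wanted.
* At the default parameters the contraction margin is positive (no
  contraction): the demonstration dataset is sub-threshold by construction,
  and the contraction machinery is exercised by parameter scans in the
  tests.
* The DIC estimator assumes a textured, roughly horizontal band and
  locally affine image motion; it degrades when inter-frame displacement
  exceeds the search radius.
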