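---
title: "How fibertwin models temporally encoded fiber imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How fibertwin models temporally encoded fiber imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

fibertwin is a desk-scale digital twin of a single-pixel imaging
instrument in which a long step-index multimode fiber (MMF) converts the
2D content of a scene into a 1D train of delayed sub-pulses. This
vignette explains the model, its assumptions, the parameters that matter,
and the choices made where the design was genuinely open.

## The encoding physics

A step-index MMF with core radius $a$, numerical aperture
$\mathrm{NA}$ and normalized frequency $V = 2\pi a\,\mathrm{NA}/\lambda$
guides a discrete set of LP modes. Under the weakly guiding (scalar)
approximation, each guided mode LP$(l,m)$ solves

$$u\,\frac{J_{l-1}(u)}{J_l(u)} \;=\; -\,w\,\frac{K_{l-1}(w)}{K_l(w)},
\qquad u^2 + w^2 = V^2 ,$$

with transverse field $J_l(ur/a)\cos l\phi$ (or $\sin l\phi$) inside the
core and a $K_l$ tail outside. `find_lp_modes()` brackets the roots of
the pole-free form $u J_{l-1}(u) K_l(w) + w K_{l-1}(w) J_l(u)$ on a
uniform grid of 4000 points per azimuthal order and refines them by
bisection to $10^{-12}$; this is robust against the poles of the ratio
form at the zeros of $J_l$. Fields are sampled analytically on a square
grid spanning 1.5 core diameters (default $128\times128$) and then made
exactly orthonormal on the grid by a symmetric (inverse square root of
the Gram matrix) orthogonalization.

Each mode's group delay per metre is $\tau = \mathrm{d}\beta/\mathrm{d}\omega$,
computed by a centred finite difference over wavelength (relative step
$10^{-4}$, re-solving each root at the perturbed wavelengths) with the
material indices held constant: we model intermodal, not material,
dispersion. For the reference fiber (50 µm core, NA 0.22, 1064 nm,
$n_\text{clad} = 1.4496$, so $V \approx 32.5$) this yields 269 spatial
modes per polarization (the $V^2/4$ regime) whose transit times over
1 km span about 50 ns — between the instrument's observed 45 ns
single-waveform span and the 55 ns ray-optics bound
$L\,\mathrm{NA}^2 / (2 n_\text{core} c)$. Delays are exactly linear in
fiber length by construction.

The cladding index is a configurable default (fused silica near
1064 nm); only the NA is specified by the hardware, so absolute transit
times (not spreads) depend on this choice.

### Orientation-degeneracy splitting

In the ideal scalar model the $\cos l\phi$ / $\sin l\phi$ orientations
of each $l>0$ pair share one propagation constant and one arrival time.
That ideal model is provably blind to the azimuthal content of the
scene: the two orientation powers only ever reach the detector as a sum,
and $\cos^2 + \sin^2 = 1$ collapses every delay bin to a purely radial
functional of the image (we measure a waveform-matrix numerical rank of
10 on an $8\times8$ scene whose image rank is 62). A real kilometre of
fiber is not ideal: core noncircularity and stress split the pair's
group delays — differential delays of tens of ps/km between the two
LP$_{11}$ orientations are documented in few-mode fibers. Because the
imaging principle demonstrably carries 2D information, the solver
applies a seeded zero-mean Gaussian orientation splitting with standard
deviation 40 ps/km (0.08% of the intermodal spread, comparable to the
pulse width so that the split is temporally resolvable);
`orientation_split_ps_km = 0` restores the ideal degenerate model, and
the propagation constants themselves stay degenerate.

## The forward encoder

The scene (object pixels of pitch 7.56 µm) is imaged onto the fiber
facet; by default the magnification is auto-fitted so the image
footprint fills 90% of the core diameter, displaced from the fiber axis
by a (2, 1.5) µm lateral offset. The offset matters: every LP mode
field is either symmetric or antisymmetric under point reflection about
the axis, so for a perfectly centred scene the set of mode powers is
exactly invariant under a 180° rotation of the image — a digit 6 and
the 9 it becomes when rotated produce identical waveforms. Real
instruments never sit at that measure-zero alignment; the default
offset is a typical ~10%-of-core-radius alignment tolerance, and
`offset_um = c(0, 0)` reproduces the degenerate idealization.

Coupling is **coherent** by default — the instrument illuminates the
scene with a coherent laser — so the mode amplitudes are
$c_m = \sum_{px}\sqrt{I_{px}}\,\psi_m(px)$ (plane-wave phases; random
speckle phases optional) and the per-mode powers are $P_m = |c_m|^2$.
An incoherent model ($P_m = \sum I_{px}|\psi_m|^2$, exactly linear in
intensity) is kept for oracle tests; note it transmits only the even
azimuthal harmonics of the scene, since $|\psi_m|^2$ contains no odd
ones.

At the detector the sub-pulses add **incoherently**: a spatially
integrating photodiode measures the total power of orthogonal modes
without cross terms, so
$P(t) = \sum_m P_m\, g(t - \tau_m)$ with $g$ a unit-area Gaussian whose
FWHM combines the 45.1 ps pulse and the 15 ps detector impulse response
in quadrature. The trace is sampled at 100 GS/s (10 ps) over a window
from 5 pulse-widths before the earliest arrival to 5 pulse- plus
5 impulse-widths after the latest, shared by all frames of a
configuration (a fixed oscilloscope trigger). White Gaussian noise at
the configured SNR (default 30 dB) is added when a noise seed is given.
Gaussian tails below $10^{-30}$ of the peak are flushed to exact zero —
they are physically meaningless, and subnormal floats make downstream
linear algebra pathologically slow.

Environmental drift is modeled abstractly by `perturb_coupling()`:
random orthogonal mixing of amplitudes within blocks of modes whose
delays differ by less than one pulse width (identity at strength 0, a
random rotation at strength 1, interpolated through the matrix
exponential of a scaled random skew-symmetric generator) plus Gaussian
delay jitter scaled by the strength. Power is conserved exactly and
every draw is seeded. Physical temperature or bend coefficients are out
of scope; only ordinal robustness claims are meaningful.

## Synthetic scenes

`make_glyphs()` renders 10–36 fixed stroke-skeleton classes with random
affine jitter (±10% scale, ±10°, ±2 px) binarized at 0.5. The stroke
width is 9% of the image side (2.5 px at $28\times28$), chosen to match
the stroke thickness and ink fraction (~13–19%) of the handwritten-digit
corpora the real instrument was trained on; matching those statistics,
not any downstream metric, is what makes the stand-in comparable.
`make_random_strokes()` draws random quadratic Bézier strokes (with
optional shift/rotate/scale augmentation), `make_resolution_target()`
builds three-bar groups at configurable pitches (2 px at the 7.56 µm
pitch is the 15.12 µm feature), and `make_grayscale()` sums random
Gaussian blobs. All generators are pure functions of their seed.

What the generators do *not* emulate: the curvature statistics and
stroke-count distribution of real handwriting, clothing textures, or
detector nonlinearity. Passing tests show the pipeline recovers
*this* family of scenes through *this* forward model; transfer to real
acquisitions additionally depends on how well the forward model matches
a particular instrument.

## Decoding

Waveforms are cropped (or zero-padded) to 4096 samples about the
training set's support centroid — the crop offset and the zero-mean /
unit-max-abs normalization are training-set statistics stored with the
model — and ground-truth images are interpolated bilinearly to the
$64\times64$ output grid. Three inverse models are provided:

* `fc5`: five fully connected layers 4096–2048–1024–2048–4096 with relu
  hidden activations and a sigmoid output, MSE loss, Adam
  (learning rate $10^{-3}$ stepping down by 0.3 at one- and two-thirds
  of the epochs, batch 128). Training runs in a compiled
  single-precision core with in-place updates; weight initialization
  and shuffling come from R's RNG, so a fit is a pure function of its
  seed.
* `unet`: this package's own four-level convolutional encoder–decoder on
  the $64\times64$ reshape (8–16–32–64 channels, 3×3 same-padding
  convolutions as im2col matrix products, 2×2 max pooling,
  nearest-neighbour upsampling, skip concatenations, sigmoid 1×1 head).
  The exact layout of the original instrument's network is not public;
  this one is defined here and validated against a pure-R reference
  implementation of the same forward/backward pass.
* `linear`: ridge-regularized least squares (primal or dual form as
  dimensions dictate), the closed-form oracle. On noiseless
  incoherent-model data it recovers pattern families whose dimension
  stays below the forward map's rank essentially exactly.

`classify_waveforms()` trains a compact 4096–512–classes softmax
classifier directly on preprocessed waveforms.

Fidelity is the pixelwise Pearson correlation (defined as 0 against a
constant image); SSIM uses the standard 11×11 Gaussian window
($\sigma = 1.5$, $K_1 = 0.01$, $K_2 = 0.03$, dynamic range 1) averaged
over the fully windowed region, cross-checked against an independent
reference implementation.

## Studies and problem sizes

The scripted studies (`run_length_ablation()`, `run_frame_rate_analysis()`,
`run_robustness()`, `run_resolution_test()`, `run_classification()`)
re-run the full pipeline per condition and emit seeded, config-hashed
tables. Default desk-scale sizes are 2000 training / 500 test pairs for
ablations — orderings stabilize well below headline sizes — while the
headline recovery and classification figures use 10,000 / 1,000 pairs
with the fully connected decoder at 30 epochs. The ablation and
robustness studies default to the linear decoder: they need ordering,
not peak quality, and the closed-form fit removes training variance
from the comparison. A bar-group pitch counts as "resolved" when the
Michelson contrast of its profile exceeds 0.2; the threshold is this
package's quantitative stand-in for a visual judgement.

## Numerical choices and degenerate inputs

Root brackets that fail to refine raise an error naming the azimuthal
order and bracket. Modes lost at a perturbed wavelength (near cutoff)
fall back to a one-sided difference with a warning. All-zero images
couple zero power (not an error); all-zero waveforms preprocess to
zeros with a warning; a constant image has fidelity 0 by convention.
Images smaller than the SSIM window fall back to a single global
window. Network logits are clamped to ±30 before the sigmoid — the
saturated tail is numerically meaningless and would otherwise produce
subnormal activations. Equality of frame span and pulse period counts
as non-overlapping (closed–open convention).

## What the idealizations would hide

Three successively removed idealizations each destroyed information the
real instrument demonstrably transmits, and are worth knowing about when
adapting the model:

* *Exact orientation degeneracy* collapses every delay bin to a radial
  functional of the scene (waveform rank 10 on an $8\times8$ scene of
  image rank 62) — hence the seeded delay splitting above.
* *Incoherent coupling* transmits only even azimuthal harmonics
  (rank 16) — hence the coherent default (rank 59).
* *Perfect axial centring* makes images and their 180° rotations
  indistinguishable — visible as a near-total 6↔9 collapse in waveform
  classification while an image-space classifier is perfect — hence the
  default lateral offset.

## Known limitations

* The original instrument's decoder was trained on GPU-class compute;
  this package's training budget is orders of magnitude smaller, and
  its reconstructions, while meeting the reference fidelity and SSIM on
  held-out glyphs, are softer than what longer conv-net training
  produces.
* The scalar LP model ignores polarization, bend physics, graded-index
  profiles, material-dispersion curves and nonlinear propagation.
* The robustness model is abstract (crosstalk + jitter); its strength
  parameter has no physical unit, so only ordinal comparisons (e.g.
  joint training tolerates at least as much perturbation as
  single-condition training) are meaningful.
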