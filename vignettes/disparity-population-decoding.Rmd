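---
title: "Decoding 2D binocular disparity from a population tuned only to horizontal disparity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding 2D binocular disparity from a population tuned only to horizontal disparity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Binocular disparity — the 2D offset between corresponding features in the
left and right retinal images — is predominantly horizontal, because the
eyes are set apart horizontally. Vertical disparities are rare and narrowly
distributed, yet they measurably influence perception, which has suggested
that early visual cortex must contain neurons tuned to a range of vertical
disparities. This package simulates the counter-example: an encoding
population in which *every* unit prefers zero vertical disparity still
carries enough information, in the joint pattern of activity across
orientation and horizontal-disparity channels, for a downstream decoder to
recover both components of the stimulus disparity — magnitude and sign —
from single noisy trials.

The mechanism is geometric. An energy-model unit's 2D disparity tuning
surface is elongated along its preferred orientation. An obliquely oriented
unit probed at a non-optimal *horizontal* disparity therefore responds best
at a non-zero *vertical* disparity, with a sign that depends on which side
of the optimum it is probed. Across a population spanning orientations and
horizontal disparities, a stimulus with vertical disparity imprints a
characteristic diagonal slant on the activity map, and a template matcher
can read that slant out.

## Encoding model

**Receptive fields.** Each binocular simple cell has one Gabor receptive
field per eye: an isotropic Gaussian envelope (s.d. $\sigma$) times a
cosine carrier of spatial frequency $f$ along the axis orthogonal to the
preferred orientation $\theta$ (measured from vertical; $90^\circ$ is
horizontal). The two eyes' fields share $\theta$, $f$, $\sigma$ but differ
in carrier phase by the phase disparity $\Delta\phi$ (split $\pm\Delta\phi/2$)
and in centre by the position disparity $(\Delta x_{pos}, \Delta y_{pos})$
(split $\mp$/$\pm$ half between the eyes, cyclopean centre at the origin).

**Position-disparity cancellation.** A phase disparity shifts the preferred
disparity by $\Delta\phi/(2\pi f)$ pixels along the carrier axis
$(\cos\theta, \sin\theta)$, which for oblique units has a vertical
component. Every unit is therefore assigned

$$(\Delta x_{pos}, \Delta y_{pos}) = (\Delta x_{enc}, 0) -
\frac{\Delta\phi}{2\pi f}(\cos\theta, \sin\theta),$$

so its preferred 2D disparity is $(\Delta x_{enc}, 0)$: the whole
population is tuned to zero vertical disparity. `empirical_peak()`
verifies this by brute-force scanning of measured tuning surfaces.

**Effective binocular correlation.** With monocular filter outputs
$v_L = \langle \mathrm{RF}_L, I_L\rangle$, $v_R$ likewise, a quadrature
pair ($\phi \in \{0, \pi/2\}$) is pooled into monocular and binocular
energy terms $M = \sum_\phi (v_L^2 + v_R^2)$, $B = \sum_\phi 2 v_L v_R$,
and the unit reports

$$C = B / M \in [-1, 1],$$

the correlation coefficient between the filtered local image patches. $C$
is exactly 1 whenever the stimulus is a pure shift equal to the unit's
interocular receptive-field transformation — for *any* image — and flips
sign exactly under anticorrelation (contrast inversion of one eye), because
$B$ is odd and $M$ even in either eye's image. Unlike raw stereo energy,
$C$ is immune to monocular contrast fluctuations, which is what makes
template matching on single trials feasible.

**Noise.** Spiking is Poisson with mean $R_m = U(1 + C)$, where $U$ is the
mean count for an uncorrelated stimulus. The default $U = 1$ is a
deliberately severe regime: even optimally driven units (mean 2 spikes)
have a coefficient of variation of $1/\sqrt{2} \approx 71\%$, and
uncorrelated-driven units 100%. (A physiological estimate of $U \approx 8$
— 100 Hz over a 160 ms judgment window — would be *less* noisy; the
default demonstrates robustness.) Stimulus-driven variability adds to this:
away from the matched disparity $C$ varies image by image.

**Population grid.** Defaults: $\theta \in \{-60,-30,0,30,60,90\}^\circ$,
$f \in \{0.200, 0.112, 0.0707, 0.0420, 0.0250\}$ cyc/px,
$\Delta\phi \in \{0, \pm\pi/4, \pm\pi/2\}$,
$\Delta x_{enc} \in \{-10,\dots,10\}$ px, phases $\{0, \pi/2\}$ — 6300
simple cells forming 3150 complex correlation detectors.

## Decoding model

`build_template_bank()` stores, for each disparity on a $21 \times 21$
grid, the mean spike count $W$ of every unit over many fresh noise images
— interpretable as synaptic weights from the encoding to a decoding
population learned from visual experience. A single-trial response vector
$R_{test}$ (3150 spike counts) is compared with each template column by the
Pearson correlation $r(\Delta x_{dec}, \Delta y_{dec})$ over units, and the
decoder responds with the half-wave-rectified
$P = \lfloor r \rfloor$. The estimate is the grid disparity maximizing
$P$. Rectification makes the decoder blind to anticorrelated stereograms,
whose response pattern is anti-correlated with every stored template
($r < 0$ almost surely), matching the absence of depth percepts from such
stimuli.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| image size | 81×81 | px | covers the largest envelope (σ = 10 px) and the ±10 px disparity range |
| σ factor | 0.25 | — | σ = 0.25/f: matches the stated envelope sizes (1.25 px at f = 0.2, 10 px at f = 0.025) |
| U | 1 | spikes | severe-noise regime; raising it only improves accuracy |
| template grid | −10..10 × −10..10 | px | 441 candidate disparities |
| images/disparity | 500 (`paper`) / 50 (`ci`) | — | Monte-Carlo averaging of stimulus noise in W |
| test trials/condition | 1000 (`paper`) / 200 (`ci`) | — | error-histogram resolution |

A note on the frequency list: the five frequencies are taken verbatim and
the period defined as $\lambda = 1/f$; the conventional period quoted for
the 0.112 cyc/px channel (8.41 px) is not its reciprocal — the frequencies
are authoritative here.

**Sensitivity to the envelope size.** The σ factor is the single most
consequential tunable. Decoding error is dominated not by Poisson spiking
but by stimulus-driven variability — the image-by-image fluctuation of $C$
in units not exactly matched to the stimulus — and larger envelopes average
more of it away. Measured at 50-image templates, 200 trials, stimulus
$(-2, 2)$: per-component RMS ≈ 1.3–1.7 px at σ = 0.25λ versus ≈ 0.5–0.65 px
at σ = 0.35λ; raising the spike budget to $U = 8$ or the template count to
500 images changes these numbers only marginally. The package default stays
σ = 0.25λ, the convention consistent with the stated per-channel envelope
sizes; `make_population(sigma_factor = 0.35)` reproduces the
higher-accuracy regime.

## Numerical choices

* **Edge truncation.** Receptive fields are evaluated over the full image
  with no windowing beyond the envelope. For the lowest-frequency channel
  (σ = 10 px) the envelope reaches the border at ≈ 3.7σ, so the matched-unit
  identity $C = 1$ holds to about $10^{-5}$ for that channel and to
  floating-point precision for all others. No renormalization is applied;
  the identity is a property of matched summation grids, and the residual
  is far below every behavioural quantity measured.
* **Narrowband bias of the cancellation.** The position-disparity formula
  is exact in the narrow-band limit. At the moderate bandwidth used
  (σ = 0.25λ), the envelope pulls the measured peak of a phase-disparity
  unit slightly back toward its position disparity — about
  $\Delta\phi/(2\pi f) / 5.9$ px along the carrier axis, i.e. up to ~0.6 px
  at f = 0.0707 for $\Delta\phi = \pi/2$. Empirical peaks therefore land
  within one grid pixel of $(\Delta x_{enc}, 0)$ for phase-disparity units
  and exactly on it for $\Delta\phi = 0$. This sub-pixel bias is inherited
  by the templates and is invisible to the decoder, which compares like
  with like.
* **M = 0 guard.** A blank aperture gives $C = 0$ (neutral evidence);
  unreachable with continuous noise stimuli but defined for safety.
* **Zero-variance Pearson guard.** If either vector in the Pearson
  correlation is constant, $r = 0$: a constant response cannot favour any
  template.
* **Tie-breaking.** The argmax of $P$ breaks exact ties toward the smallest
  $dx^2 + dy^2$, then lexicographically by $(dy, dx)$; trials with a zero
  or tied maximum are flagged *degenerate*, excluded from RMS statistics by
  default, and reported as a failure count — an anticorrelated trial must
  not masquerade as a confident $(0,0)$ estimate.
* **Noise-free templates.** $W$ uses the analytic Poisson expectation
  $U(1+\bar{C})$ rather than averaged Poisson draws (identical in the
  many-presentation limit; `empirical_noise = TRUE` forces the simulation
  for validation).
* **Seed streams.** Template images, test images, tuning-surface images
  and figure trials draw from disjoint derived-seed streams, so test
  stimuli are never template stimuli.

## What the generator emulates — and does not

The stimuli are uniform-disparity Gaussian white-noise stereograms:
every pixel i.i.d. N(0, 1), the right image an exact integer-pixel copy of
the left (or its negative), gap pixels refilled with fresh noise. This
isolates the geometry of disparity encoding from everything else. It does
*not* emulate natural images (1/f spectra, sparse structure), sub-pixel or
spatially varying disparity, monocular occlusion structure beyond the
random gap fill, or interneuronal noise correlations. Passing tests
therefore demonstrate properties of the model under its own stimulus
statistics, not performance on natural scenes.

## Problem sizes

Two named profiles (`sim_profile()`): `paper` — 500 images per template
disparity, 1000 test trials per condition, 40 images per tuning-surface
point — reproduces the reference configuration; `ci` — 50 / 200 / 10 —
is the package's own reduced profile used throughout the test suite, small
enough to run routinely while leaving every qualitative result and the
headline half-pixel error bound intact. The package's tests run the full
21×21 template grid at the `ci` profile; unit tests of the machinery use a
3-orientation, 2-frequency sub-population on 41×41 images.

## Known limitations

* Decoding is restricted to the template grid: no sub-pixel interpolation,
  and stimuli outside ±10 px cannot be represented.
* All units share one cyclopean position; spatial pooling across retinal
  locations is out of scope.
* The half-wave rectified Pearson stage is a functional model of the
  decoding area, not a circuit implementation; subtractive/divisive
  normalization realizations are discussed in the primary literature.
* Anticorrelated stimuli produce *no* response in the matched decoder, and
  a single decoder's tuning surface over anticorrelated stimuli is flat at
  ~2% of the correlated peak. The *maximum* of the rectified Pearson map
  over all 441 decoders is nevertheless usually positive for anticorrelated
  trials: the inverted response pattern anti-aligns with the negative
  side-lobes of templates at distant disparities, giving structural
  $r \approx 0.15$–$0.35$ somewhere near the grid edge even for noise-free
  responses. Anticorrelation is dissociated decoder-by-decoder, not by the
  map's global maximum.
* Early-cortical neurons show inverted, attenuated disparity tuning to
  anticorrelated stimuli; the encoding stage reproduces the inversion
  ($C \to -C$ exactly) and the model places the behavioural failure at the
  decoding stage by construction.

## A worked micro-example

```{r, eval = FALSE}
library(stereopop)
pop <- make_population(theta = c(-30, 0, 30), f = c(0.2, 0.0707),
                       dphi = c(0, pi / 2), dx_enc = -3:3)
fb <- filter_bank(pop$simple_cells, 41, 41)
bank <- build_template_bank(pop, dx_grid = -3:3, dy_grid = -3:3,
                            n_images = 30, seed = 42,
                            width = 41, height = 41, bank = fb)
sg <- generate_stereogram(41, 41, dx = -1, dy = 1, seed = 7)
rates <- response_vector(sg, pop, noise = FALSE, bank = fb)
estimate_disparity(rates, bank)
```

Decoding the noise-free mean rates typically lands on or within one pixel
of the true disparity `(-1, 1)` even though no unit in this 84-unit
population prefers a non-zero vertical disparity. Single noisy trials at
`U = 1` need the full 3150-unit population for reliable decoding — the
robustness to Poisson noise is a property of the population size, since the
Pearson matching averages noise over units.
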