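# stereopop

Population coding and template-matching decoding of two-dimensional
binocular disparity.

## The scientific problem

Binocular disparities in natural viewing are overwhelmingly horizontal, yet
vertical disparities do occur — especially in the periphery — and influence
perception. Must early visual cortex therefore contain neurons tuned to a
range of *vertical* disparities? This package simulates the counter-example:
an encoding population of binocular energy-model neurons spanning
orientations, spatial frequencies, interocular phase disparities and
horizontal disparities, but **all tuned to zero vertical disparity**, from
whose noisy single-trial spike counts a downstream template-matching decoder
nevertheless recovers both the horizontal *and* the vertical disparity of
the stimulus — magnitude and sign. The information lives in the obliquely
oriented 2D disparity-tuning surfaces of non-vertical units: probed at a
non-optimal horizontal disparity, such units respond best at a non-zero
vertical disparity, so stimulus vertical disparity imprints a diagonal slant
on the population activity map.

It is intended for computational neuroscientists studying stereopsis and
population codes, and for anyone who wants a compact, fully reproducible
testbed for "implicit" encoding of a stimulus dimension no single neuron is
tuned to.

## The model

* **Stimuli** — Gaussian-noise random-dot stereograms with exact integer 2D
  disparity: `I_R(x, y) = I_L(x − Δx, y − Δy)` on the overlap (gap refilled
  with fresh noise); anticorrelated variants invert one eye's contrast.
* **Receptive fields** — Gabors: isotropic Gaussian envelope (σ = 0.25/f)
  times a cosine carrier orthogonal to the preferred orientation θ. Eyes
  differ by a phase disparity Δφ and a position disparity
  (Δx_pos, Δy_pos) = (Δx_enc, 0) − [Δφ/(2πf)](cos θ, sin θ), chosen so every
  unit's preferred 2D disparity is (Δx_enc, 0).
* **Encoding** — each complex unit pools a quadrature pair and reports the
  effective binocular correlation C = B/M ∈ [−1, 1] (binocular over monocular
  energy terms); C = 1 exactly for matched stimuli, and flips sign under
  anticorrelation. Spiking is Poisson with mean U(1 + C), default U = 1
  (CV ≥ 71% even for optimally driven units).
* **Decoding** — templates W(unit; Δx_dec, Δy_dec) hold the population's
  mean spike count for each of 441 candidate disparities; a trial is decoded
  as the argmax over candidates of the half-wave-rectified Pearson
  correlation ⌊r⌋ between the 3150-unit spike vector and each template.

The default population is 6 orientations × 5 frequencies × 5 phase
disparities × 21 horizontal disparities = 3150 complex units (6300 simple
cells).

## Worked example

```r
library(stereopop)

pop  <- make_population()                  # the full 3150-unit grid
fb   <- filter_bank(pop$simple_cells)      # ~330 MB per eye, built once
bank <- build_template_bank(pop, n_images = 50, seed = 1, bank = fb)  # ~4 min

sg  <- generate_stereogram(81, 81, dx = -2, dy = 2, seed = 7)
spk <- response_vector(sg, pop, U = 1, seed = 8, bank = fb)
estimate_disparity(spk, bank)
#> <disparity estimate (-2, 1), max P = 0.322>
```

A single trial of Poisson spike counts (mean count ≤ 2 per unit) decodes a
stereogram carrying two pixels of *vertical* disparity to (−2, 1) — the
right horizontal disparity, and the vertical component recovered with the
~1-pixel scatter typical at this severe noise level — although no unit in
the population prefers a non-zero vertical disparity. `max P` is the
winning template's rectified Pearson correlation across the 3150 units.

Accuracy by vertical-disparity condition (same bank, 200 trials per
condition, seed 1):

```r
ex <- run_rms_experiment(pop, bank, data.frame(dx = -2, dy = c(0, 2, -8)),
                         n_test = 200, seed = 1, filters = fb)
ex$summary
#>   dx dy   n n_degenerate rms_dx rms_dy rms_max rms_2d
#> 1 -2  0 200            0  0.381  0.700   0.700  0.797
#> 2 -2  2 200            0  1.342  1.720   1.720  2.182
#> 3 -2 -8 200            0  3.597  7.633   7.633  8.438
```

Errors are smallest when the stimulus vertical disparity is 0 (sensors
tuned to the exact 2D disparity exist), grow with |Δy|, and even at
Δy = −8 the *sign* of the vertical disparity is still recovered in the
majority of trials. Anticorrelated stereograms leave the decoder's tuning
surface essentially flat (mean response ~2% of the correlated peak) — the
model analogue of the absence of depth percepts from anticorrelated
stimuli.

A thin command-line wrapper with `simulate`, `build-templates`, `decode`
and `evaluate` subcommands is installed at
`system.file("scripts", "stereopop-cli", package = "stereopop")`.

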