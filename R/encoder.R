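# The stereo energy model and its correlation normalization.
#
# For each binocular simple cell, the monocular outputs are the inner
# products v_L = <RF_L, I_L>, v_R = <RF_R, I_R>. A phase-invariant complex
# unit pools its two quadrature simple cells; splitting the pooled energy
# into monocular and binocular terms,
#
#   M = sum_phi (v_L^2 + v_R^2),   B = sum_phi 2 v_L v_R,   E = M + B,
#
# the effective binocular correlation is C = B / M, in [-1, 1], equal to 1
# exactly when the stimulus disparity matches the unit's interocular
# receptive-field transformation, and flipping sign under anticorrelation.
# Spiking is Poisson with mean R_m = U (1 + C).

#' Monocular filter outputs of binocular simple cells
#'
#' Inner product of each eye's image with the corresponding receptive
#' field. With a precomputed [filter_bank()] this is two matrix-vector
#' products; otherwise each Gabor is evaluated on the fly.
#'
#' @param stereogram a [generate_stereogram()] object.
#' @param cells simple-cell data frame; ignored when `bank` is given.
#' @param bank optional `filter_bank` over the same cells and image size.
#' @return two-column matrix `cbind(v_L, v_R)`, one row per simple cell.
#' @export
monocular_responses <- function(stereogram, cells = NULL, bank = NULL) {
  if (!is.null(bank)) {
    stopifnot(bank$width == stereogram$width,
              bank$height == stereogram$height)
    return(cbind(v_L = as.vector(bank$L %*% as.vector(stereogram$left)),
                 v_R = as.vector(bank$R %*% as.vector(stereogram$right))))
  }
  stopifnot(!is.null(cells))
  n <- nrow(cells)
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("v_L", "v_R")))
  for (i in seq_len(n)) {
    out[i, 1] <- sum(gabor_rf(cells[i, ], "left", stereogram$width,
                              stereogram$height, warn = FALSE) *
                       stereogram$left)
    out[i, 2] <- sum(gabor_rf(cells[i, ], "right", stereogram$width,
                              stereogram$height, warn = FALSE) *
                       stereogram$right)
  }
  out
}

#' Effective binocular correlation of complex units
#'
#' Computes `C = B / M` for each complex unit described by `units` (its two
#' quadrature simple cells are constructed internally), on one stereogram.
#' `C` is 1 when the stimulus is a pure shift equal to the unit's
#' interocular receptive-field transformation, -1 for the anticorrelated
#' twin of such a stimulus, and 0 by convention when `M = 0` (a blank
#' aperture carries no evidence either way; unreachable with continuous
#' noise stimuli).
#'
#' @param stereogram a stereogram.
#' @param units complex-unit data frame (rows of `pop$complex_units`, or
#'   a [neuron_spec()] without the `phi` column), or a whole population.
#' @param phi carrier phases pooled by the complex unit.
#' @return numeric vector of correlations, one per unit row.
#' @export
binocular_correlation <- function(stereogram, units, phi = c(0, pi / 2)) {
  if (inherits(units, "disparity_population")) {
    phi <- units$phi
    units <- units$complex_units
  }
  nphi <- length(phi)
  cells <- units[rep(seq_len(nrow(units)), each = nphi), , drop = FALSE]
  cells$phi <- rep(phi, times = nrow(units))
  v <- monocular_responses(stereogram, cells)
  pooled_correlation(v[, 1], v[, 2], nphi)
}

# C = B / M from interleaved per-phase monocular outputs (phase-major within
# unit); vectors of length n_units * nphi.
pooled_correlation <- function(vL, vR, nphi = 2) {
  grp <- rep(seq_len(length(vL) / nphi), each = nphi)
  B <- 2 * rowsum(vL * vR, grp, reorder = FALSE)
  M <- rowsum(vL^2 + vR^2, grp, reorder = FALSE)
  C <- ifelse(M > 0, B / M, 0)
  as.vector(C)
}

#' Batched effective binocular correlations
#'
#' Workhorse for template building and experiments: given a filter bank
#' whose rows hold each complex unit's two quadrature cells adjacently
#' (the [make_population()] ordering), and image batches as columns,
#' returns the units x images matrix of correlations.
#'
#' @param bank a `filter_bank` over `2 * n_units` simple cells.
#' @param IL,IR matrices (pixels x images) of left/right images as column
#'   vectors (`as.vector(sg$left)`).
#' @return matrix (`n_units` x images) of correlations in [-1, 1].
#' @export
correlation_batch <- function(bank, IL, IR) {
  VL <- bank$L %*% IL
  VR <- bank$R %*% IR
  n <- nrow(VL)
  odd <- seq(1, n, by = 2)
  even <- seq(2, n, by = 2)
  B <- 2 * (VL[odd, , drop = FALSE] * VR[odd, , drop = FALSE] +
              VL[even, , drop = FALSE] * VR[even, , drop = FALSE])
  M <- VL[odd, , drop = FALSE]^2 + VR[odd, , drop = FALSE]^2 +
    VL[even, , drop = FALSE]^2 + VR[even, , drop = FALSE]^2
  C <- B / M
  C[M == 0] <- 0
  C
}

#' Poisson spike counts from effective correlations
#'
#' Each unit's mean spike count is `R_m = U (1 + C)`, where `U` is the mean
#' count elicited by a binocularly uncorrelated stimulus (so `R_m` spans
#' `[0, 2U]`), and the observed count is a Poisson draw with that mean. At
#' the default `U = 1` even optimally driven units (mean 2) have a
#' coefficient of variation of ~71%, a deliberately severe noise regime.
#'
#' @param C numeric vector of correlations in [-1, 1].
#' @param U mean spikes for an uncorrelated stimulus (> 0).
#' @param seed optional integer seed.
#' @return integer vector of spike counts.
#' @export
spike_counts <- function(C, U = 1, seed = NULL) {
  stopifnot(U > 0, all(C >= -1 - 1e-9), all(C <= 1 + 1e-9))
  lambda <- pmax(U * (1 + C), 0)
  with_seed(seed, rpois(length(lambda), lambda))
}

#' Single-trial population response to a stereogram
#'
#' The full encoding-population response: effective binocular correlations
#' for every complex unit, converted to Poisson spike counts (or left as
#' noise-free mean counts with `noise = FALSE`). The result carries the
#' population's `unit_key` so the decoder can verify ordering.
#'
#' @param stereogram a stereogram.
#' @param pop a `disparity_population`.
#' @param U mean spikes for an uncorrelated stimulus.
#' @param noise draw Poisson spikes (`TRUE`) or return mean counts.
#' @param seed optional seed for the Poisson draw.
#' @param bank optional `filter_bank` over `pop$simple_cells`.
#' @return numeric vector of length `nrow(pop$complex_units)` with
#'   attribute `unit_key`.
#' @export
response_vector <- function(stereogram, pop, U = 1, noise = TRUE,
                            seed = NULL, bank = NULL) {
  C <- if (is.null(bank)) {
    binocular_correlation(stereogram, pop)
  } else {
    as.vector(correlation_batch(bank, as.vector(stereogram$left),
                                as.vector(stereogram$right)))
  }
  r <- if (noise) spike_counts(C, U = U, seed = seed) else U * (1 + C)
  r <- as.numeric(r)
  attr(r, "unit_key") <- population_key(pop)
  r
}

# Generate n stereograms at one disparity and return the population's
# Poisson spike counts as a units x trials matrix, all under one derived
# seed. Batching the trials through two matrix products is what keeps
# many-trial experiments cheap.
simulate_response_batch <- function(filters, dx, dy, n,
                                    polarity = "correlated", U = 1,
                                    seed = NULL, noise = TRUE) {
  npix <- filters$width * filters$height
  with_seed(seed, {
    IL <- matrix(NA_real_, npix, n)
    IR <- matrix(NA_real_, npix, n)
    for (k in seq_len(n)) {
      sg <- generate_stereogram(filters$width, filters$height, dx, dy,
                                polarity)
      IL[, k] <- as.vector(sg$left)
      IR[, k] <- as.vector(sg$right)
    }
    C <- correlation_batch(filters, IL, IR)
    if (!noise) return(U * (1 + C))
    lam <- pmax(U * (1 + C), 0)
    matrix(rpois(length(lam), lam), nrow = nrow(C))
  })
}
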