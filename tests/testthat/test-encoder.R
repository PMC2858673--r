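test_that("monocular responses are exact inner products", {
  pop <- mini_pop()
  sg <- generate_stereogram(41, 41, 1, -1, seed = 9)
  # blank stimulus: all outputs zero by linearity
  blank <- sg
  blank$left[] <- 0; blank$right[] <- 0
  v0 <- monocular_responses(blank, pop$simple_cells[1:6, ])
  expect_true(all(v0 == 0))
  # precomputed-bank evaluation agrees with direct per-cell evaluation
  v_direct <- monocular_responses(sg, pop$simple_cells)
  v_bank <- monocular_responses(sg, bank = mini_filters())
  expect_equal(v_bank, v_direct, tolerance = 1e-10)
})

test_that("C = 1 for stimuli matching the interocular transformation, -1 for the anticorrelated twin", {
  # zero-phase-disparity units across frequencies, matched integer shifts,
  # several seeds; includes a custom unit with non-zero vertical position
  # disparity
  cases <- list(
    list(sp = neuron_spec(0, 0.2, dx_enc = 3), d = c(3, 0)),
    list(sp = neuron_spec(30, 0.112, dx_enc = -5), d = c(-5, 0)),
    list(sp = neuron_spec(90, 0.0707, dx_enc = 8), d = c(8, 0)),
    list(sp = neuron_spec(-60, 0.042, dx_enc = 0), d = c(0, 0)),
    list(sp = neuron_spec(-30, 0.112, dx_enc = 2, dx_pos = 2, dy_pos = 4),
         d = c(2, 4)))
  for (cs in cases) for (seed in c(1, 2)) {
    sg <- generate_stereogram(81, 81, cs$d[1], cs$d[2], seed = seed)
    expect_equal(binocular_correlation(sg, cs$sp), 1, tolerance = 1e-6)
    sga <- generate_stereogram(81, 81, cs$d[1], cs$d[2],
                               polarity = "anticorrelated", seed = seed)
    expect_equal(binocular_correlation(sga, cs$sp), -1, tolerance = 1e-6)
  }
  # largest envelope (sigma = 10): border truncation perturbs the identity,
  # but only at the 1e-3 level
  sp <- neuron_spec(0, 0.025, dx_enc = 6)
  sg <- generate_stereogram(81, 81, 6, 0, seed = 1)
  expect_equal(binocular_correlation(sg, sp), 1, tolerance = 1e-3)
})

test_that("C is bounded, contrast-invariant and antisymmetric under anticorrelation", {
  pop <- mini_pop()
  units <- pop$complex_units
  for (seed in 1:3) {
    sg <- generate_stereogram(41, 41, -1, 2, seed = seed)
    C <- binocular_correlation(sg, units)
    expect_true(all(abs(C) <= 1 + 1e-12))
    # contrast scaling leaves the ratio unchanged
    sk <- sg; sk$left <- 3.7 * sk$left; sk$right <- 3.7 * sk$right
    expect_equal(binocular_correlation(sk, units), C, tolerance = 1e-12)
    # anticorrelated twin: B flips sign, M unchanged, so C flips exactly
    sa <- sg; sa$right <- -sa$right
    expect_equal(binocular_correlation(sa, units), -C, tolerance = 1e-12)
  }
})

test_that("M = 0 and zero-stimulus edge cases return neutral evidence", {
  sg <- generate_stereogram(41, 41, 0, 0, seed = 1)
  sg$left[] <- 0; sg$right[] <- 0
  C <- binocular_correlation(sg, mini_pop()$complex_units[1:5, ])
  expect_identical(C, rep(0, 5))
})

test_that("adding uniformly spaced phases beyond the quadrature pair leaves C unchanged", {
  sp <- neuron_spec(30, 0.2, dphi = pi / 4, dx_enc = 1)
  sg <- generate_stereogram(41, 41, 2, -1, seed = 6)
  C2 <- binocular_correlation(sg, sp, phi = c(0, pi / 2))
  C4 <- binocular_correlation(sg, sp, phi = pi * (0:3) / 4)
  expect_equal(C4, C2, tolerance = 1e-10)
})

test_that("spike counts are Poisson with mean U(1 + C)", {
  # C = -1: degenerate Poisson, every draw exactly zero
  expect_identical(spike_counts(rep(-1, 50), U = 1, seed = 1),
                   rep(0L, 50))
  # deterministic given seed
  expect_identical(spike_counts(rep(0.3, 10), seed = 4),
                   spike_counts(rep(0.3, 10), seed = 4))
  # C = 1, U = 1: sample mean 2 within 3 SE; CV ~ 1/sqrt(2)
  n <- 20000
  x2 <- spike_counts(rep(1, n), U = 1, seed = 2)
  expect_lt(abs(mean(x2) - 2), 3 * sqrt(2 / n))
  expect_lt(abs(sd(x2) / mean(x2) - 1 / sqrt(2)), 0.02)
  # C = 0, U = 1: mean 1, CV ~ 100%
  x1 <- spike_counts(rep(0, n), U = 1, seed = 3)
  expect_lt(abs(mean(x1) - 1), 3 * sqrt(1 / n))
  expect_lt(abs(sd(x1) / mean(x1) - 1), 0.03)
})

test_that("response vectors carry the population ordering key", {
  pop <- mini_pop()
  sg <- generate_stereogram(41, 41, 0, 0, seed = 1)
  r <- response_vector(sg, pop, seed = 1, bank = mini_filters())
  expect_length(r, nrow(pop$complex_units))
  expect_identical(attr(r, "unit_key"), population_key(pop))
  rn <- response_vector(sg, pop, noise = FALSE, bank = mini_filters())
  expect_true(all(rn >= 0 & rn <= 2))
})
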