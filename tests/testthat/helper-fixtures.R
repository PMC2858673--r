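# Shared, lazily built fixtures. The heavyweight objects (the full
# population's filter bank, the scaled-down template bank) are built once
# per test run and reused across files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

default_pop <- function() memo("pop", make_population)

default_filters <- function() {
  memo("filters", function()
    filter_bank(default_pop()$simple_cells, warn = FALSE))
}

# Scaled-down template bank: full 21x21 grid, 50 images per disparity.
ci_bank <- function() {
  memo("ci_bank", function()
    build_template_bank(default_pop(), n_images = 50, U = 1, seed = 1,
                        bank = default_filters()))
}

# Tiny population (single frequency/orientation subset) for cheap tests.
mini_pop <- function() {
  memo("mini_pop", function()
    make_population(theta = c(-30, 0, 30), f = c(0.2, 0.0707),
                    dphi = c(0, pi / 2), dx_enc = -3:3))
}

mini_filters <- function(width = 41, height = 41) {
  memo("mini_filters", function()
    filter_bank(mini_pop()$simple_cells, width, height, warn = FALSE))
}

# Small bank over a 7x7 grid on 41x41 images for decoder unit tests.
mini_bank <- function() {
  memo("mini_bank", function()
    build_template_bank(mini_pop(), dx_grid = -3:3, dy_grid = -3:3,
                        n_images = 30, U = 1, seed = 42,
                        width = 41, height = 41, bank = mini_filters()))
}

# Complex-unit parameter columns in the order binocular_correlation expects.
unit_cols <- c("theta", "f", "sigma", "dphi", "dx_enc", "dx_pos", "dy_pos")
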