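# Template bank: mean spike count per unit per candidate 2D disparity.
#
# The bank doubles as the decoder's synaptic-weight store: W(unit; dx, dy)
# is the strength of the connection from encoding unit `unit` onto the
# decoding unit tuned to (dx, dy).

#' Build the template bank
#'
#' For every disparity on the decoding grid, generates `n_images` fresh
#' correlated Gaussian-noise stereograms, computes each complex unit's
#' effective binocular correlation, and stores the noise-free mean spike
#' count `W = U (1 + mean C)`. Averaging over repeated presentations of one
#' image removes the Poisson noise exactly, so by default the Poisson
#' expectation is used directly rather than simulated
#' (`empirical_noise = TRUE` forces averaged Poisson draws for validation).
#' Image seeds derive from `seed` on a stream disjoint from the test-trial
#' stream used by [run_rms_experiment()], so test images are never template
#' images.
#'
#' @param pop a `disparity_population`.
#' @param dx_grid,dy_grid decoding-grid disparities in pixels (default
#'   -10..10, i.e. the standard 441-disparity grid).
#' @param n_images stereograms averaged per disparity (500 reproduces the
#'   reference simulations; 50 is the scaled-down profile, see
#'   [sim_profile()]).
#' @param U mean spikes for an uncorrelated stimulus.
#' @param seed master seed.
#' @param width,height stimulus size in pixels.
#' @param bank optional precomputed [filter_bank()] over
#'   `pop$simple_cells`; built (and discarded) internally if missing.
#' @param empirical_noise average `n_draws` Poisson draws per image instead
#'   of the analytic expectation.
#' @param n_draws Poisson draws per image when `empirical_noise`.
#' @param verbose print progress.
#' @return an object of class `"template_bank"`: list with matrix `W`
#'   (units x disparities, values in `[0, 2U]`), data frame `grid`
#'   (columns `dx`, `dy`, fastest-varying `dx`), `dx_grid`, `dy_grid`,
#'   `n_images`, `U`, `seed`, `width`, `height` and `unit_key`.
#' @export
build_template_bank <- function(pop, dx_grid = -10:10, dy_grid = -10:10,
                                n_images = 500, U = 1, seed = 1,
                                width = 81, height = 81, bank = NULL,
                                empirical_noise = FALSE, n_draws = 100,
                                verbose = FALSE) {
  stopifnot(length(dx_grid) >= 1, length(dy_grid) >= 1, n_images >= 1, U > 0)
  if (is.null(bank))
    bank <- filter_bank(pop$simple_cells, width, height, warn = FALSE)
  grid <- expand.grid(dx = dx_grid, dy = dy_grid, KEEP.OUT.ATTRS = FALSE)
  n_units <- nrow(pop$complex_units)
  npix <- width * height
  W <- matrix(NA_real_, n_units, nrow(grid))
  for (g in seq_len(nrow(grid))) {
    W[, g] <- with_seed(derive_seed(seed, 1L, g), {
      IL <- matrix(NA_real_, npix, n_images)
      IR <- matrix(NA_real_, npix, n_images)
      for (k in seq_len(n_images)) {
        sg <- generate_stereogram(width, height, grid$dx[g], grid$dy[g])
        IL[, k] <- as.vector(sg$left)
        IR[, k] <- as.vector(sg$right)
      }
      C <- correlation_batch(bank, IL, IR)
      if (empirical_noise) {
        lam <- pmax(U * (1 + C), 0)
        draws <- matrix(rpois(length(lam) * n_draws, rep(lam, n_draws)),
                        nrow = length(lam))
        rowMeans(matrix(rowMeans(draws), nrow = n_units))
      } else {
        U * (1 + rowMeans(C))
      }
    })
    if (verbose && g %% 25 == 0)
      message(sprintf("template bank: %d / %d disparities", g, nrow(grid)))
  }
  structure(
    list(W = W, grid = grid, dx_grid = dx_grid, dy_grid = dy_grid,
         n_images = n_images, U = U, seed = seed,
         width = width, height = height, unit_key = population_key(pop)),
    class = "template_bank")
}

#' @export
print.template_bank <- function(x, ...) {
  cat(sprintf(paste0(
    "<template_bank: %d units x %d disparities ",
    "(dx %d..%d, dy %d..%d), %d images/disparity, U = %g>\n"),
    nrow(x$W), nrow(x$grid), min(x$dx_grid), max(x$dx_grid),
    min(x$dy_grid), max(x$dy_grid), x$n_images, x$U))
  invisible(x)
}

#' Index of a disparity in the bank grid
#'
#' @param bank a `template_bank`.
#' @param dx,dy disparity in pixels.
#' @return integer column index into `bank$W`.
#' @export
grid_index <- function(bank, dx, dy) {
  i <- which(bank$grid$dx == dx & bank$grid$dy == dy)
  if (length(i) != 1)
    stop(sprintf("disparity (%g, %g) is not on the bank grid", dx, dy))
  i
}

#' Slice the mean population response at one stimulus disparity
#'
#' Extracts, for one phase disparity and one template stimulus disparity,
#' the mean spike counts arranged as orientation x preferred-horizontal-
#' disparity matrices, one per spatial-frequency channel — the standard
#' population-response map. For a stimulus with non-zero vertical disparity
#' the high-response region slants across orientation, with the slant
#' direction given by the sign of the vertical disparity; that slant is the
#' population signature the decoder reads out.
#'
#' @param bank a `template_bank`.
#' @param pop the `disparity_population` the bank was built from.
#' @param dx_stim,dy_stim template stimulus disparity (must be on the grid).
#' @param dphi phase disparity of the sub-population to display (must be
#'   one of the population's values).
#' @return named list of matrices (rows = orientations, columns = preferred
#'   horizontal disparities), one per frequency, with dimnames.
#' @export
template_slice <- function(bank, pop, dx_stim, dy_stim, dphi = 0) {
  if (!any(abs(pop$params$dphi - dphi) < 1e-9))
    stop("dphi = ", dphi, " is not in the population")
  if (!identical(bank$unit_key, population_key(pop)))
    stop("template bank was built for a different population ordering")
  g <- grid_index(bank, dx_stim, dy_stim)
  cu <- pop$complex_units
  out <- list()
  for (fv in pop$params$f) {
    sel <- which(abs(cu$f - fv) < 1e-9 & abs(cu$dphi - dphi) < 1e-9)
    sub <- cu[sel, ]
    m <- matrix(NA_real_, length(pop$params$theta),
                length(pop$params$dx_enc),
                dimnames = list(pop$params$theta, pop$params$dx_enc))
    m[cbind(match(sub$theta, pop$params$theta),
            match(sub$dx_enc, pop$params$dx_enc))] <- bank$W[sel, g]
    out[[sprintf("f=%g", fv)]] <- m
  }
  out
}

#' Per-unit 2D disparity tuning surface stored in the bank
#'
#' A complex unit's row of `W`, reshaped over the decoding grid: its mean
#' spike count as a function of 2D stimulus disparity.
#'
#' @param bank a `template_bank`.
#' @param unit complex-unit index.
#' @return matrix (rows = `dx_grid`, columns = `dy_grid`).
#' @export
unit_tuning_surface <- function(bank, unit) {
  matrix(bank$W[unit, ], length(bank$dx_grid), length(bank$dy_grid),
         dimnames = list(bank$dx_grid, bank$dy_grid))
}

#' Persist / restore a template bank
#'
#' Saves the bank (weights, grid, seeds, unit-ordering key) as a native RDS
#' container. [pearson_map()] refuses to decode against a bank whose unit
#' ordering does not match the population.
#'
#' @param bank a `template_bank`.
#' @param path file path.
#' @return `read_template_bank` returns the bank; `write_template_bank`
#'   returns `path` invisibly.
#' @export
write_template_bank <- function(bank, path) {
  stopifnot(inherits(bank, "template_bank"))
  saveRDS(bank, path)
  invisible(path)
}

#' @rdname write_template_bank
#' @export
read_template_bank <- function(path) {
  bank <- readRDS(path)
  if (!inherits(bank, "template_bank"))
    stop("file does not contain a template bank")
  bank
}
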