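# Template-matching decoder: half-wave-rectified Pearson correlation
# between a single-trial response vector and the stored templates.

#' Pearson correlation map between a response and the template bank
#'
#' For each candidate disparity, the Pearson product-moment correlation
#' over the population's units between the single-trial spike counts and
#' the stored mean counts `W`. If either vector has zero variance the
#' correlation is defined as 0 (it cannot favour any template). The
#' response's unit-ordering key (attached by [response_vector()]) is
#' checked against the bank when present.
#'
#' @param spikes numeric vector of length `nrow(bank$W)` (a single-trial
#'   response, typically spike counts).
#' @param bank a `template_bank`.
#' @return matrix of Pearson coefficients in [-1, 1]
#'   (rows = `dx_grid`, columns = `dy_grid`).
#' @export
pearson_map <- function(spikes, bank) {
  key <- attr(spikes, "unit_key")
  if (!is.null(key) && !identical(key, bank$unit_key))
    stop("response vector and template bank use different unit orderings")
  if (length(spikes) != nrow(bank$W))
    stop("response vector length does not match the bank's unit count")
  r <- if (sd(spikes) == 0) {
    rep(0, nrow(bank$grid))
  } else {
    suppressWarnings(as.vector(cor(as.numeric(spikes), bank$W)))
  }
  r[!is.finite(r)] <- 0   # zero-variance template columns
  matrix(r, length(bank$dx_grid), length(bank$dy_grid),
         dimnames = list(bank$dx_grid, bank$dy_grid))
}

# Pearson correlations of many trial columns against all templates:
# trials x disparities matrix with zero-variance rows/columns mapped to 0.
pearson_block <- function(spikes, bank) {
  r <- suppressWarnings(cor(spikes, bank$W))
  r[!is.finite(r)] <- 0
  r
}

# Argmax of the rectified map for one trial (r as a vector over the bank
# grid): deterministic tie-breaking shared by every decoding path.
argmax_estimate <- function(r, bank) {
  P <- pmax(r, 0)
  max_P <- max(P)
  tie <- which(P >= max_P - 1e-12)
  ties <- data.frame(dx = bank$grid$dx[tie], dy = bank$grid$dy[tie])
  ties <- ties[order(ties$dx^2 + ties$dy^2, ties$dy, ties$dx), ,
               drop = FALSE]
  list(dx = ties$dx[1], dy = ties$dy[1], max_P = max_P,
       degenerate = (max_P <= 0 || nrow(ties) > 1), ties = ties)
}

#' Estimate 2D stimulus disparity by template matching
#'
#' Half-wave rectifies the Pearson map (`P = max(r, 0)`) and returns the
#' disparity attaining the maximum of `P`. Rectification means
#' anticorrelated stereograms — whose Pearson correlations with the stored
#' correlated templates are almost always negative — drive no decoder
#' response at all. A trial is flagged `degenerate` when the maximum of `P`
#' is 0 or several disparities tie for the maximum; such trials carry no
#' confident estimate and are reported (and excluded from error statistics
#' by default in [run_rms_experiment()]) rather than silently resolved.
#' Ties are broken deterministically: smallest `dx^2 + dy^2`, then
#' lexicographically by `(dy, dx)`.
#'
#' @param spikes single-trial response vector.
#' @param bank a `template_bank`.
#' @return object of class `"disparity_estimate"`: list with `dx`, `dy`,
#'   `r_map`, `P_map` (matrices, rows = `dx_grid`), `max_P`, `degenerate`,
#'   and `ties` (data frame of disparities sharing the maximum).
#' @export
estimate_disparity <- function(spikes, bank) {
  r_map <- pearson_map(spikes, bank)
  est <- argmax_estimate(as.vector(r_map), bank)
  structure(
    c(est[c("dx", "dy")],
      list(r_map = r_map, P_map = pmax(r_map, 0)),
      est[c("max_P", "degenerate", "ties")]),
    class = "disparity_estimate")
}

#' @export
print.disparity_estimate <- function(x, ...) {
  cat(sprintf("<disparity estimate (%g, %g), max P = %.3f%s>\n",
              x$dx, x$dy, x$max_P,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Disparity tuning surface of one decoding unit
#'
#' Mean half-wave-rectified response `<P(dx_dec, dy_dec)>` of the decoding
#' unit tuned to `target`, averaged over `n_images` noisy test trials at
#' each test disparity. For correlated stimuli the surface is isotropic and
#' peaks where the test disparity matches the decoder's preferred
#' disparity; for anticorrelated stimuli it is nearly flat at zero.
#'
#' @param bank a `template_bank`.
#' @param pop the matching `disparity_population`.
#' @param target `c(dx, dy)` preferred disparity of the decoding unit
#'   (must be on the bank grid).
#' @param test_dx,test_dy test-stimulus disparities to probe.
#' @param n_images test trials per disparity (>= 1).
#' @param polarity stimulus polarity.
#' @param U mean spikes for an uncorrelated stimulus.
#' @param seed master seed.
#' @param filters optional `filter_bank` over `pop$simple_cells`.
#' @param noise draw Poisson spikes (`TRUE`, the default) or correlate the
#'   noise-free mean rates (stimulus-driven variability only).
#' @return matrix of mean rectified responses
#'   (rows = `test_dx`, columns = `test_dy`).
#' @export
decoder_tuning_surface <- function(bank, pop, target,
                                   test_dx = bank$dx_grid,
                                   test_dy = bank$dy_grid,
                                   n_images = 40,
                                   polarity = c("correlated",
                                                "anticorrelated"),
                                   U = bank$U, seed = NULL, filters = NULL,
                                   noise = TRUE) {
  polarity <- match.arg(polarity)
  stopifnot(n_images >= 1)
  gi <- grid_index(bank, target[1], target[2])
  if (is.null(filters))
    filters <- filter_bank(pop$simple_cells, bank$width, bank$height,
                           warn = FALSE)
  if (!identical(bank$unit_key, population_key(pop)))
    stop("template bank was built for a different population ordering")
  w <- bank$W[, gi]
  w_ok <- sd(w) > 0
  surf <- matrix(NA_real_, length(test_dx), length(test_dy),
                 dimnames = list(test_dx, test_dy))
  for (iy in seq_along(test_dy)) for (ix in seq_along(test_dx)) {
    s <- if (is.null(seed)) NULL else
      derive_seed(seed, 4L, (iy - 1L) * length(test_dx) + ix)
    spikes <- simulate_response_batch(filters, test_dx[ix], test_dy[iy],
                                      n_images, polarity, U, s,
                                      noise = noise)
    r <- if (w_ok) suppressWarnings(as.vector(cor(spikes, w))) else
      rep(0, n_images)
    r[!is.finite(r)] <- 0
    surf[ix, iy] <- mean(pmax(r, 0))
  }
  surf
}
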