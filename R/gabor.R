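# Gabor receptive fields.
#
# A binocular simple cell has one Gabor per eye, identical in orientation,
# frequency and envelope size but differing in carrier phase and centre:
#
#   left  eye: centre -(dx_pos, dy_pos)/2, carrier phase phi + dphi/2
#   right eye: centre +(dx_pos, dy_pos)/2, carrier phase phi - dphi/2
#
# With the stimulus convention I_R(x, y) = I_L(x - dx, y - dy), a correlated
# stereogram whose disparity equals the unit's position disparity (and
# dphi = 0) maps the right receptive field exactly onto the left one, so
# v_L = v_R for every image and the effective binocular correlation is 1.

#' Evaluate a binocular simple cell's Gabor receptive field in one eye
#'
#' Isotropic Gaussian envelope (s.d. `sigma`) multiplied by a cosine carrier
#' of frequency `f` along the axis orthogonal to the preferred orientation
#' `theta` (degrees from vertical). The eye determines the sign of the
#' half-offsets of centre and carrier phase (see file header). Half-pixel
#' centres are unproblematic: the Gabor is a continuous function evaluated
#' at pixel centres.
#'
#' @param spec one-row data frame as from [neuron_spec()].
#' @param eye `"left"` or `"right"`.
#' @param width,height support size in pixels; the field is evaluated over
#'   the full grid with no windowing beyond the Gaussian envelope.
#' @param warn warn when the support does not contain +/- 4 sigma around the
#'   centre (edge truncation then perturbs the exact matched-unit identity
#'   at roughly the envelope's border amplitude).
#' @return matrix of weights (rows = y, columns = x).
#' @export
gabor_rf <- function(spec, eye = c("left", "right"),
                     width = 81, height = 81, warn = TRUE) {
  eye <- match.arg(eye)
  stopifnot(nrow(spec) == 1)
  sgn <- if (eye == "left") -1 else 1
  cx <- sgn * spec$dx_pos / 2
  cy <- sgn * spec$dy_pos / 2
  phase <- spec$phi - sgn * spec$dphi / 2
  if (warn &&
      (abs(cx) + 4 * spec$sigma > (width - 1) / 2 ||
       abs(cy) + 4 * spec$sigma > (height - 1) / 2))
    warning("support does not contain 4 sigma around the RF centre; ",
            "the envelope is truncated at the image border")
  x <- image_coords(width)
  y <- image_coords(height)
  th <- spec$theta * pi / 180
  dxm <- matrix(x, height, width, byrow = TRUE) - cx
  dym <- matrix(y, height, width) - cy
  env <- exp(-(dxm^2 + dym^2) / (2 * spec$sigma^2))
  carrier <- cos(2 * pi * spec$f * (dxm * cos(th) + dym * sin(th)) + phase)
  env * carrier
}

#' Precompute receptive-field weight matrices for a set of simple cells
#'
#' Evaluates every cell's left- and right-eye Gabor over the image grid and
#' stacks them as rows, so that monocular responses to a batch of images are
#' two matrix products (`L %*% images`, `R %*% images`). For the default
#' 6300-cell population on 81x81 images each matrix is 6300 x 6561 (~330 MB
#' per eye); build it once and reuse it.
#'
#' @param cells simple-cell data frame (e.g. `pop$simple_cells`, or a subset
#'   of its rows — keep the two phases of each complex unit adjacent if the
#'   result is passed to [correlation_batch()]).
#' @param width,height image size in pixels.
#' @param warn warn once if any envelope is truncated by the border.
#' @return an object of class `"filter_bank"`: list with matrices `L`, `R`
#'   (cells x pixels, pixel order matching `as.vector(image)`), the `cells`
#'   table, `width`, `height`.
#' @export
filter_bank <- function(cells, width = 81, height = 81, warn = TRUE) {
  n <- nrow(cells)
  npix <- width * height
  L <- matrix(NA_real_, n, npix)
  R <- matrix(NA_real_, n, npix)
  if (warn && any(abs(cells$dx_pos) / 2 + 4 * cells$sigma > (width - 1) / 2 |
                  abs(cells$dy_pos) / 2 + 4 * cells$sigma > (height - 1) / 2))
    warning("some receptive-field envelopes are truncated at the image ",
            "border (support smaller than 4 sigma around the centre)")
  for (i in seq_len(n)) {
    L[i, ] <- as.vector(gabor_rf(cells[i, ], "left", width, height,
                                 warn = FALSE))
    R[i, ] <- as.vector(gabor_rf(cells[i, ], "right", width, height,
                                 warn = FALSE))
  }
  structure(list(L = L, R = R, cells = cells, width = width, height = height),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank: %d simple cells on %dx%d pixels>\n",
              nrow(x$L), x$width, x$height))
  invisible(x)
}
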