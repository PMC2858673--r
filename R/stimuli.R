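# Gaussian-noise stereogram generation.
#
# Conventions (shared with the receptive-field code):
#   * x increases rightward, y increases upward, origin at the image centre;
#     matrix element [i, j] holds the pixel at x = j - (width+1)/2,
#     y = i - (height+1)/2.
#   * A feature at position p in the left image appears at p + (dx, dy) in
#     the right image; equivalently I_R(x, y) = I_L(x - dx, y - dy) on the
#     overlap region.

#' Pixel coordinates of an image axis
#'
#' Integer coordinates centred on zero: for an 81-pixel axis, -40..40.
#'
#' @param n number of pixels.
#' @return numeric vector of length `n`.
#' @export
image_coords <- function(n) {
  seq_len(n) - (n + 1) / 2
}

#' Generate a uniform-disparity Gaussian-noise stereogram
#'
#' The left image is i.i.d. standard-normal contrast noise (zero mean, unit
#' s.d., relative to mean luminance). The right image is the left image
#' shifted by the integer disparity `(dx, dy)`; pixels that the shift leaves
#' without a partner ("the gap") are filled with fresh independent noise.
#' For `polarity = "anticorrelated"` the right image is contrast-inverted
#' (multiplied by -1), modelling anticorrelated stereograms.
#'
#' @param width,height image size in pixels (default 81, as in the
#'   simulations the model is calibrated for).
#' @param dx,dy integer horizontal / vertical disparity in pixels. Must be
#'   smaller in magnitude than the corresponding image extent, otherwise no
#'   overlap remains to carry the disparity signal.
#' @param polarity `"correlated"` or `"anticorrelated"`.
#' @param seed integer seed making the pair reproducible, or `NULL` to draw
#'   from the current RNG stream.
#' @return an object of class `"stereogram"`: a list with matrices `left`
#'   and `right` (rows = y, columns = x), and fields `dx`, `dy`, `polarity`,
#'   `seed`, `width`, `height`.
#' @examples
#' sg <- generate_stereogram(81, 81, dx = 2, dy = 1, seed = 1)
#' # overlap region of right image is an exact copy of the shifted left image
#' all.equal(sg$right[2:81, 3:81], sg$left[1:80, 1:79])
#' @export
generate_stereogram <- function(width = 81, height = 81, dx = 0, dy = 0,
                                polarity = c("correlated", "anticorrelated"),
                                seed = NULL) {
  polarity <- match.arg(polarity)
  stopifnot(width >= 1, height >= 1,
            dx == round(dx), dy == round(dy))
  dx <- as.integer(dx); dy <- as.integer(dy)
  if (abs(dx) >= width || abs(dy) >= height)
    stop("disparity magnitude must be smaller than the image extent ",
         "(no overlap would remain)")

  with_seed(seed, {
    left <- matrix(rnorm(height * width), nrow = height, ncol = width)
    right <- shift_image(left, dx, dy)
    gap <- is.na(right)
    right[gap] <- rnorm(sum(gap))
    if (polarity == "anticorrelated") right <- -right
    structure(
      list(left = left, right = right, dx = dx, dy = dy,
           polarity = polarity, seed = seed, width = width, height = height),
      class = "stereogram")
  })
}

#' Shift an image by an integer 2D displacement
#'
#' Returns the image a correlated right eye would see given left image
#' `img`: `out[x, y] = img[x - dx, y - dy]`, with `NA` where the source
#' pixel falls outside the image. This is the module's own shift operator;
#' composing it with [generate_stereogram()] recovers the left image on the
#' overlap exactly.
#'
#' @param img matrix (rows = y, columns = x).
#' @param dx,dy integer shift in pixels.
#' @return matrix of the same shape with `NA` outside the overlap.
#' @export
shift_image <- function(img, dx, dy) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(NA_real_, h, w)
  # destination rows i take source rows i - dy; likewise columns
  di <- seq_len(h); si <- di - dy
  dj <- seq_len(w); sj <- dj - dx
  keep_i <- si >= 1 & si <= h
  keep_j <- sj >= 1 & sj <= w
  out[di[keep_i], dj[keep_j]] <- img[si[keep_i], sj[keep_j]]
  out
}

#' @export
print.stereogram <- function(x, ...) {
  cat(sprintf("<stereogram %dx%d, disparity (%d, %d), %s%s>\n",
              x$width, x$height, x$dx, x$dy, x$polarity,
              if (is.null(x$seed)) "" else paste0(", seed ", x$seed)))
  invisible(x)
}
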