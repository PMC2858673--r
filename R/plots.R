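# Figure rendering. Spike-count maps use a jet-style palette; Pearson
# correlation maps use a hot-style palette, mirroring the convention that
# the two correlations must not be confused.

jet_colors <- function(n = 64) {
  colorRampPalette(c("#00007F", "blue", "#007FFF", "cyan", "#7FFF7F",
                     "yellow", "#FF7F00", "red", "#7F0000"))(n)
}

hot_colors <- function(n = 64) {
  colorRampPalette(c("black", "red", "yellow", "white"))(n)
}

#' Plot a disparity-indexed surface
#'
#' Pseudocolour image of a matrix whose rows/columns are indexed by
#' disparities (as produced by [unit_tuning_surface()],
#' [empirical_peak()]`$surface`, [decoder_tuning_surface()] or
#' [pearson_map()]), with x = horizontal and y = vertical disparity.
#'
#' @param surface matrix with disparity dimnames (rows = dx, cols = dy).
#' @param palette `"jet"` (spike counts) or `"hot"` (Pearson correlation).
#' @param main title.
#' @param mark optional `c(dx, dy)` to mark with a cross.
#' @param zlim colour range.
#' @return invisibly, the surface.
#' @export
plot_disparity_surface <- function(surface, palette = c("jet", "hot"),
                                   main = "", mark = NULL, zlim = NULL) {
  palette <- match.arg(palette)
  dxs <- as.numeric(rownames(surface))
  dys <- as.numeric(colnames(surface))
  cols <- if (palette == "jet") jet_colors() else hot_colors()
  if (is.null(zlim)) zlim <- range(surface)
  image(dxs, dys, surface, col = cols, zlim = zlim,
        xlab = "horizontal disparity (pixels)",
        ylab = "vertical disparity (pixels)", main = main, useRaster = TRUE)
  if (!is.null(mark))
    points(mark[1], mark[2], pch = 3, col = "white", lwd = 2, cex = 1.5)
  box()
  invisible(surface)
}

#' Plot population-response maps per frequency channel
#'
#' One panel per spatial-frequency channel showing response (mean spike
#' count or single-trial spikes) over preferred horizontal disparity
#' (x-axis) and orientation (y-axis), as returned by [template_slice()].
#'
#' @param slices named list of orientation x dx_enc matrices.
#' @param main overall title.
#' @param mark_dx optional stimulus horizontal disparity to mark.
#' @param zlim shared colour range (default: range over all panels).
#' @return invisibly, `slices`.
#' @export
plot_population_response <- function(slices, main = "", mark_dx = NULL,
                                     zlim = NULL) {
  if (is.null(zlim)) zlim <- range(unlist(slices))
  old <- par(mfrow = c(1, length(slices)), mar = c(4, 4, 3, 1))
  on.exit(par(old))
  for (nm in names(slices)) {
    m <- slices[[nm]]
    dxe <- as.numeric(colnames(m))
    th <- as.numeric(rownames(m))
    image(dxe, seq_along(th), t(m), col = jet_colors(), zlim = zlim,
          xlab = "preferred horizontal disparity (pixels)",
          ylab = "orientation (deg)", main = nm, yaxt = "n",
          useRaster = TRUE)
    axis(2, at = seq_along(th), labels = th)
    if (!is.null(mark_dx))
      points(mark_dx, 0.6, pch = 17, col = "white", cex = 1.2)
    box()
  }
  mtext(main, outer = TRUE, line = -1.5)
  invisible(slices)
}

#' Render the standard encoder/decoder figures to files
#'
#' Writes PNG files illustrating the simulation: per-unit disparity tuning
#' surfaces with empirical-peak markers (`"tuning"`), mean population
#' response maps for a range of stimulus vertical disparities (`"maps"`),
#' and a single-trial spike-count map (`"trial"`). An empty `which` renders
#' nothing and succeeds.
#'
#' @param pop a `disparity_population`.
#' @param bank a matching `template_bank` (its grid supplies the stimulus
#'   disparities shown).
#' @param dir output directory (created if needed).
#' @param which subset of `c("tuning", "maps", "trial")`.
#' @param units complex-unit indices for `"tuning"` panels.
#' @param dx_stim,dy_stim stimulus disparities for `"maps"` (each `dy` is
#'   one file) and `"trial"`.
#' @param seed seed for the single-trial figure.
#' @return character vector of files written.
#' @export
render_encoder_figures <- function(pop, bank, dir = tempdir(),
                                   which = c("tuning", "maps", "trial"),
                                   units = NULL,
                                   dx_stim = -2, dy_stim = c(2, 0, -2),
                                   seed = 1) {
  which <- intersect(which, c("tuning", "maps", "trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  if ("tuning" %in% which) {
    if (is.null(units))
      units <- unit_index(pop, theta = 30, f = pop$params$f[3],
                          dx_enc = min(6, max(pop$params$dx_enc)))
    for (u in units) {
      surf <- unit_tuning_surface(bank, u)
      peak <- arrayInd(which.max(surf), dim(surf))
      fn <- file.path(dir, sprintf("tuning_unit%04d.png", u))
      png(fn, 480, 480)
      plot_disparity_surface(
        surf, "jet",
        main = sprintf("unit %d: theta=%g f=%g dphi=%.2f dx_enc=%g", u,
                       pop$complex_units$theta[u], pop$complex_units$f[u],
                       pop$complex_units$dphi[u],
                       pop$complex_units$dx_enc[u]),
        mark = c(bank$dx_grid[peak[1]], bank$dy_grid[peak[2]]))
      dev.off()
      files <- c(files, fn)
    }
  }
  if ("maps" %in% which) {
    for (dy in dy_stim) {
      sl <- template_slice(bank, pop, dx_stim, dy, dphi = 0)
      fn <- file.path(dir, sprintf("population_map_dy%+d.png", dy))
      png(fn, 240 * length(sl), 300)
      plot_population_response(
        sl, main = sprintf("stimulus disparity (%g, %g)", dx_stim, dy),
        mark_dx = dx_stim)
      dev.off()
      files <- c(files, fn)
    }
  }
  if ("trial" %in% which) {
    sg <- generate_stereogram(bank$width, bank$height, dx_stim, dy_stim[1],
                              seed = derive_seed(seed, 5L, 1L))
    spk <- response_vector(sg, pop, U = bank$U,
                           seed = derive_seed(seed, 5L, 2L))
    sl <- list()
    cu <- pop$complex_units
    for (fv in pop$params$f) {
      sel <- which(abs(cu$f - fv) < 1e-9 & abs(cu$dphi) < 1e-9)
      m <- matrix(NA_real_, length(pop$params$theta),
                  length(pop$params$dx_enc),
                  dimnames = list(pop$params$theta, pop$params$dx_enc))
      m[cbind(match(cu$theta[sel], pop$params$theta),
              match(cu$dx_enc[sel], pop$params$dx_enc))] <- spk[sel]
      sl[[sprintf("f=%g", fv)]] <- m
    }
    fn <- file.path(dir, "single_trial_spikes.png")
    png(fn, 240 * length(sl), 300)
    plot_population_response(
      sl, main = sprintf("single trial, stimulus (%g, %g)",
                         dx_stim, dy_stim[1]), mark_dx = dx_stim)
    dev.off()
    files <- c(files, fn)
  }
  files
}
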