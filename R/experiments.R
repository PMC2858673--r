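# Decoding experiments: accuracy statistics and simulation profiles.

#' Named simulation profiles
#'
#' Two problem-size profiles: `"paper"` (500 template images per disparity,
#' 1000 test trials per condition, 40 images per point of a decoder tuning
#' surface — the full reference configuration) and `"ci"` (50 / 200 / 10, a
#' scaled-down profile that reproduces the qualitative results and the
#' headline error bounds at a fraction of the cost).
#'
#' @param name `"ci"` or `"paper"`.
#' @return list with `n_template_images`, `n_test`, `n_surface_images`.
#' @export
sim_profile <- function(name = c("ci", "paper")) {
  name <- match.arg(name)
  switch(name,
         ci    = list(name = "ci", n_template_images = 50, n_test = 200,
                      n_surface_images = 10),
         paper = list(name = "paper", n_template_images = 500, n_test = 1000,
                      n_surface_images = 40))
}

#' Decoding-accuracy experiment over a set of test disparities
#'
#' For each requested test disparity, generates `n_test` fresh noisy test
#' trials (stereogram, Poisson spike counts, template-matching estimate)
#' and summarises the estimation error per component. Test-image seeds are
#' drawn from a stream disjoint from the template-image stream. Degenerate
#' trials (zero or tied maximum rectified Pearson response) are excluded
#' from the RMS by default and reported as a failure count;
#' `include_degenerate = TRUE` includes their tie-broken estimates instead.
#'
#' @param pop a `disparity_population`.
#' @param bank a matching `template_bank`.
#' @param test_disparities data frame with columns `dx`, `dy` (pixels).
#' @param n_test trials per condition.
#' @param U mean spikes for an uncorrelated stimulus.
#' @param polarity stimulus polarity for the test trials.
#' @param seed master seed.
#' @param filters optional `filter_bank` over `pop$simple_cells`.
#' @param include_degenerate include degenerate trials in the RMS.
#' @return object of class `"rms_experiment"`: list with `summary` (one row
#'   per condition: `dx`, `dy`, `n`, `n_degenerate`, `rms_dx`, `rms_dy`,
#'   `rms_max`, `rms_2d`), `trials` (per-trial data frame: condition,
#'   estimate, `max_P`, `degenerate`), `n_test`, `U`, `seed`,
#'   `include_degenerate`.
#' @export
run_rms_experiment <- function(pop, bank, test_disparities, n_test = 200,
                               U = bank$U,
                               polarity = c("correlated", "anticorrelated"),
                               seed = 1, filters = NULL,
                               include_degenerate = FALSE) {
  polarity <- match.arg(polarity)
  stopifnot(is.data.frame(test_disparities),
            all(c("dx", "dy") %in% names(test_disparities)), n_test >= 1)
  if (!identical(bank$unit_key, population_key(pop)))
    stop("template bank was built for a different population ordering")
  if (is.null(filters))
    filters <- filter_bank(pop$simple_cells, bank$width, bank$height,
                           warn = FALSE)

  trials <- vector("list", nrow(test_disparities))
  for (cond in seq_len(nrow(test_disparities))) {
    dx <- test_disparities$dx[cond]
    dy <- test_disparities$dy[cond]
    spikes <- simulate_response_batch(filters, dx, dy, n_test, polarity,
                                      U, derive_seed(seed, 2L, cond))
    r <- pearson_block(spikes, bank)
    est <- lapply(seq_len(n_test),
                  function(k) argmax_estimate(r[k, ], bank))
    trials[[cond]] <- data.frame(
      dx = dx, dy = dy, trial = seq_len(n_test),
      est_dx = vapply(est, `[[`, numeric(1), "dx"),
      est_dy = vapply(est, `[[`, numeric(1), "dy"),
      max_P = vapply(est, `[[`, numeric(1), "max_P"),
      degenerate = vapply(est, `[[`, logical(1), "degenerate"))
  }
  trials <- do.call(rbind, trials)

  summarise_cond <- function(d) {
    use <- if (include_degenerate) rep(TRUE, nrow(d)) else !d$degenerate
    rms <- function(err) if (any(use)) sqrt(mean(err[use]^2)) else NA_real_
    rdx <- rms(d$est_dx - d$dx); rdy <- rms(d$est_dy - d$dy)
    data.frame(dx = d$dx[1], dy = d$dy[1], n = nrow(d),
               n_degenerate = sum(d$degenerate),
               rms_dx = rdx, rms_dy = rdy,
               rms_max = max(rdx, rdy),
               rms_2d = if (any(use))
                 sqrt(mean((d$est_dx - d$dx)[use]^2 +
                             (d$est_dy - d$dy)[use]^2)) else NA_real_)
  }
  summary <- do.call(rbind, lapply(
    split(trials, list(trials$dx, trials$dy), drop = TRUE), summarise_cond))
  summary <- summary[order(match(paste(summary$dx, summary$dy),
                                 paste(test_disparities$dx,
                                       test_disparities$dy))), ]
  rownames(summary) <- NULL

  structure(list(summary = summary, trials = trials, n_test = n_test,
                 U = U, seed = seed, polarity = polarity,
                 include_degenerate = include_degenerate),
            class = "rms_experiment")
}

#' @export
print.rms_experiment <- function(x, ...) {
  cat(sprintf("<rms_experiment: %d conditions x %d trials (seed %d, %s)>\n",
              nrow(x$summary), x$n_test, x$seed, x$polarity))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Frequency histogram of estimated disparity components
#'
#' Counts of estimated values per component for one condition — the data
#' behind per-condition estimate histograms.
#'
#' @param experiment an `rms_experiment`.
#' @param dx,dy the condition.
#' @return list of two tables, `est_dx` and `est_dy`.
#' @export
estimate_histograms <- function(experiment, dx, dy) {
  d <- experiment$trials[experiment$trials$dx == dx &
                           experiment$trials$dy == dy, ]
  if (nrow(d) == 0) stop("no trials for condition (", dx, ", ", dy, ")")
  list(est_dx = table(d$est_dx), est_dy = table(d$est_dy))
}
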