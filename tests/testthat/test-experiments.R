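test_that("simulation profiles expose the two problem sizes", {
  ci <- sim_profile("ci")
  expect_equal(ci$n_template_images, 50)
  expect_equal(ci$n_test, 200)
  paper <- sim_profile("paper")
  expect_equal(paper$n_template_images, 500)
  expect_equal(paper$n_test, 1000)
  expect_equal(paper$n_surface_images, 40)
})

test_that("RMS experiments summarise per-component accuracy and failures", {
  pop <- mini_pop(); bank <- mini_bank()
  # a generous spike budget makes the reduced fixture decode reliably
  ex <- run_rms_experiment(pop, bank,
                           data.frame(dx = c(0, -1), dy = c(0, 1)),
                           n_test = 25, U = 20, seed = 11,
                           filters = mini_filters())
  expect_s3_class(ex, "rms_experiment")
  expect_equal(nrow(ex$summary), 2)
  expect_equal(ex$summary$n, c(25, 25))
  expect_true(all(c("rms_dx", "rms_dy", "rms_max", "n_degenerate")
                  %in% names(ex$summary)))
  # horizontal disparity of a matched (dy = 0) stimulus decodes sharply
  expect_lte(ex$summary$rms_dx[1], 0.5)
  expect_lte(ex$summary$rms_max[1], 1)
  expect_equal(nrow(ex$trials), 50)
  # rms_max is the conservative per-component maximum
  expect_equal(ex$summary$rms_max, pmax(ex$summary$rms_dx,
                                        ex$summary$rms_dy))
  # reproducible given the seed
  ex2 <- run_rms_experiment(pop, bank,
                            data.frame(dx = c(0, -1), dy = c(0, 1)),
                            n_test = 25, U = 20, seed = 11,
                            filters = mini_filters())
  expect_identical(ex$summary, ex2$summary)
  h <- estimate_histograms(ex, 0, 0)
  expect_equal(sum(h$est_dx), 25)
})

test_that("degenerate trials are excluded from RMS but counted, unless included", {
  # a near-zero spike budget silences most units, so many trials have a
  # constant (all-zero) response vector and carry no estimate
  pop <- mini_pop(); bank <- mini_bank()
  exa <- run_rms_experiment(pop, bank, data.frame(dx = 0, dy = 0),
                            n_test = 20, U = 0.01, seed = 13,
                            filters = mini_filters())
  expect_gte(exa$summary$n_degenerate, 1)
  expect_equal(exa$summary$n_degenerate, sum(exa$trials$degenerate))
  exb <- run_rms_experiment(pop, bank, data.frame(dx = 0, dy = 0),
                            n_test = 20, U = 0.01, seed = 13,
                            filters = mini_filters(),
                            include_degenerate = TRUE)
  expect_false(is.na(exb$summary$rms_dx))
  # tie-broken degenerate estimates change the error statistic
  expect_false(identical(exa$summary$rms_dx, exb$summary$rms_dx))
})

test_that("figure rendering writes the requested files", {
  pop <- mini_pop(); bank <- mini_bank()
  dir <- withr::local_tempdir()
  files <- render_encoder_figures(pop, bank, dir = dir,
                                  which = c("maps", "trial"),
                                  dx_stim = -2, dy_stim = c(2, 0))
  expect_true(all(file.exists(files)))
  expect_length(files, 3)
  u <- unit_index(pop, theta = 30, f = 0.2, dphi = pi / 2, dx_enc = 2)
  f2 <- render_encoder_figures(pop, bank, dir = dir, which = "tuning",
                               units = u)
  expect_true(file.exists(f2))
  expect_length(render_encoder_figures(pop, bank, dir = dir,
                                       which = character(0)), 0)
})
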