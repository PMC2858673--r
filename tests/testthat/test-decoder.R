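test_that("Pearson map is exact for template columns and affine-invariant", {
  bank <- mini_bank()
  g <- grid_index(bank, 1, -2)
  r <- pearson_map(bank$W[, g], bank)
  expect_true(all(r >= -1 - 1e-12 & r <= 1 + 1e-12))
  expect_equal(r["1", "-2"], 1, tolerance = 1e-12, ignore_attr = TRUE)
  # Pearson correlation ignores additive and positive multiplicative shifts
  r2 <- pearson_map(3 * bank$W[, g] + 7, bank)
  expect_equal(r2, r, tolerance = 1e-12)
})

test_that("zero-variance responses decode as degenerate, not as (0, 0) estimates", {
  bank <- mini_bank()
  e <- estimate_disparity(rep(0, nrow(bank$W)), bank)
  expect_true(all(e$r_map == 0))
  expect_true(e$degenerate)
  expect_equal(nrow(e$ties), nrow(bank$grid))
})

test_that("argmax ties break toward the smallest disparity, deterministically", {
  # synthetic two-column bank with an exact tie
  W <- cbind(c(1, 2, 3, 5), c(1, 2, 3, 5), c(5, 3, 2, 1))
  bank <- structure(list(W = W, grid = data.frame(dx = c(2, -1, 0),
                                                  dy = c(0, 1, 2)),
                         dx_grid = c(2, -1, 0), dy_grid = c(0, 1, 2),
                         U = 1, unit_key = NULL),
                    class = "template_bank")
  bank$grid <- expand.grid(dx = bank$dx_grid, dy = bank$dy_grid)
  W2 <- matrix(0, 4, 9)
  W2[, 1] <- c(1, 2, 3, 5)   # (dx=2, dy=0)
  W2[, 5] <- c(1, 2, 3, 5)   # (dx=-1, dy=1), same norm -> exact tie
  bank$W <- W2
  e <- estimate_disparity(c(1, 2, 3, 5), bank)
  expect_true(e$degenerate)
  expect_equal(nrow(e$ties), 2)
  expect_equal(c(e$dx, e$dy), c(-1, 1))   # dx^2+dy^2 = 2 < 4
})

test_that("stimulus disparity is recovered from single trials to within a pixel", {
  # the reduced 84-unit fixture carries far less information than the full
  # 3150-unit population, so the check is on noise-free responses
  # (stimulus-driven variability only) and allows one pixel of scatter
  pop <- mini_pop(); bank <- mini_bank()
  near <- 0
  for (k in 1:10) {
    sg <- generate_stereogram(41, 41, -1, 1, seed = 100 + k)
    rn <- response_vector(sg, pop, noise = FALSE, bank = mini_filters())
    e <- estimate_disparity(rn, bank)
    near <- near + (abs(e$dx + 1) <= 1 && abs(e$dy - 1) <= 1)
  }
  expect_gte(near, 8)
})

test_that("anticorrelated trials anti-correlate with the true-disparity template", {
  # the template matching the stimulus disparity is the one place the
  # Pearson correlation must go negative for anticorrelated input, so the
  # rectified response of the matched decoder is zero
  pop <- mini_pop(); bank <- mini_bank()
  neg <- 0
  for (k in 1:20) {
    sg <- generate_stereogram(41, 41, -1, 1, polarity = "anticorrelated",
                              seed = 300 + k)
    spk <- response_vector(sg, pop, U = 1, seed = 400 + k,
                           bank = mini_filters())
    r <- pearson_map(spk, bank)
    neg <- neg + (r["-1", "1"] <= 0)
  }
  expect_gte(neg, 16)
})

test_that("decoder tuning surface peaks at the decoder's preferred disparity", {
  pop <- mini_pop(); bank <- mini_bank()
  surf <- decoder_tuning_surface(bank, pop, target = c(-1, 1),
                                 test_dx = -3:1, test_dy = -1:3,
                                 n_images = 8, seed = 5, noise = FALSE,
                                 filters = mini_filters())
  # the preferred disparity sits at (or within Monte-Carlo error of) the top
  expect_gte(surf["-1", "1"], 0.8 * max(surf))
  # anticorrelated: near-flat at zero
  surfa <- decoder_tuning_surface(bank, pop, target = c(-1, 1),
                                  test_dx = -3:1, test_dy = -1:3,
                                  n_images = 8, seed = 5, noise = FALSE,
                                  polarity = "anticorrelated",
                                  filters = mini_filters())
  expect_lt(mean(surfa), 0.05 * max(surf))
  expect_error(decoder_tuning_surface(bank, pop, target = c(-1, 1),
                                      n_images = 0), "n_images")
})
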