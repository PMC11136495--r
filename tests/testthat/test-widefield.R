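test_that("std projection uses the population (divisor n) convention", {
  const <- widefield_movie(array(5, c(4, 3, 3)), rate = 50)
  expect_equal(std_projection(const), matrix(0, 3, 3))

  two <- widefield_movie(array(rep(c(0, 2), each = 1), c(2, 3, 3)), rate = 50)
  expect_equal(std_projection(two), matrix(1, 3, 3))

  single <- widefield_movie(array(7, c(1, 2, 2)), rate = 50)
  expect_equal(std_projection(single), matrix(0, 2, 2))

  set.seed(1)
  mv <- array(runif(10 * 4 * 5), c(10, 4, 5))
  expect_equal(std_projection(mv), oracle_std(mv), tolerance = 1e-12)
})

test_that("stimulus-triggered dF/F matches the hand-computed response", {
  rate <- 10
  nt <- 200
  frames <- array(100, c(nt, 4, 4))
  onsets <- c(5, 10, 15)
  for (on in onsets) {
    fr <- floor(on * rate):(floor((on + 1) * rate) - 1) + 1
    frames[fr, 2, 3] <- 120
  }
  mv <- widefield_movie(frames, rate)
  img <- stimulus_triggered_dff(mv, stimulus_train("whisker", onsets))
  expected <- matrix(0, 4, 4); expected[2, 3] <- 0.2
  expect_equal(img, expected, tolerance = 1e-12)

  const <- widefield_movie(array(80, c(nt, 4, 4)), rate)
  expect_equal(stimulus_triggered_dff(const, stimulus_train("visual", onsets)),
               matrix(0, 4, 4))
})

test_that("trials without full windows are dropped; none usable is an error", {
  mv <- widefield_movie(array(100, c(50, 2, 2)), rate = 10)
  expect_warning(
    stimulus_triggered_dff(mv, stimulus_train("visual", c(0.5, 2.5))),
    "dropped")
  expect_error(
    suppressWarnings(stimulus_triggered_dff(mv, stimulus_train("visual", 0.2))),
    "no usable trials")
  expect_error(stimulus_triggered_dff(mv, stimulus_train("visual", numeric(0))),
               "no usable trials")
})

test_that("stimulus-triggered dF/F is invariant to global intensity scaling", {
  set.seed(2)
  frames <- array(100 + 20 * runif(100 * 3 * 3), c(100, 3, 3))
  train <- stimulus_train("auditory", c(3, 6))
  a <- stimulus_triggered_dff(widefield_movie(frames, 10), train)
  b <- stimulus_triggered_dff(widefield_movie(3.7 * frames, 10), train)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("threshold masks are contiguous and contain the argmax", {
  # single Gaussian blob
  g <- outer(1:21, 1:21, function(r, c) exp(-((r - 11)^2 + (c - 11)^2) / 20))
  tm <- threshold_mask(g, 0.5)
  expect_true(tm$mask[11, 11])
  expect_true(oracle_is_connected4(tm$mask))
  expect_true(tm$mask[which.max(g)])

  # two blobs, amplitudes 1.0 and 0.6, level 0.5: only the larger kept
  g2 <- outer(1:31, 1:31, function(r, c)
    exp(-((r - 8)^2 + (c - 8)^2) / 8) +
      0.6 * exp(-((r - 24)^2 + (c - 24)^2) / 8))
  tm2 <- threshold_mask(g2, 0.5)
  expect_true(tm2$mask[8, 8])
  expect_false(tm2$mask[24, 24])
  expect_true(oracle_is_connected4(tm2$mask))

  expect_error(threshold_mask(matrix(0, 4, 4)), "positive maximum")
})

test_that("the MMM bundle composes overlays and rejects bad input", {
  vessels <- matrix(runif(25), 5, 5)
  empty <- compose_mmm(vessels, list(),
                       list(bregma = c(2, 1), lambda = c(2, 4)))
  expect_length(empty$overlays, 0)
  expect_named(empty$landmarks, c("bregma", "lambda"))

  img <- matrix(0, 5, 5); img[2:3, 2:3] <- 1
  res <- sensory_map_result(img, "visual")
  one <- compose_mmm(vessels, list(res), list(bregma = c(2, 1)))
  expect_named(one$overlays, "visual")

  expect_error(compose_mmm(vessels, list(),
                           list(bregma = c(1, 1), bregma = c(2, 2))),
               "unique")
  bad <- sensory_map_result(matrix(1, 4, 4) + diag(4), "auditory")
  expect_error(compose_mmm(vessels, list(bad)), "shape")
})

test_that("a known synthetic widefield response is recovered to 1%", {
  map <- make_area_map(5, shape = c(32, 32), seed = 9)
  train <- stimulus_train("visual", c(3, 6, 9, 12))
  mv <- make_widefield(map, target_area = 2L, train, amplitude = 20,
                       baseline = 100, noise_sd = 0, rate = 10, seed = 1)
  img <- stimulus_triggered_dff(mv, train)
  f0 <- as.numeric(quantile(mv$frames, 0.10))
  expect_equal(max(img), 20 / f0, tolerance = 0.01)
  # the thresholded mask contains the target-area centroid
  tm <- threshold_mask(img)
  sel <- which(map$labels == 2L, arr.ind = TRUE)
  cen <- round(c(mean(sel[, 1L]), mean(sel[, 2L])))
  expect_true(tm$mask[cen[1L], cen[2L]])

  flat <- make_widefield(map, 2L, train, amplitude = 0, baseline = 100,
                         noise_sd = 0, rate = 10, seed = 1)
  expect_equal(max(abs(stimulus_triggered_dff(flat, train))), 0)
})
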