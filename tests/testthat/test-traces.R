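make_toy_traces <- function(n = 3, nt = 20, rate = 10, probs = NULL) {
  set.seed(99)
  roi_traces(matrix(100 + rnorm(n * nt), n, nt),
             matrix(50 + rnorm(n * nt), n, nt),
             if (is.null(probs)) rep(1, n) else probs,
             cbind(runif(n, 0, 10), runif(n, 0, 10)), rate)
}

test_that("cell screening keeps probabilities at or above the threshold", {
  tr <- make_toy_traces(probs = c(0.4, 0.5, 0.9))
  kept <- screen_cells(tr, 0.5)
  expect_equal(attr(kept, "kept_indices"), c(1L, 2L))  # 0-based
  expect_equal(nrow(kept$F), 2L)

  all_kept <- screen_cells(tr, 0)
  expect_equal(nrow(all_kept$F), 3L)

  expect_error(screen_cells(make_toy_traces(probs = rep(0.1, 3)), 0.5),
               "no ROIs survive")
})

test_that("neuropil subtraction is the elementwise F - gamma * Fneu", {
  expect_equal(neuropil_subtract(matrix(10), matrix(10)), matrix(3))
  F <- matrix(1:6, 2); Fneu <- matrix(6:1, 2)
  expect_equal(neuropil_subtract(F, Fneu, 0), F)
  expect_equal(formals(neuropil_subtract)$gamma, 0.7)
  expect_error(neuropil_subtract(F, matrix(1:4, 2)), "shape")
})

test_that("rolling percentile baseline matches the brute-force oracle", {
  expect_equal(rolling_percentile_baseline(rep(4.2, 30), 11, 10),
               rep(4.2, 30))
  x <- as.numeric(0:99)
  expect_equal(rolling_percentile_baseline(x, 100, 10),
               oracle_roll_pct(x, 100, 10), tolerance = 1e-12)
  # window longer than the trace: full-trace percentile everywhere
  expect_equal(rolling_percentile_baseline(x[1:10], 50, 15),
               rep(as.numeric(quantile(x[1:10], 0.15)), 10))
  set.seed(3)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    w <- sample(1:70, 1)
    p <- runif(1, 5, 45)
    v <- rnorm(n)
    expect_equal(rolling_percentile_baseline(v, w, p),
                 oracle_roll_pct(v, w, p), tolerance = 1e-12)
  }
  expect_error(rolling_percentile_baseline(numeric(0), 10, 10), "empty")
})

test_that("baseline stays within the window range", {
  set.seed(8)
  v <- cumsum(rnorm(200))
  f0 <- rolling_percentile_baseline(v, 31, 10)
  expect_true(all(f0 >= min(v) & f0 <= max(v)))
})

test_that("dF/F normalisation behaves and rejects bad baselines", {
  F0 <- matrix(runif(12, 1, 2), 3)
  expect_equal(dff(F0, F0), matrix(0, 3, 4))
  expect_equal(dff(1.2 * F0, F0), matrix(0.2, 3, 4), tolerance = 1e-12)
  bad <- F0; bad[2, 3] <- 0
  expect_error(dff(F0, bad), "neuron")
})

test_that("dF/F is invariant under global intensity scaling", {
  tr <- make_toy_traces(n = 4, nt = 120)
  run1 <- run_dff_pipeline(tr)
  tr2 <- tr
  tr2$F <- 5 * tr$F; tr2$Fneu <- 5 * tr$Fneu
  run2 <- run_dff_pipeline(tr2)
  expect_equal(run2$dff, run1$dff, tolerance = 1e-12)
})

test_that("resampling decimates, upsamples, and round-trips lengths", {
  x <- as.numeric(1:30)
  expect_equal(resample_to(x, 30, 10), x[seq(1, 30, by = 3)])
  expect_equal(resample_to(x, 10, 10), x)
  expect_equal(resample_to(rep(2.5, 34), 3.38, 10), rep(2.5, 101),
               tolerance = 1e-9)
  # Fourier upsampling preserves a band-limited sine
  t <- (0:59) / 10
  s <- sin(2 * pi * 0.7 * t)
  up <- resample_to(s, 10, 30)
  expect_length(up, 180)
  expect_equal(up[seq(1, 180, by = 3)], s, tolerance = 1e-6)
  expect_message(resample_to(as.numeric(1:45), 4.5, 3), "interpolation")
  expect_error(resample_to(x, -1, 10), "positive")
})

test_that("the pipeline is deterministic and truncation-friendly", {
  tr <- make_toy_traces(n = 5, nt = 200, rate = 30)
  a <- run_dff_pipeline(tr)
  b <- run_dff_pipeline(tr)
  expect_identical(a$dff, b$dff)
  expect_true(all(a$F0 > 0))
  expect_equal(ncol(a$dff), length(seq(1, 200, by = 3)))
})

test_that("generator neuropil gain 0.7 is removed bit-exactly at gamma 0.7", {
  map <- make_area_map(4, shape = c(24, 24), seed = 51)
  beh <- make_behavior(30, seed = 52)
  pop <- make_population(20, map, coupling_spec(), beh, rate_2p = 3,
                         seed = 53)
  fsub <- neuropil_subtract(pop$traces$F, pop$traces$Fneu, 0.7)
  expect_identical(fsub, attr(pop$truth, "Ftrue"))
})

test_that("sessions written as CSV arrays read back identically", {
  tr <- make_toy_traces(n = 3, nt = 15)
  td <- withr::local_tempdir()
  write_session(tr, td)
  back <- read_session(td)
  expect_equal(back$F, tr$F, tolerance = 1e-12)
  expect_equal(back$cellprob, tr$cellprob)
  expect_equal(back$rate, tr$rate)
})
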