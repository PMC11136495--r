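test_that("per-neuron correlations are Pearson r with zero-variance flags", {
  reg <- c(1, 2, 4, 3, 5, 7, 6)
  d <- rbind(reg, -reg, rep(2, 7))
  res <- neuron_behavior_corr(d, reg)
  expect_equal(res$r, c(1, -1, 0))
  expect_equal(res$zero_variance, c(FALSE, FALSE, TRUE))

  hand <- neuron_behavior_corr(matrix(c(1, 2, 4), 1), c(1, 2, 3))
  expect_equal(hand$r, cor(c(1, 2, 4), c(1, 2, 3)))
  expect_equal(round(hand$r, 3), 0.982)

  expect_error(neuron_behavior_corr(d, reg[-1]), "length")
})

test_that("one-sample t matches the closed form mean / (sd / sqrt(n))", {
  res <- onesample_t(c(0.1, 0.2, 0.3))
  expect_equal(res$t, mean(c(0.1, 0.2, 0.3)) /
                 (sd(c(0.1, 0.2, 0.3)) / sqrt(3)), tolerance = 1e-12)
  expect_equal(res$t, 3.4641, tolerance = 1e-4)
  expect_equal(res$df, 2L)

  sym <- c(-2, -1, 1, 2)
  expect_equal(onesample_t(sym)$t, 0)
  expect_error(onesample_t(0.2), "at least 2")
  expect_error(onesample_t(c(1, 1, 1)), "variance")

  # agrees with t.test and with the closed form on random samples
  set.seed(21)
  for (i in 1:25) {
    v <- rnorm(sample(3:40, 1))
    res <- onesample_t(v)
    ref <- t.test(v)
    expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p, ref$p.value, tolerance = 1e-12)
    expect_equal(res$t, mean(v) / (sd(v) / sqrt(length(v))),
                 tolerance = 1e-12)
  }
})

make_table <- function(area_id, r, acronym = NULL, group = NULL) {
  df <- data.frame(area_id = area_id,
                   acronym = if (is.null(acronym))
                     paste0("A", area_id) else acronym,
                   r_walk = r, stringsAsFactors = FALSE)
  if (!is.null(group)) df$group <- group
  df
}

test_that("area means respect the minimum-20-neurons rule", {
  tab <- make_table(rep(1L, 21), rep(c(0.1, 0.2, 0.3), 7))
  st <- area_mean_corr(tab, "r_walk")
  expect_equal(st$mean_r, 0.2, tolerance = 1e-12)
  expect_true(st$included)
  expect_equal(st$df, 20L)

  tab2 <- make_table(c(rep(1L, 19), rep(2L, 25)),
                     c(rep(0.5, 19), rep(-0.1, 25)))
  st2 <- area_mean_corr(tab2, "r_walk")
  expect_false(st2$included[st2$area_id == 1])
  expect_true(is.na(st2$t[st2$area_id == 1]))
  expect_true(st2$included[st2$area_id == 2])

  # hand-computed means for two included areas
  tab3 <- make_table(rep(c(1L, 2L), each = 20),
                     c(rep(c(0, 0.4), 10), rep(c(-0.2, 0.6), 10)))
  st3 <- area_mean_corr(tab3, "r_walk")
  expect_equal(st3$mean_r, c(0.2, 0.2), tolerance = 1e-12)

  expect_error(area_mean_corr(make_table(rep(1L, 5), runif(5)), "r_walk"),
               "minimum")
  # order invariance
  perm <- sample(nrow(tab3))
  expect_equal(area_mean_corr(tab3[perm, ], "r_walk")$mean_r, st3$mean_r)
})

test_that("group density maps report percentages per area with min-n rule", {
  # a group that is exactly the neurons of area 1
  tab <- make_table(rep(c(1L, 2L), each = 25), 0,
                    group = rep(c("g1", "g2"), each = 25))
  dm <- group_area_density(tab, "g1")
  expect_equal(dm$percent[dm$area_id == 1], 100)
  expect_equal(dm$percent[dm$area_id == 2], 0)

  # partition: per-area percentages over groups sum to 100
  set.seed(31)
  tab2 <- make_table(sample(1:3, 200, replace = TRUE), 0,
                     group = sample(c("a", "b", "c"), 200, replace = TRUE))
  per_area <- Reduce(`+`, lapply(c("a", "b", "c"), function(g)
    group_area_density(tab2, g)$percent))
  expect_equal(per_area, rep(100, 3), tolerance = 1e-9)

  # 5 of 20 neurons in the group -> 25 %
  tab3 <- make_table(rep(1L, 20), 0,
                     group = c(rep("g", 5), rep("other", 15)))
  expect_equal(group_area_density(tab3, "g")$percent, 25)

  # small areas are reported but not quantified
  tab4 <- make_table(c(rep(1L, 19), rep(2L, 30)), 0,
                     group = rep("g", 49))
  dm4 <- group_area_density(tab4, "g")
  expect_true(is.na(dm4$percent[dm4$area_id == 1]))
  expect_false(dm4$reported[dm4$area_id == 1])

  expect_error(group_area_density(tab4, "nope"), "unknown group")
})

test_that("correlation distribution stats give mode bin and adjusted skewness", {
  sym <- c(-0.3, -0.1, 0, 0.1, 0.3)
  st <- corr_distribution_stats(sym)
  expect_equal(st$skewness, 0, tolerance = 1e-12)

  st2 <- corr_distribution_stats(c(0, 0, 0, 0.9))
  expect_gt(st2$skewness, 0)
  expect_equal(st2$mode_bin, 0.025)   # all-but-one value in [0, 0.05)

  onebin <- runif(50, 0.11, 0.14)
  expect_equal(corr_distribution_stats(onebin)$mode_bin, 0.125)

  # adjusted Fisher-Pearson definition, cross-checked against e1071 type 2
  set.seed(41)
  for (i in 1:20) {
    v <- rnorm(sample(10:100, 1))
    expect_equal(corr_distribution_stats(v)$skewness,
                 e1071::skewness(v, type = 2), tolerance = 1e-12)
  }
})

test_that("motif-aligned group activity averages over label occupancies", {
  traces <- rbind(g1 = rep(1, 10), g2 = rep(c(1, 0), 5))
  all_one <- motif_aligned_group_activity(traces, rep(3L, 10))
  expect_equal(as.numeric(all_one), rowMeans(traces), ignore_attr = TRUE)

  labels <- rep(c(1L, 2L), 5)
  m <- motif_aligned_group_activity(traces, labels)
  expect_equal(m["g2", "1"], 1)
  expect_equal(m["g2", "2"], 0)

  with_absent <- motif_aligned_group_activity(traces, labels,
                                              motif_set = c(1L, 2L, 9L))
  expect_equal(attr(with_absent, "absent"), 9L)
  expect_true(all(is.na(with_absent[, "9"])))

  expect_error(motif_aligned_group_activity(traces, labels[-1]), "length")
})
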