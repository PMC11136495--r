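test_that("affine fits recover identity, translation, and a generating matrix", {
  id <- fit_transform(landmark_set(rbind(c(0, 0), c(1, 0), c(0, 1)),
                                   rbind(c(0, 0), c(1, 0), c(0, 1)),
                                   "ccf", "mmm"), "affine")
  expect_equal(id$A, cbind(diag(2), c(0, 0)), tolerance = 1e-12)
  expect_equal(id$residual, 0, tolerance = 1e-12)
  expect_equal(apply_transform(id, c(3, 4))[1, ], c(3, 4))

  src <- rbind(c(0, 0), c(4, 1), c(1, 5))
  tr <- fit_transform(landmark_set(src, src + rep(c(5, -3), each = 3),
                                   "twop", "mmm"), "affine")
  expect_equal(tr$A, cbind(diag(2), c(5, -3)), tolerance = 1e-10)
  expect_equal(apply_transform(invert_transform(tr), c(5, -3))[1, ], c(0, 0),
               tolerance = 1e-10)

  th <- 22.5 * pi / 180
  A <- rbind(c(2 * cos(th), -2 * sin(th), 0), c(2 * sin(th), 2 * cos(th), 0))
  set.seed(4)
  src8 <- cbind(runif(8, 0, 50), runif(8, 0, 50))
  fit <- fit_transform(landmark_set(src8, affine_apply(A, src8),
                                    "ccf", "mmm"), "affine")
  expect_equal(fit$A, A, tolerance = 1e-9)
})

test_that("collinear or insufficient landmarks are rejected", {
  line <- cbind(0:3, 2 * (0:3))
  expect_error(fit_transform(landmark_set(line, line + 1, "ccf", "mmm"),
                             "affine"), "collinear")
  expect_error(landmark_set(rbind(c(0, 0), c(1, 1)),
                            rbind(c(0, 0), c(1, 1)), "ccf", "mmm"),
               "at least 3")
  expect_error(landmark_set(rbind(c(0, 0), c(0, 0), c(1, 1)),
                            rbind(c(0, 0), c(1, 0), c(1, 1)), "ccf", "mmm"),
               "duplicated")
})

test_that("the auto rule picks affine below 6 pairs and piecewise at 6+", {
  set.seed(5)
  src <- cbind(runif(6, 0, 10), runif(6, 0, 10))
  dst <- src * 2
  five <- fit_transform(landmark_set(src[1:5, ], dst[1:5, ], "ccf", "mmm"))
  six <- fit_transform(landmark_set(src, dst, "ccf", "mmm"))
  expect_equal(five$kind, "affine")
  expect_equal(six$kind, "piecewise_affine")
})

test_that("piecewise transforms are exact at every control point", {
  set.seed(6)
  src <- cbind(runif(10, 0, 40), runif(10, 0, 40))
  dst <- affine_apply(random_affine(), src) + 0.5 * matrix(rnorm(20), ncol = 2)
  pw <- fit_transform(landmark_set(src, dst, "ccf", "mmm"),
                      "piecewise_affine")
  got <- apply_transform(pw, src)
  expect_equal(unclass(got)[, ], dst[, ], tolerance = 1e-9)
  expect_false(any(attr(got, "out_of_hull")))
  expect_equal(pw$residual, 0)
  # inverse piecewise round-trips the control points
  back <- apply_transform(invert_transform(pw), got)
  expect_equal(unclass(back)[, ], src[, ], tolerance = 1e-9)
})

test_that("points outside the piecewise hull fall back to the global affine", {
  src <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10), c(5, 5), c(2, 7))
  A <- rbind(c(1.5, 0, 3), c(0, 1.5, -2))
  pw <- fit_transform(landmark_set(src, affine_apply(A, src), "ccf", "mmm"))
  far <- apply_transform(pw, c(50, 50))
  expect_true(attr(far, "out_of_hull"))
  expect_equal(far[1, ], affine_apply(A, matrix(c(50, 50), 1))[1, ],
               tolerance = 1e-9)
})

test_that("affine round trip holds to 1e-9 over random transforms", {
  set.seed(7)
  for (i in 1:20) {
    A <- random_affine()
    src <- cbind(runif(5, 0, 30), runif(5, 0, 30))
    tr <- fit_transform(landmark_set(src, affine_apply(A, src),
                                     "twop", "mmm"), "affine")
    p <- cbind(runif(50, -10, 40), runif(50, -10, 40))
    back <- apply_transform(invert_transform(tr), apply_transform(tr, p))
    expect_lt(max(abs(back - p)), 1e-9)
  }
})

test_that("area assignment applies the double reverse-transformation", {
  lab <- matrix(0L, 10, 10); lab[3:7, 3:7] <- 7L
  map <- area_map(lab)
  idlm <- rbind(c(0, 0), c(9, 0), c(0, 9))
  t2p <- fit_transform(landmark_set(idlm, idlm, "twop", "mmm"), "affine")
  tccf <- fit_transform(landmark_set(idlm, idlm, "ccf", "mmm"), "affine")
  res <- assign_areas(rbind(c(4.5, 4.5), c(50, 50)), t2p, tccf, map)
  expect_equal(res$area_id, c(7L, NA_integer_))
  expect_true(res$unassigned[2])
  expect_error(assign_areas(c(1, 1), tccf, t2p, map), "frame")
})

test_that("synthetic sessions register back to ground truth at jitter 0", {
  map <- make_area_map(12, shape = c(64, 64), seed = 21)
  set.seed(22)
  nz <- which(map$labels > 0L, arr.ind = TRUE)
  pick <- nz[sample(nrow(nz), 200), ]
  cen_ccf <- cbind(pick[, 2L] - 0.5, pick[, 1L] - 0.5)
  truth_id <- map$labels[pick]
  warp <- warp_session(map, cen_ccf, jitter_px = 0, n_landmarks = 8, seed = 23)

  fit_ccf <- fit_transform(warp$landmarks_ccf_mmm, "affine")
  expect_equal(fit_ccf$A, warp$A_ccf_mmm, tolerance = 1e-9)

  t2p <- fit_transform(warp$landmarks_2p_mmm)
  tccf <- fit_transform(warp$landmarks_ccf_mmm)
  res <- assign_areas(warp$centroids_2p, t2p, tccf, map)
  off <- off_boundary(map, cen_ccf, 2L)
  acc <- mean(res$area_id[off] == truth_id[off], na.rm = FALSE)
  expect_gte(acc, 0.99)
})

test_that("assignments are equivariant under a common MMM re-mapping", {
  map <- make_area_map(8, shape = c(48, 48), seed = 31)
  set.seed(32)
  nz <- which(map$labels > 0L, arr.ind = TRUE)
  pick <- nz[sample(nrow(nz), 60), ]
  cen_ccf <- cbind(pick[, 2L] - 0.5, pick[, 1L] - 0.5)
  warp <- warp_session(map, cen_ccf, jitter_px = 0, n_landmarks = 8, seed = 33)
  base <- assign_areas(warp$centroids_2p,
                       fit_transform(warp$landmarks_2p_mmm),
                       fit_transform(warp$landmarks_ccf_mmm), map)
  extra <- rbind(c(0.9, 0.2, 12), c(-0.1, 1.1, -4))
  lm2 <- warp$landmarks_2p_mmm; lmc <- warp$landmarks_ccf_mmm
  lm2$dst <- affine_apply(extra, lm2$dst)
  lmc$dst <- affine_apply(extra, lmc$dst)
  moved <- assign_areas(warp$centroids_2p, fit_transform(lm2),
                        fit_transform(lmc), map)
  expect_equal(moved$area_id, base$area_id)
})

test_that("landmarks and transforms survive their CSV / JSON round trips", {
  set.seed(41)
  src <- cbind(runif(7, 0, 20), runif(7, 0, 20))
  lm <- landmark_set(src, src * 1.5 + 2, "twop", "mmm")
  td <- withr::local_tempdir()
  write_landmarks(lm, file.path(td, "lm.csv"))
  back <- read_landmarks(file.path(td, "lm.csv"))
  expect_equal(back$src[, ], lm$src[, ], tolerance = 1e-9)
  expect_equal(back$frame_from, "twop")

  tr <- fit_transform(lm)
  write_transform(tr, file.path(td, "t.json"))
  tr2 <- read_transform(file.path(td, "t.json"))
  p <- cbind(runif(10, 0, 20), runif(10, 0, 20))
  expect_equal(unclass(apply_transform(tr2, p))[, ],
               unclass(apply_transform(tr, p))[, ], tolerance = 1e-9)
})
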