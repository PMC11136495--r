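#' Coupling specification for synthetic populations
#'
#' Fractions of behavior-activated (ON), behavior-suppressed (OFF) and
#' uncoupled neurons, the coupling-weight magnitude range, private noise
#' and the neuropil gain used by the generator. Defaults emulate
#' spontaneous-behavior sessions in which large neuron groups are
#' activated with movement while others are suppressed; weight
#' magnitudes are chosen so that per-neuron behavior correlations fall
#' in roughly the -0.6..0.6 range typical of such recordings (a
#' generator choice, not a measured fact).
#'
#' @param frac_on,frac_off,frac_uncoupled class fractions (sum to 1).
#' @param w_min,w_max coupling weight magnitude range (on z-scored
#'   regressors).
#' @param noise_sd private Gaussian noise sd (fluorescence a.u.).
#' @param neuropil_gain gain applied to the shared neuropil signal.
#' @param decoy_frac extra low-probability decoy ROIs as a fraction of
#'   `n_neurons` (gives classifier screening real work).
#' @return a list of class `coupling_spec`.
#' @export
coupling_spec <- function(frac_on = 0.4, frac_off = 0.2,
                          frac_uncoupled = 0.4, w_min = 0.5, w_max = 1.5,
                          noise_sd = 2, neuropil_gain = 0.7,
                          decoy_frac = 0.1) {
  if (abs(frac_on + frac_off + frac_uncoupled - 1) > 1e-9)
    stop("class fractions must sum to 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(frac_on = frac_on, frac_off = frac_off,
                 frac_uncoupled = frac_uncoupled, w_min = w_min,
                 w_max = w_max, noise_sd = noise_sd,
                 neuropil_gain = neuropil_gain, decoy_frac = decoy_frac),
            class = "coupling_spec")
}

#' Synthetic cortical area map
#'
#' Voronoi partition of an elliptical cortical sheet into `n_areas`
#' labelled regions (background 0 outside the ellipse), with a synthetic
#' area table. The default of 30 areas matches the number of cortical
#' areas typically visible in a mesoscale field of view. Optionally also
#' returns a thin label volume (the labels replicated over a few z
#' slices) for projection tests.
#'
#' @param n_areas number of areas (>= 1).
#' @param shape raster shape c(rows, cols).
#' @param seed RNG seed.
#' @param volume_slices if > 0, attach a label volume this many voxels
#'   thick.
#' @return an [area_map()] (labelled `SYNxx` areas).
#' @export
make_area_map <- function(n_areas = 30L, shape = c(128L, 128L), seed = 1L,
                          volume_slices = 0L) {
  if (n_areas < 1L) stop("n_areas must be >= 1")
  set.seed(seed)
  nr <- shape[1L]; nc <- shape[2L]
  cx <- nc / 2; cy <- nr / 2
  ax <- 0.48 * nc; ay <- 0.48 * nr
  px <- rep(seq_len(nc) - 0.5, each = nr)
  py <- rep(seq_len(nr) - 0.5, times = nc)
  inside <- ((px - cx) / ax)^2 + ((py - cy) / ay)^2 <= 1
  idx_in <- which(inside)
  if (n_areas > length(idx_in)) stop("n_areas exceeds the sheet pixel count")
  seeds <- sample(idx_in, n_areas)
  sx <- px[seeds]; sy <- py[seeds]
  d2 <- outer(px[idx_in], sx, function(a, b) (a - b)^2) +
    outer(py[idx_in], sy, function(a, b) (a - b)^2)
  lab <- integer(nr * nc)
  lab[idx_in] <- max.col(-d2, ties.method = "first")
  labels <- matrix(lab, nr, nc)
  inside_m <- matrix(inside, nr, nc)
  seed_rc <- cbind((seeds - 1L) %% nr + 1L, (seeds - 1L) %/% nr + 1L)
  labels <- .enforce_connected4(labels, seed_rc, inside_m)
  hemi <- ifelse(sx < cx, "left", "right")
  tab <- area_table(seq_len(n_areas), sprintf("SYN%02d", seq_len(n_areas)),
                    sprintf("synthetic area %02d", seq_len(n_areas)), hemi)
  vol <- NULL
  if (volume_slices > 0L)
    vol <- array(rep(labels, volume_slices), c(nr, nc, volume_slices))
  area_map(labels, resolution_um = 10, table = tab, volume = vol)
}

# Pixelation can leave diagonal slivers of a Voronoi cell 4-disconnected
# from its seed. Detach such fragments and regrow the seed-connected
# components into them so every area is one 4-connected region.
.enforce_connected4 <- function(labels, seed_rc, inside) {
  nr <- nrow(labels); nc <- ncol(labels)
  for (id in seq_len(nrow(seed_rc))) {
    comp <- .label_components4(labels == id)
    keep <- comp[seed_rc[id, 1L], seed_rc[id, 2L]]
    labels[comp > 0L & comp != keep] <- 0L
  }
  repeat {
    todo <- inside & labels == 0L
    if (!any(todo)) break
    cand <- array(NA_integer_, c(nr, nc, 4L))
    cand[-nr, , 1L] <- labels[-1L, ]
    cand[-1L, , 2L] <- labels[-nr, ]
    cand[, -nc, 3L] <- labels[, -1L]
    cand[, -1L, 4L] <- labels[, -nc]
    cand[!is.na(cand) & cand == 0L] <- NA_integer_
    best <- suppressWarnings(apply(cand, c(1L, 2L), min, na.rm = TRUE))
    best[!is.finite(best)] <- 0L
    newly <- todo & best > 0L
    if (!any(newly)) break  # isolated pocket stays background
    labels[newly] <- best[newly]
  }
  labels
}

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# exponential smoothing used for behavior envelopes
.leaky <- function(drive, rate, tau) {
  a <- 1 / (tau * rate)
  stats::filter(a * drive, 1 - a, method = "recursive")
}

#' Synthetic behavioral primitives
#'
#' Generates walk speed (100 Hz), whisker motion energy (30 Hz) and
#' pupil diameter (30 Hz) with the dependency structure of spontaneous
#' head-fixed behavior: a two-state (rest/walk) Markov chain drives a
#' walk-speed envelope; whisking combines a walk-locked drive with
#' independent whisking events; the pupil is a leaky-integrator
#' (low-pass) transform of the arousal drive with time constant
#' `pupil_tau_s`, so pupil dilation lags whisking.
#'
#' @param duration_s session duration in seconds (> 0).
#' @param seed RNG seed.
#' @param p_rest_to_walk,p_walk_to_rest per-sample (100 Hz) Markov
#'   transition probabilities; defaults give mean rest bouts of 3 s,
#'   walk bouts of 1.5 s and stationary walking occupancy 1/3.
#' @param pupil_tau_s pupil low-pass time constant (s).
#' @return a [behavior_timeseries()] with channels `walk_speed`,
#'   `whisker_me`, `pupil_diam`; the 100 Hz walk state is attached as
#'   the `"walk_state"` attribute.
#' @export
make_behavior <- function(duration_s, seed = 1L,
                          p_rest_to_walk = 1 / 300, p_walk_to_rest = 1 / 150,
                          pupil_tau_s = 1) {
  if (duration_s <= 0) stop("duration_s must be > 0")
  set.seed(seed)
  n100 <- round(duration_s * 100)
  u <- runif(n100)
  state <- integer(n100)
  s <- 0L
  for (i in seq_len(n100)) {
    s <- if (s == 0L) as.integer(u[i] < p_rest_to_walk) else
      1L - as.integer(u[i] < p_walk_to_rest)
    state[i] <- s
  }
  env <- as.numeric(.leaky(6 + 3 * rnorm(n100), 100, 0.5))
  walk <- state * pmax(env, 0)
  n30 <- round(duration_s * 30)
  i100 <- pmin(n100, floor((seq_len(n30) - 1L) * 100 / 30) + 1L)
  walk30 <- state[i100]
  events <- rpois(n30, 0.15 / 30)
  ev_env <- as.numeric(.leaky(30 * events, 30, 0.6))
  drive <- walk30 + pmin(ev_env, 1.5)
  whisk <- pmax(as.numeric(.leaky(drive, 30, 0.2)) + 0.05 * rnorm(n30), 0)
  pupil <- 1 + as.numeric(.leaky(drive, 30, pupil_tau_s))
  b <- behavior_timeseries(
    walk_speed = list(values = walk, rate = 100),
    whisker_me = list(values = whisk, rate = 30),
    pupil_diam = list(values = pupil, rate = 30))
  attr(b, "walk_state") <- state
  b
}

#' Synthetic behavior-coupled neuronal population
#'
#' Places neurons uniformly over the nonzero pixels of the area map
#' (at pixel centers, in CCF/map pixel coordinates), couples each ON /
#' OFF neuron to one behavioral primitive through a softplus rate link
#' on the z-scored regressor, draws Poisson spikes, convolves them with
#' a double-exponential GCaMP6s-like kernel (rise 0.2 s, decay 1.2 s by
#' default) and adds private Gaussian noise plus a shared
#' low-frequency neuropil signal scaled by the generator gain:
#' `F = Ftrue + gain * Fneu`. Low-probability decoy ROIs are appended
#' so classifier screening has real work. The recorded ground-truth
#' trace is defined as the neuropil-free component of the stored F
#' (`F - gain * Fneu`), so neuropil subtraction at the generator gain
#' recovers it exactly.
#'
#' @param n_neurons number of real neurons.
#' @param map an [area_map()] giving positions and area ids.
#' @param spec a [coupling_spec()].
#' @param behavior a [behavior_timeseries()] from [make_behavior()].
#' @param rate_2p 2-photon sampling rate in Hz (default 3, the typical
#'   large-FOV rate).
#' @param seed RNG seed.
#' @param kernel_rise_s,kernel_decay_s calcium kernel time constants.
#' @return list with `traces` (an [roi_traces()], real neurons followed
#'   by decoys) and `truth` (data.frame with per-ROI class, coupled
#'   channel, weights, true area id and position, plus attributes
#'   `Ftrue`, `kernel`, `seed`).
#' @export
make_population <- function(n_neurons, map, spec = coupling_spec(),
                            behavior, rate_2p = 3, seed = 1L,
                            kernel_rise_s = 0.2, kernel_decay_s = 1.2) {
  stopifnot(inherits(map, "area_map"), inherits(spec, "coupling_spec"),
            inherits(behavior, "behavior_timeseries"))
  if (rate_2p <= 0) stop("rate_2p must be > 0")
  set.seed(seed)
  nz <- which(map$labels > 0L)
  if (!length(nz)) stop("area map has no nonzero pixels")
  dur <- min(vapply(behavior$channels, function(ch)
    length(ch$values) / ch$rate, numeric(1L)))
  nt <- floor(dur * rate_2p)
  tgrid <- (seq_len(nt) - 1L) / rate_2p
  regs <- vapply(c("walk_speed", "whisker_me", "pupil_diam"), function(nm) {
    ch <- behavior$channels[[nm]]
    approx((seq_along(ch$values) - 1L) / ch$rate, ch$values,
           xout = tgrid, rule = 2)$y
  }, numeric(nt))
  regs <- apply(regs, 2L, function(v) (v - mean(v)) / sd(v))
  colnames(regs) <- c("walk", "whisk", "pupil")

  n_on <- round(spec$frac_on * n_neurons)
  n_off <- round(spec$frac_off * n_neurons)
  classes <- sample(c(rep("on", n_on), rep("off", n_off),
                      rep("uncoupled", n_neurons - n_on - n_off)))
  channel <- ifelse(classes == "uncoupled", NA_character_,
                    sample(c("walk", "whisk", "pupil"), n_neurons,
                           replace = TRUE))
  wmag <- runif(n_neurons, spec$w_min, spec$w_max)
  w <- ifelse(classes == "on", wmag, ifelse(classes == "off", -wmag, 0))

  kt <- seq(0, 6 * kernel_decay_s, by = 1 / rate_2p)
  kern <- (1 - exp(-kt / kernel_rise_s)) * exp(-kt / kernel_decay_s)
  kern <- kern / max(kern)

  pix <- sample(nz, n_neurons, replace = TRUE)
  rr <- (pix - 1L) %% nrow(map$labels) + 1L
  cc <- (pix - 1L) %/% nrow(map$labels) + 1L
  xy <- cbind(x = cc - 0.5, y = rr - 0.5)
  area_ids <- map$labels[pix]

  Ftrue <- matrix(0, n_neurons, nt)
  for (i in seq_len(n_neurons)) {
    drive <- if (is.na(channel[i])) 0 else w[i] * regs[, channel[i]]
    rate_hz <- .softplus(drive)
    spikes <- rpois(nt, rate_hz / rate_2p)
    cal <- convolve(spikes, rev(kern), type = "open")[seq_len(nt)]
    Ftrue[i, ] <- 100 + 30 * cal + spec$noise_sd * rnorm(nt)
  }
  shared <- 50 + 10 * sin(2 * pi * tgrid / 120) +
    as.numeric(.leaky(5 * rnorm(nt), rate_2p, 10))
  Fneu <- matrix(shared, n_neurons, nt, byrow = TRUE)
  F <- Ftrue + spec$neuropil_gain * Fneu

  n_dec <- round(spec$decoy_frac * n_neurons)
  if (n_dec > 0L) {
    Fdec <- matrix(100 + 5 * rnorm(n_dec * nt), n_dec, nt)
    pixd <- sample(nz, n_dec, replace = TRUE)
    xyd <- cbind(x = (pixd - 1L) %/% nrow(map$labels) + 0.5,
                 y = (pixd - 1L) %% nrow(map$labels) + 0.5)
    F <- rbind(F, Fdec + spec$neuropil_gain *
                 matrix(shared, n_dec, nt, byrow = TRUE))
    Fneu <- rbind(Fneu, matrix(shared, n_dec, nt, byrow = TRUE))
    xy <- rbind(xy, xyd)
    area_ids <- c(area_ids, map$labels[pixd])
    classes <- c(classes, rep("decoy", n_dec))
    channel <- c(channel, rep(NA_character_, n_dec))
    w <- c(w, rep(0, n_dec))
    cellprob <- c(rep(1, n_neurons), runif(n_dec, 0, 0.45))
  } else cellprob <- rep(1, n_neurons)

  truth <- data.frame(
    roi = seq_len(nrow(F)) - 1L, class = classes, channel = channel,
    w = w,
    w_walk = ifelse(!is.na(channel) & channel == "walk", w, 0),
    w_whisk = ifelse(!is.na(channel) & channel == "whisk", w, 0),
    w_pupil = ifelse(!is.na(channel) & channel == "pupil", w, 0),
    bias = 0, area_id = area_ids, x = xy[, 1L], y = xy[, 2L],
    is_decoy = classes == "decoy", stringsAsFactors = FALSE)
  # ground truth := the neuropil-free component of the stored F
  attr(truth, "Ftrue") <- F - spec$neuropil_gain * Fneu
  attr(truth, "kernel") <- list(rise_s = kernel_rise_s,
                                decay_s = kernel_decay_s)
  attr(truth, "seed") <- seed
  list(traces = roi_traces(F, Fneu, cellprob, xy, rate_2p), truth = truth)
}

.affine_pts <- function(A, pts) cbind(.as_points(pts), 1) %*% t(A)

.draw_affine <- function(angle_range, scale_range, trans_range) {
  for (try in 1:20) {
    th <- runif(1, angle_range[1L], angle_range[2L]) * pi / 180
    s <- runif(1, scale_range[1L], scale_range[2L])
    tx <- runif(1, trans_range[1L], trans_range[2L])
    ty <- runif(1, trans_range[1L], trans_range[2L])
    A <- rbind(c(s * cos(th), -s * sin(th), tx),
               c(s * sin(th), s * cos(th), ty))
    if (abs(det(A[, 1:2])) > 1e-6) return(A)
  }
  stop("could not draw a non-degenerate transform")
}

#' Synthetic two-step registration geometry
#'
#' Draws ground-truth affine transforms CCF->MMM and 2p->MMM, places the
#' neurons' 2p-frame centroids consistently with their true map
#' positions, and emits the two landmark sets (bounding-box corners plus
#' random interior points) with Gaussian jitter of `jitter_px` on the
#' target coordinates.
#'
#' @param map the [area_map()] the session was generated on.
#' @param centroids_ccf n x 2 true neuron positions in map (CCF) pixels.
#' @param jitter_px landmark jitter sd in MMM pixels.
#' @param n_landmarks landmarks per set (>= 3).
#' @param seed RNG seed.
#' @return list with `landmarks_ccf_mmm`, `landmarks_2p_mmm`
#'   ([landmark_set()]s), true matrices `A_ccf_mmm`, `A_2p_mmm`, and
#'   `centroids_2p`.
#' @export
warp_session <- function(map, centroids_ccf, jitter_px = 0,
                         n_landmarks = 8L, seed = 1L) {
  stopifnot(inherits(map, "area_map"))
  if (n_landmarks < 3L) stop("need at least 3 landmarks")
  set.seed(seed)
  centroids_ccf <- .as_points(centroids_ccf)
  A_c2m <- .draw_affine(c(-15, 15), c(1.6, 2.4), c(10, 30))
  A_p2m <- .draw_affine(c(-10, 10), c(0.8, 1.2), c(5, 15))

  nzidx <- which(map$labels > 0L, arr.ind = TRUE)
  xr <- range(nzidx[, 2L] - 0.5); yr <- range(nzidx[, 1L] - 0.5)
  lm_src_ccf <- .spread_points(xr, yr, n_landmarks)
  lm_ccf <- landmark_set(lm_src_ccf,
                         .affine_pts(A_c2m, lm_src_ccf) +
                           jitter_px * matrix(rnorm(2 * n_landmarks),
                                              ncol = 2L),
                         "ccf", "mmm")

  mmm_pts <- .affine_pts(A_c2m, centroids_ccf)
  M <- A_p2m[, 1:2]
  Minv <- solve(M)
  centroids_2p <- t(Minv %*% (t(mmm_pts) - A_p2m[, 3L]))
  xr2 <- range(centroids_2p[, 1L]); yr2 <- range(centroids_2p[, 2L])
  pad <- 0.1 * c(diff(xr2), diff(yr2)) + 1
  lm_src_2p <- .spread_points(xr2 + c(-pad[1L], pad[1L]),
                              yr2 + c(-pad[2L], pad[2L]), n_landmarks)
  lm_2p <- landmark_set(lm_src_2p,
                        .affine_pts(A_p2m, lm_src_2p) +
                          jitter_px * matrix(rnorm(2 * n_landmarks),
                                             ncol = 2L),
                        "twop", "mmm")
  list(landmarks_ccf_mmm = lm_ccf, landmarks_2p_mmm = lm_2p,
       A_ccf_mmm = A_c2m, A_2p_mmm = A_p2m, centroids_2p = centroids_2p)
}

# corners of the box first, then random interior points
.spread_points <- function(xr, yr, n) {
  pts <- rbind(c(xr[1L], yr[1L]), c(xr[2L], yr[1L]),
               c(xr[2L], yr[2L]), c(xr[1L], yr[2L]))
  if (n <= 4L) return(pts[seq_len(n), , drop = FALSE])
  extra <- cbind(runif(n - 4L, xr[1L], xr[2L]),
                 runif(n - 4L, yr[1L], yr[2L]))
  rbind(pts, extra)
}

#' Synthetic widefield sensory-mapping movie
#'
#' A constant-baseline movie with a Gaussian-profile response (peak
#' `amplitude`, normalized so the grid maximum equals the amplitude
#' exactly) centered on the target area during each 1 s response window,
#' plus optional Gaussian noise.
#'
#' @param map an [area_map()] defining the frame geometry.
#' @param target_area area id receiving the response.
#' @param train a [stimulus_train()].
#' @param amplitude response peak amplitude (a.u.).
#' @param baseline baseline intensity (a.u.).
#' @param noise_sd Gaussian noise sd.
#' @param rate frame rate in Hz.
#' @param response_s response duration after each onset.
#' @param duration_s movie duration; defaults to covering all trials.
#' @param seed RNG seed.
#' @return a [widefield_movie()]; the response profile is attached as
#'   the `"profile"` attribute.
#' @export
make_widefield <- function(map, target_area, train, amplitude = 20,
                           baseline = 100, noise_sd = 0, rate = 10,
                           response_s = 1, duration_s = NULL, seed = 1L) {
  stopifnot(inherits(map, "area_map"), inherits(train, "stimulus_train"))
  if (!target_area %in% map$table$area_id) stop("unknown target area")
  set.seed(seed)
  sel <- which(map$labels == target_area, arr.ind = TRUE)
  if (!nrow(sel)) stop("target area has no pixels")
  cxy <- c(mean(sel[, 2L] - 0.5), mean(sel[, 1L] - 0.5))
  sigma <- max(sqrt(nrow(sel) / pi) / 2, 1)
  nr <- nrow(map$labels); nc <- ncol(map$labels)
  gx <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc)
  gy <- matrix(rep(seq_len(nr) - 0.5, times = nc), nr, nc)
  G <- exp(-((gx - cxy[1L])^2 + (gy - cxy[2L])^2) / (2 * sigma^2))
  G <- G / max(G)
  if (is.null(duration_s))
    duration_s <- max(train$onsets) + response_s + 1
  nt <- round(duration_s * rate)
  frames <- array(baseline, c(nt, nr, nc))
  for (on in train$onsets) {
    fr <- .frame_window(on, on + response_s, rate) + 1L
    fr <- fr[fr >= 1L & fr <= nt]
    for (f in fr) frames[f, , ] <- frames[f, , ] + amplitude * G
  }
  if (noise_sd > 0)
    frames <- pmax(frames + noise_sd * array(rnorm(length(frames)),
                                             dim(frames)), 0)
  mv <- widefield_movie(frames, rate)
  attr(mv, "profile") <- G
  mv
}

#' Write a complete synthetic session to disk
#'
#' Generates and writes one ground-truthed session bundle: area map
#' (TIFF + CSV), trace arrays (CSV session directory), behavior (long
#' CSV), landmark sets (CSV), a widefield mapping movie (TIFF), and the
#' ground truth (JSON).
#'
#' @param out_dir output directory (created).
#' @param n_neurons,duration_s,seed session size and seed.
#' @param n_areas areas in the synthetic map.
#' @param jitter_px landmark jitter passed to [warp_session()].
#' @return invisibly, the list of generated objects.
#' @export
simulate_session <- function(out_dir, n_neurons = 200L, duration_s = 120,
                             seed = 1L, n_areas = 30L, jitter_px = 0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  map <- make_area_map(n_areas, seed = seed)
  beh <- make_behavior(duration_s, seed = seed + 1L)
  pop <- make_population(n_neurons, map, coupling_spec(), beh, seed = seed + 2L)
  warp <- warp_session(map, cbind(pop$truth$x, pop$truth$y),
                       jitter_px = jitter_px, seed = seed + 3L)
  train <- stimulus_train("visual", seq(5, duration_s - 5, by = 10))
  wf <- make_widefield(map, target_area = 1L, train, seed = seed + 4L)
  write_area_map(map, file.path(out_dir, "map.tif"),
                 file.path(out_dir, "areas.csv"))
  # 2p-frame centroids are what an acquisition would provide
  tr <- pop$traces
  tr$centroids <- warp$centroids_2p
  write_session(tr, file.path(out_dir, "traces"))
  bdf <- do.call(rbind, lapply(names(beh$channels), function(nm) {
    ch <- beh$channels[[nm]]
    data.frame(channel = nm,
               time_s = ch$t0 + (seq_along(ch$values) - 1L) / ch$rate,
               value = ch$values)
  }))
  write.csv(bdf, file.path(out_dir, "behavior.csv"), row.names = FALSE)
  write_landmarks(warp$landmarks_ccf_mmm,
                  file.path(out_dir, "landmarks_ccf_mmm.csv"))
  write_landmarks(warp$landmarks_2p_mmm,
                  file.path(out_dir, "landmarks_2p_mmm.csv"))
  tiff::writeTIFF(lapply(seq_len(dim(wf$frames)[1L]), function(i)
    wf$frames[i, , ] / max(wf$frames)), file.path(out_dir, "widefield.tif"),
    bits.per.sample = 16L)
  jsonlite::write_json(pop$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(list(map = map, behavior = beh, population = pop, warp = warp,
                 widefield = wf))
}
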