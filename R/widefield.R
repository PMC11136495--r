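#' Widefield fluorescence movie
#'
#' @param frames 3D numeric array (time x rows x cols), nonnegative.
#' @param rate frame rate in Hz (> 0).
#' @return an object of class `widefield_movie`.
#' @export
widefield_movie <- function(frames, rate = 50) {
  if (is.null(dim(frames)) || length(dim(frames)) != 3L || dim(frames)[1L] < 1L)
    stop("frames must be a (time x rows x cols) array with >= 1 frame")
  if (any(frames < 0)) stop("intensities must be nonnegative")
  if (!is.numeric(rate) || rate <= 0) stop("rate must be > 0")
  structure(list(frames = frames, rate = rate), class = "widefield_movie")
}

#' Sensory stimulus train
#'
#' Onset times of repeated presentations of one sensory modality
#' (visual full-field noise, auditory tone cloud, or a 1 s 5 Hz burst of
#' whisker deflections).
#'
#' @param modality `"visual"`, `"auditory"` or `"whisker"`.
#' @param onsets onset times in seconds, strictly increasing.
#' @return an object of class `stimulus_train`.
#' @export
stimulus_train <- function(modality, onsets) {
  modality <- match.arg(modality, c("visual", "auditory", "whisker"))
  onsets <- as.numeric(onsets)
  if (length(onsets) && any(diff(onsets) <= 0))
    stop("onsets must be strictly increasing")
  structure(list(modality = modality, onsets = onsets),
            class = "stimulus_train")
}

#' Standard-deviation projection of a movie
#'
#' Per-pixel standard deviation across time with the population
#' convention (divisor n), the projection used to visualise cortical
#' vasculature from a 30 s widefield movie.
#'
#' @param movie a [widefield_movie()] or (time x rows x cols) array.
#' @return a 2D image matrix.
#' @export
std_projection <- function(movie) {
  frames <- if (inherits(movie, "widefield_movie")) movie$frames else movie
  if (length(dim(frames)) != 3L) stop("expected a (time x rows x cols) array")
  m <- colMeans(frames)           # rows x cols
  m2 <- colMeans(frames^2)
  sqrt(pmax(m2 - m^2, 0))
}

# closed-open frame windows in 0-based frame indices
.frame_window <- function(t0, t1, rate) {
  a <- floor(t0 * rate); b <- floor(t1 * rate)
  if (b <= a) integer(0) else seq.int(a, b - 1L)
}

#' Stimulus-triggered mean dF/F response image
#'
#' For each usable trial and pixel computes
#' `(mean response - mean baseline) / F0` where the baseline window is
#' `[onset - baseline_s, onset)`, the response window
#' `[onset, onset + response_s)` (closed-open, frame boundaries floored),
#' and `F0` is the global 10th percentile of all movie intensities.
#' Trials without a full baseline or response window inside the movie are
#' dropped with a warning. Returns the mean over trials.
#'
#' @param movie a [widefield_movie()].
#' @param train a [stimulus_train()].
#' @param baseline_s,response_s window durations in seconds.
#' @return a 2D mean dF/F image.
#' @export
stimulus_triggered_dff <- function(movie, train, baseline_s = 1,
                                   response_s = 1) {
  stopifnot(inherits(movie, "widefield_movie"),
            inherits(train, "stimulus_train"))
  nt <- dim(movie$frames)[1L]
  rate <- movie$rate
  f0 <- as.numeric(quantile(movie$frames, 0.10, type = 7))
  if (f0 <= 0) stop("F0 (global 10th percentile) must be positive")
  usable <- list()
  dropped <- 0L
  for (on in train$onsets) {
    bw <- .frame_window(on - baseline_s, on, rate)
    rw <- .frame_window(on, on + response_s, rate)
    if (!length(bw) || !length(rw) || min(bw) < 0L || max(rw) >= nt) {
      dropped <- dropped + 1L
    } else {
      usable[[length(usable) + 1L]] <- list(bw = bw + 1L, rw = rw + 1L)
    }
  }
  if (dropped > 0L)
    warning(sprintf("dropped %d trial(s) without full baseline/response windows",
                    dropped))
  if (!length(usable)) stop("no usable trials")
  acc <- 0
  for (tr in usable) {
    resp <- colMeans(movie$frames[tr$rw, , , drop = FALSE])
    base <- colMeans(movie$frames[tr$bw, , , drop = FALSE])
    acc <- acc + (resp - base) / f0
  }
  acc / length(usable)
}

#' Threshold a response image into a contiguous mask
#'
#' Pixels at or above `level_frac` of the image maximum are kept, then
#' reduced to the largest 4-connected component so the suprathreshold
#' area is contiguous. Returns the mask and its boundary outline (mask
#' pixels with a 4-neighbor outside the mask or off the raster).
#'
#' @param image 2D numeric image with a positive maximum.
#' @param level_frac threshold as a fraction of the maximum (default 0.5).
#' @return list with logical matrices `mask` and `outline`.
#' @export
threshold_mask <- function(image, level_frac = 0.5) {
  image <- as.matrix(image)
  mx <- max(image)
  if (!is.finite(mx) || mx <= 0) stop("image must have a positive maximum")
  mask <- image >= level_frac * mx
  lab <- .label_components4(mask)
  if (max(lab) > 1L) {
    sizes <- tabulate(lab[lab > 0L])
    mask <- lab == which.max(sizes)
  }
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  interior <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  list(mask = mask, outline = mask & !interior)
}

#' Sensory response map bundle
#'
#' Packages the mean response image of one modality with its thresholded
#' mask and outline.
#'
#' @param response_image 2D mean dF/F image.
#' @param modality stimulus modality.
#' @param level_frac threshold fraction passed to [threshold_mask()].
#' @return an object of class `sensory_map_result`.
#' @export
sensory_map_result <- function(response_image, modality, level_frac = 0.5) {
  tm <- threshold_mask(response_image, level_frac)
  structure(list(response_image = response_image, mask = tm$mask,
                 outline = tm$outline, modality = modality),
            class = "sensory_map_result")
}

#' Compose the multimodal map (MMM)
#'
#' Layers thresholded sensory-response masks and outlines onto the
#' vasculature image together with the skull landmarks (bregma, lambda,
#' ...) that anchor CCF registration. Purely compositional: no
#' resampling is performed, all layers must share the vasculature
#' image's shape.
#'
#' @param vessels 2D vasculature image (e.g. a [std_projection()]).
#' @param results list of [sensory_map_result()] overlays.
#' @param skull_landmarks named list (or n x 2 matrix with rownames) of
#'   (x, y) landmark positions; names must be unique.
#' @return an object of class `mmm` with elements `vessels`, `overlays`
#'   (named by modality) and `landmarks`.
#' @export
compose_mmm <- function(vessels, results = list(), skull_landmarks = list()) {
  vessels <- as.matrix(vessels)
  if (length(skull_landmarks)) {
    nm <- if (is.matrix(skull_landmarks)) rownames(skull_landmarks) else
      names(skull_landmarks)
    if (is.null(nm) || anyDuplicated(nm))
      stop("skull landmarks must have unique names")
  }
  overlays <- list()
  for (res in results) {
    stopifnot(inherits(res, "sensory_map_result"))
    if (!identical(dim(res$mask), dim(vessels)))
      stop("overlay shape does not match the vasculature image")
    overlays[[res$modality]] <- list(mask = res$mask, outline = res$outline)
  }
  structure(list(vessels = vessels, overlays = overlays,
                 landmarks = skull_landmarks), class = "mmm")
}
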