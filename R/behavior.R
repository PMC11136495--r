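#' Behavioral primitive time series
#'
#' Container for the arousal/movement primitives on their native clocks:
#' walk speed from the wheel encoder (100 Hz), whisker motion energy and
#' pupil diameter from the face cameras (30 Hz). Arbitrary extra
#' channels are allowed.
#'
#' @param ... named channels, each a list with `values` (numeric),
#'   `rate` (Hz > 0) and optional `t0` (start time in seconds, default
#'   0), or a bare numeric vector (then `rates` must name its rate).
#' @param rates optional named rates for bare-vector channels.
#' @return an object of class `behavior_timeseries`.
#' @export
behavior_timeseries <- function(..., rates = NULL) {
  chans <- list(...)
  if (length(chans) == 1L && is.null(names(chans)) && is.list(chans[[1L]]) &&
      !is.null(names(chans[[1L]])) && !("values" %in% names(chans[[1L]])))
    chans <- chans[[1L]]
  if (is.null(names(chans)) || any(names(chans) == ""))
    stop("channels must be named")
  out <- lapply(names(chans), function(nm) {
    ch <- chans[[nm]]
    if (is.numeric(ch)) ch <- list(values = ch, rate = rates[[nm]])
    if (is.null(ch$rate) || ch$rate <= 0) stop("channel rate must be > 0")
    if (is.null(ch$t0)) ch$t0 <- 0
    ch$values <- as.numeric(ch$values)
    ch[c("values", "rate", "t0")]
  })
  names(out) <- names(chans)
  structure(list(channels = out), class = "behavior_timeseries")
}

#' @export
print.behavior_timeseries <- function(x, ...) {
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    cat(sprintf("  %s: %d samples at %g Hz (t0 = %g s)\n", nm,
                length(ch$values), ch$rate, ch$t0))
  }
  invisible(x)
}

#' Motion energy of a video region
#'
#' `ME[t] = sum over the ROI of |frame_t - frame_(t-1)|`, with
#' `ME[1] = 0`. Invariant to adding a constant to all frames.
#'
#' @param frames (time x rows x cols) video array with >= 2 frames.
#' @param roi logical matrix selecting the pixels to sum over.
#' @return numeric vector, one value per frame.
#' @export
motion_energy <- function(frames, roi) {
  if (length(dim(frames)) != 3L || dim(frames)[1L] < 2L)
    stop("frames must be a (time x rows x cols) array with >= 2 frames")
  roi <- as.matrix(roi)
  if (!identical(dim(roi), dim(frames)[2:3]))
    stop("roi must match the frame shape")
  if (!any(roi)) stop("roi is empty")
  nt <- dim(frames)[1L]
  flat <- matrix(frames, nt)[, as.vector(roi), drop = FALSE]
  c(0, rowSums(abs(flat[-1L, , drop = FALSE] - flat[-nt, , drop = FALSE])))
}

#' Harmonize behavior channels onto one 10 Hz grid
#'
#' Resamples every channel (via [resample_to()]: decimation without
#' prior filtering for integer ratios) onto a single grid at
#' `target_rate` covering the overlapping time span of all channels.
#'
#' @param b a [behavior_timeseries()].
#' @param target_rate common analysis rate, default 10 Hz.
#' @return list with `mat` (channels x time matrix, rownames = channel
#'   names) and `times` (grid in seconds).
#' @export
harmonize <- function(b, target_rate = 10) {
  stopifnot(inherits(b, "behavior_timeseries"))
  t0 <- vapply(b$channels, function(ch) ch$t0, numeric(1L))
  tend <- vapply(b$channels, function(ch)
    ch$t0 + length(ch$values) / ch$rate, numeric(1L))
  lo <- max(t0); hi <- min(tend)
  if (hi <= lo) stop("channels have no overlapping time span")
  rows <- lapply(b$channels, function(ch) {
    v <- resample_to(ch$values, ch$rate, target_rate)
    # drop leading samples before the common span
    skip <- round((lo - ch$t0) * target_rate)
    v[(skip + 1L):length(v)]
  })
  len <- min(lengths(rows), floor((hi - lo) * target_rate))
  mat <- do.call(rbind, lapply(rows, function(v) v[seq_len(len)]))
  rownames(mat) <- names(b$channels)
  list(mat = mat, times = lo + (seq_len(len) - 1L) / target_rate)
}

#' Detect supra-threshold bouts in a behavioral series
#'
#' Maximal runs of samples strictly above `threshold`, discarded when
#' shorter than `min_duration_s` (the 900 ms default mirrors common
#' behavioral-motif segmentation settings). Intervals are reported as
#' closed-open `[start_s, end_s)` on the series' clock.
#'
#' @param series numeric vector sampled at `rate`.
#' @param threshold detection threshold (finite; channel units).
#' @param min_duration_s minimum bout duration in seconds.
#' @param rate sampling rate in Hz, default 10.
#' @return data.frame of class `bout_list` with columns `start_s`,
#'   `end_s`; threshold and rate kept as attributes.
#' @export
detect_bouts <- function(series, threshold, min_duration_s = 0.9,
                         rate = 10) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  above <- series > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / rate) >= min_duration_s
  out <- data.frame(start_s = (starts[keep] - 1L) / rate,
                    end_s = ends[keep] / rate)
  attr(out, "threshold") <- threshold
  attr(out, "rate") <- rate
  class(out) <- c("bout_list", "data.frame")
  out
}
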