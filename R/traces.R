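#' ROI fluorescence traces from a segmentation session
#'
#' Raw and neuropil fluorescence for every segmented ROI, the
#' classifier-assigned cell probabilities, ROI centroids in 2p pixels,
#' and the acquisition rate. This mirrors the per-session outputs of
#' Suite2p-style ROI extraction, which this package consumes rather than
#' reproduces.
#'
#' @param F neurons x time raw fluorescence matrix.
#' @param Fneu neurons x time neuropil fluorescence matrix (same shape).
#' @param cellprob per-neuron cell probability in `[0, 1]`.
#' @param centroids neurons x 2 matrix of (x, y) centroids in 2p pixels.
#' @param rate acquisition rate in Hz (> 0).
#' @return an object of class `roi_traces`.
#' @export
roi_traces <- function(F, Fneu, cellprob, centroids, rate) {
  F <- as.matrix(F); Fneu <- as.matrix(Fneu)
  if (!identical(dim(F), dim(Fneu))) stop("F and Fneu must share shape")
  n <- nrow(F)
  if (length(cellprob) != n) stop("cellprob length must equal neuron count")
  if (any(cellprob < 0 | cellprob > 1)) stop("cellprob must lie in [0, 1]")
  centroids <- .as_points(centroids)
  if (nrow(centroids) != n) stop("centroids must have one row per neuron")
  if (!is.numeric(rate) || rate <= 0) stop("rate must be > 0")
  structure(list(F = F, Fneu = Fneu, cellprob = as.numeric(cellprob),
                 centroids = centroids, rate = rate),
            class = "roi_traces")
}

#' @export
print.roi_traces <- function(x, ...) {
  cat(sprintf("roi_traces: %d ROIs x %d samples at %.3g Hz\n",
              nrow(x$F), ncol(x$F), x$rate))
  invisible(x)
}

#' dF/F extraction configuration
#'
#' Defaults follow standard mesoscale GCaMP6s practice: neuropil
#' coefficient 0.7, rolling 10th (or 15th) percentile baseline over a
#' 30-60 s window, classifier threshold 0.5, and a common 10 Hz analysis
#' grid.
#'
#' @param neuropil_coef neuropil subtraction coefficient gamma in `[0, 1]`.
#' @param baseline_percentile rolling-baseline percentile (0, 50).
#' @param baseline_window_s rolling window length in seconds (> 0).
#' @param prob_threshold minimum cell probability kept.
#' @param target_rate analysis rate in Hz.
#' @return a list of class `trace_config`.
#' @export
trace_config <- function(neuropil_coef = 0.7, baseline_percentile = 10,
                         baseline_window_s = 30, prob_threshold = 0.5,
                         target_rate = 10) {
  if (neuropil_coef < 0 || neuropil_coef > 1)
    stop("neuropil_coef must lie in [0, 1]")
  if (baseline_percentile <= 0 || baseline_percentile >= 50)
    stop("baseline_percentile must lie in (0, 50)")
  if (baseline_window_s <= 0) stop("baseline_window_s must be > 0")
  structure(list(neuropil_coef = neuropil_coef,
                 baseline_percentile = baseline_percentile,
                 baseline_window_s = baseline_window_s,
                 prob_threshold = prob_threshold,
                 target_rate = target_rate), class = "trace_config")
}

#' Screen ROIs by classifier cell probability
#'
#' Keeps ROIs whose cell probability is at or above the threshold (ROIs
#' with probability below 0.5 are excluded by default) and records the
#' surviving original indices in the `"kept_indices"` attribute
#' (0-based).
#'
#' @param traces an [roi_traces()].
#' @param threshold minimum probability kept.
#' @return the screened [roi_traces()].
#' @export
screen_cells <- function(traces, threshold = 0.5) {
  stopifnot(inherits(traces, "roi_traces"))
  keep <- traces$cellprob >= threshold
  if (!any(keep))
    stop(sprintf("no ROIs survive screening (0 of %d at threshold %.2f)",
                 length(keep), threshold))
  out <- roi_traces(traces$F[keep, , drop = FALSE],
                    traces$Fneu[keep, , drop = FALSE],
                    traces$cellprob[keep],
                    traces$centroids[keep, , drop = FALSE],
                    traces$rate)
  attr(out, "kept_indices") <- which(keep) - 1L
  out
}

#' Neuropil subtraction
#'
#' `Fsub = F - gamma * Fneu`, the standard correction for out-of-focus
#' surround fluorescence with the conventional coefficient 0.7.
#'
#' @param F,Fneu matrices of identical shape.
#' @param gamma neuropil coefficient.
#' @return the corrected matrix.
#' @export
neuropil_subtract <- function(F, Fneu, gamma = 0.7) {
  F <- as.matrix(F); Fneu <- as.matrix(Fneu)
  if (!identical(dim(F), dim(Fneu))) stop("F and Fneu must share shape")
  F - gamma * Fneu
}

#' Rolling-percentile baseline
#'
#' For each sample, the linear-interpolation percentile of the trace
#' over a centered window of `window_frames` samples; the window is
#' clamped at the trace edges (it shrinks near boundaries), so a window
#' longer than the trace yields the full-trace percentile everywhere.
#'
#' @param trace numeric vector or neurons x time matrix.
#' @param window_frames window length in samples (>= 1).
#' @param percentile percentile in (0, 100).
#' @return baseline of the same shape as `trace`.
#' @export
rolling_percentile_baseline <- function(trace, window_frames, percentile) {
  if (window_frames < 1L) stop("window_frames must be >= 1")
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must lie in (0, 100)")
  if (is.matrix(trace)) {
    if (ncol(trace) == 0L) stop("empty trace")
    out <- t(apply(trace, 1L, .roll_percentile_cpp,
                   window = as.integer(window_frames), p = percentile))
    dimnames(out) <- dimnames(trace)
    return(out)
  }
  if (!length(trace)) stop("empty trace")
  .roll_percentile_cpp(as.numeric(trace), as.integer(window_frames),
                       percentile)
}

#' Baseline-normalised fluorescence (dF/F)
#'
#' `(Fsub - F0) / F0` elementwise; every baseline value must be
#' strictly positive.
#'
#' @param Fsub neuropil-subtracted fluorescence (vector or matrix).
#' @param F0 baseline of the same shape.
#' @return dF/F of the same shape.
#' @export
dff <- function(Fsub, F0) {
  if (!identical(dim(Fsub), dim(F0)) || length(Fsub) != length(F0))
    stop("Fsub and F0 must share shape")
  if (any(F0 <= 0)) {
    bad <- if (is.matrix(F0)) which(apply(F0 <= 0, 1L, any)) else 1L
    stop("non-positive baseline for neuron(s): ",
         paste(bad - 1L, collapse = ", "))
  }
  (Fsub - F0) / F0
}

# Fourier-method upsampling of a real series to m > n samples: zero-pad
# the spectrum, splitting the Nyquist bin symmetrically for even n
.fourier_resample <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  stopifnot(m > n)
  X <- fft(x)
  Y <- complex(real = numeric(m), imaginary = numeric(m))
  if (n %% 2L == 0L) {
    h <- n %/% 2L
    Y[1:h] <- X[1:h]
    Y[h + 1L] <- X[h + 1L] / 2
    Y[m - h + 1L] <- X[h + 1L] / 2
    if (h > 1L) Y[(m - h + 2L):m] <- X[(h + 2L):n]
  } else {
    h <- (n - 1L) %/% 2L
    Y[1:(h + 1L)] <- X[1:(h + 1L)]
    if (h > 0L) Y[(m - h + 1L):m] <- X[(n - h + 1L):n]
  }
  Re(fft(Y, inverse = TRUE)) / n
}

#' Resample a series to a target rate
#'
#' Integer downsample ratios take every k-th sample with no prior
#' filtering; upsampling uses Fourier-method resampling to
#' `round(n * target / src)` samples; non-integer downsampling falls
#' back to linear interpolation onto the target grid (noted via a
#' message).
#'
#' @param series numeric vector, or neurons x time matrix.
#' @param src_rate source rate in Hz (> 0).
#' @param target_rate target rate in Hz (> 0), default 10.
#' @return the resampled series (vector or matrix).
#' @export
resample_to <- function(series, src_rate, target_rate = 10) {
  if (src_rate <= 0 || target_rate <= 0) stop("rates must be positive")
  if (is.matrix(series)) {
    rows <- lapply(seq_len(nrow(series)), function(i)
      resample_to(series[i, ], src_rate, target_rate))
    return(do.call(rbind, rows))
  }
  n <- length(series)
  if (src_rate == target_rate) return(series)
  ratio <- src_rate / target_rate
  if (ratio > 1 && abs(ratio - round(ratio)) < 1e-9) {
    k <- as.integer(round(ratio))
    return(series[seq.int(1L, n, by = k)])
  }
  if (target_rate > src_rate) {
    m <- as.integer(round(n * target_rate / src_rate))
    return(.fourier_resample(as.numeric(series), m))
  }
  message("non-integer downsample ratio; using linear interpolation")
  t_src <- (seq_len(n) - 1L) / src_rate
  t_new <- seq(0, t_src[n], by = 1 / target_rate)
  approx(t_src, series, xout = t_new, rule = 2)$y
}

#' Run the full dF/F pipeline on a session
#'
#' Screens ROIs by cell probability, subtracts neuropil, computes the
#' rolling-percentile baseline, normalises to dF/F, and resamples to
#' the common analysis grid.
#'
#' @param traces an [roi_traces()].
#' @param config a [trace_config()].
#' @return list of class `dff_result`: `dff` (neurons x time at
#'   `rate`), `F0` (at acquisition rate), `rate`, `kept_indices`
#'   (0-based original indices), `centroids`.
#' @export
run_dff_pipeline <- function(traces, config = trace_config()) {
  stopifnot(inherits(traces, "roi_traces"))
  kept <- screen_cells(traces, config$prob_threshold)
  fsub <- neuropil_subtract(kept$F, kept$Fneu, config$neuropil_coef)
  win <- max(1L, as.integer(round(config$baseline_window_s * kept$rate)))
  f0 <- rolling_percentile_baseline(fsub, win, config$baseline_percentile)
  d <- dff(fsub, f0)
  d10 <- resample_to(d, kept$rate, config$target_rate)
  structure(list(dff = d10, F0 = f0, rate = config$target_rate,
                 kept_indices = attr(kept, "kept_indices"),
                 centroids = kept$centroids),
            class = "dff_result")
}

#' Session trace I/O as plain CSV arrays
#'
#' Reads / writes a segmentation session as four CSV files in a
#' directory: `F.csv` and `Fneu.csv` (neurons x time, no header),
#' `cellprob.csv` (one probability per line) and `centroids.csv`
#' (columns `x,y`), plus `rate.txt` holding the acquisition rate.
#'
#' @param traces an [roi_traces()]; `dir` the session directory.
#' @param dir session directory.
#' @name traces_io
#' @export
write_session <- function(traces, dir) {
  stopifnot(inherits(traces, "roi_traces"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(traces$F, file.path(dir, "F.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(traces$Fneu, file.path(dir, "Fneu.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  writeLines(format(traces$cellprob, digits = 17),
             file.path(dir, "cellprob.csv"))
  write.csv(data.frame(x = traces$centroids[, 1L],
                       y = traces$centroids[, 2L]),
            file.path(dir, "centroids.csv"), row.names = FALSE)
  writeLines(format(traces$rate, digits = 17), file.path(dir, "rate.txt"))
  invisible(dir)
}

#' @rdname traces_io
#' @export
read_session <- function(dir) {
  F <- as.matrix(read.csv(file.path(dir, "F.csv"), header = FALSE))
  Fneu <- as.matrix(read.csv(file.path(dir, "Fneu.csv"), header = FALSE))
  dimnames(F) <- dimnames(Fneu) <- NULL
  cellprob <- as.numeric(readLines(file.path(dir, "cellprob.csv")))
  cen <- read.csv(file.path(dir, "centroids.csv"))
  rate <- as.numeric(readLines(file.path(dir, "rate.txt")))
  roi_traces(F, Fneu, cellprob, cbind(cen$x, cen$y), rate)
}
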