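#' Per-neuron correlation with a behavioral regressor
#'
#' Pearson correlation of every neuron's dF/F trace with one behavioral
#' primitive on the common grid. Zero-variance neurons get `r = 0` and a
#' flag (rather than `NA`) so that area means remain defined; flagged
#' neurons are excluded from t-tests downstream.
#'
#' @param dff_10hz neurons x time matrix.
#' @param regressor_10hz numeric vector of the same time length (>= 3).
#' @return data.frame with columns `r` and `zero_variance`.
#' @export
neuron_behavior_corr <- function(dff_10hz, regressor_10hz) {
  dff_10hz <- as.matrix(dff_10hz)
  nt <- ncol(dff_10hz)
  if (length(regressor_10hz) != nt)
    stop("regressor length must match the dF/F time axis")
  if (nt < 3L) stop("need at least 3 timepoints")
  s_reg <- sd(regressor_10hz)
  rs <- apply(dff_10hz, 1L, function(x) {
    if (sd(x) == 0 || s_reg == 0) NA_real_ else cor(x, regressor_10hz)
  })
  flagged <- is.na(rs)
  rs[flagged] <- 0
  data.frame(r = rs, zero_variance = flagged)
}

#' One-sample t-test (closed form)
#'
#' `t = mean / (sd / sqrt(n))` with the n-1 divisor in `sd`,
#' `df = n - 1`, and a Student-t p-value (two-sided by default; the
#' one-sided alternative tests for a mean greater than zero).
#'
#' @param values numeric sample, `n >= 2`, nonzero variance.
#' @param alternative `"two.sided"` or `"greater"`.
#' @return list with `t`, `df`, `p`.
#' @export
onesample_t <- function(values, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  s <- sd(values)
  if (s == 0) stop("zero variance")
  t <- mean(values) / (s / sqrt(n))
  df <- n - 1L
  p <- if (alternative == "two.sided") 2 * pt(-abs(t), df) else
    pt(t, df, lower.tail = FALSE)
  list(t = t, df = df, p = p)
}

#' Per-area mean correlations with a one-sample t-test
#'
#' Averages the per-neuron correlations of one behavioral channel
#' within each cortical area and tests whether the mean differs from
#' zero. Only areas with at least `min_n` neurons are included
#' (excluded areas are still reported, with their n and
#' `included = FALSE`). Zero-variance (flagged) neurons enter the mean
#' as r = 0 but are dropped from the t-test.
#'
#' @param table neuron table: data.frame with columns `area_id`,
#'   `acronym`, the correlation column named by `channel` (e.g.
#'   `r_walk`), and optionally `zero_variance`.
#' @param channel name of the correlation column.
#' @param min_n minimum neurons per included area (default 20).
#' @param alternative passed to [onesample_t()] (two-sided default).
#' @return data.frame of class `area_stats` with per-area `n`,
#'   `mean_r`, `t`, `df`, `p`, `included`.
#' @export
area_mean_corr <- function(table, channel, min_n = 20L,
                           alternative = "two.sided") {
  if (!channel %in% names(table)) stop("unknown correlation column: ", channel)
  tab <- table[!is.na(table$area_id), , drop = FALSE]
  if (!nrow(tab)) stop("no neurons with area assignments")
  flagged <- if ("zero_variance" %in% names(tab)) tab$zero_variance else
    rep(FALSE, nrow(tab))
  areas <- sort(unique(tab$area_id))
  rows <- lapply(areas, function(a) {
    sel <- tab$area_id == a
    r <- tab[[channel]][sel]
    n <- sum(sel)
    inc <- n >= min_n
    tt <- list(t = NA_real_, df = NA_integer_, p = NA_real_)
    if (inc) {
      rt <- tab[[channel]][sel & !flagged]
      if (length(rt) >= 2L && sd(rt) > 0)
        tt <- onesample_t(rt, alternative)
    }
    data.frame(area_id = a,
               acronym = tab$acronym[which(sel)[1L]],
               n = n, mean_r = mean(r), t = tt$t, df = tt$df, p = tt$p,
               included = inc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!any(out$included)) stop("no areas reach the minimum neuron count")
  class(out) <- c("area_stats", "data.frame")
  out
}

#' Density of a sorted group across cortical areas
#'
#' For each area with at least `min_n` neurons in the table, the
#' percent of that area's neurons that belong to the given group.
#' Smaller areas are reported as not-reported (percent `NA`), matching
#' the convention of leaving unreliable density estimates blank.
#'
#' @param table neuron table with columns `area_id`, `acronym`, `group`.
#' @param group group label to map.
#' @param min_n minimum neurons per reported area (default 20).
#' @return data.frame of class `density_map` with per-area `n`,
#'   `n_in_group`, `percent`, `reported`.
#' @export
group_area_density <- function(table, group, min_n = 20L) {
  tab <- table[!is.na(table$area_id), , drop = FALSE]
  if (!"group" %in% names(tab)) stop("table has no group column")
  if (!group %in% tab$group) stop("unknown group: ", group)
  areas <- sort(unique(tab$area_id))
  rows <- lapply(areas, function(a) {
    sel <- tab$area_id == a
    n <- sum(sel)
    k <- sum(sel & tab$group == group)
    rep_ok <- n >= min_n
    data.frame(area_id = a, acronym = tab$acronym[which(sel)[1L]],
               n = n, n_in_group = k,
               percent = if (rep_ok) 100 * k / n else NA_real_,
               reported = rep_ok, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "group") <- group
  class(out) <- c("density_map", "data.frame")
  out
}

#' Mode bin and skewness of a correlation distribution
#'
#' Histogram mode over `[-1, 1]` in bins of width 0.05 (the center of
#' the fullest bin; first on ties) and the adjusted Fisher-Pearson
#' skewness coefficient
#' `G1 = g1 * sqrt(n (n - 1)) / (n - 2)` with `g1 = m3 / m2^(3/2)`.
#'
#' @param r numeric vector of correlations (>= 3 values).
#' @return list with `mode_bin` (bin center) and `skewness`.
#' @export
corr_distribution_stats <- function(r) {
  n <- length(r)
  if (n < 3L) stop("need at least 3 values")
  breaks <- seq(-1, 1, by = 0.05)
  counts <- tabulate(findInterval(r, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE),
                     nbins = length(breaks) - 1L)
  mode_bin <- breaks[which.max(counts)] + 0.025
  m <- mean(r)
  m2 <- mean((r - m)^2)
  m3 <- mean((r - m)^3)
  g1 <- if (m2 > 0) m3 / m2^1.5 else 0
  skew <- g1 * sqrt(n * (n - 1)) / (n - 2)
  list(mode_bin = mode_bin, skewness = skew)
}

#' Mean group activity per behavioral motif
#'
#' Entry (g, m) is the mean of group g's trace over the samples
#' carrying motif label m. Motifs with zero labelled samples are
#' reported as absent (`NA` column, listed in the `"absent"`
#' attribute). Unlabelled samples are marked with `NA` in
#' `motif_labels` and ignored.
#'
#' @param group_mean_traces groups x time matrix (rownames = groups).
#' @param motif_labels integer label per sample (`NA` = unlabelled),
#'   same length as the time axis.
#' @param motif_set motifs to report; defaults to the labels present.
#' @return groups x motifs matrix with an `"absent"` attribute.
#' @export
motif_aligned_group_activity <- function(group_mean_traces, motif_labels,
                                         motif_set = NULL) {
  group_mean_traces <- as.matrix(group_mean_traces)
  if (length(motif_labels) != ncol(group_mean_traces))
    stop("label stream length must match the trace time axis")
  if (is.null(motif_set))
    motif_set <- sort(unique(motif_labels[!is.na(motif_labels)]))
  out <- matrix(NA_real_, nrow(group_mean_traces), length(motif_set),
                dimnames = list(rownames(group_mean_traces),
                                as.character(motif_set)))
  absent <- logical(length(motif_set))
  for (j in seq_along(motif_set)) {
    sel <- !is.na(motif_labels) & motif_labels == motif_set[j]
    if (!any(sel)) {
      absent[j] <- TRUE
    } else {
      out[, j] <- rowMeans(group_mean_traces[, sel, drop = FALSE])
    }
  }
  attr(out, "absent") <- motif_set[absent]
  out
}

#' Paint a group density map onto the area raster
#'
#' Renders a [group_area_density()] result as an image on the
#' [area_map()] raster: reported areas on a white-to-red scale,
#' not-reported areas white, background grey.
#'
#' @param density a `density_map`.
#' @param map the [area_map()] the table was assigned against.
#' @param ... passed to [graphics::image()].
#' @importFrom graphics image
#' @importFrom grDevices colorRampPalette
#' @export
plot_density_map <- function(density, map, ...) {
  stopifnot(inherits(density, "density_map"), inherits(map, "area_map"))
  pct <- density$percent[match(map$labels, density$area_id)]
  img <- matrix(pct, nrow(map$labels), ncol(map$labels))
  img[map$labels == 0L] <- NA
  img[is.na(img) & map$labels > 0L] <- 0
  pal <- colorRampPalette(c("white", "red"))(64L)
  image(t(img)[, rev(seq_len(nrow(img)))], col = pal, axes = FALSE,
        zlim = c(0, max(img, na.rm = TRUE) + 1e-9), ...)
  invisible(img)
}
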