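# Independent brute-force oracles used to pin down the fast implementations.

# rolling percentile: explicit window extraction + R's linear-interpolation
# quantile, one call per sample
oracle_roll_pct <- function(x, w, p) {
  n <- length(x)
  back <- (w - 1L) %/% 2L
  fwd <- w - 1L - back
  vapply(seq_len(n), function(t) {
    lo <- max(1L, t - back)
    hi <- min(n, t + fwd)
    as.numeric(quantile(x[lo:hi], p / 100, type = 7))
  }, numeric(1L))
}

# peak nonnegative-lag cross-correlation: plain loop over lags
oracle_xcorr <- function(x, y, L) {
  n <- length(x)
  best <- -Inf; best_lag <- 0L
  for (l in 0:L) {
    a <- x[1:(n - l)]; b <- y[(1 + l):n]
    r <- if (sd(a) == 0 || sd(b) == 0) 0 else cor(a, b)
    if (r > best) { best <- r; best_lag <- l }
  }
  list(value = best, lag = best_lag)
}

# bout detection: explicit sample-by-sample run scan
oracle_bouts <- function(series, thr, min_dur, rate) {
  above <- series > thr
  bouts <- NULL
  i <- 1L; n <- length(series)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      if ((j - i + 1L) / rate >= min_dur)
        bouts <- rbind(bouts, c((i - 1L) / rate, j / rate))
      i <- j + 1L
    } else i <- i + 1L
  }
  if (is.null(bouts)) matrix(numeric(0), 0L, 2L) else bouts
}

# per-pixel std projection (divisor n): explicit pixel loop
oracle_std <- function(frames) {
  d <- dim(frames)
  out <- matrix(0, d[2L], d[3L])
  for (r in seq_len(d[2L])) for (c in seq_len(d[3L])) {
    v <- frames[, r, c]
    out[r, c] <- sqrt(mean((v - mean(v))^2))
  }
  out
}

# area lookup: per-point exhaustive scan over all pixels
oracle_lookup <- function(map, pts) {
  lab <- map$labels
  nr <- nrow(lab); nc <- ncol(lab)
  vapply(seq_len(nrow(pts)), function(i) {
    x <- pts[i, 1L]; y <- pts[i, 2L]
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (floor(x) == c - 1L && floor(y) == r - 1L) {
        v <- lab[r, c]
        return(if (v == 0L) NA_integer_ else v)
      }
    }
    NA_integer_
  }, integer(1L))
}

# nearest-neighbor label-volume rotation about the AP axis + first-nonzero
# projection, as explicit voxel loops
oracle_rotate_project <- function(vol, theta_deg) {
  d <- dim(vol); ny <- d[1L]; nx <- d[2L]; nz <- d[3L]
  nzi <- which(vol != 0, arr.ind = TRUE)
  cx <- mean(nzi[, 2L]); cz <- mean(nzi[, 3L])
  th <- theta_deg * pi / 180
  rot <- array(0L, d)
  for (y in 1:ny) for (x in 1:nx) for (z in 1:nz) {
    sx <- round(cx + cos(th) * (x - cx) + sin(th) * (z - cz))
    sz <- round(cz - sin(th) * (x - cx) + cos(th) * (z - cz))
    if (sx >= 1 && sx <= nx && sz >= 1 && sz <= nz)
      rot[y, x, z] <- vol[y, sx, sz]
  }
  out <- matrix(0L, ny, nx)
  for (y in 1:ny) for (x in 1:nx) for (z in 1:nz)
    if (out[y, x] == 0L && rot[y, x, z] != 0L) out[y, x] <- rot[y, x, z]
  out
}

# 4-connectivity check of a logical mask by iterative dilation from one seed
oracle_is_connected4 <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(TRUE)
  nr <- nrow(mask)
  reach <- matrix(FALSE, nr, ncol(mask))
  reach[idx[1L]] <- TRUE
  repeat {
    grown <- reach
    grown[-1L, ] <- grown[-1L, ] | reach[-nr, ]
    grown[-nr, ] <- grown[-nr, ] | reach[-1L, ]
    grown[, -1L] <- grown[, -1L] | reach[, -ncol(mask)]
    grown[, -ncol(mask)] <- grown[, -ncol(mask)] | reach[, -1L]
    grown <- grown & mask
    if (identical(grown, reach)) break
    reach <- grown
  }
  all(reach[mask])
}

# random small affine with bounded condition, for round-trip properties
random_affine <- function() {
  repeat {
    A <- rbind(c(runif(1, 0.5, 2), runif(1, -0.5, 0.5), runif(1, -20, 20)),
               c(runif(1, -0.5, 0.5), runif(1, 0.5, 2), runif(1, -20, 20)))
    if (abs(det(A[, 1:2])) > 0.1) return(A)
  }
}

affine_apply <- function(A, pts) cbind(pts, 1) %*% t(A)
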