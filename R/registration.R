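#' Landmark point-pair set
#'
#' User-curated pairs of corresponding points between two coordinate
#' frames (`ccf`, `mmm`, `twop`), e.g. bounding-box corners, bregma and
#' lambda, or blood-vessel intersections.
#'
#' @param src,dst n x 2 matrices of (x, y) in the source / target frame.
#' @param frame_from,frame_to frame names, one of `"ccf"`, `"mmm"`,
#'   `"twop"`.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(src, dst, frame_from, frame_to) {
  src <- .as_points(src); dst <- .as_points(dst)
  frame_from <- match.arg(frame_from, c("ccf", "mmm", "twop"))
  frame_to <- match.arg(frame_to, c("ccf", "mmm", "twop"))
  if (nrow(src) != nrow(dst)) stop("src and dst must pair up")
  if (nrow(src) < 3L) stop("at least 3 landmark pairs are required")
  if (any(!is.finite(src)) || any(!is.finite(dst)))
    stop("landmark coordinates must be finite")
  if (anyDuplicated(src) > 0L) stop("duplicated source points")
  structure(list(src = src, dst = dst, frame_from = frame_from,
                 frame_to = frame_to), class = "landmark_set")
}

# --- Delaunay triangulation (Bowyer-Watson) ------------------------------
# Returns an m x 3 matrix of vertex indices into pts, or a 0-row matrix
# when the points are degenerate (e.g. collinear).
.circum <- function(p, a, b, c) {
  ax <- p[a, 1L]; ay <- p[a, 2L]; bx <- p[b, 1L]; by <- p[b, 2L]
  cx <- p[c, 1L]; cy <- p[c, 2L]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(NULL)
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  c(ux, uy, (ax - ux)^2 + (ay - uy)^2)
}

.delaunay <- function(pts) {
  n <- nrow(pts)
  span <- max(apply(pts, 2L, function(v) diff(range(v))), 1)
  cx <- mean(range(pts[, 1L])); cy <- mean(range(pts[, 2L]))
  big <- 50 * span
  allp <- rbind(pts,
                c(cx - big, cy - big), c(cx + big, cy - big), c(cx, cy + big))
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L
  tris <- list(c(s1, s2, s3))
  ccs <- list(.circum(allp, s1, s2, s3))
  for (i in seq_len(n)) {
    px <- allp[i, 1L]; py <- allp[i, 2L]
    bad <- vapply(ccs, function(cc) {
      !is.null(cc) && (px - cc[1L])^2 + (py - cc[2L])^2 <= cc[3L] * (1 + 1e-12)
    }, logical(1L))
    bad[vapply(ccs, is.null, logical(1L))] <- FALSE
    edges <- list()
    for (t in which(bad)) {
      v <- tris[[t]]
      edges <- c(edges, list(sort(v[c(1L, 2L)]), sort(v[c(2L, 3L)]),
                             sort(v[c(1L, 3L)])))
    }
    keep_tri <- tris[!bad]; keep_cc <- ccs[!bad]
    if (length(edges)) {
      key <- vapply(edges, paste, character(1L), collapse = "-")
      boundary <- edges[key %in% names(which(table(key) == 1L))]
      for (e in boundary) {
        newt <- c(e[1L], e[2L], i)
        cc <- .circum(allp, newt[1L], newt[2L], newt[3L])
        if (is.null(cc)) next  # degenerate sliver, skip
        keep_tri <- c(keep_tri, list(newt))
        keep_cc <- c(keep_cc, list(cc))
      }
    }
    tris <- keep_tri; ccs <- keep_cc
  }
  keep <- vapply(tris, function(v) all(v <= n), logical(1L))
  if (!any(keep)) return(matrix(integer(0), 0L, 3L))
  do.call(rbind, tris[keep])
}

# exact affine mapping a source triangle onto a target triangle (2 x 3)
.tri_affine <- function(src3, dst3) {
  X <- cbind(src3, 1)
  t(solve(X, dst3))   # 2 x 3 after transpose of 3 x 2
}

.fit_affine_matrix <- function(src, dst) {
  X <- cbind(src, 1)
  if (qr(X)$rank < 3L) stop("landmarks are collinear; affine fit is degenerate")
  t(qr.solve(X, dst))  # 2 x 3
}

#' Fit a planar transform from landmark pairs
#'
#' Affine transforms are least-squares fits on homogeneous coordinates;
#' piecewise-affine transforms are a Delaunay triangulation of the
#' source points with one exact affine map per triangle (exact at every
#' control point), plus a global affine used for points outside the
#' source hull. `kind = "auto"` picks affine for fewer than 6 pairs and
#' piecewise-affine for 6 or more.
#'
#' @param landmarks a [landmark_set()].
#' @param kind `"auto"`, `"affine"` or `"piecewise_affine"`.
#' @return an object of class `transform2d` with a fitted RMS residual
#'   (pixels) in `$residual`.
#' @export
fit_transform <- function(landmarks, kind = c("auto", "affine",
                                              "piecewise_affine")) {
  stopifnot(inherits(landmarks, "landmark_set"))
  kind <- match.arg(kind)
  n <- nrow(landmarks$src)
  if (kind == "auto") kind <- if (n < 6L) "affine" else "piecewise_affine"
  A <- .fit_affine_matrix(landmarks$src, landmarks$dst)
  if (kind == "affine") {
    pred <- cbind(landmarks$src, 1) %*% t(A)
    res <- sqrt(mean(rowSums((pred - landmarks$dst)^2)))
    return(structure(list(kind = "affine", A = A, landmarks = landmarks,
                          frame_from = landmarks$frame_from,
                          frame_to = landmarks$frame_to, residual = res),
                     class = "transform2d"))
  }
  if (n < 4L) stop("piecewise-affine fitting needs at least 4 pairs")
  tri <- .delaunay(landmarks$src)
  if (nrow(tri) == 0L) stop("source points are degenerate (collinear)")
  affines <- lapply(seq_len(nrow(tri)), function(i) {
    .tri_affine(landmarks$src[tri[i, ], , drop = FALSE],
                landmarks$dst[tri[i, ], , drop = FALSE])
  })
  structure(list(kind = "piecewise_affine", tri = tri, affines = affines,
                 A = A, landmarks = landmarks,
                 frame_from = landmarks$frame_from,
                 frame_to = landmarks$frame_to, residual = 0),
            class = "transform2d")
}

#' @export
print.transform2d <- function(x, ...) {
  cat(sprintf("transform2d (%s): %s -> %s, residual %.3g px\n",
              x$kind, x$frame_from, x$frame_to, x$residual))
  invisible(x)
}

#' Apply a fitted transform to points
#'
#' Points outside the source hull of a piecewise-affine transform are
#' mapped through the global affine fitted to all pairs and flagged in
#' the `"out_of_hull"` attribute of the result.
#'
#' @param trans a `transform2d` from [fit_transform()].
#' @param points n x 2 matrix of source-frame (x, y).
#' @return n x 2 matrix of target-frame points, with a logical
#'   `"out_of_hull"` attribute (all `FALSE` for affine transforms).
#' @export
apply_transform <- function(trans, points) {
  stopifnot(inherits(trans, "transform2d"))
  points <- .as_points(points)
  n <- nrow(points)
  if (trans$kind == "affine") {
    out <- cbind(points, 1) %*% t(trans$A)
    attr(out, "out_of_hull") <- rep(FALSE, n)
    return(out)
  }
  out <- matrix(NA_real_, n, 2L)
  assigned <- rep(FALSE, n)
  src <- trans$landmarks$src
  for (i in seq_len(nrow(trans$tri))) {
    left <- which(!assigned)
    if (!length(left)) break
    v <- trans$tri[i, ]
    a <- src[v[1L], ]; b <- src[v[2L], ]; cc <- src[v[3L], ]
    det <- (b[2L] - cc[2L]) * (a[1L] - cc[1L]) +
      (cc[1L] - b[1L]) * (a[2L] - cc[2L])
    if (abs(det) < 1e-12) next
    dx <- points[left, 1L] - cc[1L]; dy <- points[left, 2L] - cc[2L]
    l1 <- ((b[2L] - cc[2L]) * dx + (cc[1L] - b[1L]) * dy) / det
    l2 <- ((cc[2L] - a[2L]) * dx + (a[1L] - cc[1L]) * dy) / det
    l3 <- 1 - l1 - l2
    tol <- -1e-9
    inside <- l1 >= tol & l2 >= tol & l3 >= tol
    if (any(inside)) {
      hit <- left[inside]
      out[hit, ] <- cbind(points[hit, , drop = FALSE], 1) %*%
        t(trans$affines[[i]])
      assigned[hit] <- TRUE
    }
  }
  ooh <- !assigned
  if (any(ooh))
    out[ooh, ] <- cbind(points[ooh, , drop = FALSE], 1) %*% t(trans$A)
  attr(out, "out_of_hull") <- ooh
  out
}

#' Invert a fitted transform
#'
#' Affine transforms are inverted in closed form (the 2 x 2 linear part
#' must be nonsingular); piecewise-affine transforms are refitted with
#' source and target landmark roles swapped, which is exact at every
#' control point.
#'
#' @param trans a `transform2d`.
#' @return the inverse `transform2d`.
#' @export
invert_transform <- function(trans) {
  stopifnot(inherits(trans, "transform2d"))
  swapped <- landmark_set(trans$landmarks$dst, trans$landmarks$src,
                          trans$frame_to, trans$frame_from)
  if (trans$kind == "affine") {
    M <- trans$A[, 1:2]
    if (abs(det(M)) <= 1e-12) stop("affine transform is singular")
    Minv <- solve(M)
    A <- cbind(Minv, -Minv %*% trans$A[, 3L])
    return(structure(list(kind = "affine", A = A, landmarks = swapped,
                          frame_from = trans$frame_to,
                          frame_to = trans$frame_from,
                          residual = trans$residual), class = "transform2d"))
  }
  fit_transform(swapped, "piecewise_affine")
}

#' Assign a CCF area to every neuron (double reverse-transformation)
#'
#' Each 2-photon centroid is mapped into the multimodal-map frame via
#' `t_2p_to_mmm`, then into the CCF frame via the inverse of
#' `t_ccf_to_mmm`, and finally looked up on the area label map. Points
#' landing off-map or on background come back unassigned (`NA`), and
#' points extrapolated outside a piecewise hull are flagged.
#'
#' @param centroids_2p n x 2 matrix of neuron centroids (x, y) in 2p
#'   pixels.
#' @param t_2p_to_mmm fitted `transform2d` from frame `twop` to `mmm`.
#' @param t_ccf_to_mmm fitted `transform2d` from frame `ccf` to `mmm`.
#' @param map an [area_map()] in the CCF frame.
#' @return data.frame with columns `neuron_id`, `x_ccf`, `y_ccf`,
#'   `area_id`, `acronym`, `out_of_hull`, `unassigned`.
#' @export
assign_areas <- function(centroids_2p, t_2p_to_mmm, t_ccf_to_mmm, map) {
  stopifnot(inherits(t_2p_to_mmm, "transform2d"),
            inherits(t_ccf_to_mmm, "transform2d"),
            inherits(map, "area_map"))
  if (t_2p_to_mmm$frame_from != "twop" || t_2p_to_mmm$frame_to != "mmm")
    stop("t_2p_to_mmm must map frame 'twop' to 'mmm'")
  if (t_ccf_to_mmm$frame_from != "ccf" || t_ccf_to_mmm$frame_to != "mmm")
    stop("t_ccf_to_mmm must map frame 'ccf' to 'mmm'")
  centroids_2p <- .as_points(centroids_2p)
  mmm <- apply_transform(t_2p_to_mmm, centroids_2p)
  ooh <- attr(mmm, "out_of_hull")
  ccf <- apply_transform(invert_transform(t_ccf_to_mmm), mmm)
  ooh <- ooh | attr(ccf, "out_of_hull")
  ids <- lookup_areas(map, ccf)
  acr <- map$table$acronym[match(ids, map$table$area_id)]
  data.frame(neuron_id = seq_len(nrow(centroids_2p)) - 1L,
             x_ccf = ccf[, 1L], y_ccf = ccf[, 2L],
             area_id = ids, acronym = acr,
             out_of_hull = ooh, unassigned = is.na(ids),
             stringsAsFactors = FALSE)
}

#' Landmark CSV and transform JSON serialisation
#'
#' Landmarks are stored as CSV with columns
#' `frame_from, frame_to, x_src, y_src, x_dst, y_dst`; transforms as
#' JSON holding the landmark pairs and fitted kind, refitted on read.
#'
#' @param lm a [landmark_set()]; `t` a `transform2d`; `path` file path.
#' @name registration_io
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  df <- data.frame(frame_from = lm$frame_from, frame_to = lm$frame_to,
                   x_src = lm$src[, 1L], y_src = lm$src[, 2L],
                   x_dst = lm$dst[, 1L], y_dst = lm$dst[, 2L])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname registration_io
#' @export
read_landmarks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  landmark_set(cbind(df$x_src, df$y_src), cbind(df$x_dst, df$y_dst),
               df$frame_from[1L], df$frame_to[1L])
}

#' @rdname registration_io
#' @param trans a `transform2d` to serialise.
#' @export
write_transform <- function(trans, path) {
  stopifnot(inherits(trans, "transform2d"))
  obj <- list(kind = trans$kind, frame_from = trans$frame_from,
              frame_to = trans$frame_to, residual = trans$residual,
              src = trans$landmarks$src, dst = trans$landmarks$dst)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname registration_io
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lm <- landmark_set(obj$src, obj$dst, obj$frame_from, obj$frame_to)
  fit_transform(lm, obj$kind)
}
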