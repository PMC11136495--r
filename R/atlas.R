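#' Cortical area lookup table
#'
#' Builds the table naming every labelled cortical area of an [area_map()]:
#' one row per area with its integer id, short acronym, full name and
#' hemisphere. Area ids must be unique, and acronyms unique within a
#' hemisphere.
#'
#' @param area_id positive integer ids.
#' @param acronym short area acronyms (e.g. `"VISp"`).
#' @param full_name full area names; defaults to the acronyms.
#' @param hemisphere one of `"left"`, `"right"`, `"midline"` per area.
#' @return a `data.frame` of class `area_table`.
#' @export
area_table <- function(area_id, acronym, full_name = acronym,
                       hemisphere = "right") {
  area_id <- as.integer(area_id)
  if (any(is.na(area_id)) || any(area_id <= 0L))
    stop("area_id must be positive integers")
  if (anyDuplicated(area_id)) stop("area_id values must be unique")
  hemisphere <- rep_len(as.character(hemisphere), length(area_id))
  if (!all(hemisphere %in% c("left", "right", "midline")))
    stop("hemisphere must be 'left', 'right' or 'midline'")
  acronym <- rep_len(as.character(acronym), length(area_id))
  if (anyDuplicated(paste(hemisphere, acronym)))
    stop("acronyms must be unique within a hemisphere")
  tab <- data.frame(area_id = area_id, acronym = acronym,
                    full_name = rep_len(as.character(full_name), length(area_id)),
                    hemisphere = hemisphere, stringsAsFactors = FALSE)
  class(tab) <- c("area_table", "data.frame")
  tab
}

#' Cortical area label map
#'
#' A 2D integer raster naming the cortical area of every pixel (0 =
#' background / off-map), together with its [area_table()] and pixel
#' resolution. Optionally carries the 3D label volume it was projected
#' from.
#'
#' @param labels integer matrix of area labels; 0 is background.
#' @param resolution_um microns per pixel (> 0).
#' @param table an [area_table()] covering every nonzero label.
#' @param volume optional 3D integer label array (y, x, z).
#' @param voxel_um voxel size of `volume` in microns.
#' @return an object of class `area_map`.
#' @export
area_map <- function(labels, resolution_um = 1, table = NULL,
                     volume = NULL, voxel_um = resolution_um) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (nrow(labels) < 1L || ncol(labels) < 1L) stop("labels raster must be >= 1x1")
  if (any(labels < 0L)) stop("labels must be nonnegative")
  if (!is.numeric(resolution_um) || resolution_um <= 0)
    stop("resolution_um must be > 0")
  ids <- sort(unique(labels[labels > 0L]))
  if (is.null(table)) {
    table <- if (length(ids)) area_table(ids, paste0("A", ids)) else
      area_table(integer(0), character(0))
  }
  if (!all(ids %in% table$area_id))
    stop("every nonzero label must appear in the area table")
  structure(list(labels = labels, resolution_um = resolution_um,
                 table = table, volume = volume, voxel_um = voxel_um),
            class = "area_map")
}

#' @export
print.area_map <- function(x, ...) {
  cat(sprintf("area_map: %d x %d px (%.3g um/px), %d areas%s\n",
              nrow(x$labels), ncol(x$labels), x$resolution_um,
              nrow(x$table), if (is.null(x$volume)) "" else ", with volume"))
  invisible(x)
}

#' Projection specification for a label volume
#'
#' Describes the orthographic surface projection used to flatten a 3D
#' cortical label volume: a rotation `angle_deg` about the
#' anterior-posterior axis (positive = roll toward the viewer's right)
#' followed by a first-nonzero-voxel projection along `view_axis`. The
#' side-mount preparation uses a 22.5 degree roll; the dorsal mount 0.
#'
#' @param angle_deg rotation in degrees, in `[-90, 90]`.
#' @param view_axis axis of projection; only `"z"` (top-down after
#'   rotation) is supported.
#' @return an object of class `projection_spec`.
#' @export
projection_spec <- function(angle_deg = 0, view_axis = "z") {
  if (!is.numeric(angle_deg) || length(angle_deg) != 1L || is.na(angle_deg) ||
      angle_deg < -90 || angle_deg > 90)
    stop("angle_deg must be a single value in [-90, 90]")
  view_axis <- match.arg(view_axis, "z")
  structure(list(angle_deg = angle_deg, view_axis = view_axis),
            class = "projection_spec")
}

#' Side-mount projection preset (22.5 degree roll)
#' @return a [projection_spec()] with `angle_deg = 22.5`.
#' @export
side_mount_spec <- function() projection_spec(22.5)

#' Project a 3D label volume to a surface-view area map
#'
#' Rotates the label volume about the anterior-posterior (y) axis using
#' nearest-neighbor interpolation (labels are categorical) around the
#' centroid of the nonzero voxels, then takes the first nonzero voxel
#' along each top-down ray (z ascending) to form the surface view.
#'
#' @param volume 3D integer label array with dims (y, x, z).
#' @param spec a [projection_spec()].
#' @param resolution_um microns per pixel of the result.
#' @param table optional [area_table()] for the result.
#' @return an [area_map()] with the same y/x dimensions as `volume`.
#' @export
project_map <- function(volume, spec = projection_spec(0),
                        resolution_um = 1, table = NULL) {
  if (!inherits(spec, "projection_spec")) spec <- projection_spec(spec)
  if (is.null(dim(volume)) || length(dim(volume)) != 3L || !any(volume != 0))
    stop("volume must be a nonempty 3D label array")
  storage.mode(volume) <- "integer"
  d <- dim(volume)
  ny <- d[1L]; nx <- d[2L]; nz <- d[3L]
  theta <- spec$angle_deg * pi / 180
  rot <- volume
  if (theta != 0) {
    nzidx <- which(volume != 0, arr.ind = TRUE)
    cx <- mean(nzidx[, 2L]); cz <- mean(nzidx[, 3L])
    # inverse mapping on the (x, z) grid, shared across y slices
    grid <- expand.grid(x = seq_len(nx), z = seq_len(nz))
    dxv <- grid$x - cx; dzv <- grid$z - cz
    sx <- round(cx + cos(theta) * dxv + sin(theta) * dzv)
    sz <- round(cz - sin(theta) * dxv + cos(theta) * dzv)
    ok <- sx >= 1 & sx <= nx & sz >= 1 & sz <= nz
    rot <- array(0L, d)
    for (y in seq_len(ny)) {
      slice <- matrix(0L, nx, nz)
      src <- cbind(sx[ok], sz[ok])
      slice[cbind(grid$x[ok], grid$z[ok])] <- volume[cbind(y, src)]
      rot[y, , ] <- slice
    }
  }
  labels <- matrix(0L, ny, nx)
  for (z in seq_len(nz)) {
    sl <- rot[, , z]
    fill <- labels == 0L & sl != 0L
    labels[fill] <- sl[fill]
  }
  area_map(labels, resolution_um = resolution_um, table = table)
}

#' Area boundary outline
#'
#' A pixel is part of the outline iff any of its 4-neighbors carries a
#' different label, except that edges between two background pixels are
#' never outlined. Raster borders do not by themselves create outline.
#'
#' @param map an [area_map()] or integer label matrix.
#' @return a logical matrix of the same shape.
#' @export
outline <- function(map) {
  lab <- if (inherits(map, "area_map")) map$labels else as.matrix(map)
  nr <- nrow(lab); nc <- ncol(lab)
  out <- matrix(FALSE, nr, nc)
  diffn <- function(a, b) a != b & (a != 0L | b != 0L)
  if (nr > 1L) {
    d <- diffn(lab[-nr, , drop = FALSE], lab[-1L, , drop = FALSE])
    out[-nr, ] <- out[-nr, , drop = FALSE] | d
    out[-1L, ] <- out[-1L, , drop = FALSE] | d
  }
  if (nc > 1L) {
    d <- diffn(lab[, -nc, drop = FALSE], lab[, -1L, drop = FALSE])
    out[, -nc] <- out[, -nc, drop = FALSE] | d
    out[, -1L] <- out[, -1L, drop = FALSE] | d
  }
  out
}

#' Look up the cortical area of points on a label map
#'
#' Nearest-pixel lookup under the package coordinate convention (a point
#' maps to the pixel containing it, i.e. floor of its 0-based x/y).
#' Points outside the raster, or landing on background (label 0), return
#' the unassigned sentinel `NA`.
#'
#' @param map an [area_map()].
#' @param points n x 2 matrix of (x, y) in map pixel coordinates.
#' @return integer vector of area ids, `NA` = unassigned.
#' @export
lookup_areas <- function(map, points) {
  stopifnot(inherits(map, "area_map"))
  points <- .as_points(points)
  if (any(!is.finite(points))) stop("points must be finite")
  col <- floor(points[, 1L]) + 1L
  row <- floor(points[, 2L]) + 1L
  lab <- map$labels
  ok <- row >= 1L & row <= nrow(lab) & col >= 1L & col <= ncol(lab)
  ids <- rep(NA_integer_, nrow(points))
  ids[ok] <- lab[cbind(row[ok], col[ok])]
  ids[!is.na(ids) & ids == 0L] <- NA_integer_
  ids
}

#' Test clearance of points from area boundaries
#'
#' A point is "off-boundary" when every pixel within Chebyshev radius
#' `min_px` of its pixel (clipped to the raster) carries the same label
#' as its own pixel. Used to restrict registration-accuracy scoring to
#' neurons that are unambiguously inside one area.
#'
#' @param map an [area_map()].
#' @param points n x 2 matrix of (x, y) map pixel coordinates.
#' @param min_px clearance radius in pixels.
#' @return logical vector; `FALSE` for points off the raster.
#' @export
off_boundary <- function(map, points, min_px = 2L) {
  stopifnot(inherits(map, "area_map"))
  points <- .as_points(points)
  lab <- map$labels
  nr <- nrow(lab); nc <- ncol(lab)
  col <- floor(points[, 1L]) + 1L
  row <- floor(points[, 2L]) + 1L
  vapply(seq_len(nrow(points)), function(i) {
    r <- row[i]; c <- col[i]
    if (r < 1L || r > nr || c < 1L || c > nc) return(FALSE)
    rr <- max(1L, r - min_px):min(nr, r + min_px)
    cc <- max(1L, c - min_px):min(nc, c + min_px)
    all(lab[rr, cc] == lab[r, c])
  }, logical(1L))
}

#' Write / read an area map as TIFF + CSV
#'
#' The label raster is stored as a 16-bit grayscale TIFF and the area
#' table as a CSV with columns `area_id, acronym, full_name, hemisphere`.
#'
#' @param map an [area_map()].
#' @param tif_path path of the TIFF label raster.
#' @param csv_path path of the area-table CSV.
#' @param resolution_um microns per pixel recorded on read.
#' @name area_map_io
#' @export
write_area_map <- function(map, tif_path, csv_path) {
  stopifnot(inherits(map, "area_map"))
  if (max(map$labels) > 65535L) stop("labels exceed 16-bit TIFF range")
  tiff::writeTIFF(map$labels / 65535, tif_path, bits.per.sample = 16L)
  write.csv(as.data.frame(map$table), csv_path, row.names = FALSE)
  invisible(c(tif_path, csv_path))
}

#' @rdname area_map_io
#' @export
read_area_map <- function(tif_path, csv_path = NULL, resolution_um = 1) {
  img <- tiff::readTIFF(tif_path)
  labels <- matrix(as.integer(round(img * 65535)), nrow(img), ncol(img))
  tab <- NULL
  if (!is.null(csv_path)) {
    df <- read.csv(csv_path, stringsAsFactors = FALSE)
    tab <- area_table(df$area_id, df$acronym, df$full_name, df$hemisphere)
  }
  area_map(labels, resolution_um = resolution_um, table = tab)
}
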