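#' Medial axis and morphometrics of one segmented cell
#'
#' Extracts the cell's centerline from an integer label mask: the binary
#' footprint is skeletonized, the skeleton is pruned to its longest geodesic
#' path, both ends are extended to the cell boundary along the terminal
#' tangents, and the polyline is smoothed with a fixed-window moving average
#' and resampled at 1-pixel arc steps. Cell length is the arc length of the
#' resulting pole-to-pole axis times the pixel size; width at each axis
#' position is the transverse chord of the footprint through that position
#' (near the poles the chord inside the mask), and \code{mean_width} averages
#' it over the full axis.
#'
#' @param mask integer matrix: label image (0 = background); or a logical
#'   matrix for a single cell.
#' @param cell_id label value of the cell to measure (ignored for logical
#'   masks).
#' @param pixel_size pixel size in micrometres per pixel. Masks carry no
#'   physical calibration, so this is always required.
#' @param min_area_px cells smaller than this many pixels are skipped with a
#'   warning (segmentation debris).
#' @param smooth_window moving-average window (axis points) for centerline
#'   smoothing.
#' @param aspect_threshold cells with length/mean_width below this are
#'   flagged \code{non_rod} (e.g. round cells, for which an axis is not
#'   meaningful).
#' @return Object of class \code{cell_axis}: list with \code{cell_id},
#'   \code{polyline} (n x 2 matrix of x,y pixel coordinates),
#'   \code{n} (number of axis positions), \code{length_um},
#'   \code{widths_um}, \code{mean_width_um}, and logical flags
#'   \code{on_border}, \code{non_rod}. \code{NULL} (with a warning) for
#'   cells below the area threshold.
#' @export
medial_axis <- function(mask, cell_id = NULL, pixel_size,
                        min_area_px = 20L, smooth_window = 5L,
                        aspect_threshold = 1.5) {
  stopifnot(is.matrix(mask), is.numeric(pixel_size), pixel_size > 0)
  if (is.logical(mask)) {
    fp <- mask
    if (is.null(cell_id)) cell_id <- 1L
  } else {
    if (is.null(cell_id)) stop("cell_id required for a label mask")
    fp <- mask == cell_id
  }
  if (!any(fp)) stop("cell_id ", cell_id, " not present in mask")
  area <- sum(fp)
  if (area < min_area_px) {
    warning("cell ", cell_id, " below minimum area (", area, " px); skipped")
    return(NULL)
  }
  pix <- which(fp, arr.ind = TRUE)
  on_border <- any(pix[, 1L] == 1L | pix[, 1L] == nrow(fp) |
                   pix[, 2L] == 1L | pix[, 2L] == ncol(fp))

  # work in the cell's bounding box; coordinates mapped back at the end
  r0 <- min(pix[, 1L]); r1 <- max(pix[, 1L])
  c0 <- min(pix[, 2L]); c1 <- max(pix[, 2L])
  sub <- fp[r0:r1, c0:c1, drop = FALSE]
  # thinning is not rotation-equivariant on the pixel grid, so the
  # skeleton is computed in a canonical orientation chosen by a rule that
  # is itself invariant under grid rotations of the input; the axis is
  # mapped back afterwards. This makes the whole measurement exactly
  # equivariant under 90-degree image rotations.
  can <- canonical_orientation(sub)
  pl <- axis_polyline(can$m, smooth_window)
  widths_px <- transverse_widths(pl, can$m)
  len_px <- polyline_length(pl)
  pl <- can$map_back(pl)
  pl[, 1L] <- pl[, 1L] + (c0 - 1L)
  pl[, 2L] <- pl[, 2L] + (r0 - 1L)
  length_um <- len_px * pixel_size
  mean_width_um <- mean(widths_px) * pixel_size
  structure(list(
    cell_id = cell_id,
    polyline = pl,
    n = nrow(pl),
    length_px = len_px,
    length_um = length_um,
    widths_um = widths_px * pixel_size,
    mean_width_um = mean_width_um,
    pixel_size = pixel_size,
    area_px = area,
    on_border = on_border,
    non_rod = (length_um / mean_width_um) < aspect_threshold),
    class = "cell_axis")
}

#' @export
print.cell_axis <- function(x, ...) {
  cat(sprintf("cell_axis %s: length %.2f um, mean width %.2f um, %d axis positions%s%s\n",
              x$cell_id, x$length_um, x$mean_width_um, x$n,
              if (x$on_border) " [on border]" else "",
              if (x$non_rod) " [non-rod]" else ""))
  invisible(x)
}

# skeletonize, prune to the longest geodesic path, extend to the boundary,
# smooth and resample at 1-px arc steps (all in one frame)
axis_polyline <- function(m, smooth_window) {
  skel <- thin_mask(m)
  path <- skeleton_path(skel)
  # x = column, y = row, pixel centres at integer coordinates
  pl <- cbind(x = as.numeric(path[, 2L]), y = as.numeric(path[, 1L]))
  pl <- extend_to_boundary(pl, m)
  pl <- smooth_polyline(pl, smooth_window)
  resample_polyline(pl, step = 1)
}

rot_cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

# canonical grid orientation of a footprint: landscape (ncol >= nrow),
# ties broken by the lexicographically smallest pixel pattern; returns the
# rotated matrix and a function mapping (x, y) polyline coordinates back
# into the input frame
canonical_orientation <- function(m) {
  subs <- vector("list", 4L)
  subs[[1L]] <- m
  for (k in 2:4) subs[[k]] <- rot_cw(subs[[k - 1L]])
  landscape <- vapply(subs, function(s) ncol(s) >= nrow(s), logical(1))
  cand <- if (any(landscape)) which(landscape) else 1:4
  pat <- vapply(subs[cand], function(s)
    paste(as.integer(s), collapse = ""), character(1))
  k <- cand[order(pat)[1L]]
  map_back <- function(pl) {
    for (j in rev(seq_len(k - 1L))) {
      rows_prev <- nrow(subs[[j]])
      pl <- cbind(x = pl[, 2L], y = rows_prev + 1 - pl[, 1L])
    }
    pl
  }
  list(m = subs[[k]], map_back = map_back)
}

inside_fp <- function(fp, x, y) {
  r <- round(y); c <- round(x)
  ok <- r >= 1 & r <= nrow(fp) & c >= 1 & c <= ncol(fp)
  out <- logical(length(x))
  out[ok] <- fp[cbind(r[ok], c[ok])]
  out
}

# extend both polyline ends to the mask boundary along the terminal tangent
extend_to_boundary <- function(pl, fp, step = 0.25, tangent_span = 3L) {
  n <- nrow(pl)
  ext_end <- function(pl) {
    n <- nrow(pl)
    i0 <- max(1L, n - tangent_span)
    d <- pl[n, ] - pl[i0, ]
    nd <- sqrt(sum(d^2))
    if (nd < 1e-9) {
      # single-pixel skeleton (round cell): extend along the longest chord
      d <- c(1, 0); nd <- 1
    }
    d <- d / nd
    p <- pl[n, ]
    pts <- NULL
    repeat {
      q <- p + step * d
      if (!inside_fp(fp, q[1L], q[2L])) break
      pts <- rbind(pts, q)
      p <- q
    }
    if (!is.null(pts)) pl <- rbind(pl, pts)
    pl
  }
  pl <- ext_end(pl)
  pl <- ext_end(pl[rev(seq_len(nrow(pl))), , drop = FALSE])
  pl[rev(seq_len(nrow(pl))), , drop = FALSE]
}

# moving average with symmetric shrinking windows (endpoints kept fixed)
smooth_polyline <- function(pl, window = 5L) {
  n <- nrow(pl)
  if (n < 3L || window < 3L) return(pl)
  k <- window %/% 2L
  out <- pl
  for (i in seq_len(n)) {
    m <- min(k, i - 1L, n - i)
    if (m < 1L) next
    out[i, ] <- colMeans(pl[(i - m):(i + m), , drop = FALSE])
  }
  out
}

polyline_length <- function(pl) {
  if (nrow(pl) < 2L) return(0)
  sum(sqrt(rowSums(diff(pl)^2)))
}

resample_polyline <- function(pl, step = 1) {
  if (nrow(pl) < 2L) return(pl)
  seg <- sqrt(rowSums(diff(pl)^2))
  keep <- c(TRUE, seg > 1e-12)
  pl <- pl[keep, , drop = FALSE]
  if (nrow(pl) < 2L) return(pl)
  s <- c(0, cumsum(sqrt(rowSums(diff(pl)^2))))
  total <- s[length(s)]
  targets <- unique(c(seq(0, total, by = step), total))
  cbind(x = approx(s, pl[, 1L], xout = targets)$y,
        y = approx(s, pl[, 2L], xout = targets)$y)
}

# unit normals from central-difference tangents
polyline_normals <- function(pl) {
  n <- nrow(pl)
  tx <- numeric(n); ty <- numeric(n)
  ip <- pmin(n, seq_len(n) + 1L)
  im <- pmax(1L, seq_len(n) - 1L)
  tx <- pl[ip, 1L] - pl[im, 1L]
  ty <- pl[ip, 2L] - pl[im, 2L]
  nrm <- sqrt(tx^2 + ty^2)
  nrm[nrm < 1e-12] <- 1
  cbind(x = -ty / nrm, y = tx / nrm)
}

# transverse chord of the footprint at each axis position (px)
transverse_widths <- function(pl, fp, step = 0.25, max_half = 50) {
  nor <- polyline_normals(pl)
  vapply(seq_len(nrow(pl)), function(i) {
    p <- pl[i, ]; v <- nor[i, ]
    reach <- function(sign) {
      d <- 0
      repeat {
        nxt <- d + step
        if (nxt > max_half) break
        q <- p + sign * nxt * v
        if (!inside_fp(fp, q[1L], q[2L])) break
        d <- nxt
      }
      d
    }
    reach(1) + reach(-1)
  }, numeric(1))
}

#' Measure all cells of a label mask
#'
#' Convenience wrapper running \code{\link{medial_axis}} over every label in
#' the mask.
#'
#' @inheritParams medial_axis
#' @param exclude_border drop cells touching the image border (default
#'   TRUE; their geometry is truncated).
#' @return Named list of \code{cell_axis} objects (names = label values);
#'   skipped cells are omitted.
#' @export
measure_cells <- function(mask, pixel_size, min_area_px = 20L,
                          exclude_border = TRUE, ...) {
  labels <- sort(setdiff(unique(as.vector(mask)), 0L))
  out <- list()
  for (lab in labels) {
    ax <- withCallingHandlers(
      medial_axis(mask, lab, pixel_size, min_area_px = min_area_px, ...),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(ax)) next
    if (exclude_border && ax$on_border) next
    out[[as.character(lab)]] <- ax
  }
  out
}
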