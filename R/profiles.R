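#' Fluorescence intensity profile along a cell axis
#'
#' At every axis position the intensities of 5 pixels perpendicular to the
#' axis (nearest-pixel sampling at offsets -2..2 px along the local normal,
#' clipped to the image) are summed, yielding the raw profile \eqn{I_i},
#' \eqn{i = 1..n}, where \eqn{n} is the number of axis positions.
#'
#' @param image numeric matrix: fluorescence image, same shape as the mask
#'   the axis was measured on.
#' @param axis a \code{\link{cell_axis}}.
#' @param halfwidth_px number of perpendicular pixels on each side of the
#'   axis (default 2, i.e. 5 pixels in total).
#' @return Object of class \code{axis_profile}: list with \code{cell_id},
#'   \code{values} (raw \eqn{I_i}), \code{n}, \code{length_um} and
#'   \code{normalized} (\code{NULL} until
#'   \code{\link{normalize_profile}} is applied).
#' @export
axis_profile <- function(image, axis, halfwidth_px = 2L) {
  stopifnot(is.matrix(image), inherits(axis, "cell_axis"))
  pl <- axis$polyline
  if (any(round(pl[, 2L]) < 1 | round(pl[, 2L]) > nrow(image) |
          round(pl[, 1L]) < 1 | round(pl[, 1L]) > ncol(image)))
    stop("axis lies outside the image")
  nor <- polyline_normals(pl)
  offs <- seq(-halfwidth_px, halfwidth_px)
  vals <- vapply(seq_len(nrow(pl)), function(i) {
    xs <- round(pl[i, 1L] + offs * nor[i, 1L])
    ys <- round(pl[i, 2L] + offs * nor[i, 2L])
    keep <- ys >= 1 & ys <= nrow(image) & xs >= 1 & xs <= ncol(image)
    sum(image[cbind(ys[keep], xs[keep])])
  }, numeric(1))
  structure(list(cell_id = axis$cell_id, values = vals, n = length(vals),
                 length_um = axis$length_um, normalized = NULL),
            class = "axis_profile")
}

#' Normalize an intensity profile to unit mean
#'
#' Applies \deqn{I_i^{norm} = I_i \cdot n / \sum_j I_j,} where \eqn{n} is
#' the profile length, so that every normalized profile sums to \eqn{n} and
#' has mean 1; cells of different brightness then share one intensity scale
#' in demographs.
#'
#' @param profile an \code{\link{axis_profile}}.
#' @return The profile with \code{normalized} filled.
#' @examples
#' p <- structure(list(cell_id = "c", values = c(1, 3), n = 2L,
#'                     length_um = 0.2, normalized = NULL),
#'                class = "axis_profile")
#' normalize_profile(p)$normalized  # 0.5 1.5
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "axis_profile"))
  s <- sum(profile$values)
  if (!is.finite(s) || s <= 0)
    stop("profile sum is not positive; normalization undefined (cell ",
         profile$cell_id, ")")
  profile$normalized <- profile$values * profile$n / s
  profile
}

#' Build a demograph from normalized profiles
#'
#' Rows are per-cell normalized profiles sorted ascending by cell length;
#' each profile is placed centred on the common midcell column in absolute
#' pixels (profiles are not rescaled to relative cell coordinates, so the
#' absolute length range is preserved); positions outside a cell are the
#' sentinel \code{NA}.
#'
#' @param profiles list of normalized \code{\link{axis_profile}} objects.
#' @param lengths optional numeric vector of cell lengths (um); defaults to
#'   the profiles' own \code{length_um}.
#' @return Object of class \code{demograph}: list with \code{matrix}
#'   (cells x axis positions, NA-padded), \code{lengths} (sorted,
#'   micrometres), \code{cell_ids}, \code{midcell_col}.
#' @export
build_demograph <- function(profiles, lengths = NULL) {
  if (length(profiles) == 0L) stop("no profiles supplied")
  ok <- vapply(profiles, function(p) !is.null(p$normalized), logical(1))
  if (!all(ok)) stop("all profiles must be normalized first")
  if (is.null(lengths))
    lengths <- vapply(profiles, function(p) p$length_um, numeric(1))
  stopifnot(length(lengths) == length(profiles))
  ord <- order(lengths)
  profiles <- profiles[ord]
  lengths <- lengths[ord]
  ns <- vapply(profiles, function(p) p$n, integer(1))
  ncols <- max(ns)
  if (ncols %% 2L == 0L) ncols <- ncols + 1L  # odd, so midcell is one column
  mid <- (ncols + 1L) %/% 2L
  m <- matrix(NA_real_, nrow = length(profiles), ncol = ncols)
  for (i in seq_along(profiles)) {
    n <- ns[i]
    off <- mid - ((n + 1L) %/% 2L)
    m[i, (off + 1L):(off + n)] <- profiles[[i]]$normalized
  }
  structure(list(matrix = m, lengths = lengths,
                 cell_ids = vapply(profiles, function(p)
                   as.character(p$cell_id), character(1)),
                 midcell_col = mid),
            class = "demograph")
}

#' @export
print.demograph <- function(x, ...) {
  cat(sprintf("demograph: %d cells x %d axis positions, lengths %.2f-%.2f um\n",
              nrow(x$matrix), ncol(x$matrix), min(x$lengths), max(x$lengths)))
  invisible(x)
}

#' Plot a demograph
#'
#' Heatmap of the demograph matrix: x = axis position relative to midcell,
#' y = cells in order of increasing length.
#'
#' @param x a \code{\link{build_demograph}} result.
#' @param pixel_size pixel size (um/px) to label the x axis in micrometres;
#'   if \code{NULL} the axis is in pixels.
#' @param col color palette.
#' @param ... passed to \code{graphics::image}.
#' @export
plot_demograph <- function(x, pixel_size = NULL,
                           col = grDevices::hcl.colors(64, "viridis"), ...) {
  stopifnot(inherits(x, "demograph"))
  pos <- seq_len(ncol(x$matrix)) - x$midcell_col
  xlab <- "axis position from midcell (px)"
  if (!is.null(pixel_size)) {
    pos <- pos * pixel_size
    xlab <- "axis position from midcell (µm)"
  }
  graphics::image(x = pos, y = seq_len(nrow(x$matrix)),
                  z = t(x$matrix)[, nrow(x$matrix):1, drop = FALSE],
                  col = col, xlab = xlab,
                  ylab = "cells (short → long)", useRaster = TRUE, ...)
  invisible(x)
}

#' Per-group cell length statistics
#'
#' Standard descriptive statistics of cell length per sample group, as
#' reported alongside length violin plots (mean +/- SD with n).
#'
#' @param axes list of \code{\link{cell_axis}} objects, or a numeric vector
#'   of lengths (um).
#' @param groups group label per cell (recycled if length 1).
#' @return data.frame with columns \code{group}, \code{n}, \code{mean_um},
#'   \code{sd_um}, \code{flag} (\code{"n=1"} when the SD is degenerate);
#'   the raw per-cell lengths are attached as attribute \code{"lengths"}
#'   (data.frame \code{group}, \code{length_um}) for violin plotting or
#'   CSV export.
#' @export
length_stats <- function(axes, groups = "all") {
  lengths <- if (is.numeric(axes)) axes else
    vapply(axes, function(a) a$length_um, numeric(1))
  if (length(lengths) == 0L) stop("no cells")
  groups <- rep_len(as.character(groups), length(lengths))
  out <- lapply(sort(unique(groups)), function(g) {
    v <- lengths[groups == g]
    data.frame(group = g, n = length(v), mean_um = mean(v),
               sd_um = if (length(v) > 1L) sd(v) else 0,
               flag = if (length(v) == 1L) "n=1" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  attr(out, "lengths") <- data.frame(group = groups, length_um = lengths,
                                     stringsAsFactors = FALSE)
  out
}
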