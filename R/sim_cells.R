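#' Configuration for the synthetic cell renderer
#'
#' Describes a field of non-overlapping rod-shaped (spherocylindrical)
#' cells rendered into a label mask and a matched fluorescence image, with
#' known per-cell geometry and signal model, emulating fixed E. coli cells
#' imaged by widefield fluorescence microscopy. Defaults mirror typical
#' exponential-phase E. coli on a 100 nm/px camera: pole-to-pole lengths
#' 1.5-6 um, widths 0.8-1.2 um, gentle curvature (sagitta below 5% of
#' length), a ~1 px PSF-proxy Gaussian blur and additive Gaussian camera
#' noise.
#'
#' @param image_size c(rows, cols) in pixels.
#' @param pixel_size_um micrometres per pixel.
#' @param n_cells number of cells to place.
#' @param length_range_um pole-to-pole length range (uniform).
#' @param width_range_um cell width (diameter) range (uniform).
#' @param curvature_max maximal centerline sagitta as a fraction of the
#'   spine length (uniform in [0, curvature_max]).
#' @param model signal model for every cell: \code{"uniform"} (flat
#'   cytoplasmic signal), \code{"septal"} (uniform plus a transverse
#'   Gaussian band at midcell) or \code{"membrane"} (signal concentrated at
#'   the cell outline); or a vector of length \code{n_cells}.
#' @param baseline in-cell baseline intensity (a.u.).
#' @param amplitude septal/membrane band amplitude above baseline (a.u.).
#' @param band_sigma_px Gaussian sigma of the septal band along the axis
#'   (px).
#' @param blur_sigma_px PSF-proxy Gaussian blur sigma (px; 0 disables).
#' @param noise_sd additive Gaussian noise SD (a.u.; 0 disables). The label
#'   mask is never affected by blur or noise.
#' @return List of class \code{cell_sim_config}.
#' @export
cell_sim_config <- function(image_size = c(512L, 512L),
                            pixel_size_um = 0.1,
                            n_cells = 40L,
                            length_range_um = c(1.5, 6),
                            width_range_um = c(0.8, 1.2),
                            curvature_max = 0.05,
                            model = "septal",
                            baseline = 100,
                            amplitude = 60,
                            band_sigma_px = 2,
                            blur_sigma_px = 1,
                            noise_sd = 10) {
  stopifnot(length(image_size) == 2L, all(image_size >= 64L),
            pixel_size_um > 0, n_cells >= 1L,
            length_range_um[1L] <= length_range_um[2L],
            width_range_um[1L] <= width_range_um[2L],
            length_range_um[1L] > width_range_um[2L],
            curvature_max >= 0, curvature_max < 0.1,
            all(model %in% c("uniform", "septal", "membrane")),
            baseline > 0, amplitude >= 0, band_sigma_px > 0,
            blur_sigma_px >= 0, noise_sd >= 0)
  structure(list(image_size = as.integer(image_size),
                 pixel_size_um = pixel_size_um, n_cells = as.integer(n_cells),
                 length_range_um = length_range_um,
                 width_range_um = width_range_um,
                 curvature_max = curvature_max, model = model,
                 baseline = baseline, amplitude = amplitude,
                 band_sigma_px = band_sigma_px,
                 blur_sigma_px = blur_sigma_px, noise_sd = noise_sd),
            class = "cell_sim_config")
}

#' Render synthetic cells with ground truth
#'
#' Renders each cell as a spherocylinder of constant radius around a
#' (possibly gently curved) centerline: a pixel belongs to the cell iff its
#' distance to the centerline is at most width/2, which produces the
#' hemispherical poles automatically. The septal model adds a transverse
#' Gaussian band at arc position 0.5 L. The fluorescence image is then
#' blurred and noise is added; the label mask is exact.
#'
#' The truth table records, per cell, the planted pole-to-pole
#' \code{length_um} (centerline arc length plus one width), the diameter
#' \code{width_um}, and \code{mean_width_um}, the analytic mean transverse
#' chord over the full pole-to-pole axis
#' \eqn{((L-w)w + \pi w^2/4)/L} - the quantity the pipeline's averaged
#' width estimates (chords shrink over the poles).
#'
#' @param config a \code{\link{cell_sim_config}}.
#' @param seed integer random seed; fixes the output exactly.
#' @return List with \code{mask} (integer label matrix), \code{fluor}
#'   (numeric matrix, a.u.), \code{truth} (data.frame: \code{cell_id},
#'   \code{length_um}, \code{width_um}, \code{mean_width_um},
#'   \code{model}, \code{amplitude}, \code{orientation_rad},
#'   \code{sagitta_frac}, \code{area_px}) and \code{config}.
#' @export
generate_cells <- function(config = cell_sim_config(), seed = 1L) {
  stopifnot(inherits(config, "cell_sim_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  nr <- config$image_size[1L]; nc <- config$image_size[2L]
  px <- config$pixel_size_um
  mask <- matrix(0L, nr, nc)
  fluor <- matrix(0, nr, nc)
  occupied <- matrix(FALSE, nr, nc)  # with safety margin between cells
  models <- rep_len(config$model, config$n_cells)
  truth <- vector("list", config$n_cells)

  for (id in seq_len(config$n_cells)) {
    placed_ok <- FALSE
    for (try in 1:200) {
      L_um <- runif(1, config$length_range_um[1L], config$length_range_um[2L])
      w_um <- runif(1, config$width_range_um[1L], config$width_range_um[2L])
      L <- L_um / px; w <- w_um / px; r <- w / 2
      spine <- L - w                      # centerline length (px)
      sag <- runif(1, 0, config$curvature_max) * spine
      theta <- runif(1, 0, pi)
      margin <- L / 2 + r + 3
      cx <- runif(1, margin, nc - margin)
      cy <- runif(1, margin, nr - margin)
      cl <- centerline_points(cx, cy, theta, spine, sag)
      # candidate footprint in the bounding box
      bb <- cell_bbox(cl, r, nr, nc)
      d <- dist_to_centerline(cl, bb)
      inside <- d$dist <= r
      if (!any(inside)) next
      rows <- bb$rows[d$ri[inside]]
      cols <- bb$cols[d$ci[inside]]
      # reject overlap (2 px margin) with already-placed cells
      dil <- d$dist <= r + 2
      if (any(occupied[cbind(bb$rows[d$ri[dil]], bb$cols[d$ci[dil]])])) next
      cells_px <- cbind(rows, cols)
      mask[cells_px] <- id
      occupied[cells_px] <- TRUE
      base_val <- rep(config$baseline, nrow(cells_px))
      s_mid <- (cl$total_arc) / 2
      if (models[id] == "septal") {
        base_val <- base_val + config$amplitude *
          exp(-(d$arc[inside] - s_mid)^2 / (2 * config$band_sigma_px^2))
      } else if (models[id] == "membrane") {
        base_val <- base_val + config$amplitude *
          exp(-(r - d$dist[inside])^2 / (2 * 1^2))
      }
      fluor[cells_px] <- base_val
      arc <- cl$total_arc
      Lpp <- (arc + w) * px              # pole-to-pole truth length
      truth[[id]] <- data.frame(
        cell_id = id, length_um = Lpp, width_um = w_um,
        mean_width_um = ((Lpp - w_um) * w_um + pi * w_um^2 / 4) / Lpp,
        model = models[id],
        amplitude = if (models[id] == "uniform") 0 else config$amplitude,
        orientation_rad = theta, sagitta_frac = if (spine > 0) sag / spine else 0,
        area_px = nrow(cells_px), stringsAsFactors = FALSE)
      placed_ok <- TRUE
      break
    }
    if (!placed_ok)
      stop("could not place cell ", id,
           " without overlap; reduce n_cells or enlarge image_size")
  }
  if (config$blur_sigma_px > 0) {
    img <- EBImage::gblur(EBImage::Image(fluor), sigma = config$blur_sigma_px)
    fluor <- EBImage::imageData(img)
  }
  if (config$noise_sd > 0)
    fluor <- fluor + matrix(rnorm(nr * nc, sd = config$noise_sd), nr, nc)
  list(mask = mask, fluor = fluor, truth = do.call(rbind, truth),
       config = config)
}

# centerline as a dense polyline: straight segment of given length bent into
# a shallow parabola with the given sagitta, centred on (cx, cy), rotated by
# theta; returns point coordinates plus cumulative arc length
centerline_points <- function(cx, cy, theta, spine, sag, n = 201L) {
  t <- seq(-1, 1, length.out = n)
  xs <- t * spine / 2
  ys <- sag * (1 - t^2) - sag / 2
  u <- c(cos(theta), sin(theta))
  v <- c(-sin(theta), cos(theta))
  X <- cx + xs * u[1L] + ys * v[1L]
  Y <- cy + xs * u[2L] + ys * v[2L]
  arc <- c(0, cumsum(sqrt(diff(X)^2 + diff(Y)^2)))
  list(x = X, y = Y, arc = arc, total_arc = arc[n])
}

cell_bbox <- function(cl, r, nr, nc) {
  pad <- r + 3
  rows <- max(1L, floor(min(cl$y) - pad)):min(nr, ceiling(max(cl$y) + pad))
  cols <- max(1L, floor(min(cl$x) - pad)):min(nc, ceiling(max(cl$x) + pad))
  list(rows = rows, cols = cols)
}

# distance of every bbox pixel centre to the centerline polyline, plus the
# arc position of the nearest centerline point (nearest-sample
# approximation; the centerline is densely sampled)
dist_to_centerline <- function(cl, bb) {
  gx <- rep(bb$cols, each = length(bb$rows))
  gy <- rep(bb$rows, times = length(bb$cols))
  best_d2 <- rep(Inf, length(gx))
  best_arc <- numeric(length(gx))
  for (j in seq_along(cl$x)) {
    d2 <- (gx - cl$x[j])^2 + (gy - cl$y[j])^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_arc[upd] <- cl$arc[j]
  }
  ri <- rep(seq_along(bb$rows), times = length(bb$cols))
  ci <- rep(seq_along(bb$cols), each = length(bb$rows))
  list(dist = sqrt(best_d2), arc = best_arc, ri = ri, ci = ci)
}

#' Write a rendered cell field to TIFF files plus a truth CSV
#'
#' The fluorescence image is written as 16-bit grayscale TIFF (values
#' clipped to [0, 65535] and scaled), the label mask as 16-bit integer
#' TIFF, and the truth table as CSV.
#'
#' @param sim a \code{\link{generate_cells}} result.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Invisibly, the paths written (named: mask, fluor, truth).
#' @export
write_cell_images <- function(sim, dir, prefix = "cells") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mask_path <- file.path(dir, paste0(prefix, "_mask.tif"))
  fluor_path <- file.path(dir, paste0(prefix, "_fluor.tif"))
  truth_path <- file.path(dir, paste0(prefix, "_truth.csv"))
  # intensities are quantized to integer counts (16-bit camera units)
  # before writing; integer/65535 values survive the TIFF round trip
  # exactly
  tiff::writeTIFF(sim$mask / 65535, mask_path, bits.per.sample = 16L,
                  compression = "none")
  f <- round(pmin(pmax(sim$fluor, 0), 65535)) / 65535
  tiff::writeTIFF(f, fluor_path, bits.per.sample = 16L,
                  compression = "none")
  write_table(sim$truth, truth_path, format = "csv", key = "cell_id")
  invisible(c(mask = mask_path, fluor = fluor_path, truth = truth_path))
}

#' Read a label mask written by \code{write_cell_images}
#' @param path 16-bit TIFF path.
#' @return Integer label matrix.
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Read a fluorescence image written by \code{write_cell_images}
#' @param path 16-bit TIFF path.
#' @return Numeric matrix in the original arbitrary units.
#' @export
read_fluor_image <- function(path) {
  m <- tiff::readTIFF(path)
  m * 65535
}
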