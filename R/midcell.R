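#' Midcell fluorescence intensity of one cell
#'
#' Mean pixel intensity over a transverse band of 3-pixel width (along the
#' axis) centred at arc position 0.5 L, clipped to the cell mask, minus the
#' background taken the same way at the quarter position(s). By default the
#' background averages the bands at 0.25 L and 0.75 L, because cell polarity
#' in a segmentation is arbitrary; \code{quarter = "one"} reproduces a
#' single-sided reading using the 0.25 L band only.
#'
#' @param image numeric matrix: fluorescence image.
#' @param mask integer (or logical) matrix: the label mask the axis was
#'   measured on.
#' @param axis a \code{\link{cell_axis}}.
#' @param band_px band width along the axis in pixels (default 3).
#' @param quarter \code{"both"} (average 0.25 L and 0.75 L) or \code{"one"}
#'   (0.25 L only).
#' @return One-row data.frame: \code{cell_id}, \code{midcell_raw},
#'   \code{background_raw}, \code{net}, \code{flag} (\code{"short"} with
#'   \code{NA} values when the axis is too short for non-overlapping
#'   bands).
#' @export
midcell_intensity <- function(image, mask, axis, band_px = 3L,
                              quarter = c("both", "one")) {
  stopifnot(is.matrix(image), inherits(axis, "cell_axis"))
  quarter <- match.arg(quarter)
  if (is.logical(mask)) fp <- mask else fp <- mask == axis$cell_id
  n <- axis$n
  half <- (band_px - 1) / 2
  centers <- c(mid = 0.5, q1 = 0.25, q3 = 0.75) * (n - 1) + 1
  # bands must fit and must not overlap (very short cells)
  if (axis$length_px < 7 ||
      centers["q1"] + half >= centers["mid"] - half ||
      centers["mid"] + half >= centers["q3"] - half) {
    return(data.frame(cell_id = axis$cell_id, midcell_raw = NA_real_,
                      background_raw = NA_real_, net = NA_real_,
                      flag = "short", stringsAsFactors = FALSE))
  }
  band_mean <- function(center) {
    sel <- which(abs(seq_len(n) - center) <= half + 1e-9)
    px <- band_pixels(axis$polyline, sel, fp)
    mean(image[px])
  }
  midcell_raw <- band_mean(centers["mid"])
  background_raw <- if (quarter == "both") {
    (band_mean(centers["q1"]) + band_mean(centers["q3"])) / 2
  } else {
    band_mean(centers["q1"])
  }
  data.frame(cell_id = axis$cell_id, midcell_raw = midcell_raw,
             background_raw = background_raw,
             net = midcell_raw - background_raw, flag = "",
             stringsAsFactors = FALSE)
}

# unique in-mask pixels of the transverse chords at the selected axis
# positions
band_pixels <- function(pl, sel, fp, step = 0.25, max_half = 50) {
  nor <- polyline_normals(pl)
  px <- lapply(sel, function(i) {
    p <- pl[i, ]; v <- nor[i, ]
    offs <- seq(-max_half, max_half, by = step)
    xs <- round(p[1L] + offs * v[1L])
    ys <- round(p[2L] + offs * v[2L])
    keep <- ys >= 1 & ys <= nrow(fp) & xs >= 1 & xs <= ncol(fp)
    xs <- xs[keep]; ys <- ys[keep]
    inside <- fp[cbind(ys, xs)]
    # clip to the contiguous in-mask run containing the axis point
    ctr <- which.min(abs(offs[keep]))
    run <- inside
    if (!run[ctr]) return(NULL)
    lo <- ctr; while (lo > 1L && run[lo - 1L]) lo <- lo - 1L
    hi <- ctr; while (hi < length(run) && run[hi + 1L]) hi <- hi + 1L
    cbind(ys[lo:hi], xs[lo:hi])
  })
  px <- do.call(rbind, px[!vapply(px, is.null, logical(1))])
  unique(px)
}

#' Relative midcell intensity, normalized to a reference sample
#'
#' Divides every cell's net midcell intensity by the per-replicate median
#' net intensity of the designated reference sample (typically the
#' wild-type), so replicates with different illumination or expression
#' normalize independently and the reference sample's median maps to 1.0.
#'
#' @param measures data.frame with at least columns \code{net},
#'   \code{sample_id}, \code{replicate_id} (e.g. rbind-ed
#'   \code{\link{midcell_intensity}} rows plus sample/replicate columns).
#' @param reference_sample_id the \code{sample_id} used as reference.
#' @return \code{measures} with a \code{relative} column added.
#' @export
relative_midcell <- function(measures, reference_sample_id) {
  stopifnot(is.data.frame(measures),
            all(c("net", "sample_id", "replicate_id") %in% names(measures)))
  measures$relative <- NA_real_
  for (rep_id in unique(measures$replicate_id)) {
    sel <- measures$replicate_id == rep_id
    ref <- measures$net[sel & measures$sample_id == reference_sample_id &
                          !is.na(measures$net)]
    if (length(ref) == 0L)
      stop("replicate '", rep_id, "' has no reference sample ('",
           reference_sample_id, "') measurements")
    med <- median(ref)
    if (!is.finite(med) || med <= 0)
      stop("replicate '", rep_id,
           "' has non-positive reference median net intensity (", med,
           "); relative intensity undefined")
    measures$relative[sel] <- measures$net[sel] / med
  }
  measures
}
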