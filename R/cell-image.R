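#' Construct a segmented single-cell image
#'
#' The unit of polarization and biosensor analysis: a binary mask plus one
#' or more aligned intensity channels. Pixel coordinates follow the image
#' convention: origin at the top-left pixel, `x` increasing rightward
#' (columns), `y` increasing downward (rows), pixel centers at integer
#' coordinates starting at 1.
#'
#' @param mask Integer/logical matrix; non-zero marks cell pixels.
#' @param channels Named list of numeric matrices, same dimensions as
#'   `mask`.
#' @param pixel_size Pixel edge length in micrometres.
#' @param source_direction Optional 2D unit vector pointing from the cell
#'   toward the chemoattractant source, in (x, y) image coordinates
#'   (y downward); normalized internally.
#' @return A list of class `cell_image`.
#' @export
cell_image <- function(mask, channels = list(), pixel_size = 1,
                       source_direction = NULL) {
  if (!is.matrix(mask)) stop_input("`mask` must be a matrix")
  mask <- (mask != 0) * 1L
  if (sum(mask) == 0L) stop_input("`mask` is empty (no cell pixels)")
  if (length(channels)) {
    if (is.null(names(channels)) || any(names(channels) == "")) {
      stop_input("`channels` must be a named list")
    }
    for (nm in names(channels)) {
      ch <- channels[[nm]]
      if (!is.matrix(ch) || !all(dim(ch) == dim(mask))) {
        stop_input("channel '%s' does not match the mask dimensions", nm)
      }
    }
  }
  assert_scalar_number(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  if (!is.null(source_direction)) {
    source_direction <- unit2(source_direction, "source_direction")
  }
  structure(list(mask = mask, channels = channels, pixel_size = pixel_size,
                 source_direction = source_direction),
            class = "cell_image")
}

#' @export
print.cell_image <- function(x, ...) {
  cat(sprintf("<cell_image> %dx%d px, %d cell px, channels: %s\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

assert_cell_image <- function(x) {
  if (!inherits(x, "cell_image")) stop_input("expected a `cell_image`")
  invisible(x)
}

# Pixel coordinates of mask pixels: columns x (col index), y (row index),
# plus the R linear index used for deterministic tie-breaking.
mask_coords <- function(mask) {
  idx <- which(mask != 0)
  rc <- arrayInd(idx, dim(mask))
  list(x = rc[, 2], y = rc[, 1], index = idx)
}

#' Geometric centroid of the cell mask
#'
#' @param image A [cell_image()].
#' @return Named vector `c(x, y)` in pixel coordinates (unweighted mean of
#'   cell-pixel centers).
#' @export
object_centroid <- function(image) {
  assert_cell_image(image)
  co <- mask_coords(image$mask)
  c(x = mean(co$x), y = mean(co$y))
}

#' Intensity-weighted centroid of a channel over the mask
#'
#' @param image A [cell_image()].
#' @param channel Channel name.
#' @return Named vector `c(x, y)` in pixel coordinates.
#' @export
signal_centroid <- function(image, channel) {
  assert_cell_image(image)
  ch <- image$channels[[channel]]
  if (is.null(ch)) stop_input("no channel named '%s'", channel)
  co <- mask_coords(image$mask)
  w <- ch[co$index]
  tot <- sum(w)
  if (tot <= 0) stop_compute("total masked intensity is not positive")
  c(x = sum(w * co$x) / tot, y = sum(w * co$y) / tot)
}

#' Centroid-displacement polarization index
#'
#' The index compares the center of a fluorescent signal (e.g. active
#' Rac1) to the geometric center of the cell in absolute pixel
#' coordinates:
#' `1 - |(X_signal / X_object) * (Y_signal / Y_object)|`.
#' It is 0 when the centroids coincide and may be negative. Note that the
#' formula divides by the object's coordinates, so it depends on where the
#' cell sits in the image frame; coordinates follow the package's
#' top-left-origin, 1-based pixel convention, and zero coordinates are
#' refused. See [centroid_displacement()] for a translation-invariant
#' companion metric.
#'
#' @param object_c,signal_c Centroids as `c(x, y)` pixel coordinates (from
#'   [object_centroid()] and [signal_centroid()]).
#' @return The index (unclamped; negative values are reported as-is).
#' @export
polarization_index <- function(object_c, signal_c) {
  if (length(object_c) != 2L || length(signal_c) != 2L ||
      !all(is.finite(c(object_c, signal_c)))) {
    stop_input("centroids must be finite (x, y) pairs")
  }
  if (any(object_c == 0)) {
    stop_compute(paste0(
      "object centroid has a zero coordinate; the index divides by the ",
      "object coordinates and is origin-dependent - shift the crop or use ",
      "centroid_displacement()"))
  }
  1 - abs((signal_c[[1]] / object_c[[1]]) * (signal_c[[2]] / object_c[[2]]))
}

#' Translation-invariant centroid displacement
#'
#' Companion metric to [polarization_index()]: the Euclidean distance
#' between signal and object centroids in micrometres. This is NOT the
#' coordinate-ratio index; it is provided because the ratio formula
#' depends on the position of the cell in the frame, whereas displacement
#' does not.
#'
#' @param image A [cell_image()].
#' @param channel Channel name.
#' @return Distance in micrometres.
#' @export
centroid_displacement <- function(image, channel) {
  oc <- object_centroid(image)
  sc <- signal_centroid(image, channel)
  sqrt(sum((sc - oc)^2)) * image$pixel_size
}

#' Aspect ratio of the mask's moment-equivalent ellipse
#'
#' Minor over major axis length of the ellipse with the same second
#' central moments as the mask, in (0, 1\]: 1 for a circle, small values
#' for elongated (polarized) cells. This matches the orientation of
#' imaging-flow-cytometry aspect-ratio scores (higher = rounder).
#'
#' @param image A [cell_image()].
#' @return Aspect ratio in (0, 1\].
#' @export
aspect_ratio <- function(image) {
  assert_cell_image(image)
  co <- mask_coords(image$mask)
  if (length(co$x) < 5L) stop_input("mask too small for an aspect ratio")
  cx <- co$x - mean(co$x); cy <- co$y - mean(co$y)
  n <- length(cx)
  S <- matrix(c(sum(cx * cx), sum(cx * cy), sum(cx * cy), sum(cy * cy)),
              2, 2) / n
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0 || ev[2] <= 0) {
    stop_compute("degenerate (collinear) mask: aspect ratio undefined")
  }
  sqrt(ev[2] / ev[1])
}

#' Classify polarization from an aspect-ratio score
#'
#' Cells with aspect ratio below `low` are classified `polarized`
#' (elongated), above `high` `unpolarized` (round), and in between
#' `intermediate` (a class the two-gate convention leaves implicit).
#'
#' @param ar Aspect ratio(s) in (0, 1\] (vectorized).
#' @param low,high Gate thresholds (defaults 0.5 and 0.8, `low < high`).
#' @return Character vector of classifications.
#' @export
classify_polarization <- function(ar, low = 0.5, high = 0.8) {
  if (!is.numeric(ar) || any(!is.finite(ar)) || any(ar <= 0) || any(ar > 1)) {
    stop_input("`ar` must be in (0, 1]")
  }
  if (!(low < high)) stop_input("`low` must be < `high`")
  ifelse(ar < low, "polarized", ifelse(ar > high, "unpolarized",
                                       "intermediate"))
}

#' Percent of cells per polarization class
#'
#' Computes class percentages over in-focus records only; the three
#' classes always sum to 100.
#'
#' @param records data.frame with columns `ar`, `classification`,
#'   `in_focus` (as produced by [simulate_flow_population()], or
#'   assembled from [aspect_ratio()] + [classify_polarization()]).
#' @return Named numeric vector `c(polarized, intermediate, unpolarized)`
#'   in percent.
#' @export
percent_polarized <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("classification", "in_focus") %in% names(records))) {
    stop_input("`records` must have columns classification, in_focus")
  }
  rec <- records[records$in_focus, , drop = FALSE]
  if (nrow(rec) == 0L) stop_input("no in-focus records")
  cls <- factor(rec$classification,
                levels = c("polarized", "intermediate", "unpolarized"))
  if (anyNA(cls)) stop_input("unknown classification label")
  100 * as.vector(table(cls)) / nrow(rec) -> pct
  names(pct) <- levels(cls)
  pct
}
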