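# Synthetic single-cell images and aspect-ratio populations.

#' Pixels on the 8-connected boundary of a mask
#'
#' A mask pixel is a perimeter pixel when at least one of its 8 neighbours
#' (or the outside of the image) is background.
#'
#' @param mask Binary matrix.
#' @return Logical matrix marking perimeter pixels.
#' @export
perimeter_mask <- function(mask) {
  if (!is.matrix(mask)) stop_input("`mask` must be a matrix")
  m <- (mask != 0)
  nr <- nrow(m); nc <- ncol(m)
  # pad with background so border pixels count as boundary
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  all_nb <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    all_nb <- all_nb & pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  m & !all_nb
}

#' Parameters for the synthetic cell-image generator
#'
#' @param grid_size Image size in pixels (square grid).
#' @param pixel_size Micrometres per pixel.
#' @param cell_axes `c(major, minor)` full axis lengths in micrometres
#'   (major along x); `minor <= major`.
#' @param cell_center `c(x, y)` pixel coordinates of the cell center
#'   (default: grid center).
#' @param signal_offset `c(dx, dy)` displacement in pixels of the
#'   noise-free signal centroid from the object centroid.
#' @param membrane_enrichment Ratio of perimeter to interior mean
#'   intensity (>= 1; 1 = uniform).
#' @param noise_sd Gaussian pixel noise s.d. in intensity units.
#' @param source_direction Optional 2D chemoattractant direction stamped
#'   on the generated image (for biosensor analysis).
#' @param seed Integer seed.
#' @return A list of class `image_sim_params`.
#' @export
image_sim_params <- function(grid_size = 64L, pixel_size = 0.5,
                             cell_axes = c(12, 8), cell_center = NULL,
                             signal_offset = c(0, 0),
                             membrane_enrichment = 1, noise_sd = 0,
                             source_direction = NULL, seed = 1L) {
  assert_scalar_number(grid_size, "grid_size", min = 8)
  assert_scalar_number(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  if (length(cell_axes) != 2L || any(cell_axes <= 0)) {
    stop_input("`cell_axes` must be two positive lengths (major, minor)")
  }
  if (cell_axes[2] > cell_axes[1]) {
    stop_input("minor axis must not exceed major axis")
  }
  if (is.null(cell_center)) cell_center <- rep((grid_size + 1) / 2, 2)
  if (length(cell_center) != 2L) stop_input("`cell_center` must be (x, y)")
  if (length(signal_offset) != 2L || !all(is.finite(signal_offset))) {
    stop_input("`signal_offset` must be a finite (dx, dy) pair")
  }
  assert_scalar_number(membrane_enrichment, "membrane_enrichment", min = 1)
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  if (!is.null(source_direction)) {
    source_direction <- unit2(source_direction, "source_direction")
  }
  structure(
    list(grid_size = as.integer(grid_size), pixel_size = pixel_size,
         cell_axes = as.numeric(cell_axes),
         cell_center = as.numeric(cell_center),
         signal_offset = as.numeric(signal_offset),
         membrane_enrichment = membrane_enrichment, noise_sd = noise_sd,
         source_direction = source_direction, seed = as.integer(seed)),
    class = "image_sim_params"
  )
}

#' Simulate a segmented fluorescent cell image
#'
#' Generates an elliptical cell mask plus one intensity channel
#' (`"signal"`). The noise-free channel is constructed so that (a) the
#' mean intensity on the 8-connected perimeter band over the mean interior
#' intensity equals `membrane_enrichment`, and (b) the intensity-weighted
#' centroid sits exactly `signal_offset` pixels from the object centroid
#' (a linear intensity tilt solves for the required gradient, so the
#' displacement is exact before noise). Gaussian noise with s.d.
#' `noise_sd` is then added to every pixel.
#'
#' @param params An [image_sim_params()] object.
#' @return A [cell_image()] with the generating parameters attached as
#'   attribute `"sim_params"`.
#' @export
simulate_cell_image <- function(params) {
  if (!inherits(params, "image_sim_params")) {
    stop_input("`params` must come from image_sim_params()")
  }
  p <- params
  a <- p$cell_axes[1] / 2 / p$pixel_size  # semi-axes in pixels
  b <- p$cell_axes[2] / 2 / p$pixel_size
  cx <- p$cell_center[1]; cy <- p$cell_center[2]
  if (cx - a < 1 || cx + a > p$grid_size ||
      cy - b < 1 || cy + b > p$grid_size) {
    stop_input("cell extends outside the image grid")
  }
  xs <- matrix(seq_len(p$grid_size), p$grid_size, p$grid_size, byrow = TRUE)
  ys <- matrix(seq_len(p$grid_size), p$grid_size, p$grid_size)
  mask <- (((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1) * 1L
  if (sum(mask) < 5L) stop_input("cell too small at this grid resolution")

  base <- 100
  per <- perimeter_mask(mask)
  w <- ifelse(per, p$membrane_enrichment, 1)  # membrane weight per pixel
  co <- mask_coords(mask)
  wm <- w[co$index]
  W <- sum(wm)
  c_obj <- c(mean(co$x), mean(co$y))
  c_w <- c(sum(wm * co$x), sum(wm * co$y)) / W
  dx <- co$x - c_w[1]; dy <- co$y - c_w[2]
  S <- matrix(c(sum(wm * dx * dx), sum(wm * dx * dy),
                sum(wm * dx * dy), sum(wm * dy * dy)), 2, 2)
  target <- c_obj + p$signal_offset
  tilt <- solve(S, (target - c_w) * W)
  lin <- 1 + tilt[1] * dx + tilt[2] * dy
  if (any(lin <= 0)) {
    stop_input("`signal_offset` too large for this cell: intensity would go negative")
  }
  channel <- matrix(0, p$grid_size, p$grid_size)
  channel[co$index] <- base * wm * lin
  if (p$noise_sd > 0) {
    channel <- withr::with_seed(p$seed, {
      channel + matrix(stats::rnorm(length(channel), 0, p$noise_sd),
                       p$grid_size, p$grid_size)
    })
  }
  img <- cell_image(mask, channels = list(signal = channel),
                    pixel_size = p$pixel_size,
                    source_direction = p$source_direction)
  attr(img, "sim_params") <- p
  img
}

#' Simulate an imaging-flow-cytometry aspect-ratio population
#'
#' Draws per-cell aspect-ratio scores from two beta distributions: an
#' elongated ("polarized") class concentrated below 0.5 and a round
#' ("unpolarized") class concentrated above 0.8, mixed at
#' `frac_polarized`. True class labels are retained as ground truth, and
#' each record carries an in-focus flag (a stand-in for image-based focus
#' gating).
#'
#' @param n Number of cells.
#' @param frac_polarized Fraction of truly polarized cells, in \[0, 1\].
#' @param ar_params Named list of beta shape pairs,
#'   `list(polarized = c(a, b), unpolarized = c(a, b))`. Defaults give
#'   means ~0.3 and ~0.9.
#' @param in_focus_frac Probability a record is in focus (default 1).
#' @param seed Integer seed.
#' @return data.frame with columns `ar`, `true_class`, `classification`
#'   (via [classify_polarization()] at the default gates), `in_focus`.
#' @export
simulate_flow_population <- function(n, frac_polarized,
                                     ar_params = list(
                                       polarized = c(12, 28),
                                       unpolarized = c(27, 3)),
                                     in_focus_frac = 1, seed = 1L) {
  assert_scalar_number(n, "n", min = 1)
  assert_scalar_number(frac_polarized, "frac_polarized", min = 0, max = 1)
  assert_scalar_number(in_focus_frac, "in_focus_frac", min = 0, max = 1)
  if (!all(c("polarized", "unpolarized") %in% names(ar_params)) ||
      any(unlist(ar_params) <= 0)) {
    stop_input("`ar_params` needs positive beta shapes for both classes")
  }
  withr::with_seed(as.integer(seed), {
    polar <- stats::runif(n) < frac_polarized
    ar <- numeric(n)
    ar[polar] <- stats::rbeta(sum(polar), ar_params$polarized[1],
                              ar_params$polarized[2])
    ar[!polar] <- stats::rbeta(sum(!polar), ar_params$unpolarized[1],
                               ar_params$unpolarized[2])
    ar <- pmin(pmax(ar, .Machine$double.eps), 1)
    in_focus <- stats::runif(n) < in_focus_frac
    data.frame(
      ar = ar,
      true_class = ifelse(polar, "polarized", "unpolarized"),
      classification = classify_polarization(ar),
      in_focus = in_focus,
      stringsAsFactors = FALSE
    )
  })
}
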