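# Front-half membrane biosensor analysis: per-frame perimeter/area
# intensity ratio facing the chemoattractant source, and series relative
# to stimulation onset.

#' A single biosensor movie frame
#'
#' @param image A [cell_image()] with `source_direction` set.
#' @param t Seconds since chemokine application (>= 0).
#' @return A list of class `biosensor_frame`.
#' @export
biosensor_frame <- function(image, t) {
  assert_cell_image(image)
  if (is.null(image$source_direction)) {
    stop_input("biosensor frames need `source_direction` on the image")
  }
  assert_scalar_number(t, "t", min = 0)
  structure(list(image = image, t = t), class = "biosensor_frame")
}

#' Partition a cell into the front half facing the chemokine source
#'
#' Every mask pixel gets a projection score
#' `(p - object_centroid) . source_direction`. The front area is the top
#' half of mask pixels by score (exactly `ceiling(area / 2)` pixels; ties
#' broken by ascending pixel index), and the front perimeter is the top
#' half of perimeter pixels (8-connected boundary band) by the same
#' score. Rank-based halves keep "50%" exact for asymmetric shapes, where
#' a geometric half-plane cut would not.
#'
#' @param image A [cell_image()] with `source_direction` set.
#' @return List with `front_area`, `front_perimeter`, `perimeter` (linear
#'   pixel indices into the image matrices) and `scores` (named by index,
#'   for diagnostics).
#' @export
front_partition <- function(image) {
  assert_cell_image(image)
  dir <- image$source_direction
  if (is.null(dir)) stop_input("`source_direction` is not set on this image")
  co <- mask_coords(image$mask)
  cx <- mean(co$x); cy <- mean(co$y)
  scores <- (co$x - cx) * dir[1] + (co$y - cy) * dir[2]
  take_front <- function(sub) {
    k <- ceiling(length(sub) / 2)
    ord <- order(-scores[sub], co$index[sub])
    co$index[sub][ord][seq_len(k)]
  }
  per <- which(perimeter_mask(image$mask))
  is_per <- co$index %in% per
  list(
    front_area = take_front(seq_along(co$index)),
    front_perimeter = take_front(which(is_per)),
    perimeter = co$index[is_per],
    scores = stats::setNames(scores, co$index)
  )
}

#' Front perimeter / front area intensity ratio
#'
#' The biosensor readout for one frame: fluorescence intensity of the 50%
#' of the cell perimeter facing the chemokine source divided by the
#' intensity of the 50% of the cell area facing the source. "Intensity"
#' is the mean over each pixel set by default, making the ratio
#' dimensionless and independent of cell size; `mode = "sum"` uses
#' integrated intensities instead.
#'
#' @param frame A [biosensor_frame()] (or a [cell_image()] with
#'   `source_direction` set).
#' @param channel Channel name.
#' @param mode `"mean"` (default) or `"sum"`.
#' @return The ratio (>= 0).
#' @export
pip3_ratio <- function(frame, channel, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  image <- if (inherits(frame, "biosensor_frame")) frame$image else frame
  assert_cell_image(image)
  ch <- image$channels[[channel]]
  if (is.null(ch)) stop_input("no channel named '%s'", channel)
  fp <- front_partition(image)
  agg <- if (mode == "mean") mean else sum
  denom <- agg(ch[fp$front_area])
  if (denom <= 0) stop_compute("front-area intensity is not positive")
  agg(ch[fp$front_perimeter]) / denom
}

#' Biosensor ratio series relative to stimulation onset
#'
#' Computes the front ratio for every frame and divides by the ratio of
#' the first frame (time 0, when the chemokine was applied), so the series
#' starts at exactly 1.
#'
#' @param frames List of [biosensor_frame()]s with strictly increasing
#'   times; the first frame is the t = 0 baseline.
#' @param channel Channel name.
#' @param mode Passed to [pip3_ratio()].
#' @return data.frame with columns `t`, `ratio`, `relative`.
#' @export
relative_series <- function(frames, channel, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  if (!is.list(frames) || length(frames) < 1L ||
      !all(vapply(frames, inherits, logical(1), "biosensor_frame"))) {
    stop_input("`frames` must be a non-empty list of biosensor_frame objects")
  }
  tv <- vapply(frames, `[[`, numeric(1), "t")
  if (any(diff(tv) <= 0)) stop_input("frame times must be strictly increasing")
  ratios <- vapply(frames, pip3_ratio, numeric(1), channel = channel,
                   mode = mode)
  if (ratios[1] <= 0) stop_compute("baseline (t = 0) ratio is not positive")
  data.frame(t = tv, ratio = ratios, relative = ratios / ratios[1])
}

#' Per-timepoint mean and s.e.m. across biosensor series
#'
#' @param series_set List of data.frames from [relative_series()], all on
#'   the same time grid.
#' @param value_col Column to summarize (default `"relative"`).
#' @return data.frame with `t`, `n`, `mean`, `sem` per timepoint.
#' @export
group_mean_series <- function(series_set, value_col = "relative") {
  if (!is.list(series_set) || length(series_set) < 1L) {
    stop_input("`series_set` must be a non-empty list of series tables")
  }
  t0 <- series_set[[1]]$t
  for (s in series_set) {
    if (!is.data.frame(s) || is.null(s$t) || is.null(s[[value_col]])) {
      stop_input("each series needs columns `t` and `%s`", value_col)
    }
    if (length(s$t) != length(t0) || any(s$t != t0)) {
      stop_input("series do not share a common time grid")
    }
  }
  vals <- vapply(series_set, `[[`, numeric(length(t0)), value_col)
  vals <- matrix(vals, nrow = length(t0))
  n <- ncol(vals)
  data.frame(
    t = t0, n = n,
    mean = rowMeans(vals),
    sem = if (n > 1) apply(vals, 1, stats::sd) / sqrt(n) else rep(0, length(t0))
  )
}

#' Simulate a biosensor frame series with an enrichment schedule
#'
#' Convenience generator for testing the biosensor pipeline: one synthetic
#' cell imaged repeatedly, with the membrane (perimeter-band) enrichment
#' following `enrichment` over time — emulating chemokine-induced
#' accumulation of a membrane biosensor. The cell does not move between
#' frames (as under actin-polymerization arrest).
#'
#' @param enrichment Numeric vector (>= 1) of membrane enrichment per
#'   frame.
#' @param t Frame times in seconds (default every 10 s from 0).
#' @param params An [image_sim_params()] used as the frame template; its
#'   `membrane_enrichment` is overridden per frame and its seed is offset
#'   per frame so noise is independent across frames.
#' @return List of [biosensor_frame()]s.
#' @export
simulate_biosensor_series <- function(enrichment,
                                      t = seq(0, by = 10,
                                              length.out = length(enrichment)),
                                      params = image_sim_params(
                                        source_direction = c(1, 0))) {
  if (!is.numeric(enrichment) || any(enrichment < 1)) {
    stop_input("`enrichment` must be numeric with all values >= 1")
  }
  if (length(t) != length(enrichment)) {
    stop_input("`t` and `enrichment` must have equal length")
  }
  if (is.null(params$source_direction)) {
    stop_input("`params` must carry a source_direction")
  }
  lapply(seq_along(enrichment), function(k) {
    pk <- params
    pk$membrane_enrichment <- enrichment[k]
    pk$seed <- params$seed + k - 1L
    biosensor_frame(simulate_cell_image(pk), t[k])
  })
}
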