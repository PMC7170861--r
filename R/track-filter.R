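#' Track exclusion criteria
#'
#' Defaults follow standard chemotaxis-chamber practice for lymphocyte
#' recordings: objects smaller than 16 um^3 are excluded (segmentation
#' debris), static objects are excluded, and tracks shorter than 50 um
#' total path are excluded. "Static" is operationalized as net start-to-end
#' displacement below `static_displacement_threshold` (default 2 um:
#' sub-cell-diameter displacement over the whole recording is immobility).
#' The 50 um rule is applied to total path length (the tracking-software
#' notion of track length); switch `length_measure` to
#' `"net_displacement"` for the displacement-based reading.
#'
#' @param min_volume Minimum mean object volume, um^3 (default 16). Tracks
#'   without a volume skip this rule (with a warning at filter time).
#' @param min_path_length Minimum track length, um (default 50).
#' @param static_displacement_threshold Net displacement below which a
#'   track counts as static, um (default 2).
#' @param target_duration Target track duration for window selection,
#'   minutes (default 60).
#' @param duration_tolerance Fractional tolerance around
#'   `target_duration` (default 0.2).
#' @param length_measure `"path_length"` (default) or `"net_displacement"`:
#'   which length the `min_path_length` rule tests.
#' @return A list of class `filter_criteria`.
#' @export
filter_criteria <- function(min_volume = 16, min_path_length = 50,
                            static_displacement_threshold = 2,
                            target_duration = 60, duration_tolerance = 0.2,
                            length_measure = c("path_length",
                                               "net_displacement")) {
  assert_scalar_number(min_volume, "min_volume", min = 0)
  assert_scalar_number(min_path_length, "min_path_length", min = 0)
  assert_scalar_number(static_displacement_threshold,
                       "static_displacement_threshold", min = 0)
  assert_scalar_number(target_duration, "target_duration", min = 0)
  assert_scalar_number(duration_tolerance, "duration_tolerance", min = 0)
  structure(
    list(min_volume = min_volume, min_path_length = min_path_length,
         static_displacement_threshold = static_displacement_threshold,
         target_duration = target_duration,
         duration_tolerance = duration_tolerance,
         length_measure = match.arg(length_measure)),
    class = "filter_criteria"
  )
}

track_length_for_rule <- function(tr, criteria) {
  if (criteria$length_measure == "path_length") path_length(tr)
  else sqrt(sum(net_displacement(tr)^2))
}

#' Apply exclusion filters to a set of tracks
#'
#' Each track is tested against the rules in a fixed order and rejected
#' with the first applicable reason: `"volume"` (volume below
#' `min_volume`, only when a volume is present), `"static"` (net
#' displacement below the static threshold), `"short"` (track length below
#' `min_path_length`). Retained and rejected tracks partition the input,
#' and filtering the retained set again changes nothing.
#'
#' @param tracks List of [track()] objects.
#' @param criteria A [filter_criteria()] object.
#' @param rule_order Order in which rules are tested; permute to probe
#'   sensitivity to rule ordering (the reported reason is the first hit).
#' @return A list with `retained` (list of tracks) and `rejections`
#'   (data.frame of `id`, `reason`).
#' @export
filter_tracks <- function(tracks, criteria = filter_criteria(),
                          rule_order = c("volume", "static", "short")) {
  stopifnot(is.list(tracks))
  if (!inherits(criteria, "filter_criteria")) {
    stop_input("`criteria` must come from filter_criteria()")
  }
  rule_order <- match.arg(rule_order, c("volume", "static", "short"),
                          several.ok = TRUE)
  any_missing_volume <- FALSE
  reason_of <- function(tr) {
    for (rule in rule_order) {
      hit <- switch(rule,
        volume = {
          if (is.na(tr$volume)) { any_missing_volume <<- TRUE; FALSE }
          else tr$volume < criteria$min_volume
        },
        static = sqrt(sum(net_displacement(tr)^2)) <
          criteria$static_displacement_threshold,
        short = track_length_for_rule(tr, criteria) <
          criteria$min_path_length
      )
      if (hit) return(rule)
    }
    NA_character_
  }
  reasons <- vapply(tracks, function(tr) { assert_track(tr); reason_of(tr) },
                    character(1))
  if (any_missing_volume) {
    warning("some tracks have no volume; the volume rule was skipped for them",
            call. = FALSE)
  }
  keep <- is.na(reasons)
  list(
    retained = tracks[keep],
    rejections = data.frame(
      id = vapply(tracks[!keep], `[[`, character(1), "id"),
      reason = reasons[!keep],
      stringsAsFactors = FALSE
    )
  )
}

#' Select tracks from the middle of a recording
#'
#' Emulates the manual track-selection step of chamber assays: keep tracks
#' whose duration is within `target_duration * (1 +/- duration_tolerance)`
#' and whose temporal midpoint lies in the central half of the recording
#' span; return them sorted by descending path length (tracks "sorted by
#' migration length").
#'
#' @param tracks List of [track()] objects.
#' @param criteria A [filter_criteria()] object (supplies the duration
#'   window).
#' @param recording_span Numeric `c(t0, t1)` in minutes.
#' @return List of retained tracks, longest path first.
#' @export
select_analysis_window <- function(tracks, criteria = filter_criteria(),
                                   recording_span) {
  if (!is.numeric(recording_span) || length(recording_span) != 2L ||
      recording_span[2] <= recording_span[1]) {
    stop_input("`recording_span` must be c(t0, t1) with t1 > t0")
  }
  if (!inherits(criteria, "filter_criteria")) {
    stop_input("`criteria` must come from filter_criteria()")
  }
  t0 <- recording_span[1]; t1 <- recording_span[2]
  span <- t1 - t0
  central <- c(t0 + span / 4, t1 - span / 4)
  lo <- criteria$target_duration * (1 - criteria$duration_tolerance)
  hi <- criteria$target_duration * (1 + criteria$duration_tolerance)
  keep <- vapply(tracks, function(tr) {
    assert_track(tr)
    dur <- track_duration(tr)
    mid <- (tr$t[1] + tr$t[length(tr$t)]) / 2
    dur >= lo && dur <= hi && mid >= central[1] && mid <= central[2]
  }, logical(1))
  kept <- tracks[keep]
  kept[order(vapply(kept, path_length, numeric(1)), decreasing = TRUE)]
}
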