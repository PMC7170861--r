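# Readers and writers for the package's plain-text interchange formats.
# All writes are atomic (write to a sibling temp file, then rename), and
# numbers are written at full precision so round trips are exact to
# parsing precision.

TRACK_COLUMNS <- c("track_id", "frame", "t_min", "x_um", "y_um",
                   "volume_um3", "group")

#' Write tracks to CSV
#'
#' One row per point, header
#' `track_id,frame,t_min,x_um,y_um,volume_um3,group`.
#'
#' @param tracks List of [track()] objects.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(is.list(tracks))
  rows <- lapply(tracks, function(tr) {
    assert_track(tr)
    data.frame(track_id = tr$id, frame = seq_along(tr$t) - 1L,
               t_min = tr$t, x_um = tr$x, y_um = tr$y,
               volume_um3 = tr$volume, group = tr$group,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df)) df <- as.data.frame(stats::setNames(
    replicate(length(TRACK_COLUMNS), character(0), simplify = FALSE),
    TRACK_COLUMNS))
  atomic_write(path, function(tmp) {
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
                     tmp, row.names = FALSE, quote = FALSE)
  })
}

#' Read tracks from CSV
#'
#' Expects the dialect written by [write_tracks()]. Rows are grouped by
#' `track_id` and ordered by time; a non-increasing time within a track
#' is a validation error naming the track.
#'
#' @param path Input file.
#' @return List of [track()] objects (empty, with a warning, for a file
#'   holding only the header).
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(track_id = "character"))
  missing <- setdiff(TRACK_COLUMNS, names(df))
  if (length(missing)) {
    stop_input("track file %s is missing columns: %s", path,
               paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    warning(sprintf("track file %s has a header but no rows", path),
            call. = FALSE)
    return(list())
  }
  bad <- !is.finite(df$t_min) | !is.finite(df$x_um) | !is.finite(df$y_um)
  if (any(bad)) {
    stop_input("malformed rows (non-numeric coordinates) at lines: %s",
               paste(which(bad) + 1L, collapse = ", "))
  }
  lapply(split(df, df$track_id)[unique(df$track_id)], function(d) {
    d <- d[order(d$t_min), , drop = FALSE]
    if (any(diff(d$t_min) <= 0)) {
      stop_input("track '%s': duplicated or non-increasing timestamps",
                 d$track_id[1])
    }
    track(d$track_id[1], t = d$t_min, x = d$x_um, y = d$y_um,
          group = d$group[1], volume = d$volume_um3[1])
  }) |> unname()
}

#' Write an isotherm to CSV (`conc_uM,response_RU`)
#' @param iso An [isotherm()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_isotherm <- function(iso, path) {
  if (!inherits(iso, "isotherm")) stop_input("`iso` must be an isotherm()")
  df <- data.frame(conc_uM = iso$concentrations,
                   response_RU = iso$responses)
  atomic_write(path, function(tmp) {
    utils::write.csv(format(df, digits = 17, trim = TRUE), tmp,
                     row.names = FALSE, quote = FALSE)
  })
}

#' Read an isotherm from CSV (`conc_uM,response_RU`)
#' @param path Input file.
#' @param label Optional surface label.
#' @return An [isotherm()].
#' @export
read_isotherm <- function(path, label = NA_character_) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  df <- utils::read.csv(path)
  if (!all(c("conc_uM", "response_RU") %in% names(df))) {
    stop_input("isotherm file needs columns conc_uM, response_RU")
  }
  isotherm(df$conc_uM, df$response_RU, label = label)
}

#' Read a kinase dose-response table (`conc_uM,activity`)
#' @param path Input file.
#' @return data.frame for [kinase_fold()].
#' @export
read_kinase_table <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  df <- utils::read.csv(path)
  if (!all(c("conc_uM", "activity") %in% names(df))) {
    stop_input("kinase file needs columns conc_uM, activity")
  }
  df
}

#' Write a cell image as plain text
#'
#' Serializes a [cell_image()] to text: `<prefix>.json` holds the
#' metadata (pixel size, source direction, channel names) and each page —
#' the mask and every channel — is a headerless CSV matrix
#' `<prefix>_<page>.csv`. A plain-text stand-in for multi-page image
#' formats, used so fixtures stay diffable and dependency-free.
#'
#' @param image A [cell_image()].
#' @param prefix Path prefix (no extension).
#' @return The metadata path, invisibly.
#' @export
write_cell_image <- function(image, prefix) {
  assert_cell_image(image)
  write_page <- function(mat, path) {
    atomic_write(path, function(tmp) {
      utils::write.table(format(mat, digits = 17, trim = TRUE), tmp,
                         sep = ",", row.names = FALSE, col.names = FALSE,
                         quote = FALSE)
    })
  }
  write_page(image$mask, paste0(prefix, "_mask.csv"))
  for (nm in names(image$channels)) {
    write_page(image$channels[[nm]], paste0(prefix, "_", nm, ".csv"))
  }
  meta <- list(pixel_size = image$pixel_size,
               source_direction = image$source_direction,
               channels = as.list(names(image$channels)))
  atomic_write(paste0(prefix, ".json"), function(tmp) {
    jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA,
                         null = "null")
  })
}

#' Read a cell image written by [write_cell_image()]
#' @param prefix Path prefix used at write time.
#' @return A [cell_image()].
#' @export
read_cell_image <- function(prefix) {
  meta_path <- paste0(prefix, ".json")
  if (!file.exists(meta_path)) stop_input("file not found: %s", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  read_page <- function(path) {
    as.matrix(utils::read.csv(path, header = FALSE))
  }
  mask <- read_page(paste0(prefix, "_mask.csv"))
  chans <- lapply(stats::setNames(nm = unlist(meta$channels) %||% character(0)),
                  function(nm) {
                    m <- read_page(paste0(prefix, "_", nm, ".csv"))
                    dimnames(m) <- NULL
                    m
                  })
  dimnames(mask) <- NULL
  cell_image(mask, channels = chans, pixel_size = meta$pixel_size,
             source_direction = meta$source_direction)
}
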