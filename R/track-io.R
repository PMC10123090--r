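#' Read tracks from CSV
#'
#' The track CSV dialect has header `track_id,frame,x_um,y_um` with optional
#' `t_s` and `state` columns; coordinates in micrometres, 0-based frames.
#'
#' @param path Path to a CSV file.
#' @param frame_interval Frame interval in seconds (default 0.024).
#' @param condition Optional condition label.
#' @return A [track_tbl()].
#' @export
read_tracks_csv <- function(path, frame_interval = 0.024,
                            condition = NA_character_) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("track_id", "frame", "x_um", "y_um")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("track CSV %s is missing required column(s): %s",
                  basename(path), paste(missing_cols, collapse = ", ")))
  }
  bad <- which(!is.finite(df$x_um) | !is.finite(df$y_um) | is.na(df$frame))
  if (length(bad) > 0) {
    abort(sprintf("malformed rows in %s (file lines, incl. header): %s",
                  basename(path),
                  paste(utils::head(bad + 1L, 10), collapse = ", ")))
  }
  df$t_s <- NULL
  track_tbl(df, frame_interval = frame_interval, condition = condition,
            provenance = sprintf("read_tracks_csv(%s)", basename(path)))
}

#' Write tracks to CSV
#'
#' Writes the `track_id,frame,x_um,y_um,t_s` dialect read by
#' [read_tracks_csv()]; coordinates are preserved to at least 6 decimals
#' (written at full precision).
#'
#' @param ts A [track_tbl()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(ts, path) {
  cols <- intersect(c("track_id", "frame", "x_um", "y_um", "t_s", "state"),
                    names(ts))
  readr::write_csv(as_tibble(ts)[cols], path, progress = FALSE)
  invisible(path)
}

#' Read tracks from TrackMate model XML
#'
#' Consumes the TrackMate model XML dialect: `<Spot>` elements with
#' `POSITION_X`/`POSITION_Y` (micrometres), `FRAME` and `ID` attributes, and
#' `<Track>` elements whose `<Edge>`s connect spot IDs. Detection and linking
#' settings are not interpreted; they are captured as provenance strings only.
#' Files whose spatial units are not micrometres are rejected rather than
#' silently rescaled.
#'
#' @inheritParams read_tracks_csv
#' @return A [track_tbl()] equivalent to what [read_tracks_csv()] would return
#'   for the same data.
#' @export
read_trackmate_xml <- function(path, frame_interval = 0.024,
                               condition = NA_character_) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  doc <- xml2::read_xml(path)
  model <- xml2::xml_find_first(doc, ".//Model")
  if (is.na(model)) abort("not a TrackMate model XML: no <Model> element")
  units <- xml2::xml_attr(model, "spatialunits")
  ok_units <- c("um", "µm", "micron", "microns", "micrometer",
                "micrometers", "μm")
  if (is.na(units) || !(tolower(units) %in% ok_units)) {
    abort(sprintf(
      "unknown spatial units %s in %s: only micrometre-calibrated TrackMate XML is supported",
      if (is.na(units)) "<missing>" else shQuote(units), basename(path)))
  }

  spots <- xml2::xml_find_all(doc, ".//AllSpots//Spot")
  if (length(spots) == 0) abort("no <Spot> elements found")
  spot_df <- tibble(
    id = xml2::xml_attr(spots, "ID"),
    frame = as.integer(xml2::xml_attr(spots, "FRAME")),
    x_um = as.numeric(xml2::xml_attr(spots, "POSITION_X")),
    y_um = as.numeric(xml2::xml_attr(spots, "POSITION_Y")))

  tracks <- xml2::xml_find_all(doc, ".//AllTracks/Track")
  if (length(tracks) == 0) abort("no <Track> elements found")
  edges <- purrr::map_dfr(tracks, function(tr) {
    e <- xml2::xml_find_all(tr, ".//Edge")
    tibble(track_id = xml2::xml_attr(tr, "TRACK_ID"),
           source = xml2::xml_attr(e, "SPOT_SOURCE_ID"),
           target = xml2::xml_attr(e, "SPOT_TARGET_ID"))
  })
  membership <- edges |>
    tidyr::pivot_longer(c("source", "target"), values_to = "id") |>
    distinct(.data$track_id, .data$id)
  df <- inner_join(membership, spot_df, by = "id") |>
    mutate(track_id = paste0("track_", .data$track_id)) |>
    select("track_id", "frame", "x_um", "y_um") |>
    arrange(.data$track_id, .data$frame)

  settings <- xml2::xml_find_first(doc, ".//Settings")
  prov <- sprintf("read_trackmate_xml(%s)", basename(path))
  if (!is.na(settings)) {
    link <- xml2::xml_find_first(settings, ".//TrackerSettings")
    if (!is.na(link)) {
      at <- xml2::xml_attrs(link)
      prov <- c(prov, paste0("trackmate.", names(at), "=", unname(at)))
    }
  }
  track_tbl(df, frame_interval = frame_interval, condition = condition,
            provenance = prov)
}

#' Filter tracks by bleach window and minimum length
#'
#' Localizations recorded before `bleach_cutoff_frame` (the dye bleaching
#' phase at the start of an acquisition) are dropped first; tracks left with
#' fewer than `min_length` localizations are then removed. Both steps are
#' recorded in the provenance, and the operation is idempotent.
#'
#' @param ts A [track_tbl()].
#' @param min_length Minimum retained track length in localizations
#'   (default 5).
#' @param bleach_cutoff_frame Frames `< bleach_cutoff_frame` are discarded
#'   (default 500).
#' @return The filtered [track_tbl()].
#' @export
filter_tracks <- function(ts, min_length = 5, bleach_cutoff_frame = 500) {
  if (min_length < 2) abort("`min_length` must be >= 2")
  df <- as_tibble(ts) |>
    filter(.data$frame >= bleach_cutoff_frame) |>
    group_by(.data$track_id) |>
    filter(n() >= min_length) |>
    ungroup()
  restore_track_tbl(df, ts,
                    note = sprintf("filter_tracks(min_length=%d, bleach_cutoff_frame=%d)",
                                   min_length, bleach_cutoff_frame))
}
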