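make_fixture_tracks <- function(lengths, frame_interval = 0.024,
                                first_frame = 600L) {
  df <- purrr::imap_dfr(lengths, function(L, i) {
    tibble::tibble(track_id = sprintf("t%02d", i),
                   frame = first_frame + seq_len(L) - 1L,
                   x_um = round(stats::runif(L, 0, 10), 6),
                   y_um = round(stats::runif(L, 0, 10), 6))
  })
  if (length(lengths) == 0) {
    df <- tibble::tibble(track_id = character(), frame = integer(),
                         x_um = numeric(), y_um = numeric())
  }
  track_tbl(df, frame_interval = frame_interval)
}

test_that("track CSV round-trip is lossless", {
  set.seed(1)
  ts <- make_fixture_tracks(c(5, 7, 9))
  expect_equal(nrow(ts), 21)
  expect_equal(length(unique(ts$track_id)), 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks_csv(ts, path)
  back <- read_tracks_csv(path)
  expect_equal(as.data.frame(back)[c("track_id", "frame", "x_um", "y_um")],
               as.data.frame(ts)[c("track_id", "frame", "x_um", "y_um")],
               tolerance = 1e-9)
})

test_that("missing or malformed CSV columns produce named errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(track_id = "a", frame = 0, y_um = 1), path)
  expect_error(read_tracks_csv(path), "x_um")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("track_id,frame,x_um,y_um", "a,0,1.0,2.0", "a,1,NA,2.0"), path2)
  expect_error(read_tracks_csv(path2), "malformed")
  expect_error(read_tracks_csv("does-not-exist.csv"), "not found")
})

test_that("non-monotone frames within a track are rejected with the track named", {
  df <- tibble::tibble(track_id = c("bad", "bad"), frame = c(5L, 5L),
                       x_um = c(0, 1), y_um = c(0, 1))
  expect_error(track_tbl(df, 0.024), "bad")
})

test_that("TrackMate XML and CSV readers agree on the same data", {
  ts <- simulate_tracks(15, d = 0.2, seed = 21)
  csv <- withr::local_tempfile(fileext = ".csv")
  xml <- withr::local_tempfile(fileext = ".xml")
  write_tracks_csv(ts, csv)
  sptmix:::write_trackmate_xml(ts, xml)
  a <- read_tracks_csv(csv)
  b <- read_trackmate_xml(xml)
  key <- function(x) {
    dplyr::arrange(as.data.frame(x)[c("frame", "x_um", "y_um")], frame, x_um)
  }
  expect_equal(key(a), key(b), tolerance = 1e-12)
  expect_equal(length(unique(a$track_id)), length(unique(b$track_id)))
  # linking settings captured as provenance
  expect_true(any(grepl("LINKING_MAX_DISTANCE",
                        attr(b, "provenance"))))
})

test_that("a minimal hand-built TrackMate XML parses with correct coordinates", {
  xml <- withr::local_tempfile(fileext = ".xml")
  writeLines('<TrackMate version="6.0.1">
 <Model spatialunits="um" timeunits="s">
  <AllSpots>
   <SpotsInFrame frame="0">
    <Spot ID="0" FRAME="0" POSITION_X="1.25" POSITION_Y="2.5"/>
   </SpotsInFrame>
   <SpotsInFrame frame="1">
    <Spot ID="1" FRAME="1" POSITION_X="1.5" POSITION_Y="2.25"/>
   </SpotsInFrame>
  </AllSpots>
  <AllTracks>
   <Track TRACK_ID="0"><Edge SPOT_SOURCE_ID="0" SPOT_TARGET_ID="1"/></Track>
  </AllTracks>
 </Model>
</TrackMate>', xml)
  ts <- read_trackmate_xml(xml)
  expect_equal(nrow(ts), 2)
  expect_equal(ts$x_um, c(1.25, 1.5))
  expect_equal(ts$y_um, c(2.5, 2.25))
})

test_that("pixel-calibrated or uncalibrated TrackMate XML is refused", {
  xml <- withr::local_tempfile(fileext = ".xml")
  writeLines('<TrackMate><Model spatialunits="pixel"><AllSpots>
    <SpotsInFrame frame="0"><Spot ID="0" FRAME="0" POSITION_X="1" POSITION_Y="1"/></SpotsInFrame>
    </AllSpots><AllTracks><Track TRACK_ID="0"/></AllTracks></Model></TrackMate>', xml)
  expect_error(read_trackmate_xml(xml), "spatial units")
})

test_that("filtering drops the bleach window first, then short tracks", {
  # 6 localizations, but only 4 survive the bleach cutoff -> removed
  df <- tibble::tibble(track_id = "a", frame = c(498L, 499L, 500L, 501L, 502L, 503L),
                       x_um = 0, y_um = 0)
  ts <- track_tbl(df, 0.024)
  expect_equal(nrow(filter_tracks(ts, min_length = 5, bleach_cutoff_frame = 500)), 0)
  expect_equal(nrow(filter_tracks(ts, min_length = 4, bleach_cutoff_frame = 500)), 4)
})

test_that("filtering retains exactly the tracks long enough after the cutoff", {
  set.seed(2)
  lens <- c(rep(3, 37), rep(8, 63))   # 37 short, 63 long
  ts <- make_fixture_tracks(sample(lens))
  kept <- filter_tracks(ts, min_length = 5, bleach_cutoff_frame = 500)
  expect_equal(length(unique(kept$track_id)), 63)
})

test_that("filtering is idempotent and preserves empty track sets", {
  set.seed(3)
  ts <- make_fixture_tracks(c(5, 6, 3))
  once <- filter_tracks(ts)
  twice <- filter_tracks(once)
  expect_equal(as.data.frame(once), as.data.frame(twice), ignore_attr = TRUE)
  empty <- filter_tracks(make_fixture_tracks(integer(0)))
  expect_equal(nrow(empty), 0)
})
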