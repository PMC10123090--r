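#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   inner_join left_join n bind_rows distinct pull rename across
#' @importFrom stats lm coef optim optimize pf rnorm runif rgeom kmeans sd
#'   quantile setNames predict resid
#' @importFrom utils head tail
NULL

# run `expr` under a private RNG stream when seed is given, leaving the
# caller's RNG state untouched; seed = NULL uses the ambient stream
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict && x <= lower) abort(sprintf("`%s` must be > %g.", name, lower))
  if (!strict && x < lower) abort(sprintf("`%s` must be >= %g.", name, lower))
  invisible(x)
}

#' Construct a track table
#'
#' A track table is the package's central container: one row per localization,
#' with physical coordinates in micrometres and 0-based integer frame indices.
#' It is an ordinary tibble (so all dplyr verbs apply) carrying the frame
#' interval, a condition label and provenance strings as attributes.
#'
#' @param df Data frame with columns `track_id`, `frame`, `x_um`, `y_um`
#'   (and optionally `t_s`, `state`).
#' @param frame_interval Time between consecutive frames, seconds.
#' @param condition Free-text condition label.
#' @param provenance Character vector describing where the data came from and
#'   which filters have been applied.
#' @return A `track_tbl` tibble with a `t_s` column (`frame * frame_interval`).
#' @export
track_tbl <- function(df, frame_interval, condition = NA_character_,
                      provenance = character()) {
  stopifnot_scalar_number(frame_interval, "frame_interval", 0, strict = TRUE)
  req <- c("track_id", "frame", "x_um", "y_um")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("track table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  out <- as_tibble(df)
  out$frame <- as.integer(out$frame)
  if (!all(is.finite(out$x_um)) || !all(is.finite(out$y_um))) {
    abort("track coordinates must be finite")
  }
  out <- arrange(out, .data$track_id, .data$frame)
  out$t_s <- out$frame * frame_interval
  # frames must be strictly increasing within a track
  bad <- out |>
    group_by(.data$track_id) |>
    summarise(ok = all(diff(.data$frame) > 0) || n() == 1L) |>
    filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(sprintf("non-monotone frames within track(s): %s",
                  paste(utils::head(bad$track_id, 5), collapse = ", ")))
  }
  structure(out,
            class = c("track_tbl", class(as_tibble(out))),
            frame_interval = frame_interval,
            condition = condition,
            provenance = provenance)
}

#' @export
print.track_tbl <- function(x, ...) {
  nt <- length(unique(x$track_id))
  cat(sprintf("# Track table: %d tracks, %d localizations, frame interval %g s\n",
              nt, nrow(x), frame_interval(x)))
  if (!is.na(attr(x, "condition"))) cat("# Condition:", attr(x, "condition"), "\n")
  NextMethod()
}

#' Frame interval of a track table
#' @param ts A `track_tbl`.
#' @return Frame interval in seconds.
#' @export
frame_interval <- function(ts) {
  fi <- attr(ts, "frame_interval")
  if (is.null(fi)) abort("not a track table: no frame_interval attribute")
  fi
}

track_provenance <- function(ts) attr(ts, "provenance") %||% character()

add_provenance <- function(ts, note) {
  attr(ts, "provenance") <- c(track_provenance(ts), note)
  ts
}

# rebuild attributes after dplyr operations stripped the subclass
restore_track_tbl <- function(df, template, note = NULL) {
  out <- track_tbl(df,
                   frame_interval = frame_interval(template),
                   condition = attr(template, "condition"),
                   provenance = track_provenance(template))
  if (!is.null(note)) out <- add_provenance(out, note)
  out
}
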