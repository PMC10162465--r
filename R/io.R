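#' Read and write recordings as delimited text
#'
#' A recording is stored as a CSV (column `time_s` plus one column per
#' channel) next to a small JSON sidecar (`<path>.json`) holding the sampling
#' rate and start time.
#'
#' @param rec An [mc_recording()].
#' @param path CSV file path.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns an [mc_recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "mc_recording"))
  readr::write_csv(as_tibble(rec), path)
  jsonlite::write_json(list(rate = rec$rate, t0 = rec$t0),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  vals <- as.matrix(tbl[setdiff(names(tbl), "time_s")])
  mc_recording(vals, rate = meta$rate, t0 = meta$t0)
}

#' Read and write percept timelines as event tables
#'
#' The timeline is stored as a CSV event table (`time_s`, `percept`,
#' `button_s`) with a JSON sidecar for the reaction time, block duration and
#' triplet duration.
#'
#' @param timeline A `percept_timeline`.
#' @param path CSV file path.
#' @return `write_timeline()` returns `path` invisibly; `read_timeline()`
#'   returns a `percept_timeline`.
#' @export
write_timeline <- function(timeline, path) {
  stopifnot(inherits(timeline, "percept_timeline"))
  tbl <- tibble::tibble(
    time_s = c(0, timeline$switch_times),
    percept = timeline$percepts,
    button_s = c(NA_real_, timeline$button_times)
  )
  readr::write_csv(tbl, path)
  jsonlite::write_json(
    list(reaction_time = timeline$reaction_time,
         block_duration = timeline$block_duration,
         triplet_duration = timeline$triplet_duration),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_timeline
#' @export
read_timeline <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  structure(
    list(
      switch_times = tbl$time_s[-1],
      percepts = tbl$percept,
      button_times = tbl$button_s[-1],
      reaction_time = meta$reaction_time,
      block_duration = meta$block_duration,
      triplet_duration = meta$triplet_duration
    ),
    class = "percept_timeline"
  )
}
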