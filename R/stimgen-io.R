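#' Write a stream or trial schedule to JSON
#'
#' Serializes a `stream_spec` or `trial_schedule` to a self-describing JSON
#' document (event onsets/offsets, syllable onsets, image tokens, side map)
#' that round-trips exactly through [read_schedule_json()].
#'
#' @param x A `stream_spec` or `trial_schedule`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule_json <- function(x, path) {
  if (inherits(x, "stream_spec")) {
    doc <- list(type = "stream",
                word_duration_ms = x$word_duration_ms,
                total_duration_ms = x$total_duration_ms,
                events = x$events)
  } else if (inherits(x, "trial_schedule")) {
    doc <- list(type = "trials",
                end_ms = x$end_ms,
                attractor_ms = x$attractor_ms,
                word_duration_ms = x$word_duration_ms,
                timeline = x$timeline,
                trials = x$trials)
  } else {
    stop("x must be a stream_spec or trial_schedule")
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a schedule JSON written by [write_schedule_json()]
#'
#' @param path File path.
#' @return A `stream_spec`-like or `trial_schedule`-like list (the `config`
#'   element of a stream is not serialized and is absent after a round trip).
#' @export
read_schedule_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(doc$type, "stream")) {
    structure(list(events = tibble::as_tibble(doc$events),
                   total_duration_ms = doc$total_duration_ms,
                   word_duration_ms = doc$word_duration_ms,
                   config = NULL),
              class = "stream_spec")
  } else if (identical(doc$type, "trials")) {
    tr <- tibble::as_tibble(doc$trials)
    for (col in c("trial_id", "unique_id", "block")) {
      if (col %in% names(tr)) tr[[col]] <- as.integer(tr[[col]])
    }
    if ("woman" %in% names(tr)) tr$woman <- as.character(tr$woman)
    structure(list(trials = tr,
                   timeline = tibble::as_tibble(doc$timeline),
                   end_ms = doc$end_ms,
                   attractor_ms = doc$attractor_ms,
                   word_duration_ms = doc$word_duration_ms),
              class = "trial_schedule")
  } else {
    stop("unrecognized schedule document")
  }
}

#' Export a schedule as tab-separated text
#'
#' Human-readable TSV of the stream events or the trial list.
#'
#' @param x A `stream_spec` or `trial_schedule`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule_tsv <- function(x, path) {
  tab <- if (inherits(x, "stream_spec")) x$events
         else if (inherits(x, "trial_schedule")) x$trials
         else stop("x must be a stream_spec or trial_schedule")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
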