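#' Build the counterbalanced test-trial schedule
#'
#' Produces the 16 preferential-looking test trials of one session: 8 unique
#' trials, each presented twice, 8 trials per tested (cued) word, with the
#' correct image on the left and right equally often for each word. The two
#' lateral images of a trial differ only in the tested dimension: for
#' action-word tests, the two head gestures performed by the same woman (the
#' woman is the third counterbalancing factor); for object-word tests, the two
#' women's pictures (the third factor is a nominal presentation block, since
#' the display is fully determined by word and side).
#'
#' The presentation order is a uniform shuffle constrained to at most
#' `max_run` consecutive trials of the same word and of the same correct side.
#'
#' Each trial follows a fixed timeline relative to the lateral-image onset at
#' t = 0: central attractor, first word presentation over two empty squares,
#' 1000 ms silence, second word presentation synchronized with image onset,
#' 1000 ms silence, third word presentation, trial end at `end_ms` (4700 ms).
#'
#' @param config A [design_config()].
#' @param seed Optional integer seed for the order shuffle.
#' @param attractor_ms Central attractor duration (excluded from analysis).
#' @param end_ms Trial end relative to image onset (default 4700).
#' @param max_run Maximum run length of same word / same side (default 2).
#' @return An object of class `trial_schedule`: list with `trials` (tibble:
#'   `trial_id`, `unique_id`, `word`, `correct_image`, `incorrect_image`,
#'   `correct_side`, `woman`/`block`), `timeline` (tibble of named intervals)
#'   and `end_ms`.
#' @export
build_test_trials <- function(config, seed = NULL,
                              attractor_ms = 1500, end_ms = 4700,
                              max_run = 2L) {
  stopifnot(inherits(config, "design_config"))
  if (!is.null(seed)) set.seed(seed)
  words <- config$words
  cued <- words[words$cued, , drop = FALSE]
  stopifnot(nrow(cued) == 2L)
  role <- cued$role[1L]

  grid <- expand.grid(word = cued$label, correct_side = c("left", "right"),
                      variant = c(1L, 2L), stringsAsFactors = FALSE)
  if (role == "action") {
    grid$woman <- c("A", "B")[grid$variant]
    gest <- config$pairing[grid$word]
    other <- ifelse(gest == "ud", "lr", "ud")
    grid$correct_image <- paste0("vid_", grid$woman, "_", gest)
    grid$incorrect_image <- paste0("vid_", grid$woman, "_", other)
    grid$block <- NA_integer_
  } else {
    womw <- config$pairing[grid$word]
    other <- ifelse(womw == "A", "B", "A")
    grid$correct_image <- paste0("pic_", womw)
    grid$incorrect_image <- paste0("pic_", other)
    grid$woman <- NA_character_
    grid$block <- grid$variant
  }
  grid$unique_id <- seq_len(nrow(grid))
  trials <- grid[rep(seq_len(nrow(grid)), 2L), , drop = FALSE]

  ord <- shuffle_constrained(trials$word, trials$correct_side, max_run)
  trials <- trials[ord, , drop = FALSE]
  trials$trial_id <- seq_len(nrow(trials))
  rownames(trials) <- NULL

  word_ms <- 3 * (config$consonant_ms + config$vowel_ms)
  timeline <- tibble::tibble(
    event = c("attractor", "word_1", "silence_1", "word_2_images_on",
              "silence_2", "word_3", "images_continue"),
    start_ms = c(-(attractor_ms + word_ms + 1000), -(word_ms + 1000), -1000,
                 0, word_ms, word_ms + 1000, 2 * word_ms + 1000),
    end_ms = c(-(word_ms + 1000), -1000, 0, word_ms, word_ms + 1000,
               2 * word_ms + 1000, end_ms)
  )
  structure(list(
    trials = tibble::as_tibble(trials[, c("trial_id", "unique_id", "word",
                                          "correct_image", "incorrect_image",
                                          "correct_side", "woman", "block")]),
    timeline = timeline,
    end_ms = end_ms,
    attractor_ms = attractor_ms,
    word_duration_ms = word_ms
  ), class = "trial_schedule")
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat("<trial_schedule>", nrow(x$trials), "trials, images on 0 -",
      x$end_ms, "ms\n")
  print(utils::head(x$trials, 4))
  invisible(x)
}

# Uniform shuffle rejected until no more than max_run consecutive equal words
# or equal sides.
shuffle_constrained <- function(word, side, max_run, max_tries = 5000L) {
  n <- length(word)
  runs_ok <- function(v) max(rle(v)$lengths) <= max_run
  for (i in seq_len(max_tries)) {
    ord <- sample.int(n)
    if (runs_ok(word[ord]) && runs_ok(side[ord])) return(ord)
  }
  stop("could not satisfy the run-length constraints")
}
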