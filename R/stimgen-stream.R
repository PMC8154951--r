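#' Experimental design configuration
#'
#' Bundles everything that defines one stream version: the four words, the
#' word-image pairing, phoneme durations and repetition counts. Image tokens
#' are the two women's face pictures (`pic_A`, `pic_B`) and the four
#' head-gesture videos (`vid_<woman>_<gesture>`, gestures `ud` = up-and-down,
#' `lr` = left-to-right). Each object-word is paired with one woman's picture;
#' each action-word with one gesture (performed by both women).
#'
#' @param words A word tibble from [make_words()].
#' @param pairing Named character vector mapping the two object-word labels to
#'   a woman (`"A"`/`"B"`) and the two action-word labels to a gesture
#'   (`"ud"`/`"lr"`). Default pairs them in row order.
#' @param n_repetitions Presentations of each word in the familiarization
#'   stream (default 24). Must be even; image-level transition balance is
#'   exact when divisible by 4.
#' @param consonant_ms,vowel_ms Phoneme durations in ms (defaults 170 and 286,
#'   giving 456 ms syllables and 1368 ms words).
#' @param version_id Counterbalancing version (1-3), see
#'   [counterbalance_versions()].
#' @return An object of class `design_config`.
#' @export
design_config <- function(words = make_words(seed = 1L),
                          pairing = NULL,
                          n_repetitions = 24L,
                          consonant_ms = 170,
                          vowel_ms = 286,
                          version_id = 1L) {
  stopifnot(is.data.frame(words), nrow(words) == 4L)
  if (sum(words$role == "object") != 2L || sum(words$role == "action") != 2L) {
    stop("need exactly 2 object-words and 2 action-words")
  }
  cued <- words[words$cued, , drop = FALSE]
  if (nrow(cued) != 2L) stop("exactly 2 words must be cued")
  if (length(unique(cued$role)) != 1L || length(unique(cued$harmony)) != 1L) {
    stop("the 2 cued words must share role and harmony type")
  }
  if (n_repetitions %% 2L != 0L) {
    stop("n_repetitions must be even: exact between-word transition balance is impossible otherwise")
  }
  if (consonant_ms < 0 || vowel_ms < 0 || consonant_ms + vowel_ms <= 0) {
    stop("phoneme durations must be non-negative with positive syllable length")
  }
  obj <- words$label[words$role == "object"]
  act <- words$label[words$role == "action"]
  if (is.null(pairing)) {
    pairing <- c(stats::setNames(c("A", "B"), obj), stats::setNames(c("ud", "lr"), act))
  }
  if (!setequal(names(pairing), words$label)) stop("pairing must name all 4 words")
  if (!setequal(unname(pairing[obj]), c("A", "B"))) {
    stop("object-words must be paired with the two women A and B")
  }
  if (!setequal(unname(pairing[act]), c("ud", "lr"))) {
    stop("action-words must be paired with the two gestures ud and lr")
  }
  structure(list(
    words = words,
    pairing = pairing,
    n_repetitions = as.integer(n_repetitions),
    consonant_ms = consonant_ms,
    vowel_ms = vowel_ms,
    version_id = as.integer(version_id)
  ), class = "design_config")
}

#' @export
print.design_config <- function(x, ...) {
  cat("<design_config> version", x$version_id, "-", x$n_repetitions,
      "repetitions/word,", 3 * (x$consonant_ms + x$vowel_ms), "ms/word\n")
  p <- x$pairing[x$words$label]
  cat(paste0("  ", x$words$label, " (", x$words$role,
             ifelse(x$words$cued, paste0(", cued ", x$words$harmony, " harmony"), ""),
             ") -> ", p, collapse = "\n"), "\n")
  invisible(x)
}

# Random closed Eulerian circuit on a small multigraph.
# counts: square matrix, counts[i, j] = number of parallel i -> j edges.
# Returns the visited node sequence of length sum(counts) (circular: the
# successor of the last element is the first).
random_eulerian_circuit <- function(counts) {
  n_edges <- sum(counts)
  stopifnot(n_edges > 0L, all(rowSums(counts) == colSums(counts)))
  k <- nrow(counts)
  walk_from <- function(v, cnt) {
    path <- integer(0)
    repeat {
      out <- cnt[v, ]
      if (sum(out) == 0L) break
      nxt <- sample.int(k, 1L, prob = out)
      cnt[nxt_idx(v, nxt)] <- cnt[v, nxt] - 1L
      path <- c(path, nxt)
      v <- nxt
    }
    list(path = path, cnt = cnt)
  }
  nxt_idx <- function(i, j) i + (j - 1L) * k
  start <- which(rowSums(counts) > 0L)[1L]
  w <- walk_from(start, counts)
  tour <- c(start, w$path)
  cnt <- w$cnt
  while (sum(cnt) > 0L) {
    pos <- which(rowSums(cnt)[tour] > 0L)[1L]
    if (is.na(pos)) stop("multigraph is not connected; no Eulerian circuit")
    w <- walk_from(tour[pos], cnt)
    tour <- append(tour, w$path, after = pos)
    cnt <- w$cnt
  }
  tour[-length(tour)]
}

#' Build the TP-balanced familiarization sequence
#'
#' Constructs the ordered (word, image) event sequence of one familiarization
#' stream. The stream alternates strictly between picture events (object-word
#' with the paired woman's face) and video events (action-word with the paired
#' gesture, performed by the woman of the immediately preceding picture), so
#' each object/action pair is "made by the same woman".
#'
#' Order is randomized as a closed Eulerian circuit over the word-transition
#' multigraph (cut at a random rotation), so every allowed word-to-word
#' transition occurs exactly `n_repetitions / 2` times on the circular
#' closure; the empirical between-word transitional probability is exactly
#' 0.5, the within-word syllable TP is 1, and (when `n_repetitions` is
#' divisible by 4) every image-to-image TP is exactly 0.5.
#'
#' @param config A [design_config()].
#' @param seed Optional integer seed.
#' @return A tibble with columns `event`, `word`, `role`, `image`, `kind`
#'   (`picture`/`video`), `woman`, `gesture` (`NA` for pictures).
#' @examples
#' seq <- build_familiarization_sequence(design_config(), seed = 3)
#' table(seq$word)
#' @export
build_familiarization_sequence <- function(config, seed = NULL) {
  stopifnot(inherits(config, "design_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_repetitions
  words <- config$words
  obj_of <- stats::setNames(
    words$label[words$role == "object"][match(c("A", "B"), config$pairing[words$label[words$role == "object"]])],
    c("A", "B")
  )
  act_of <- stats::setNames(
    words$label[words$role == "action"][match(c("ud", "lr"), config$pairing[words$label[words$role == "action"]])],
    c("ud", "lr")
  )

  # Stage 1: circular woman sequence over the 2n picture/video blocks, with
  # each of the four ordered woman transitions occurring exactly n/2 times.
  counts <- matrix(n %/% 2L, 2L, 2L, dimnames = list(c("A", "B"), c("A", "B")))
  circuit <- random_eulerian_circuit(counts)            # length 2n, values 1/2
  women <- c("A", "B")[circuit]
  succ <- c(women[-1L], women[1L])                      # circular successor

  # Stage 2: gesture allocation per woman, balanced within successor classes
  # so each video token is followed by each woman's picture (n/4)-ish times.
  gestures <- character(length(women))
  base <- n %/% 4L
  extra <- (n %/% 2L) - 2L * base                       # 0 or 1
  e <- if (extra) sample(0:1, 1L) else 0L
  for (w in c("A", "B")) {
    for_w <- which(women == w)
    # complementary rounding across women keeps the word-level balance exact
    # even when n/4 is not an integer
    u_first <- base + (if (w == "A") e else extra - e)
    idx_a <- for_w[succ[for_w] == "A"]
    idx_b <- for_w[succ[for_w] == "B"]
    gestures[idx_a] <- sample(rep(c("ud", "lr"), c(u_first, length(idx_a) - u_first)))
    u_b <- (n %/% 2L) - u_first
    gestures[idx_b] <- sample(rep(c("ud", "lr"), c(u_b, length(idx_b) - u_b)))
  }

  # Random rotation of the circular block sequence.
  rot <- sample.int(length(women), 1L)
  ord <- c(rot:length(women), if (rot > 1L) 1:(rot - 1L))
  women <- women[ord]
  gestures <- gestures[ord]

  n_blocks <- length(women)
  ev_word <- character(2L * n_blocks)
  ev_kind <- rep(c("picture", "video"), n_blocks)
  ev_woman <- character(2L * n_blocks)
  ev_gesture <- rep(NA_character_, 2L * n_blocks)
  ev_word[seq(1L, by = 2L, length.out = n_blocks)] <- obj_of[women]
  ev_word[seq(2L, by = 2L, length.out = n_blocks)] <- act_of[gestures]
  ev_woman[seq(1L, by = 2L, length.out = n_blocks)] <- women
  ev_woman[seq(2L, by = 2L, length.out = n_blocks)] <- women
  ev_gesture[seq(2L, by = 2L, length.out = n_blocks)] <- gestures

  tibble::tibble(
    event = seq_along(ev_word),
    word = ev_word,
    role = words$role[match(ev_word, words$label)],
    kind = ev_kind,
    woman = ev_woman,
    gesture = ev_gesture,
    image = ifelse(ev_kind == "picture",
                   paste0("pic_", ev_woman),
                   paste0("vid_", ev_woman, "_", ev_gesture))
  )
}

#' Lay the event sequence onto the stream timing grid
#'
#' Events are contiguous and non-overlapping; each lasts one word, i.e.
#' `3 * (consonant_ms + vowel_ms)` (1368 ms under the defaults), with syllable
#' onsets at 0, 1 and 2 syllable lengths within the event.
#'
#' @param sequence A sequence tibble from [build_familiarization_sequence()].
#' @param config The [design_config()] providing phoneme durations.
#' @return An object of class `stream_spec`: list with `events` (the sequence
#'   plus `onset_ms`, `offset_ms`, `syl1_ms`, `syl2_ms`, `syl3_ms`),
#'   `total_duration_ms`, `word_duration_ms` and `config`.
#' @export
schedule_stream <- function(sequence, config) {
  stopifnot(is.data.frame(sequence), nrow(sequence) >= 1L,
            inherits(config, "design_config"))
  syl_ms <- config$consonant_ms + config$vowel_ms
  word_ms <- 3 * syl_ms
  n <- nrow(sequence)
  onset <- (seq_len(n) - 1L) * word_ms
  events <- sequence
  events$onset_ms <- onset
  events$offset_ms <- onset + word_ms
  events$syl1_ms <- onset
  events$syl2_ms <- onset + syl_ms
  events$syl3_ms <- onset + 2 * syl_ms
  structure(list(
    events = events,
    total_duration_ms = n * word_ms,
    word_duration_ms = word_ms,
    config = config
  ), class = "stream_spec")
}

#' @export
print.stream_spec <- function(x, ...) {
  cat("<stream_spec>", nrow(x$events), "events,",
      x$total_duration_ms, "ms total\n")
  invisible(x)
}

tp_matrix <- function(seq_vec, circular) {
  pairs <- if (circular) {
    cbind(seq_vec, c(seq_vec[-1L], seq_vec[1L]))
  } else {
    if (length(seq_vec) < 2L) return(NULL)
    cbind(seq_vec[-length(seq_vec)], seq_vec[-1L])
  }
  tab <- table(factor(pairs[, 1L]), factor(pairs[, 2L]))
  m <- unclass(tab / rowSums(tab))
  m[rowSums(tab) == 0L, ] <- NA_real_
  m
}

#' Empirical transitional-probability tables of a stream
#'
#' Computes the empirical conditional probability of each successor at the
#' word, image and syllable level. By default transitions are counted on the
#' circular closure of the sequence (the stream is constructed as a closed
#' Eulerian circuit, so designed probabilities are exact); set
#' `circular = FALSE` for plain linear counting.
#'
#' @param x A sequence tibble, or a `stream_spec`.
#' @param words The word tibble (taken from the `stream_spec` config when
#'   available) used to expand events into syllables.
#' @param circular Count the last-to-first transition (default `TRUE`).
#' @return A list of class `transition_table` with row-stochastic matrices
#'   `word`, `image`, `syllable`, plus `within_word_syllable` and
#'   `between_word` vectors of the corresponding probabilities.
#' @export
compute_transition_table <- function(x, words = NULL, circular = TRUE) {
  if (inherits(x, "stream_spec")) {
    if (is.null(words)) words <- x$config$words
    x <- x$events
  }
  stopifnot(is.data.frame(x))
  if (nrow(x) == 0L) stop("empty sequence")
  word_tp <- tp_matrix(x$word, circular)
  image_tp <- if ("image" %in% names(x)) tp_matrix(x$image, circular) else NULL

  syl_tp <- NULL
  within <- NULL
  between <- NULL
  if (!is.null(words)) {
    idx <- match(x$word, words$label)
    syl_seq <- as.vector(rbind(words$s1[idx], words$s2[idx], words$s3[idx]))
    syl_tp <- tp_matrix(syl_seq, circular)
    w_first <- words$s1
    w_mid <- c(words$s1, words$s2)
    within <- syl_tp[cbind(match(c(words$s1, words$s2), rownames(syl_tp)),
                           match(c(words$s2, words$s3), colnames(syl_tp)))]
    names(within) <- paste(c(words$s1, words$s2), c(words$s2, words$s3), sep = ">")
    last <- match(words$s3, rownames(syl_tp))
    btw <- syl_tp[last, match(w_first, colnames(syl_tp)), drop = FALSE]
    between <- btw[!is.na(btw) & btw > 0]
  }
  structure(list(word = word_tp, image = image_tp, syllable = syl_tp,
                 within_word_syllable = within, between_word = between,
                 circular = circular),
            class = "transition_table")
}

#' @export
print.transition_table <- function(x, ...) {
  cat("<transition_table>", if (x$circular) "(circular)" else "(linear)", "\n")
  cat("word-level:\n")
  print(round(x$word, 3))
  invisible(x)
}

#' Generate the three counterbalanced stream versions
#'
#' Returns three configurations that differ only in the word-image pairing:
#' across the versions every object-word is paired with each woman and every
#' action-word with each gesture at least once.
#'
#' @param base_config A [design_config()]; its pairing defines version 1.
#' @return A list of 3 `design_config` objects with `version_id` 1-3.
#' @export
counterbalance_versions <- function(base_config) {
  stopifnot(inherits(base_config, "design_config"))
  words <- base_config$words
  obj <- words$label[words$role == "object"]
  act <- words$label[words$role == "action"]
  p1 <- base_config$pairing
  swap <- function(p, labels) { p[labels] <- p[rev(labels)]; p }
  p2 <- swap(swap(p1, obj), act)   # both pairings swapped
  p3 <- swap(p1, obj)              # object pairing swapped only
  lapply(seq_len(3L), function(v) {
    design_config(words = words,
                  pairing = list(p1, p2, p3)[[v]],
                  n_repetitions = base_config$n_repetitions,
                  consonant_ms = base_config$consonant_ms,
                  vowel_ms = base_config$vowel_ms,
                  version_id = v)
  })
}
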