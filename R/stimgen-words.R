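#' Default phoneme inventory
#'
#' A small Spanish-legal consonant-vowel inventory from which nonsense words
#' are assembled. Any inventory with at least 3 consonants and 3 vowels can be
#' substituted.
#'
#' @param consonants Character vector of single consonants.
#' @param vowels Character vector of single vowels.
#' @return A list with elements `consonants` and `vowels`.
#' @export
phoneme_inventory <- function(consonants = c("b", "d", "k", "l", "m", "n", "p", "s", "t"),
                              vowels = c("a", "e", "i", "o", "u")) {
  consonants <- unique(as.character(consonants))
  vowels <- unique(as.character(vowels))
  structure(list(consonants = consonants, vowels = vowels),
            class = "phoneme_inventory")
}

syllables_of <- function(word) strsplit(word, "-", fixed = TRUE)[[1]]

word_harmony <- function(syllables) {
  cons <- substr(syllables, 1L, 1L)
  vows <- substr(syllables, 2L, 2L)
  if (length(unique(vows)) == 1L) return("vowel")
  if (length(unique(cons)) == 1L) return("consonant")
  "none"
}

#' Construct harmony-cued nonsense words
#'
#' Builds the four trisyllabic (CVCVCV) nonsense words of one familiarization
#' stream: two object-words (paired with face pictures) and two action-words
#' (paired with head-gesture videos). The two words of `cued_role` carry the
#' requested phonological harmony (the same vowel, or the same consonant,
#' repeated in all three syllables); the other two words are harmony-free.
#' All 12 syllables are pairwise distinct, which forces the within-word
#' syllable transitional probability to 1 in the stream.
#'
#' Alternatively, an explicit `words` vector (four strings of hyphen-separated
#' CV syllables, ordered object, object, action, action) can be supplied, e.g.
#' to reproduce a published word list; it is validated against the same
#' invariants.
#'
#' @param harmony `"vowel"` or `"consonant"`: the cue carried by the tested words.
#' @param cued_role `"action"` or `"object"`: which word type carries the cue
#'   (and is tested).
#' @param inventory A [phoneme_inventory()].
#' @param seed Optional integer seed for reproducible word synthesis.
#' @param words Optional character vector of 4 words (syllables separated by
#'   `-`), bypassing synthesis.
#' @return A tibble with one row per word: `label`, `s1`, `s2`, `s3`,
#'   `harmony`, `role`, `cued`.
#' @examples
#' make_words("vowel", "action", seed = 7)
#' @export
make_words <- function(harmony = c("vowel", "consonant"),
                       cued_role = c("action", "object"),
                       inventory = phoneme_inventory(),
                       seed = NULL,
                       words = NULL) {
  harmony <- match.arg(harmony)
  cued_role <- match.arg(cued_role)
  roles <- c("object", "object", "action", "action")

  if (is.null(words)) {
    if (length(inventory$consonants) < 3L || length(inventory$vowels) < 3L) {
      stop("inventory exhausted: need at least 3 consonants and 3 vowels")
    }
    if (!is.null(seed)) {
      old <- globalenv()$.Random.seed
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
    }
    words <- synthesize_words(harmony, inventory)
    # synthesized order: cued pair first; map onto roles
    if (cued_role == "object") words <- words[c(1, 2, 3, 4)]
    else words <- words[c(3, 4, 1, 2)]
  } else {
    if (length(words) != 4L) stop("`words` must contain exactly 4 words")
  }

  syl <- lapply(words, syllables_of)
  if (any(lengths(syl) != 3L)) stop("each word must have exactly 3 CV syllables")
  if (any(nchar(unlist(syl)) != 2L)) stop("each syllable must be a single CV pair")
  if (anyDuplicated(unlist(syl))) {
    stop("inventory exhausted: the 12 syllables must be pairwise distinct")
  }
  harm <- vapply(syl, word_harmony, character(1))
  cued <- roles == cued_role
  if (any(harm[cued] != harmony)) {
    stop(sprintf("cued words must carry %s harmony", harmony))
  }
  if (any(harm[!cued] != "none")) {
    stop("uncued words must be harmony-free")
  }

  tibble::tibble(
    label = vapply(syl, paste, character(1), collapse = ""),
    s1 = vapply(syl, `[`, character(1), 1L),
    s2 = vapply(syl, `[`, character(1), 2L),
    s3 = vapply(syl, `[`, character(1), 3L),
    harmony = harm,
    role = roles,
    cued = cued
  )
}

# Rejection-sampled assembly of 2 harmony-cued + 2 harmony-free words with 12
# pairwise-distinct syllables. Returns cued pair first.
synthesize_words <- function(harmony, inventory, max_tries = 200L) {
  cons <- inventory$consonants
  vows <- inventory$vowels
  for (try in seq_len(max_tries)) {
    used <- character(0)
    ok <- TRUE
    cued <- character(2)
    if (harmony == "vowel") {
      hv <- sample(vows, 2L)
      for (i in 1:2) {
        cc <- sample(cons, 3L)
        s <- paste0(cc, hv[i])
        if (any(s %in% used)) { ok <- FALSE; break }
        used <- c(used, s)
        cued[i] <- paste(s, collapse = "-")
      }
    } else {
      hc <- sample(cons, 2L)
      for (i in 1:2) {
        vv <- sample(vows, 3L)
        s <- paste0(hc[i], vv)
        if (any(s %in% used)) { ok <- FALSE; break }
        used <- c(used, s)
        cued[i] <- paste(s, collapse = "-")
      }
    }
    if (!ok) next
    uncued <- character(2)
    for (i in 1:2) {
      found <- FALSE
      for (sub in seq_len(50L)) {
        cc <- sample(cons, 3L, replace = TRUE)
        vv <- sample(vows, 3L, replace = TRUE)
        s <- paste0(cc, vv)
        if (anyDuplicated(s) || any(s %in% used)) next
        if (length(unique(vv)) == 1L || length(unique(cc)) == 1L) next
        used <- c(used, s)
        uncued[i] <- paste(s, collapse = "-")
        found <- TRUE
        break
      }
      if (!found) { ok <- FALSE; break }
    }
    if (ok) return(c(cued, uncued))
  }
  stop("inventory exhausted: could not assemble 12 distinct syllables")
}
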