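test_that("synthesized words satisfy the harmony and syllable-distinctness invariants", {
  for (seed in c(1, 7, 23)) {
    for (h in c("vowel", "consonant")) {
      for (role in c("action", "object")) {
        w <- make_words(h, role, seed = seed)
        expect_equal(nrow(w), 4)
        syl <- c(w$s1, w$s2, w$s3)
        expect_equal(anyDuplicated(syl), 0L)
        expect_true(all(nchar(syl) == 2))
        cued <- w[w$cued, ]
        expect_equal(cued$role, rep(role, 2))
        expect_equal(cued$harmony, rep(h, 2))
        if (h == "vowel") {
          expect_true(all(substr(cued$s1, 2, 2) == substr(cued$s2, 2, 2) &
                            substr(cued$s2, 2, 2) == substr(cued$s3, 2, 2)))
        } else {
          expect_true(all(substr(cued$s1, 1, 1) == substr(cued$s2, 1, 1) &
                            substr(cued$s2, 1, 1) == substr(cued$s3, 1, 1)))
        }
        expect_equal(w$harmony[!w$cued], rep("none", 2))
      }
    }
  }
})

test_that("word synthesis fails cleanly on an exhausted inventory", {
  tiny <- phoneme_inventory(consonants = c("b", "d", "k"), vowels = c("a", "e"))
  expect_error(make_words("vowel", "action", inventory = tiny, seed = 1),
               "inventory exhausted")
  expect_error(make_words("vowel", "action",
                          words = c("ba-ba-ba", "be-de-ke", "bo-do-ko", "bu-du-ku")),
               "distinct")
})

test_that("user-supplied word lists are validated against the design invariants", {
  w <- make_words("vowel", "action",
                  words = c("ke-li-su", "le-no-pi", "pe-de-te", "ni-si-ki"))
  expect_equal(w$label, c("kelisu", "lenopi", "pedete", "nisiki"))
  expect_equal(w$harmony, c("none", "none", "vowel", "vowel"))
  expect_error(
    make_words("consonant", "action",
               words = c("ke-li-su", "le-no-pi", "pe-de-te", "ni-si-ki")),
    "consonant harmony")
})

test_that("the familiarization sequence has exact counts, balance and alternation", {
  cfg <- default_design()
  s <- build_familiarization_sequence(cfg, seed = 3)
  expect_equal(nrow(s), 96)
  expect_true(all(table(s$word) == 24))
  # strict picture/video alternation
  expect_true(all(s$kind == rep(c("picture", "video"), 48)))
  # same-woman pairing inside each picture -> video pair
  expect_true(all(s$woman[s$kind == "picture"] ==
                    s$woman[s$kind == "video"]))
  # circular word transitions: every allowed transition exactly 12 times
  tr <- circular_transitions(s$word)
  expect_true(all(tr[tr > 0] == 12))
  expect_equal(sum(tr > 0), 8)
})

test_that("transition tables show TP 1 within words and 0.5 between words and images", {
  cfg <- default_design()
  s <- build_familiarization_sequence(cfg, seed = 3)
  tt <- compute_transition_table(s, words = cfg$words)
  expect_true(all(tt$within_word_syllable == 1))
  expect_true(all(tt$between_word == 0.5))
  expect_true(all(tt$word[tt$word > 0] == 0.5))
  expect_true(all(tt$image[tt$image > 0] == 0.5))
})

test_that("TP balance holds across many seeds (property)", {
  cfg <- default_design()
  for (seed in 1:50) {
    s <- build_familiarization_sequence(cfg, seed = seed)
    expect_true(all(table(s$word) == 24))
    tr <- circular_transitions(s$word)
    expect_true(all(tr[tr > 0] == 12))
    tt <- compute_transition_table(s, words = cfg$words)
    expect_true(all(tt$image[tt$image > 0] == 0.5))
  }
})

test_that("different seeds give different orders; odd repetition counts error", {
  cfg <- default_design()
  s1 <- build_familiarization_sequence(cfg, seed = 1)
  s2 <- build_familiarization_sequence(cfg, seed = 2)
  expect_false(identical(s1$word, s2$word))
  expect_error(design_config(words = default_words(), n_repetitions = 23),
               "even")
})

test_that("a 2-repetition stream matches the brute-force enumeration of balanced circuits", {
  cfg <- design_config(words = default_words(), n_repetitions = 2)
  s <- build_familiarization_sequence(cfg, seed = 0)
  expect_equal(nrow(s), 8)
  tr <- circular_transitions(s$word)
  expect_true(all(tr[tr > 0] == 1))
  # brute force: enumerate all orderings of the 4 picture/video blocks and
  # keep those whose circular word transitions are all distinct
  blocks <- expand.grid(woman = c("A", "B"), gesture = c("ud", "lr"),
                        stringsAsFactors = FALSE)
  words <- cfg$words
  obj_of <- setNames(names(cfg$pairing)[match(c("A", "B"), cfg$pairing)], c("A", "B"))
  act_of <- setNames(names(cfg$pairing)[match(c("ud", "lr"), cfg$pairing)], c("ud", "lr"))
  perms <- list()
  for (p in asplit(gtools_permutations <- rbind(
    # all 24 permutations of 1:4, generated without extra packages
    do.call(rbind, lapply(1:4, function(a)
      do.call(rbind, lapply(setdiff(1:4, a), function(b)
        do.call(rbind, lapply(setdiff(1:4, c(a, b)), function(c_)
          c(a, b, c_, setdiff(1:4, c(a, b, c_)))))))))), 1)) {
    ws <- as.vector(rbind(obj_of[blocks$woman[p]], act_of[blocks$gesture[p]]))
    tr_p <- circular_transitions(ws)
    if (all(tr_p[tr_p > 0] == 1)) {
      perms[[length(perms) + 1]] <- ws
    }
  }
  expect_gt(length(perms), 0)
  # generator output, rotated to every phase, must match an enumerated circuit
  matches <- any(vapply(perms, function(ws) {
    any(vapply(seq_along(s$word), function(r) {
      identical(unname(ws), unname(s$word[c(r:8, if (r > 1) 1:(r - 1))]))
    }, logical(1)))
  }, logical(1)))
  expect_true(matches)
})

test_that("stream scheduling places events on the exact timing grid", {
  cfg <- default_design()
  s <- build_familiarization_sequence(cfg, seed = 3)
  st <- schedule_stream(s, cfg)
  expect_equal(st$total_duration_ms, 96 * 3 * (170 + 286)) # 131328
  expect_equal(st$word_duration_ms, 1368)
  expect_equal(st$events$onset_ms, (0:95) * 1368)
  expect_equal(st$events$syl2_ms - st$events$syl1_ms, rep(456, 96))
  expect_true(all(st$events$offset_ms - st$events$onset_ms == 1368))

  one <- schedule_stream(s[1, ], cfg)
  expect_equal(one$total_duration_ms, 1368)

  deg <- design_config(words = default_words(), consonant_ms = 0, vowel_ms = 100)
  st0 <- schedule_stream(build_familiarization_sequence(deg, seed = 1), deg)
  expect_equal(st0$word_duration_ms, 300)
})

test_that("transition tables handle degenerate and empty input", {
  expect_error(compute_transition_table(data.frame()), "empty")
  degen <- data.frame(word = c("w1", "w1"))
  tt <- compute_transition_table(degen, circular = FALSE)
  expect_equal(unname(tt$word["w1", "w1"]), 1)
})

test_that("the test schedule is balanced, repeated and timed as designed", {
  cfg <- default_design()
  sch <- build_test_trials(cfg, seed = 5)
  tr <- sch$trials
  expect_equal(nrow(tr), 16)
  expect_equal(length(unique(tr$unique_id)), 8)
  expect_true(all(table(tr$unique_id) == 2))
  expect_true(all(table(tr$word) == 8))
  expect_true(all(table(tr$word, tr$correct_side) == 4))
  # only cued (action) words are tested; lateral images differ only in gesture
  expect_true(all(tr$word %in% cfg$words$label[cfg$words$cued]))
  expect_true(all(substr(tr$correct_image, 5, 5) == substr(tr$incorrect_image, 5, 5)))
  # run-length constraint
  expect_lte(max(rle(tr$word)$lengths), 2)
  expect_lte(max(rle(tr$correct_side)$lengths), 2)
  # the two repeats of a unique trial are identical apart from position
  for (u in unique(tr$unique_id)) {
    reps <- tr[tr$unique_id == u, setdiff(names(tr), "trial_id")]
    expect_identical(reps[1, ], reps[2, ])
  }
  # timeline: image onset at 0, end at 4700, word repetitions 1 s apart
  tl <- sch$timeline
  expect_equal(tl$start_ms[tl$event == "word_2_images_on"], 0)
  expect_equal(max(tl$end_ms), 4700)
  expect_equal(tl$start_ms[tl$event == "silence_1"], -1000)
  expect_equal(tl$start_ms[tl$event == "word_3"] -
                 tl$end_ms[tl$event == "word_2_images_on"], 1000)
})

test_that("object-word test trials pit the two women's pictures", {
  cfg <- design_config(words = make_words("vowel", "object", seed = 2))
  sch <- build_test_trials(cfg, seed = 1)
  tr <- sch$trials
  expect_true(all(substr(tr$correct_image, 1, 3) == "pic"))
  expect_true(all(substr(tr$correct_image, 5, 5) != substr(tr$incorrect_image, 5, 5)))
  expect_true(all(table(tr$word, tr$correct_side) == 4))
})

test_that("counterbalancing produces 3 distinct pairings covering all word-image pairs", {
  cfg <- default_design()
  versions <- counterbalance_versions(cfg)
  expect_length(versions, 3)
  expect_equal(vapply(versions, function(v) v$version_id, integer(1)), 1:3)
  maps <- lapply(versions, function(v) v$pairing[sort(names(v$pairing))])
  expect_false(identical(maps[[1]], maps[[2]]))
  expect_false(identical(maps[[1]], maps[[3]]))
  expect_false(identical(maps[[2]], maps[[3]]))
  # coverage: every object-word sees both women, every action-word both gestures
  for (lab in names(maps[[1]])) {
    vals <- vapply(maps, `[[`, character(1), lab)
    expect_equal(length(unique(vals)), 2)
  }
  # deterministic in version_id
  again <- counterbalance_versions(cfg)
  expect_identical(maps[[2]], again[[2]]$pairing[sort(names(again[[2]]$pairing))])
})

test_that("schedules round-trip through the JSON export", {
  cfg <- default_design()
  st <- schedule_stream(build_familiarization_sequence(cfg, seed = 3), cfg)
  f <- tempfile(fileext = ".json")
  write_schedule_json(st, f)
  back <- read_schedule_json(f)
  expect_equal(back$total_duration_ms, st$total_duration_ms)
  expect_equal(as.data.frame(back$events), as.data.frame(st$events))

  sch <- build_test_trials(cfg, seed = 5)
  f2 <- tempfile(fileext = ".json")
  write_schedule_json(sch, f2)
  back2 <- read_schedule_json(f2)
  expect_equal(as.data.frame(back2$trials), as.data.frame(sch$trials))
  expect_equal(back2$end_ms, 4700)

  f3 <- tempfile(fileext = ".tsv")
  write_schedule_tsv(st, f3)
  expect_equal(nrow(utils::read.delim(f3)), 96)
})
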