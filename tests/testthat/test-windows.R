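## two contestants with fully controlled sentence scores:
## clip 1 dialogue scores (a->b, b->a), clip 2 dialogue score (a->b only of
## each direction as stated per test)
controlled_corpus <- function() {
  as_utterances(tibble::tibble(
    speaker = c("a", "b", "a", "b", "a", "b"),
    recipient = c("b", "a", "b", "a", "CAMERA", "CAMERA"),
    clip = c(1L, 1L, 2L, 2L, 1L, 1L),
    sentence_index = c(1L, 2L, 1L, 2L, 3L, 4L),
    ## mini-lexicon sentiment: 0.2 = happy/(sqrt(1))? use exact-score words
    text = c("happy", "sad", "very happy", "happy", "good", "bad")
  ))
}

test_that("gist windows are cumulative sentence-weighted means and recent windows are clip-local", {
  lex <- mini_lexicon()
  utt <- controlled_corpus()
  ## sentence scores: clip1 {+1, -1}, clip2 {1.8/sqrt(2), +1}
  g2 <- window_scores(utt, window_spec("gist", "specific", 2), "sentiment",
                      unit = c("a", "b"), lexicon = lex)
  expect_equal(g2$value, (1 - 1 + 1.8 / sqrt(2) + 1) / 4)
  expect_equal(g2$n_sentences, 4L)
  r2 <- window_scores(utt, window_spec("recent", "specific", 2), "sentiment",
                      unit = c("a", "b"), lexicon = lex)
  expect_equal(r2$value, (1.8 / sqrt(2) + 1) / 2)
  ## gist(1) == recent(1) for any feature
  for (feat in c("sentiment", "clout", "similarity")) {
    expect_equal(
      window_scores(utt, window_spec("gist", "specific", 1), feat,
                    unit = c("a", "b"), lexicon = lex)$value,
      window_scores(utt, window_spec("recent", "specific", 1), feat,
                    unit = c("a", "b"), lexicon = lex)$value)
  }
  expect_error(window_scores(utt, window_spec("gist", "specific", 9),
                             "sentiment", unit = c("a", "b"), lexicon = lex),
               "out of range")
})

test_that("gist scores satisfy the running-mean identity over clips", {
  world <- generate_world(world_config(observers = 2), seed = 33)
  utt <- generate_transcript(world)
  dy <- strsplit(world$affinity$dyad[1], "|", fixed = TRUE)[[1]]
  per_clip <- lapply(1:4, function(cl) {
    window_scores(utt, window_spec("recent", "specific", cl), "sentiment", unit = dy)
  })
  g4 <- window_scores(utt, window_spec("gist", "specific", 4), "sentiment", unit = dy)
  num <- sum(vapply(per_clip, function(s) {
    if (is.na(s$value)) 0 else s$value * s$n_sentences
  }, numeric(1)))
  den <- sum(vapply(per_clip, `[[`, 0L, "n_sentences"))
  expect_equal(g4$value * g4$n_sentences, num)
  expect_equal(g4$n_sentences, den)
})

test_that("dyad-level general scores average members and are absent when one is silent", {
  lex <- mini_lexicon()
  utt <- controlled_corpus()
  ## general sentiment at clip 1: a says {happy, good} -> 1; b says {sad, bad} -> -1
  gg <- dyad_general_score(utt, c("a", "b"), window_spec("gist", "general", 1),
                           "sentiment", lexicon = lex)
  expect_equal(gg$value, 0)            # mean of +1 and -1
  expect_equal(gg$level, "gist_general")

  ## identical pooled speech: general similarity is 1
  both_same <- as_utterances(tibble::tibble(
    speaker = c("a", "b"), recipient = "CAMERA", clip = 1L,
    sentence_index = 1:2, text = "river stone bridge"))
  expect_equal(dyad_general_score(both_same, c("a", "b"),
                                  window_spec("recent", "general", 1),
                                  "similarity")$value, 1)

  ## silent member: absent score
  only_a <- as_utterances(tibble::tibble(
    speaker = "a", recipient = "CAMERA", clip = 1L, sentence_index = 1L,
    text = "river stone"))
  gs <- dyad_general_score(only_a, c("a", "b"),
                           window_spec("recent", "general", 1), "sentiment",
                           lexicon = lex)
  expect_true(is.na(gs$value))
  expect_equal(gs$n_sentences, 0L)
})

test_that("adding an all-neutral clip pulls a positive gist sentiment toward zero", {
  lex <- mini_lexicon()
  utt <- as_utterances(tibble::tibble(
    speaker = c("a", "b", "a", "b"),
    recipient = c("b", "a", "b", "a"),
    clip = c(1L, 1L, 2L, 2L),
    sentence_index = c(1L, 2L, 1L, 2L),
    text = c("happy", "good", "the camp", "the fire")
  ))
  g1 <- window_scores(utt, window_spec("gist", "specific", 1), "sentiment",
                      unit = c("a", "b"), lexicon = lex)$value
  g2 <- window_scores(utt, window_spec("gist", "specific", 2), "sentiment",
                      unit = c("a", "b"), lexicon = lex)$value
  expect_gt(g1, 0)
  expect_lt(g2, g1)
  expect_gt(g2, 0)
})

test_that("season-mode episode ranges exclude later episodes", {
  cfg <- world_config(observers = 2, clips = 8)
  world <- generate_world(cfg, seed = 12)
  utt <- generate_transcript(world)
  spec <- window_spec("gist", "specific", 8, season_mode = TRUE, episode_range = 1:5)
  win <- convrel:::select_window(utt, spec)
  expect_true(all(win$clip <= 5))
  expect_error(window_spec("gist", "specific", 3, episode_range = 1:5),
               "season mode")

  early <- early_similarity(utt, world$roster, mode = "specific", episodes = 1:5)
  expect_equal(nrow(early), choose(length(world$roster$contestants), 2))
  expect_true(all(early$n_episodes <= 5))
})

test_that("the model table is the complete-case factorial of responses and features", {
  ## 2 participants x 3 dyads x 2 conditions x 2 clips, all features present
  dyads <- c("a|b", "a|c", "b|c")
  pct <- expand.grid(participant = c("p1", "p2"), condition = c("friend", "rival"),
                     clip = 1:2, dyad = dyads, stringsAsFactors = FALSE)
  pct$chosen <- 3L; pct$presented <- 10L; pct$pct <- 0.3
  feats <- expand.grid(unit = dyads, clip = 1:2, stringsAsFactors = FALSE)
  feats$level <- "gist_specific"; feats$feature <- "similarity"
  feats$value <- runif(nrow(feats)); feats$n_sentences <- 2L
  tab <- assemble_model_table(tibble::as_tibble(pct), tibble::as_tibble(feats),
                              "similarity", "gist_specific")
  expect_equal(nrow(tab), 24)
  expect_named(tab, c("participant", "dyad", "condition", "clip",
                      "chosen", "presented", "x"))

  ## a dyad lacking dialogue at one clip: its rows are dropped with a message
  feats$value[feats$unit == "a|b" & feats$clip == 2] <- NA
  expect_message(
    tab2 <- assemble_model_table(tibble::as_tibble(pct), tibble::as_tibble(feats),
                                 "similarity", "gist_specific"),
    "dropped 4")
  expect_equal(nrow(tab2), 20)

  ## empty feature table: empty result with a warning
  expect_warning(
    empty <- assemble_model_table(tibble::as_tibble(pct),
                                  tibble::as_tibble(feats)[0, ],
                                  "similarity", "gist_specific"),
    "empty")
  expect_equal(nrow(empty), 0)
})
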