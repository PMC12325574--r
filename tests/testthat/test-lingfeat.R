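test_that("sentence sentiment applies the stated shifter rules", {
  lex <- mini_lexicon()
  p <- sentiment_params()
  expect_equal(sentence_sentiment("the tribe met today", lex, p), 0)
  expect_equal(sentence_sentiment("happy", lex, p), 1)
  expect_equal(sentence_sentiment("not happy", lex, p), -1 / sqrt(2))
  expect_equal(sentence_sentiment("very happy", lex, p), 1.8 / sqrt(2))
  ## odd negator count turns the amplifier into a de-amplifier
  expect_equal(sentence_sentiment("not very happy", lex, p),
               -1 * (1 / 1.8) / sqrt(3))
  ## double negation cancels
  expect_equal(sentence_sentiment("not never happy", lex, p), 1 / sqrt(3))
  ## adversative before amplifies, after shrinks
  expect_equal(sentence_sentiment("but happy", lex, p), 1.85 / sqrt(2))
  expect_equal(sentence_sentiment("happy but", lex, p), (1 / 1.85) / sqrt(2))
  ## un-normalized mode returns the raw token-score sum
  p2 <- sentiment_params(normalize_by_sqrt_length = FALSE)
  expect_equal(sentence_sentiment("very happy", lex, p2), 1.8)
  expect_error(sentence_sentiment("   ", lex, p), "empty")
})

test_that("negation flips the sign and amplification is monotone", {
  lex <- mini_lexicon()
  p <- sentiment_params()
  withr::with_seed(14, {
    for (i in 1:25) {
      word <- sample(names(lex$polarity), 1)
      filler <- paste(sample(c("the", "camp", "fire", "today"),
                             sample(0:2, 1), replace = TRUE), collapse = " ")
      plain <- trimws(paste(filler, word))
      s0 <- sentence_sentiment(plain, lex, p)
      expect_equal(sign(sentence_sentiment(paste("not", plain), lex, p)), -sign(s0))
      if (lex$polarity[[word]] > 0) {
        amped <- sentence_sentiment(paste(filler, "very", word), lex, p)
        expect_gt(amped * sqrt(length(tokenize(paste(filler, "very", word)))),
                  s0 * sqrt(length(tokenize(plain))))
      }
    }
  })
})

test_that("sentiment matches the independent brute-force oracle on random sentences", {
  lex <- mini_lexicon()
  p <- sentiment_params()
  withr::with_seed(31, {
    for (i in 1:200) {
      s <- random_lexicon_sentence(lex)
      expect_equal(sentence_sentiment(s, lex, p), oracle_sentiment(s, lex, p),
                   info = s)
    }
  })
})

test_that("the clout proxy is bounded, centered, and monotone in its categories", {
  expect_gt(sentence_clout("we trust you"), 50)
  expect_lt(sentence_clout("i am never alone"), 50)
  withr::with_seed(6, {
    texts <- replicate(30, paste(sample(c("we", "you", "i", "not", "camp",
                                          "the", "fire", "team", "help"),
                                        sample(2:10, 1), replace = TRUE),
                                 collapse = " "))
  })
  scores <- sentence_clout(texts)
  expect_true(all(scores >= 1 & scores <= 99))
  ## appending a we-word never lowers the score; an i-word never raises it
  expect_true(all(sentence_clout(paste(texts, "we")) >= scores - 1e-9))
  expect_true(all(sentence_clout(paste(texts, "i")) <= scores + 1e-9))
  expect_error(sentence_clout(""), "empty")
})

test_that("cosine similarity matches hand computations and is scale-invariant", {
  expect_equal(cosine_similarity(c(1, 2), c(1, 2)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2), c(2, 1)), 0.8)
  expect_equal(cosine_similarity(c(1, 2), 3 * c(2, 1)), 0.8)
  expect_equal(cosine_similarity(c(1, 2), c(2, 1)),
               cosine_similarity(c(2, 1), c(1, 2)))
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero-norm")
  expect_error(cosine_similarity(1:2, 1:3), "equal length")
})

test_that("the hashed embedder is deterministic with the contracted dimension", {
  be <- hash_embedder()
  expect_equal(be$dim, 512L)
  v1 <- be$embed("the tribe has spoken")
  expect_identical(v1, be$embed("the tribe has spoken"))
  expect_length(v1, 512L)
  expect_true(any(v1 != 0))
  expect_true(all(is.finite(v1)))
  ## token order does not matter, token multiset does
  expect_identical(be$embed("fire water"), be$embed("water fire"))
  expect_false(identical(be$embed("fire water"), be$embed("fire fire water")))
})

test_that("dyad similarity pools by direction and is absent for one-sided talk", {
  utt <- as_utterances(tibble::tibble(
    speaker = c("a", "a", "b"),
    recipient = c("b", "b", "a"),
    clip = 1L, sentence_index = 1:3,
    text = c("river stone bridge", "lantern meadow", "river stone lantern")
  ))
  be <- hash_embedder()
  ## oracle: embed the pooled chunks by hand
  expected <- cosine_similarity(be$embed("river stone bridge lantern meadow"),
                                be$embed("river stone lantern"))
  expect_equal(dyad_similarity(utt, c("a", "b"), be), expected)

  ## identical two-sided text: similarity 1 under either mode
  same <- as_utterances(tibble::tibble(
    speaker = c("a", "b"), recipient = c("b", "a"), clip = 1L,
    sentence_index = 1:2, text = "river stone bridge"))
  expect_equal(dyad_similarity(same, c("a", "b"), be), 1)
  expect_equal(dyad_similarity(same, c("a", "b"), be, mode = "crosspair_mean"), 1)

  ## one-directional dialogue: absent score, not an error
  oneway <- as_utterances(tibble::tibble(
    speaker = "a", recipient = "b", clip = 1L, sentence_index = 1L,
    text = "river stone"))
  expect_true(is.na(dyad_similarity(oneway, c("a", "b"), be)))

  ## crosspair mean averages all sentence pairs
  cp <- dyad_similarity(utt, c("a", "b"), be, mode = "crosspair_mean")
  hand <- mean(c(
    cosine_similarity(be$embed("river stone bridge"), be$embed("river stone lantern")),
    cosine_similarity(be$embed("lantern meadow"), be$embed("river stone lantern"))))
  expect_equal(cp, hand)
})

test_that("lexicon constructors enforce disjoint lowercase classes", {
  expect_error(sentiment_lexicon(c(happy = 1), negators = "happy",
                                 amplifiers = character(),
                                 deamplifiers = character(),
                                 adversatives = character()),
               "disjoint")
  expect_error(sentiment_lexicon(c(Happy = 1), negators = character(),
                                 amplifiers = character(),
                                 deamplifiers = character(),
                                 adversatives = character()),
               "lowercase")
  lex <- default_lexicon()
  expect_gt(length(lex$polarity), 80)
  expect_true(all(lex$polarity %in% c(-1, 1)))
})
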