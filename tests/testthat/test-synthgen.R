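test_that("worlds are reproducible and validated", {
  cfg <- world_config(observers = 3)
  w1 <- generate_world(cfg, seed = 5)
  w2 <- generate_world(cfg, seed = 5)
  expect_identical(w1$affinity, w2$affinity)
  expect_identical(w1$strengths, w2$strengths)
  expect_equal(nrow(w1$affinity), choose(7, 2))
  expect_true(all(abs(w1$affinity$affinity) <= 1))
  ## the mirrored rival surface
  expect_equal(w1$affinity$rival_affinity, -w1$affinity$affinity)

  ## degenerate mixture: every dyad lands in the friend cluster
  wf <- generate_world(world_config(mixture_weights = c(1, 0, 0)), seed = 2)
  expect_true(all(wf$affinity$cluster == "friend"))
  expect_true(all(wf$affinity$affinity > 0))

  expect_error(world_config(n_contestants = 2), "n_contestants")
  expect_error(world_config(tau = 0), "tau")
  expect_error(world_config(missing_fraction = 1), "missing_fraction")
  ## one message lists every offending field
  expect_error(world_config(tau = -1, clips = 0), "tau.*clips|clips.*tau")
})

test_that("generated affinities follow the stated mixture distribution", {
  ## distributional oracle: simulate the mixture directly and compare by a
  ## two-sample Kolmogorov-Smirnov test over ~1,000 dyads
  cfg <- world_config(n_contestants = 18)   # 153 dyads per world
  aff <- unlist(lapply(1:7, function(i) {
    generate_world(cfg, seed = 100 + i)$affinity$affinity
  }))
  expect_gt(length(aff), 1000)
  oracle <- withr::with_seed(1234, {
    cl <- sample(1:3, length(aff), replace = TRUE)
    pmin(1, pmax(-1, stats::rnorm(length(aff),
                                  c(0.7, 0, -0.7)[cl],
                                  c(0.1, 0.15, 0.1)[cl])))
  })
  ks <- suppressWarnings(stats::ks.test(aff, oracle))
  expect_gt(ks$p.value, 0.01)
})

test_that("transcripts track affinity monotonically at zero noise", {
  cfg <- world_config(observers = 2, sigma = 0, exchanges_per_clip = 12,
                      sentiment_slope = 3, topic_slope = 3, clout_slope = 3,
                      mixture_weights = c(1, 0, 1), cluster_sd = 0.01)
  world <- generate_world(cfg, seed = 17)
  utt <- generate_transcript(world)
  hi <- strsplit(world$affinity$dyad[which.max(world$affinity$affinity)], "|",
                 fixed = TRUE)[[1]]
  lo <- strsplit(world$affinity$dyad[which.min(world$affinity$affinity)], "|",
                 fixed = TRUE)[[1]]
  for (cl in 1:3) {
    s_hi <- window_scores(utt, window_spec("gist", "specific", cl), "sentiment", unit = hi)
    s_lo <- window_scores(utt, window_spec("gist", "specific", cl), "sentiment", unit = lo)
    expect_gt(s_hi$value, s_lo$value)
  }
  ## embedding similarity orders the same way
  sim_hi <- dyad_similarity(utt, hi)
  sim_lo <- dyad_similarity(utt, lo)
  expect_gt(sim_hi, sim_lo)
  ## and the clout proxy does too
  c_hi <- window_scores(utt, window_spec("gist", "specific", 3), "clout", unit = hi)
  c_lo <- window_scores(utt, window_spec("gist", "specific", 3), "clout", unit = lo)
  expect_gt(c_hi$value, c_lo$value)
})

test_that("silenced dyads produce no specific-level scores", {
  cfg <- world_config(observers = 2, exchanges_per_clip = 0)
  world <- generate_world(cfg, seed = 3)
  utt <- generate_transcript(world)        # confessionals only
  expect_true(all(utt$addressee_type == "confessional"))
  s <- window_scores(utt, window_spec("gist", "specific", 2), "sentiment",
                     unit = strsplit(world$affinity$dyad[1], "|", fixed = TRUE)[[1]])
  expect_true(is.na(s$value))
  ## general scores still exist
  g <- window_scores(utt, window_spec("gist", "general", 2), "sentiment",
                     unit = world$roster$contestants[1])
  expect_false(is.na(g$value))
})

test_that("responses miss at the configured rate and saturate at low temperature", {
  cfg <- world_config(observers = 4, missing_fraction = 0.1)
  trials <- generate_responses(generate_world(cfg, seed = 19))
  n <- nrow(trials)
  miss <- sum(is.na(trials$selected))
  expect_gt(miss, stats::qbinom(0.005, n, 0.1))
  expect_lt(miss, stats::qbinom(0.995, n, 0.1))

  ## near-deterministic observers agree almost perfectly on friend judgments
  cfg0 <- world_config(observers = 10, tau = 0.01, missing_fraction = 0)
  world0 <- generate_world(cfg0, seed = 29)
  pct <- percent_chosen(generate_responses(world0))
  m <- response_matrix(pct, "friend", world0$roster)
  obs <- median_similarity(pairwise_similarity(m))$median
  expect_gt(obs, 0.99)
})

test_that("indifferent worlds give near-chance percent chosen", {
  cfg <- world_config(observers = 12, mixture_weights = c(0, 1, 0),
                      neutral_sd = 0, tau = 1)
  world <- generate_world(cfg, seed = 41)
  expect_true(all(world$affinity$affinity == 0))
  pct <- percent_chosen(generate_responses(world))
  fr <- pct[pct$condition == "friend", ]
  expect_equal(mean(fr$pct), 0.5, tolerance = 0.03)
})

test_that("a complete simulated study passes all input validation", {
  sim <- simulate_study(world_config(observers = 3), seed = 77)
  expect_s3_class(as_utterances(sim$utterances), "tbl_df")
  expect_s3_class(as_trials(sim$trials), "tbl_df")
  expect_identical(simulate_study(world_config(observers = 3), seed = 77)$trials,
                   sim$trials)
  ## block structure: each condition exactly twice per observer
  blocks <- dplyr::distinct(sim$trials, participant, block, condition)
  per <- dplyr::count(blocks, participant, condition)
  expect_true(all(per$n == 2))
})
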