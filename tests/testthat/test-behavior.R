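test_that("the full design enumerates every target with every choice pair", {
  ros7 <- roster(contestant_names_for_test(7))
  d7 <- enumerate_design(ros7, "friend")
  expect_equal(nrow(d7), 105)

  expect_equal(nrow(enumerate_design(roster(c("a", "b", "c")), "rival")), 3)
  expect_equal(nrow(enumerate_design(roster(letters[1:4]), "win")), 12)
  expect_error(enumerate_design(roster(c("a", "b")), "friend"), "at least 3")

  ## the trial set is seed-invariant; only the order changes
  a <- enumerate_design(ros7, "win", seed = 1)
  b <- enumerate_design(ros7, "win", seed = 2)
  key <- function(d) sort(paste(d$target, d$choice_a, d$choice_b))
  expect_identical(key(a), key(b))
  expect_false(identical(a$target, b$target))
})

test_that("symmetric percent chosen averages the two directional proportions", {
  pct <- percent_chosen(worked_example_trials())
  row <- pct[pct$dyad == "ana|ben", ]
  expect_equal(row$pct, 0.7)            # (80% + 60%) / 2
  expect_equal(row$chosen, 7L)
  expect_equal(row$presented, 10L)

  ## pooled-count mode divides summed counts instead
  pooled <- percent_chosen(worked_example_trials(), method = "pooled")
  expect_equal(pooled$pct[pooled$dyad == "ana|ben"], 0.7)  # equal denominators here
})

test_that("directional win proportions are chosen over presented", {
  tr <- as_trials(tibble::tibble(
    participant = "p1", block = 1L, condition = "win", clip = 1L,
    target = "ana", choice_a = "ben", choice_b = "cam",
    selected = c("ben", "ben", "ben", "cam", "cam")
  ))
  pct <- percent_chosen(tr)
  expect_equal(pct$pct[pct$dyad == "ben>ana"], 0.6)   # 3 of 5
  expect_equal(pct$pct[pct$dyad == "cam>ana"], 0.4)
})

test_that("missed responses are dropped from numerator and denominator", {
  tr <- worked_example_trials()
  tr$selected[1] <- NA_character_
  pct <- percent_chosen(tr)
  row <- pct[pct$dyad == "ana|ben", ]
  ## A now chosen on 3 of 4 answered B-target trials
  expect_equal(row$pct, (3 / 4 + 3 / 5) / 2)
  expect_equal(row$presented, 9L)
})

test_that("symmetric proportions are invariant to relabeling the dyad members", {
  sim <- simulate_study(world_config(observers = 3), seed = 21)
  pct <- percent_chosen(sim$trials)
  sym <- pct[pct$condition %in% c("friend", "rival"), ]
  ## keys are unordered: each dyad appears once per participant x condition
  expect_false(any(grepl(">", sym$dyad, fixed = TRUE)))
  counts <- dplyr::count(sym, participant, condition, dyad)
  expect_true(all(counts$n == 1))
  ## within any fully answered trial set, chosen counts sum to answered trials
  win <- pct[pct$condition == "win" & pct$participant == "obs01", ]
  answered <- sum(!is.na(sim$trials$selected[
    sim$trials$condition == "win" & sim$trials$participant == "obs01"]))
  expect_equal(sum(win$chosen), answered)
})

test_that("response vectors follow the canonical key order with NA for unseen keys", {
  ros <- roster(contestant_names_for_test(7))
  sim <- simulate_study(world_config(observers = 2), seed = 5)
  pct <- percent_chosen(sim$trials)
  vf <- response_vector(pct, "obs01", "friend", sim$world$roster)
  expect_length(vf, choose(7, 2))
  vw <- response_vector(pct, "obs01", "win", sim$world$roster)
  expect_length(vw, 7 * 6)
  expect_error(response_vector(pct, "nobody", "friend", sim$world$roster), "no rows")

  ## identical trials and selections give identical vectors
  tr2 <- sim$trials[sim$trials$participant == "obs01", ]
  tr2$participant <- "obs99"
  pct2 <- percent_chosen(dplyr::bind_rows(sim$trials, tr2))
  expect_identical(response_vector(pct2, "obs99", "friend", sim$world$roster), vf)
})

test_that("trial validation catches malformed rows", {
  tr <- worked_example_trials()
  bad <- tr; bad$choice_b[1] <- "ben"
  expect_error(as_trials(bad), "pairwise distinct")
  bad <- tr; bad$selected[2] <- "someone"
  expect_error(as_trials(bad), "one of the two choices")
  bad <- tr; bad$rt <- 6
  expect_error(as_trials(bad), "rt")
})
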