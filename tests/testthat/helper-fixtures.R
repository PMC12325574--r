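## shared fixtures, built in code

mini_lexicon <- function() {
  sentiment_lexicon(
    polarity = c(happy = 1, good = 1, great = 1, sad = -1, bad = -1, awful = -1),
    negators = c("not", "never"),
    amplifiers = c("very", "really"),
    deamplifiers = c("slightly", "somewhat"),
    adversatives = c("but", "however")
  )
}

## a 3-contestant corpus exercising every addressee type
tiny_corpus <- function() {
  as_utterances(tibble::tibble(
    speaker = c("ana", "ben", "ana", "cam", "ben"),
    recipient = c("ben", "ana", "GROUP", "CAMERA", "HOST"),
    clip = c(1L, 1L, 1L, 2L, 2L),
    sentence_index = 1:5,
    text = c("we trust you", "i like the plan", "good morning everyone",
             "i feel alone out here", "the water was cold")
  ))
}

tiny_roster <- function() roster(c("ana", "ben", "cam"))

## trials reproducing the worked percent-chosen example: contestant A chosen on
## 80% of B-target trials, B on 60% of A-target trials
worked_example_trials <- function(condition = "friend") {
  as_trials(tibble::tibble(
    participant = "p1", block = 1L, condition = condition, clip = 1L,
    target = rep(c("ben", "ana"), each = 5),
    choice_a = rep(c("ana", "ben"), each = 5),
    choice_b = "cam",
    selected = c("ana", "ana", "ana", "ana", "cam",
                 "ben", "ben", "ben", "cam", "cam")
  ))
}

## simulate straight from the relational model's own data-generating process
sim_from_relmodel <- function(seed, n_participants = 30, n_dyads = 21,
                              b = c(0.5, -0.3, 1.3, -2.5),
                              sd_d = 0.5, sd_p = 0.3, phi = 20,
                              presented = 10) {
  withr::with_seed(seed, {
    dyads <- paste0("d", seq_len(n_dyads))
    x <- stats::rnorm(n_dyads)
    g <- expand.grid(participant = sprintf("p%02d", seq_len(n_participants)),
                     dyad = dyads, condition = c("friend", "rival"),
                     stringsAsFactors = FALSE)
    g$x <- x[match(g$dyad, dyads)]
    rv <- as.numeric(g$condition == "rival")
    dcell <- as.integer(factor(paste(g$dyad, g$condition)))
    pcell <- as.integer(factor(paste(g$participant, g$condition)))
    ud <- stats::rnorm(max(dcell), 0, sd_d)
    up <- stats::rnorm(max(pcell), 0, sd_p)
    eta <- b[1] + b[2] * rv + b[3] * g$x + b[4] * rv * g$x +
      ud[dcell] + up[pcell]
    g$presented <- presented
    g$chosen <- rbetabinom(nrow(g), presented, stats::plogis(eta), phi)
    tibble::as_tibble(g)
  })
}

contestant_names_for_test <- function(n) convrel:::contestant_names(n)

fast_spec <- function(...) {
  model_spec(chains = 2, iter = 1400, warmup = 500,
             on_nonconvergence = "warn", ...)
}
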