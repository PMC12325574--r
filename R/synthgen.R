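#' Configuration of a synthetic observation study
#'
#' Defaults mirror the study design the package emulates: 7 contestants
#' observed over 6 clips by 50 observers who complete the full
#' forced-choice design twice per condition (friend, rival, win). Latent
#' signed dyadic affinities are drawn from a three-cluster mixture (friends
#' near +0.7, rivals near -0.7, neutral near 0); per-contestant win
#' strengths are uniform. Transcript generation turns affinity into
#' linguistic signal through logistic rates: the positive-polarity word
#' rate, the shared-topic rate (driving embedding similarity), and the
#' we/you-versus-i pronoun rate (driving the clout proxy) all increase with
#' affinity, each perturbed by Gaussian noise with sd `sigma`. Observers
#' choose with a softmax of affinity (or win-strength) differences at
#' temperature `tau`.
#'
#' @param n_contestants,clips,observers Study dimensions.
#' @param tau Observer decision temperature (> 0); smaller is more
#'   deterministic.
#' @param sigma Linguistic noise sd on the logistic rates.
#' @param mixture_weights Length-3 non-negative weights (friend, neutral,
#'   rival clusters), normalized internally.
#' @param cluster_mean Friend-cluster center (rival cluster mirrors it).
#' @param cluster_sd,neutral_sd Cluster spreads.
#' @param exchanges_per_clip Poisson mean of exchange rounds per dyad and
#'   clip (each round is one sentence in each direction); 0 silences all
#'   dyads.
#' @param confessionals_per_clip Confessional (CAMERA) sentences per
#'   contestant and clip, feeding the general levels.
#' @param sentiment_slope,topic_slope,clout_slope Logistic effect sizes of
#'   affinity on the three linguistic rates.
#' @param polar_rate Probability a dialogue sentence carries a polarized
#'   word at all.
#' @param missing_fraction Probability an observer misses a trial.
#' @param decouple_conditions If `TRUE`, rival judgments are driven by an
#'   independent affinity surface instead of the mirrored friend surface
#'   (robustness option).
#' @return A list of class `convrel_world_config`.
#' @export
world_config <- function(n_contestants = 7L, clips = 6L, observers = 50L,
                         tau = 0.35, sigma = 0.6,
                         mixture_weights = c(friend = 1, neutral = 1, rival = 1) / 3,
                         cluster_mean = 0.7, cluster_sd = 0.1, neutral_sd = 0.15,
                         exchanges_per_clip = 4, confessionals_per_clip = 2L,
                         sentiment_slope = 1.5, topic_slope = 2,
                         clout_slope = 1.5, polar_rate = 0.7,
                         missing_fraction = 0.02,
                         decouple_conditions = FALSE) {
  cfg <- list(n_contestants = as.integer(n_contestants), clips = as.integer(clips),
              observers = as.integer(observers), tau = tau, sigma = sigma,
              mixture_weights = mixture_weights / sum(mixture_weights),
              cluster_mean = cluster_mean, cluster_sd = cluster_sd,
              neutral_sd = neutral_sd,
              exchanges_per_clip = exchanges_per_clip,
              confessionals_per_clip = as.integer(confessionals_per_clip),
              sentiment_slope = sentiment_slope, topic_slope = topic_slope,
              clout_slope = clout_slope, polar_rate = polar_rate,
              missing_fraction = missing_fraction,
              decouple_conditions = isTRUE(decouple_conditions))
  bad <- character()
  if (cfg$n_contestants < 3) bad <- c(bad, "n_contestants (need >= 3)")
  if (cfg$clips < 1) bad <- c(bad, "clips (need >= 1)")
  if (cfg$observers < 1) bad <- c(bad, "observers (need >= 1)")
  if (cfg$tau <= 0) bad <- c(bad, "tau (need > 0)")
  if (cfg$sigma < 0) bad <- c(bad, "sigma (need >= 0)")
  if (length(cfg$mixture_weights) != 3 || any(cfg$mixture_weights < 0)) {
    bad <- c(bad, "mixture_weights (need 3 non-negative weights)")
  }
  if (cfg$exchanges_per_clip < 0) bad <- c(bad, "exchanges_per_clip (need >= 0)")
  if (cfg$missing_fraction < 0 || cfg$missing_fraction >= 1) {
    bad <- c(bad, "missing_fraction (need in [0, 1))")
  }
  if (length(bad)) {
    stop("invalid world config: ", paste(bad, collapse = "; "), call. = FALSE)
  }
  structure(cfg, class = "convrel_world_config")
}

contestant_names <- function(n) {
  base <- c("ana", "ben", "cam", "dee", "eli", "fay", "gus", "hal", "ivy",
            "jon", "kat", "leo", "mia", "ned", "ora", "pia", "quin", "rex")
  if (n <= length(base)) base[seq_len(n)] else paste0("c", seq_len(n))
}

#' Draw a synthetic world of latent relationships
#'
#' @param config A [world_config()].
#' @param seed Integer seed; identical config and seed give identical
#'   worlds.
#' @return An object of class `convrel_world`: the roster, a dyad-level
#'   affinity table (with cluster labels), win strengths, the config, and
#'   the seed.
#' @export
generate_world <- function(config = world_config(), seed) {
  stopifnot(inherits(config, "convrel_world_config"))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  ros <- roster(contestant_names(config$n_contestants))
  dyads <- canonical_dyads(ros)
  withr::with_seed(seed, {
    cluster <- sample(c("friend", "neutral", "rival"), length(dyads),
                      replace = TRUE, prob = config$mixture_weights)
    centers <- c(friend = config$cluster_mean, neutral = 0,
                 rival = -config$cluster_mean)
    sds <- c(friend = config$cluster_sd, neutral = config$neutral_sd,
             rival = config$cluster_sd)
    a <- pmin(1, pmax(-1, stats::rnorm(length(dyads), centers[cluster], sds[cluster])))
    rival_a <- if (config$decouple_conditions) {
      cl2 <- sample(c("friend", "neutral", "rival"), length(dyads),
                    replace = TRUE, prob = config$mixture_weights)
      pmin(1, pmax(-1, stats::rnorm(length(dyads), centers[cl2], sds[cl2])))
    } else {
      -a
    }
    strengths <- stats::runif(config$n_contestants)
  })
  structure(
    list(roster = ros,
         affinity = tibble::tibble(dyad = dyads, cluster = cluster,
                                   affinity = a, rival_affinity = rival_a),
         strengths = stats::setNames(strengths, ros$contestants),
         config = config, seed = as.integer(seed)),
    class = "convrel_world"
  )
}

#' @export
print.convrel_world <- function(x, ...) {
  cat("<convrel_world> ", length(x$roster$contestants), " contestants, ",
      x$config$clips, " clips, ", x$config$observers, " observers (seed ",
      x$seed, ")\n", sep = "")
  print(table(x$affinity$cluster))
  invisible(x)
}

affinity_lookup <- function(world) {
  stats::setNames(world$affinity$affinity, world$affinity$dyad)
}

world_topics <- function(world) {
  ## a fixed topic vocabulary: each dyad owns a subset of shared topic
  ## tokens; each contestant owns a private pool. drawn deterministically
  ## from the world seed.
  withr::with_seed(world$seed + 1L, {
    global <- sprintf("topic%02d", 1:40)
    dyad_topics <- lapply(world$affinity$dyad, function(d) sample(global, 6))
    names(dyad_topics) <- world$affinity$dyad
    private <- lapply(world$roster$contestants, function(cn) {
      paste0("hobby", cn, sprintf("%02d", 1:8))
    })
    names(private) <- world$roster$contestants
    list(dyad = dyad_topics, private = private)
  })
}

synth_wordpools <- function() {
  lex <- default_lexicon()
  list(
    positive = names(lex$polarity)[lex$polarity > 0],
    negative = names(lex$polarity)[lex$polarity < 0],
    we_pron = c("we", "us"), you_pron = c("you"), i_pron = c("i", "me"),
    social_verb = c("talk", "tell", "share", "help", "meet", "join", "plan", "vote"),
    plain_verb = c("see", "walk", "carry", "build", "find", "hold", "watch")
  )
}

synth_sentence <- function(a, speaker, dyad_key, topics, pools, config) {
  e <- function() stats::rnorm(1, 0, config$sigma)
  p_we <- stats::plogis(config$clout_slope * a + e())
  p_pos <- stats::plogis(config$sentiment_slope * a + e())
  p_shared <- stats::plogis(config$topic_slope * a + e())
  pron <- if (stats::runif(1) < p_we) {
    sample(c(pools$we_pron, pools$you_pron), 1)
  } else {
    sample(pools$i_pron, 1)
  }
  verb <- if (stats::runif(1) < p_we) sample(pools$social_verb, 1) else sample(pools$plain_verb, 1)
  pick_topic <- function() {
    if (!is.null(dyad_key) && stats::runif(1) < p_shared) {
      sample(topics$dyad[[dyad_key]], 1)
    } else {
      sample(topics$private[[speaker]], 1)
    }
  }
  words <- c(pron, verb, "the", pick_topic(), pick_topic())
  if (stats::runif(1) < config$polar_rate) {
    polar <- if (stats::runif(1) < p_pos) sample(pools$positive, 1) else sample(pools$negative, 1)
    words <- c(words, polar)
  }
  paste(words, collapse = " ")
}

#' Generate a template transcript from a synthetic world
#'
#' Per clip, each dyad exchanges a Poisson number of sentence rounds whose
#' word choices track the dyad's affinity: higher affinity raises the
#' positive-word rate (sentiment), the shared-topic rate (embedding
#' similarity), and the we/you-word rate while lowering the i-word rate
#' (clout). Each contestant additionally speaks confessional (CAMERA)
#' sentences per clip, driven by their mean affinity, feeding the general
#' levels.
#'
#' @param world A [generate_world()] result.
#' @return A validated utterance tibble.
#' @export
generate_transcript <- function(world) {
  stopifnot(inherits(world, "convrel_world"))
  config <- world$config
  pools <- synth_wordpools()
  if (length(pools$positive) == 0 || length(pools$negative) == 0) {
    stop("empty lexicon", call. = FALSE)
  }
  topics <- world_topics(world)
  aff <- affinity_lookup(world)
  mean_aff <- vapply(world$roster$contestants, function(cn) {
    mean(aff[grep(paste0("(^|\\|)", cn, "($|\\|)"), names(aff))])
  }, numeric(1))

  withr::with_seed(world$seed + 2L, {
    rows <- list()
    for (clip in seq_len(config$clips)) {
      idx <- 1L
      for (d in world$affinity$dyad) {
        members <- strsplit(d, "|", fixed = TRUE)[[1]]
        n_rounds <- stats::rpois(1, config$exchanges_per_clip)
        if (n_rounds == 0) next
        for (r in seq_len(n_rounds)) {
          for (k in 1:2) {
            sp <- members[k]; rec <- members[3 - k]
            rows[[length(rows) + 1L]] <- tibble::tibble(
              speaker = sp, recipient = rec, addressee_type = "dyadic",
              clip = clip, sentence_index = idx,
              text = synth_sentence(aff[[d]], sp, d, topics, pools, config))
            idx <- idx + 1L
          }
        }
      }
      for (cn in world$roster$contestants) {
        for (s in seq_len(config$confessionals_per_clip)) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            speaker = cn, recipient = "CAMERA", addressee_type = "confessional",
            clip = clip, sentence_index = idx,
            text = synth_sentence(mean_aff[[cn]], cn, NULL, topics, pools, config))
          idx <- idx + 1L
        }
      }
    }
    if (length(rows) == 0) {
      stop("generated transcript is empty; increase exchanges_per_clip or confessionals_per_clip",
           call. = FALSE)
    }
    as_utterances(dplyr::bind_rows(rows))
  })
}

#' Simulate observers' forced-choice responses
#'
#' Each observer completes six blocks — every condition twice, order
#' randomized — with the full trial design per block. Friend choices follow
#' a logistic in the affinity difference of the two candidate dyads at
#' temperature `tau`; rival choices use the negated (or decoupled) affinity
#' surface; win choices use win-strength differences. A configurable
#' fraction of responses is missing.
#'
#' @param world A [generate_world()] result.
#' @return A validated trial tibble.
#' @export
generate_responses <- function(world) {
  stopifnot(inherits(world, "convrel_world"))
  config <- world$config
  ros <- world$roster
  aff <- affinity_lookup(world)
  raff <- stats::setNames(world$affinity$rival_affinity, world$affinity$dyad)
  strengths <- world$strengths
  tau <- config$tau

  value_of <- function(condition, choice, target) {
    switch(condition,
           friend = aff[[dyad_key(choice, target)]],
           rival = raff[[dyad_key(choice, target)]],
           win = strengths[[choice]])
  }

  withr::with_seed(world$seed + 3L, {
    all_trials <- list()
    for (o in seq_len(config$observers)) {
      pid <- sprintf("obs%02d", o)
      block_conditions <- sample(rep(c("friend", "rival", "win"), 2))
      for (blk in seq_along(block_conditions)) {
        cond <- block_conditions[blk]
        clip <- (blk - 1L) %% config$clips + 1L
        design <- enumerate_design(ros, cond, block = blk, clip = clip)
        design <- design[sample.int(nrow(design)), ]
        v1 <- mapply(value_of, cond, design$choice_a, design$target)
        v2 <- mapply(value_of, cond, design$choice_b, design$target)
        p_a <- stats::plogis((v1 - v2) / tau)
        pick_a <- stats::runif(nrow(design)) < p_a
        selected <- ifelse(pick_a, design$choice_a, design$choice_b)
        miss <- stats::runif(nrow(design)) < config$missing_fraction
        selected[miss] <- NA_character_
        all_trials[[length(all_trials) + 1L]] <- tibble::tibble(
          participant = pid, block = design$block, condition = cond,
          clip = design$clip, target = design$target,
          choice_a = design$choice_a, choice_b = design$choice_b,
          selected = selected,
          rt = ifelse(miss, NA_real_, round(stats::runif(nrow(design), 0.4, 4.8), 3)))
      }
    }
    as_trials(dplyr::bind_rows(all_trials))
  })
}

#' Simulate a complete synthetic study
#'
#' Ground truth (world), transcript, and observer responses in one call,
#' all reproducible from one seed.
#'
#' @param config A [world_config()].
#' @param seed Integer seed.
#' @return A list with `world`, `utterances`, `trials`.
#' @export
simulate_study <- function(config = world_config(), seed) {
  world <- generate_world(config, seed)
  list(world = world,
       utterances = generate_transcript(world),
       trials = generate_responses(world))
}
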