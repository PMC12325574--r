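#' Temporal/dyadic aggregation window
#'
#' A window pairs a time mode — `gist` (cumulative: clips 1..c) or `recent`
#' (clip c only) — with an interaction mode — `specific` (dyadic dialogue
#' between the two members only) or `general` (everything a contestant said,
#' including confessionals, group talk, and host interactions). In season
#' mode the clip index is an episode number and an inclusive
#' `episode_range` (e.g., 1-5 for the early-similarity analysis) can
#' restrict the corpus.
#'
#' @param time_mode `"gist"` or `"recent"`.
#' @param interaction_mode `"specific"` or `"general"`.
#' @param clip Positive clip (or episode) index c.
#' @param season_mode Logical; clip indices are episode numbers.
#' @param episode_range Optional inclusive integer range; only valid in
#'   season mode.
#' @return A list of class `convrel_window`.
#' @export
window_spec <- function(time_mode = c("gist", "recent"),
                        interaction_mode = c("specific", "general"),
                        clip, season_mode = FALSE, episode_range = NULL) {
  time_mode <- match.arg(time_mode)
  interaction_mode <- match.arg(interaction_mode)
  clip <- as.integer(clip)
  stopifnot(length(clip) == 1, clip >= 1)
  if (!is.null(episode_range) && !season_mode) {
    stop("episode_range is only valid in season mode", call. = FALSE)
  }
  structure(
    list(time_mode = time_mode, interaction_mode = interaction_mode,
         clip = clip, season_mode = season_mode,
         episode_range = if (!is.null(episode_range)) as.integer(range(episode_range))),
    class = "convrel_window"
  )
}

window_level <- function(spec) paste(spec$time_mode, spec$interaction_mode, sep = "_")

select_window <- function(utterances, spec) {
  if (spec$clip > max(utterances$clip)) {
    stop("clip ", spec$clip, " is out of range (corpus has clips 1..",
         max(utterances$clip), ")", call. = FALSE)
  }
  clips <- if (spec$time_mode == "gist") seq_len(spec$clip) else spec$clip
  if (!is.null(spec$episode_range)) {
    clips <- clips[clips >= spec$episode_range[1] & clips <= spec$episode_range[2]]
  }
  utterances[utterances$clip %in% clips, ]
}

feature_score_row <- function(unit, clip, level, feature, value, n_sentences) {
  tibble::tibble(unit = unit, clip = as.integer(clip), level = level,
                 feature = feature, value = value,
                 n_sentences = as.integer(n_sentences))
}

#' Windowed feature score for a dyad or an individual
#'
#' Computes one linguistic feature over one window. Sentiment and clout are
#' means of sentence-level scores over every utterance the window selects
#' (so a gist score is the cumulative, sentence-count-weighted running mean,
#' not a mean of per-clip means). Similarity is [dyad_similarity()] over the
#' windowed dyadic dialogue (specific) or the cosine of the two members'
#' pooled general speech (general; see [dyad_general_score()]). A window
#' that selects no qualifying dialogue yields an `NA` value with
#' `n_sentences = 0` — absent, never zero-filled.
#'
#' @param utterances A validated utterance tibble.
#' @param spec A [window_spec()].
#' @param feature `"sentiment"`, `"clout"`, or `"similarity"`.
#' @param unit A length-2 dyad, or a single contestant identifier for
#'   general sentiment/clout. Similarity always needs a dyad.
#' @param lexicon,clout_cats,backend,sent_params Feature machinery; defaults
#'   are the built-ins.
#' @param similarity_mode Passed to [dyad_similarity()].
#' @return A one-row feature-score tibble
#'   (`unit, clip, level, feature, value, n_sentences`).
#' @export
window_scores <- function(utterances, spec,
                          feature = c("sentiment", "clout", "similarity"),
                          unit, lexicon = default_lexicon(),
                          clout_cats = default_clout_categories(),
                          backend = hash_embedder(),
                          sent_params = sentiment_params(),
                          similarity_mode = "pooled") {
  feature <- match.arg(feature)
  level <- window_level(spec)
  unit_key <- if (length(unit) == 2) dyad_key(unit[1], unit[2]) else as.character(unit)
  if (feature == "similarity" && length(unit) != 2) {
    stop("similarity is a dyad-level feature; unit must be a pair", call. = FALSE)
  }
  win <- select_window(utterances, spec)

  if (feature == "similarity") {
    if (spec$interaction_mode == "specific") {
      dy <- filter_dialogue(win, "specific", dyad = unit)
      value <- dyad_similarity(win, unit, backend = backend, mode = similarity_mode)
      n <- nrow(dy)
    } else {
      return(dyad_general_score(utterances, unit, spec, "similarity",
                                backend = backend))
    }
    return(feature_score_row(unit_key, spec$clip, level, feature, value, n))
  }

  if (spec$interaction_mode == "specific") {
    sel <- filter_dialogue(win, "specific", dyad = unit)
  } else {
    if (length(unit) == 2) {
      return(dyad_general_score(utterances, unit, spec, feature,
                                lexicon = lexicon, clout_cats = clout_cats,
                                sent_params = sent_params))
    }
    sel <- filter_dialogue(win, "general", speaker = unit)
  }
  if (nrow(sel) == 0) {
    return(feature_score_row(unit_key, spec$clip, level, feature, NA_real_, 0))
  }
  scores <- switch(feature,
                   sentiment = sentence_sentiment(sel$text, lexicon, sent_params),
                   clout = sentence_clout(sel$text, clout_cats))
  feature_score_row(unit_key, spec$clip, level, feature, mean(scores), nrow(sel))
}

#' Dyad-level general feature score
#'
#' The models predict dyad-level judgments, but general scores are computed
#' per contestant. For sentiment and clout the dyad-level general score is
#' the unweighted mean of the two members' individual general scores; for
#' similarity it is the cosine between the two members' pooled general
#' speech. The score is absent (`NA`) when either member is silent in the
#' window.
#'
#' @inheritParams window_scores
#' @param dyad Length-2 character vector.
#' @return A one-row feature-score tibble.
#' @export
dyad_general_score <- function(utterances, dyad, spec,
                               feature = c("sentiment", "clout", "similarity"),
                               lexicon = default_lexicon(),
                               clout_cats = default_clout_categories(),
                               backend = hash_embedder(),
                               sent_params = sentiment_params()) {
  feature <- match.arg(feature)
  stopifnot(length(dyad) == 2)
  key <- dyad_key(dyad[1], dyad[2])
  level <- paste(spec$time_mode, "general", sep = "_")
  win <- select_window(utterances, spec)
  speech <- lapply(dyad, function(m) filter_dialogue(win, "general", speaker = m))
  n_each <- vapply(speech, nrow, integer(1))
  if (any(n_each == 0)) {
    return(feature_score_row(key, spec$clip, level, feature, NA_real_, 0))
  }
  if (feature == "similarity") {
    value <- cosine_similarity(
      backend$embed(paste(speech[[1]]$text, collapse = " ")),
      backend$embed(paste(speech[[2]]$text, collapse = " "))
    )
  } else {
    member_means <- vapply(speech, function(s) {
      scores <- switch(feature,
                       sentiment = sentence_sentiment(s$text, lexicon, sent_params),
                       clout = sentence_clout(s$text, clout_cats))
      mean(scores)
    }, numeric(1))
    value <- mean(member_means)
  }
  feature_score_row(key, spec$clip, level, feature, value, sum(n_each))
}

#' Feature scores for every dyad, clip, feature, and level
#'
#' Convenience grid over [window_scores()]: all roster dyads crossed with
#' the requested clips, features, and levels, in one tidy table.
#'
#' @inheritParams window_scores
#' @param roster A [roster()].
#' @param clips Integer vector of clip indices (default: all in the corpus).
#' @param features Subset of `c("similarity", "sentiment", "clout")`.
#' @param levels Subset of the four `time_interaction` level names.
#' @return A tidy feature-score tibble.
#' @export
feature_table <- function(utterances, roster, clips = NULL,
                          features = c("similarity", "sentiment", "clout"),
                          levels = c("gist_specific", "recent_specific",
                                     "gist_general", "recent_general"),
                          lexicon = default_lexicon(),
                          clout_cats = default_clout_categories(),
                          backend = hash_embedder(),
                          sent_params = sentiment_params(),
                          similarity_mode = "pooled") {
  if (is.null(clips)) clips <- sort(unique(utterances$clip))
  dyads <- utils::combn(roster$contestants, 2, simplify = FALSE)
  grid <- expand.grid(level = levels, feature = features, clip = clips,
                      di = seq_along(dyads), stringsAsFactors = FALSE)
  rows <- purrr::pmap(grid, function(level, feature, clip, di) {
    parts <- strsplit(level, "_", fixed = TRUE)[[1]]
    spec <- window_spec(parts[1], parts[2], clip = clip)
    window_scores(utterances, spec, feature, unit = dyads[[di]],
                  lexicon = lexicon, clout_cats = clout_cats,
                  backend = backend, sent_params = sent_params,
                  similarity_mode = similarity_mode)
  })
  dplyr::bind_rows(rows)
}

#' Merge per-clip behavioral responses with feature scores
#'
#' Builds the model-ready table: one row per (participant, dyad, condition,
#' clip) carrying the chosen/presented counts from the per-block
#' percent-chosen table and the requested feature's value at the matching
#' clip and level. Rows whose feature value is absent are dropped (complete
#' cases); the drop count is messaged.
#'
#' @param pct_table [percent_chosen()] output with `pool_blocks = FALSE`
#'   (so each row carries its block's clip index).
#' @param features A [feature_table()] output.
#' @param feature,level Which feature/level column to attach.
#' @param conditions Conditions to keep (the relational models use friend
#'   and rival).
#' @return A tibble `participant, dyad, condition, clip, chosen, presented,
#'   x` with attributes `feature` and `level`.
#' @export
assemble_model_table <- function(pct_table, features, feature, level,
                                 conditions = c("friend", "rival")) {
  if (!"clip" %in% names(pct_table)) {
    stop("pct_table must be computed per block (pool_blocks = FALSE) so rows carry clips",
         call. = FALSE)
  }
  fx <- features[features$feature == feature & features$level == level, ]
  if (nrow(fx) == 0) {
    warning("no feature scores for ", feature, " at level ", level,
            "; model table is empty")
    return(structure(tibble::tibble(), feature = feature, level = level))
  }
  resp <- pct_table[pct_table$condition %in% conditions, ]
  if (any(!resp$dyad %in% fx$unit)) {
    missing_clips <- setdiff(unique(resp$clip), unique(fx$clip))
    if (length(missing_clips)) {
      stop("feature scores missing for clip(s): ",
           paste(missing_clips, collapse = ", "), call. = FALSE)
    }
  }
  merged <- dplyr::inner_join(resp, fx[, c("unit", "clip", "value")],
                              by = c(dyad = "unit", clip = "clip"))
  n_dropped <- sum(is.na(merged$value))
  if (n_dropped > 0) {
    message("assemble_model_table: dropped ", n_dropped,
            " row(s) with absent ", level, " ", feature, " scores")
  }
  out <- merged[!is.na(merged$value),
                c("participant", "dyad", "condition", "clip",
                  "chosen", "presented", "value")]
  names(out)[names(out) == "value"] <- "x"
  structure(out, feature = feature, level = level)
}

#' Early-window similarity per dyad (season mode)
#'
#' For the relational-homophily question: semantic similarity of each dyad
#' over the first episodes of a season, averaged across episodes. `specific`
#' uses only the dyad's own dialogue within each episode; `general` uses
#' each member's full speech (confessionals, group, host included) pooled
#' per episode. Episodes where the score is undefined (no two-sided dyadic
#' dialogue, or a silent member) are skipped; a dyad with no defined episode
#' is `NA`.
#'
#' @param utterances Season-mode utterance tibble (clip = episode number).
#' @param roster A [roster()].
#' @param mode `"general"` or `"specific"`.
#' @param episodes Episodes to include (default 1:5, the pre-merge window).
#' @param backend,similarity_mode See [dyad_similarity()].
#' @return A tibble `dyad, value, n_episodes`.
#' @export
early_similarity <- function(utterances, roster, mode = c("general", "specific"),
                             episodes = 1:5, backend = hash_embedder(),
                             similarity_mode = "pooled") {
  mode <- match.arg(mode)
  dyads <- utils::combn(roster$contestants, 2, simplify = FALSE)
  rows <- lapply(dyads, function(dy) {
    per_ep <- vapply(episodes, function(ep) {
      spec <- window_spec("recent", mode, clip = ep, season_mode = TRUE,
                          episode_range = range(episodes))
      if (ep > max(utterances$clip)) return(NA_real_)
      ws <- window_scores(utterances, spec, "similarity", unit = dy,
                          backend = backend, similarity_mode = similarity_mode)
      ws$value
    }, numeric(1))
    tibble::tibble(dyad = dyad_key(dy[1], dy[2]),
                   value = if (all(is.na(per_ep))) NA_real_ else mean(per_ep, na.rm = TRUE),
                   n_episodes = sum(!is.na(per_ep)))
  })
  dplyr::bind_rows(rows)
}
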