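#' Parameters of the valence-shifter sentiment scorer
#'
#' The cluster examined around each polarized word spans `window_before`
#' tokens before and `window_after` after (defaults 4 and 2). Each amplifier
#' in the cluster multiplies the polarity by `amplifier_weight` (default
#' 1.8); an odd number of negators flips the sign and turns amplifiers into
#' de-amplifiers. Each de-amplifier multiplies by `deamplifier_factor`
#' (default 1/1.8, the reciprocal of the amplifier weight — the shrink
#' magnitude is a package choice). Adversative conjunctions weight the
#' polarized word by `adversative_weight` (default 1.85) per conjunction
#' before it in the sentence, and by its reciprocal per conjunction after.
#' The summed token scores are divided by the square root of the token count
#' when `normalize_by_sqrt_length` (the default), yielding an unbounded
#' sentence score.
#'
#' @param window_before,window_after Non-negative cluster sizes.
#' @param amplifier_weight,adversative_weight Positive multipliers.
#' @param deamplifier_factor Positive shrink factor, typically < 1.
#' @param normalize_by_sqrt_length Logical.
#' @return A list of class `convrel_sentiment_params`.
#' @export
sentiment_params <- function(window_before = 4L, window_after = 2L,
                             amplifier_weight = 1.8,
                             adversative_weight = 1.85,
                             deamplifier_factor = 1 / 1.8,
                             normalize_by_sqrt_length = TRUE) {
  stopifnot(window_before >= 0, window_after >= 0,
            amplifier_weight > 0, adversative_weight > 0,
            deamplifier_factor > 0)
  structure(
    list(window_before = as.integer(window_before),
         window_after = as.integer(window_after),
         amplifier_weight = amplifier_weight,
         adversative_weight = adversative_weight,
         deamplifier_factor = deamplifier_factor,
         normalize_by_sqrt_length = isTRUE(normalize_by_sqrt_length)),
    class = "convrel_sentiment_params"
  )
}

#' Tokenize a sentence
#'
#' Lowercases, splits on non-alphanumeric characters, and keeps
#' apostrophe-internal contractions ("don't") as single tokens.
#'
#' @param text Character scalar.
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize <- function(text) {
  stopifnot(length(text) == 1)
  x <- tolower(text)
  x <- gsub("[^a-z0-9']+", " ", x)
  toks <- strsplit(trimws(x), " +")[[1]]
  toks <- gsub("^'+|'+$", "", toks)           # strip quote-style apostrophes
  toks[nzchar(toks)]
}

score_tokens <- function(tokens, lexicon, params) {
  pol <- lexicon$polarity[tokens]
  hits <- which(!is.na(pol))
  if (length(hits) == 0) return(0)
  is_neg <- tokens %in% lexicon$negators
  is_amp <- tokens %in% lexicon$amplifiers
  is_deamp <- tokens %in% lexicon$deamplifiers
  is_adv <- tokens %in% lexicon$adversatives
  n <- length(tokens)
  total <- 0
  for (i in hits) {
    cluster <- setdiff(seq(max(1, i - params$window_before),
                           min(n, i + params$window_after)), i)
    n_negators <- sum(is_neg[cluster])
    p <- unname(pol[i])
    if (n_negators %% 2 == 1) p <- -p
    a <- sum(is_amp[cluster])
    d <- sum(is_deamp[cluster])
    if (n_negators %% 2 == 1) { d <- d + a; a <- 0 }   # amplifiers de-amplify under negation
    w <- params$amplifier_weight^a * params$deamplifier_factor^d
    adv_before <- if (i > 1) sum(is_adv[seq_len(i - 1)]) else 0
    adv_after <- if (i < n) sum(is_adv[seq(i + 1, n)]) else 0
    m <- params$adversative_weight^adv_before / params$adversative_weight^adv_after
    total <- total + p * w * m
  }
  total
}

#' Sentence-level sentiment with valence shifters
#'
#' Scores each sentence by summing the polarity of dictionary words, each
#' weighted by the valence shifters (negators, amplifiers, de-amplifiers,
#' adversative conjunctions) found in its surrounding cluster; see
#' [sentiment_params()] for the exact weighting rules. A sentence with no
#' polarized tokens scores 0.
#'
#' @param text Character vector of sentences (each must tokenize to at least
#'   one word).
#' @param lexicon A [sentiment_lexicon()]; defaults to the built-in one.
#' @param params A [sentiment_params()].
#' @return Numeric vector of unbounded sentence scores.
#' @examples
#' sentence_sentiment("very happy")   # 1.8 / sqrt(2)
#' @export
sentence_sentiment <- function(text, lexicon = default_lexicon(),
                               params = sentiment_params()) {
  vapply(text, function(s) {
    tokens <- tokenize(s)
    if (length(tokens) == 0) stop("cannot score an empty sentence", call. = FALSE)
    raw <- score_tokens(tokens, lexicon, params)
    if (params$normalize_by_sqrt_length) raw / sqrt(length(tokens)) else raw
  }, numeric(1), USE.NAMES = FALSE)
}
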