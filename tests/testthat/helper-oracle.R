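## Independent brute-force oracle for the valence-shifter sentiment rules.
## Written deliberately from scratch (explicit loops, no shared helpers with
## the package) so it can serve as a cross-check.

oracle_sentiment <- function(text, lexicon, params) {
  words <- tolower(text)
  words <- gsub("[^a-z0-9']+", " ", words)
  words <- strsplit(trimws(words), " +")[[1]]
  words <- gsub("^'+|'+$", "", words)
  words <- words[nchar(words) > 0]
  if (length(words) == 0) stop("empty")
  total <- 0
  for (i in seq_along(words)) {
    w <- words[i]
    if (!w %in% names(lexicon$polarity)) next
    p <- lexicon$polarity[[w]]
    lo <- i - params$window_before
    hi <- i + params$window_after
    n_neg <- 0; n_amp <- 0; n_deamp <- 0
    for (j in seq_along(words)) {
      if (j == i || j < lo || j > hi) next
      if (words[j] %in% lexicon$negators) n_neg <- n_neg + 1
      if (words[j] %in% lexicon$amplifiers) n_amp <- n_amp + 1
      if (words[j] %in% lexicon$deamplifiers) n_deamp <- n_deamp + 1
    }
    flipped <- (n_neg %% 2) == 1
    if (flipped) p <- -p
    if (flipped) { n_deamp <- n_deamp + n_amp; n_amp <- 0 }
    weight <- params$amplifier_weight^n_amp * params$deamplifier_factor^n_deamp
    before <- 0; after <- 0
    for (j in seq_along(words)) {
      if (words[j] %in% lexicon$adversatives) {
        if (j < i) before <- before + 1
        if (j > i) after <- after + 1
      }
    }
    weight <- weight * params$adversative_weight^before /
      params$adversative_weight^after
    total <- total + p * weight
  }
  if (params$normalize_by_sqrt_length) total / sqrt(length(words)) else total
}

## random sentences assembled from all lexicon classes plus neutral filler
random_lexicon_sentence <- function(lexicon, min_len = 1, max_len = 12) {
  vocab <- c(names(lexicon$polarity), lexicon$negators, lexicon$amplifiers,
             lexicon$deamplifiers, lexicon$adversatives,
             "the", "a", "camp", "fire", "walks", "today", "maybe")
  n <- sample(min_len:max_len, 1)
  paste(sample(vocab, n, replace = TRUE), collapse = " ")
}
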