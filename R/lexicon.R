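#' Sentiment lexicon with valence-shifter classes
#'
#' Bundles a polarity dictionary (word -> +1/-1) with the four
#' valence-shifter classes: negators (flip the sign), amplifiers (weight the
#' polarized word up), de-amplifiers (weight it down), and adversative
#' conjunctions ("but", "however", ...). The five classes must be disjoint
#' and lowercase.
#'
#' @param polarity Named numeric vector of +1/-1 values, names are words.
#' @param negators,amplifiers,deamplifiers,adversatives Character vectors.
#' @return An object of class `convrel_lexicon`.
#' @export
sentiment_lexicon <- function(polarity, negators, amplifiers, deamplifiers,
                              adversatives) {
  if (is.null(names(polarity)) || any(!polarity %in% c(-1, 1))) {
    stop("polarity must be a named vector of +1/-1 values", call. = FALSE)
  }
  classes <- list(polarity = names(polarity), negators = negators,
                  amplifiers = amplifiers, deamplifiers = deamplifiers,
                  adversatives = adversatives)
  all_words <- unlist(classes, use.names = FALSE)
  if (any(all_words != tolower(all_words))) {
    stop("lexicon entries must be lowercase", call. = FALSE)
  }
  if (anyDuplicated(all_words)) {
    stop("lexicon word classes must be disjoint; duplicated: ",
         paste(unique(all_words[duplicated(all_words)]), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(polarity = polarity, negators = as.character(negators),
         amplifiers = as.character(amplifiers),
         deamplifiers = as.character(deamplifiers),
         adversatives = as.character(adversatives)),
    class = "convrel_lexicon"
  )
}

read_wordlist <- function(path) {
  words <- readLines(path, warn = FALSE, encoding = "UTF-8")
  words <- trimws(words)
  words[nzchar(words)]
}

lexicon_file <- function(name) {
  system.file("extdata", "lexicons", name, package = "convrel", mustWork = TRUE)
}

#' Built-in sentiment lexicon
#'
#' A small general-purpose lexicon (about 90 polarity words plus standard
#' negator/amplifier/de-amplifier/adversative lists) shipped as plain-text
#' word lists under `extdata/lexicons/`. Full-scale lexicons can be loaded
#' with [load_lexicon()].
#'
#' @return A `convrel_lexicon`.
#' @export
default_lexicon <- function() {
  load_lexicon(
    positive = lexicon_file("positive.txt"),
    negative = lexicon_file("negative.txt"),
    negators = lexicon_file("negators.txt"),
    amplifiers = lexicon_file("amplifiers.txt"),
    deamplifiers = lexicon_file("deamplifiers.txt"),
    adversatives = lexicon_file("adversatives.txt")
  )
}

#' Load a sentiment lexicon from plain-text word lists
#'
#' Each file holds one lowercase word per line.
#'
#' @param positive,negative,negators,amplifiers,deamplifiers,adversatives
#'   File paths.
#' @return A `convrel_lexicon`.
#' @export
load_lexicon <- function(positive, negative, negators, amplifiers,
                         deamplifiers, adversatives) {
  pos <- read_wordlist(positive); neg <- read_wordlist(negative)
  polarity <- c(stats::setNames(rep(1, length(pos)), pos),
                stats::setNames(rep(-1, length(neg)), neg))
  sentiment_lexicon(polarity,
                    negators = read_wordlist(negators),
                    amplifiers = read_wordlist(amplifiers),
                    deamplifiers = read_wordlist(deamplifiers),
                    adversatives = read_wordlist(adversatives))
}

#' Word-category lists for the clout proxy
#'
#' Five token categories drive the clout score: first-person plural (`we`),
#' second person (`you`), social words, first-person singular (`i`), and
#' negations. These are independent of the sentiment lexicon and need not be
#' disjoint from it.
#'
#' @param we,you,social,i,negations Character vectors of lowercase words.
#' @return An object of class `convrel_clout_categories`.
#' @export
clout_categories <- function(we, you, social, i, negations) {
  cats <- list(we = we, you = you, social = social, i = i,
               negations = negations)
  cats <- lapply(cats, as.character)
  if (any(unlist(cats) != tolower(unlist(cats)))) {
    stop("clout category entries must be lowercase", call. = FALSE)
  }
  structure(cats, class = "convrel_clout_categories")
}

#' Built-in clout word categories
#'
#' @return A `convrel_clout_categories` read from the shipped word lists.
#' @export
default_clout_categories <- function() {
  clout_categories(
    we = read_wordlist(lexicon_file("clout_we.txt")),
    you = read_wordlist(lexicon_file("clout_you.txt")),
    social = read_wordlist(lexicon_file("clout_social.txt")),
    i = read_wordlist(lexicon_file("clout_i.txt")),
    negations = read_wordlist(lexicon_file("clout_negations.txt"))
  )
}
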