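#' Clout proxy: a 1-99 language-based status score
#'
#' A transparent stand-in for proprietary clout scoring. The score is driven
#' by per-token rates of five word categories: it increases with
#' first-person-plural (`we`), second-person (`you`), and social words, and
#' decreases with first-person-singular (`i`) and negation words — the
#' direction pattern established for language markers of status and
#' confidence. The raw rate contrast `r_we + r_you + r_social - r_i - r_neg`
#' is mapped to `1 + 98 * plogis(gain * raw)`, bounding the score in
#' \[1, 99\] with 50 at a neutral rate balance. Only ordinal properties
#' (bounds, monotonicity) are meaningful; no numeric agreement with any
#' proprietary tool is implied.
#'
#' @param text Character vector of non-empty sentences.
#' @param categories A [clout_categories()]; defaults to the built-in lists.
#' @param gain Positive logistic gain (default 5) controlling how fast the
#'   score saturates as the rate contrast grows.
#' @return Numeric vector of scores in \[1, 99\].
#' @export
sentence_clout <- function(text, categories = default_clout_categories(),
                           gain = 5) {
  stopifnot(gain > 0)
  vapply(text, function(s) {
    tokens <- tokenize(s)
    if (length(tokens) == 0) stop("cannot score an empty sentence", call. = FALSE)
    n <- length(tokens)
    rate <- function(words) sum(tokens %in% words) / n
    raw <- rate(categories$we) + rate(categories$you) +
      rate(categories$social) - rate(categories$i) - rate(categories$negations)
    1 + 98 * stats::plogis(gain * raw)
  }, numeric(1), USE.NAMES = FALSE)
}
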