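#' Contestant roster
#'
#' A roster names the contestants whose relationships are under study and,
#' optionally, speakers (such as a host) whose dialogue is excluded from all
#' analyses.
#'
#' @param contestants Character vector of unique, non-empty contestant
#'   identifiers. Order is meaningful: it fixes the canonical dyad-key order
#'   used by [response_vector()].
#' @param excluded_speakers Character vector of speaker identifiers whose
#'   utterances are dropped on read (e.g., the host).
#' @return An object of class `convrel_roster`.
#' @examples
#' roster(c("ana", "ben", "cam"))
#' @export
roster <- function(contestants, excluded_speakers = character()) {
  contestants <- as.character(contestants)
  if (length(contestants) == 0 || anyNA(contestants) || any(!nzchar(trimws(contestants)))) {
    stop("roster contestants must be non-empty strings", call. = FALSE)
  }
  if (anyDuplicated(contestants)) {
    stop("roster contestants must be unique", call. = FALSE)
  }
  if (any(contestants %in% reserved_recipients())) {
    stop("contestant identifiers may not collide with reserved recipient tokens ",
         paste(reserved_recipients(), collapse = ", "), call. = FALSE)
  }
  structure(
    list(contestants = contestants, excluded_speakers = as.character(excluded_speakers)),
    class = "convrel_roster"
  )
}

#' @export
print.convrel_roster <- function(x, ...) {
  cat("<convrel_roster> ", length(x$contestants), " contestants: ",
      paste(x$contestants, collapse = ", "), "\n", sep = "")
  if (length(x$excluded_speakers)) {
    cat("  excluded speakers: ", paste(x$excluded_speakers, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Reserved recipient tokens for non-dyadic speech
#'
#' `GROUP` marks speech addressed to several contestants at once, `CAMERA`
#' marks confessionals, and `HOST` marks exchanges with the host.
#'
#' @return Character vector of the three reserved tokens.
#' @export
reserved_recipients <- function() c("GROUP", "CAMERA", "HOST")

#' Canonical dyad keys for a roster
#'
#' Unordered keys are `"a|b"` with members sorted by roster order; ordered
#' (win) keys are `"beater>target"` over all ordered pairs.
#'
#' @param roster A [roster()].
#' @param directional If `TRUE`, return ordered (beater, target) keys.
#' @return Character vector of dyad keys in canonical order.
#' @export
canonical_dyads <- function(roster, directional = FALSE) {
  stopifnot(inherits(roster, "convrel_roster"))
  cs <- roster$contestants
  if (directional) {
    grid <- expand.grid(target = cs, beater = cs, stringsAsFactors = FALSE)
    grid <- grid[grid$beater != grid$target, c("beater", "target")]
    grid <- grid[order(match(grid$beater, cs), match(grid$target, cs)), ]
    paste(grid$beater, grid$target, sep = ">")
  } else {
    pairs <- utils::combn(cs, 2)
    paste(pairs[1, ], pairs[2, ], sep = "|")
  }
}

#' Build an unordered dyad key from two contestant identifiers
#'
#' @param a,b Contestant identifiers (vectorized).
#' @param roster Optional [roster()]; when given, members are ordered by
#'   roster position so keys match [canonical_dyads()], otherwise
#'   lexicographically.
#' @return Character vector of `"x|y"` keys.
#' @export
dyad_key <- function(a, b, roster = NULL) {
  a <- as.character(a); b <- as.character(b)
  if (any(a == b)) stop("a dyad needs two distinct members", call. = FALSE)
  if (!is.null(roster)) {
    swap <- match(a, roster$contestants) > match(b, roster$contestants)
  } else {
    swap <- a > b
  }
  swap[is.na(swap)] <- FALSE
  first <- ifelse(swap, b, a)
  second <- ifelse(swap, a, b)
  paste(first, second, sep = "|")
}

dyad_members <- function(key) strsplit(key, "|", fixed = TRUE)
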