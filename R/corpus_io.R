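#' @importFrom rlang .data
NULL

transcript_columns <- c("speaker", "recipient", "addressee_type", "clip",
                        "sentence_index", "text")

addressee_from_recipient <- function(recipient) {
  dplyr::case_match(
    recipient,
    "GROUP" ~ "group",
    "CAMERA" ~ "confessional",
    "HOST" ~ "host",
    .default = "dyadic"
  )
}

#' Validate a table of sentence-level utterances
#'
#' An utterance table holds one sentence of dialogue per row, annotated with
#' speaker, recipient (a contestant identifier or one of the reserved tokens
#' `GROUP`/`CAMERA`/`HOST`), an addressee type, a 1-based clip index (episode
#' number in season mode), and the sentence's order within the clip. The
#' addressee type is derived from the recipient when absent.
#'
#' @param x A data frame with columns `speaker`, `recipient`, `clip`,
#'   `sentence_index`, `text` and optionally `addressee_type`.
#' @return A validated tibble sorted by `(clip, sentence_index)`.
#' @export
as_utterances <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"addressee_type" %in% names(x)) {
    x$addressee_type <- addressee_from_recipient(as.character(x$recipient))
  }
  missing_cols <- setdiff(transcript_columns, names(x))
  if (length(missing_cols)) {
    stop("transcript is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- x[transcript_columns]
  x$speaker <- as.character(x$speaker)
  x$recipient <- as.character(x$recipient)
  x$addressee_type <- as.character(x$addressee_type)
  x$text <- as.character(x$text)

  clip_num <- suppressWarnings(as.numeric(x$clip))
  bad_clip <- which(is.na(clip_num) | clip_num < 1 | clip_num != round(clip_num))
  if (length(bad_clip)) {
    stop("malformed clip index at row(s): ",
         paste(utils::head(bad_clip, 5), collapse = ", "), call. = FALSE)
  }
  x$clip <- as.integer(clip_num)
  si <- suppressWarnings(as.numeric(x$sentence_index))
  bad_si <- which(is.na(si) | si < 1 | si != round(si))
  if (length(bad_si)) {
    stop("malformed sentence_index at row(s): ",
         paste(utils::head(bad_si, 5), collapse = ", "), call. = FALSE)
  }
  x$sentence_index <- as.integer(si)

  if (any(!nzchar(trimws(x$text)))) {
    stop("utterance text must be non-empty at row(s): ",
         paste(utils::head(which(!nzchar(trimws(x$text))), 5), collapse = ", "),
         call. = FALSE)
  }
  ok_types <- c("dyadic", "group", "confessional", "host")
  if (any(!x$addressee_type %in% ok_types)) {
    stop("addressee_type must be one of ", paste(ok_types, collapse = ", "),
         call. = FALSE)
  }
  dy <- x$addressee_type == "dyadic"
  if (any(dy & x$recipient %in% reserved_recipients())) {
    stop("dyadic utterances must name a contestant recipient", call. = FALSE)
  }
  if (any(!dy & !x$recipient %in% reserved_recipients())) {
    stop("non-dyadic utterances must use a reserved recipient token (",
         paste(reserved_recipients(), collapse = ", "), ")", call. = FALSE)
  }
  if (any(dy & x$speaker == x$recipient)) {
    stop("speaker and recipient must differ for dyadic utterances", call. = FALSE)
  }
  x <- dplyr::arrange(x, .data$clip, .data$sentence_index)
  x
}

#' Read a sentence-segmented transcript
#'
#' Reads a tab-separated (default) or comma-separated transcript with a
#' header row, validates it, drops utterances by excluded speakers, and
#' returns rows sorted by `(clip, sentence_index)`.
#'
#' @param path Path to the transcript file.
#' @param roster A [roster()]; utterances by `roster$excluded_speakers` are
#'   dropped (with a message giving the count) and remaining speakers must be
#'   roster contestants.
#' @param comma If `TRUE`, read comma-separated input instead of the
#'   canonical tab-separated dialect (free text routinely contains commas, so
#'   TSV is the default).
#' @return A validated utterance tibble.
#' @export
read_transcript <- function(path, roster, comma = FALSE) {
  stopifnot(inherits(roster, "convrel_roster"))
  if (!file.exists(path)) stop("transcript file not found: ", path, call. = FALSE)
  reader <- if (comma) readr::read_csv else readr::read_tsv
  x <- suppressMessages(reader(path, col_types = readr::cols(.default = readr::col_character()),
                               progress = FALSE))
  if (nrow(x) == 0) stop("empty corpus: ", path, call. = FALSE)
  required <- setdiff(transcript_columns, "addressee_type")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("transcript is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  drop <- x$speaker %in% roster$excluded_speakers
  if (any(drop)) {
    message("read_transcript: dropped ", sum(drop),
            " utterance(s) by excluded speaker(s)")
    x <- x[!drop, ]
  }
  if (nrow(x) == 0) stop("empty corpus after speaker exclusion: ", path, call. = FALSE)
  unknown <- setdiff(unique(x$speaker), roster$contestants)
  if (length(unknown)) {
    stop("unknown speaker(s) not in roster: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  as_utterances(x)
}

#' Write a transcript in the canonical tab-separated dialect
#'
#' Column order is canonical so that repeated writes of the same utterances
#' are byte-identical, and `read_transcript(write_transcript(x))` returns `x`.
#'
#' @param utterances A validated utterance tibble ([as_utterances()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(utterances, path) {
  if (nrow(utterances) > 0) utterances <- as_utterances(utterances)
  utterances <- tibble::as_tibble(utterances)[transcript_columns]
  readr::write_tsv(utterances, path, progress = FALSE)
  invisible(path)
}

#' Select dyad-specific or speaker-general dialogue
#'
#' `specific` keeps only dyadic dialogue spoken between the two members of
#' `dyad` (both directions). `general` keeps everything a single speaker said
#' regardless of addressee — dyadic dialogue, group talk, confessionals, and
#' host interactions alike.
#'
#' @param utterances A validated utterance tibble.
#' @param mode `"specific"` or `"general"`.
#' @param dyad For `specific`: an unordered pair of contestant identifiers
#'   (length-2 character vector).
#' @param speaker For `general`: a single contestant identifier.
#' @param roster Optional [roster()] used to reject unknown contestants.
#' @return The matching subset of `utterances` (possibly empty).
#' @export
filter_dialogue <- function(utterances, mode = c("specific", "general"),
                            dyad = NULL, speaker = NULL, roster = NULL) {
  mode <- match.arg(mode)
  if (mode == "specific") {
    if (is.null(dyad) || length(dyad) != 2) {
      stop("specific mode requires a dyad of two contestants", call. = FALSE)
    }
    dyad <- as.character(dyad)
    if (!is.null(roster)) {
      unknown <- setdiff(dyad, roster$contestants)
      if (length(unknown)) {
        stop("unknown contestant(s): ", paste(unknown, collapse = ", "),
             call. = FALSE)
      }
    }
    keep <- utterances$addressee_type == "dyadic" &
      ((utterances$speaker == dyad[1] & utterances$recipient == dyad[2]) |
         (utterances$speaker == dyad[2] & utterances$recipient == dyad[1]))
    utterances[keep, ]
  } else {
    if (is.null(speaker) || length(speaker) != 1) {
      stop("general mode requires a single speaker", call. = FALSE)
    }
    speaker <- as.character(speaker)
    if (!is.null(roster) && !speaker %in% roster$contestants) {
      stop("unknown contestant(s): ", speaker, call. = FALSE)
    }
    utterances[utterances$speaker == speaker, ]
  }
}
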