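trial_columns <- c("participant", "block", "condition", "clip", "target",
                   "choice_a", "choice_b", "selected")

#' Validate a table of forced-choice trials
#'
#' One row per trial of the target-plus-two-choices task: a target contestant
#' shown with two distinct choice contestants, and the observer's selection
#' (`NA` for a missed response; the string `"MISSING"` is accepted on input
#' and converted). Reaction time `rt`, when present, must lie in (0, 5]
#' seconds — observers had up to 5 s to respond.
#'
#' @param x Data frame with columns `participant`, `block`, `condition`,
#'   `clip`, `target`, `choice_a`, `choice_b`, `selected`, optionally `rt`.
#' @return A validated trial tibble.
#' @export
as_trials <- function(x) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(trial_columns, names(x))
  if (length(missing_cols)) {
    stop("trials table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x$participant <- as.character(x$participant)
  x$condition <- as.character(x$condition)
  for (col in c("target", "choice_a", "choice_b", "selected")) {
    x[[col]] <- as.character(x[[col]])
  }
  x$selected[x$selected %in% "MISSING"] <- NA_character_
  x$block <- as.integer(x$block)
  x$clip <- as.integer(x$clip)
  if (any(!x$condition %in% c("friend", "rival", "win"))) {
    stop("condition must be one of friend, rival, win", call. = FALSE)
  }
  trio <- cbind(x$target, x$choice_a, x$choice_b)
  if (any(apply(trio, 1, anyDuplicated) > 0)) {
    stop("target, choice_a, choice_b must be pairwise distinct", call. = FALSE)
  }
  sel_ok <- is.na(x$selected) | x$selected == x$choice_a | x$selected == x$choice_b
  if (any(!sel_ok)) {
    stop("selected must be one of the two choices or MISSING, bad row(s): ",
         paste(utils::head(which(!sel_ok), 5), collapse = ", "), call. = FALSE)
  }
  if ("rt" %in% names(x)) {
    rt <- x$rt
    if (any(!is.na(rt) & (rt <= 0 | rt > 5))) {
      stop("rt must lie in (0, 5] seconds when present", call. = FALSE)
    }
  }
  x
}

#' Enumerate the full forced-choice design for one block
#'
#' One trial per (target, unordered pair of two other contestants):
#' `n * choose(n - 1, 2)` trials, every possible pairwise combination per
#' target. With the study's 7 contestants this is 105 trials per block.
#'
#' @param roster A [roster()] with at least 3 contestants.
#' @param condition `"friend"`, `"rival"`, or `"win"`.
#' @param block Block number (each condition is run twice).
#' @param clip Clip shown before this block (attached to every trial).
#' @param seed Optional integer; when given, the trial order is randomized
#'   reproducibly. The set of trials never depends on the seed.
#' @return A trial-template tibble (no `selected` column).
#' @export
enumerate_design <- function(roster, condition = c("friend", "rival", "win"),
                             block = 1L, clip = block, seed = NULL) {
  condition <- match.arg(condition)
  stopifnot(inherits(roster, "convrel_roster"))
  cs <- roster$contestants
  n <- length(cs)
  if (n < 3) stop("the design needs at least 3 contestants", call. = FALSE)
  per_target <- lapply(cs, function(t) {
    others <- setdiff(cs, t)
    pairs <- utils::combn(others, 2)
    tibble::tibble(target = t, choice_a = pairs[1, ], choice_b = pairs[2, ])
  })
  out <- dplyr::bind_rows(per_target)
  out <- tibble::tibble(
    block = as.integer(block), condition = condition, clip = as.integer(clip),
    target = out$target, choice_a = out$choice_a, choice_b = out$choice_b
  )
  if (!is.null(seed)) {
    ord <- withr::with_seed(seed, sample.int(nrow(out)))
    out <- out[ord, ]
  }
  out
}

directional_counts <- function(trials) {
  ## one row per (target, choice) with presented/chosen counts; missed
  ## responses are excluded from both counts
  answered <- trials[!is.na(trials$selected), ]
  if (nrow(answered) == 0) {
    return(tibble::tibble(target = character(), choice = character(),
                          presented = integer(), chosen = integer()))
  }
  long <- dplyr::bind_rows(
    tibble::tibble(target = answered$target, choice = answered$choice_a,
                   hit = answered$selected == answered$choice_a),
    tibble::tibble(target = answered$target, choice = answered$choice_b,
                   hit = answered$selected == answered$choice_b)
  )
  dplyr::summarise(dplyr::group_by(long, .data$target, .data$choice),
                   presented = dplyr::n(), chosen = sum(.data$hit),
                   .groups = "drop")
}

#' Percent-chosen table from forced-choice trials
#'
#' For the symmetric conditions (friend, rival) responses are aggregated
#' regardless of which contestant was the target: the dyad proportion is the
#' mean of the two directional proportions (X chosen when Y was the target,
#' and Y chosen when X was the target). If one direction was never presented
#' the other stands alone. Win responses are kept directional: the key is
#' (likely beater, target) and the proportion is chosen/presented for that
#' ordered pair. Missed responses count in neither numerator nor denominator.
#'
#' @param trials A validated trial tibble ([as_trials()]).
#' @param symmetric Optional logical overriding the per-condition default
#'   (friend/rival symmetric, win directional).
#' @param pool_blocks If `TRUE` (default) the two blocks of each condition
#'   are merged; if `FALSE` proportions are computed per block and the
#'   block's clip index is kept for the model-table merge.
#' @param method For symmetric conditions: `"mean"` (default) averages the
#'   two directional proportions; `"pooled"` divides summed chosen by summed
#'   presented counts. The two differ when directional denominators differ.
#' @return A tibble with one row per (participant, condition\[, clip\],
#'   dyad): `chosen` and `presented` are summed counts, `pct` the proportion
#'   in \[0, 1\] under the chosen aggregation rule.
#' @export
percent_chosen <- function(trials, symmetric = NULL, pool_blocks = TRUE,
                           method = c("mean", "pooled")) {
  method <- match.arg(method)
  trials <- as_trials(trials)
  group_cols <- c("participant", "condition", if (!pool_blocks) "clip")

  one_group <- function(df) {
    cond <- df$condition[1]
    sym <- if (is.null(symmetric)) cond %in% c("friend", "rival") else symmetric
    counts <- directional_counts(df)
    if (nrow(counts) == 0) return(tibble::tibble())
    if (sym) {
      counts$dyad <- dyad_key(counts$choice, counts$target)
      counts$dir_pct <- counts$chosen / counts$presented
      out <- dplyr::summarise(
        dplyr::group_by(counts, .data$dyad),
        chosen = sum(.data$chosen), presented = sum(.data$presented),
        pct = if (method == "mean") mean(.data$dir_pct) else
          sum(.data$chosen) / sum(.data$presented),
        .groups = "drop"
      )
    } else {
      out <- tibble::tibble(
        dyad = paste(counts$choice, counts$target, sep = ">"),
        chosen = counts$chosen, presented = counts$presented,
        pct = counts$chosen / counts$presented
      )
    }
    out
  }

  keys <- dplyr::distinct(trials[group_cols])
  res <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    df <- dplyr::semi_join(trials, keys[i, ], by = group_cols)
    tab <- one_group(df)
    if (nrow(tab)) res[[i]] <- dplyr::bind_cols(keys[rep(i, nrow(tab)), ], tab)
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    warning("no answered trials: percent-chosen table is empty")
    return(tibble::tibble(participant = character(), condition = character(),
                          dyad = character(), chosen = integer(),
                          presented = integer(), pct = numeric()))
  }
  dplyr::arrange(out, dplyr::across(dplyr::all_of(c(group_cols, "dyad"))))
}

#' Response vector over the canonical dyad order
#'
#' Lays a participant's percent-chosen values for one condition out over the
#' canonical key order ([canonical_dyads()]): length `choose(n, 2)` for the
#' symmetric conditions, `n * (n - 1)` for win. Keys the participant was
#' never presented are `NA`, never zero-filled.
#'
#' @param table A percent-chosen table from [percent_chosen()] (pooled
#'   blocks).
#' @param participant Participant identifier present in `table`.
#' @param condition Condition name.
#' @param roster The [roster()] fixing the canonical order.
#' @return A named numeric vector of proportions with `NA` for absent keys.
#' @export
response_vector <- function(table, participant, condition, roster) {
  rows <- table[table$participant == participant & table$condition == condition, ]
  if (nrow(rows) == 0) {
    stop("participant ", participant, " has no rows for condition ", condition,
         call. = FALSE)
  }
  keys <- canonical_dyads(roster, directional = condition == "win")
  out <- stats::setNames(rep(NA_real_, length(keys)), keys)
  out[rows$dyad] <- rows$pct
  out
}

#' Response-vector matrix for all participants in a condition
#'
#' @inheritParams response_vector
#' @return A keys x participants numeric matrix (columns named by
#'   participant) suitable for [pairwise_similarity()].
#' @export
response_matrix <- function(table, condition, roster) {
  parts <- sort(unique(table$participant[table$condition == condition]))
  if (length(parts) == 0) stop("no participants for condition ", condition, call. = FALSE)
  vapply(parts, function(p) response_vector(table, p, condition, roster),
         numeric(length(canonical_dyads(roster, directional = condition == "win"))))
}
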