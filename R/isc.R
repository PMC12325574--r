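#' Participant-pairwise Pearson similarity matrix
#'
#' Correlates every pair of participants' response vectors over the keys
#' where both have defined values. Pairs sharing fewer than `min_shared`
#' keys, or where either vector is constant over the shared keys, get an
#' undefined (`NA`) entry; undefined entries are excluded from the median
#' summary, never zero-imputed.
#'
#' @param vectors A keys x participants numeric matrix (see
#'   [response_matrix()]) or a named list of equal-length numeric vectors.
#' @param min_shared Minimum number of shared defined keys per pair
#'   (default 3).
#' @return A symmetric participants x participants correlation matrix with
#'   unit diagonal where defined.
#' @export
pairwise_similarity <- function(vectors, min_shared = 3) {
  m <- if (is.list(vectors)) do.call(cbind, vectors) else as.matrix(vectors)
  np <- ncol(m)
  if (np < 2) stop("need at least 2 participants", call. = FALSE)
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  shared <- crossprod(!is.na(m))          # pairwise counts of shared keys
  r[shared < min_shared] <- NA_real_
  ## a constant vector over the shared keys yields NA from cor() already;
  ## restore the unit diagonal for participants with any defined values
  diag(r)[colSums(!is.na(m)) > 0] <- 1
  r
}

lower_tri_values <- function(matrix) matrix[lower.tri(matrix)]

#' Median pairwise similarity
#'
#' Summarizes a response-similarity matrix by the median (and SD) of its
#' defined strictly-lower-triangle entries.
#'
#' @param matrix Output of [pairwise_similarity()].
#' @return A list with `median`, `sd`, `n_pairs` (defined pairs), and
#'   `n_undefined` (excluded pairs).
#' @export
median_similarity <- function(matrix) {
  vals <- lower_tri_values(matrix)
  defined <- vals[!is.na(vals)]
  if (length(defined) == 0) stop("no defined pairwise similarities", call. = FALSE)
  list(median = stats::median(defined), sd = stats::sd(defined),
       n_pairs = length(defined), n_undefined = sum(is.na(vals)))
}

resample_columns <- function(m, method) {
  ## one null draw: disrupt the dyad alignment across participants while
  ## preserving each participant's own value distribution and NA pattern
  for (j in seq_len(ncol(m))) {
    idx <- which(!is.na(m[, j]))
    if (length(idx) > 1) {
      vals <- m[idx, j]
      m[idx, j] <- if (method == "resample") {
        sample(vals, length(idx), replace = TRUE)
      } else {
        sample(vals)                      # label permutation within participant
      }
    }
  }
  m
}

#' Intersubject correlation with a bootstrap null distribution
#'
#' Computes the observed median pairwise similarity, then builds a null
#' distribution by `B` iterations in which every participant's vector is
#' independently shuffled and resampled with replacement from that
#' participant's own observed percent-chosen values (destroying the dyad
#' alignment between participants), recomputing the pairwise matrix and its
#' median each time. The p-value is the proportion of null medians falling
#' at or above the observed median (no +1 correction by default).
#'
#' @inheritParams pairwise_similarity
#' @param B Number of null iterations (the full analysis uses 10,000; tests
#'   use fewer).
#' @param seed Integer seed; the whole procedure is reproducible under it.
#' @param method `"resample"` (default: within-participant resampling with
#'   replacement) or `"permute"` (within-participant permutation), exposed
#'   for sensitivity analysis.
#' @param small_sample_correction If `TRUE`, use the (B+1) rule:
#'   `p = (1 + #{null >= obs}) / (B + 1)`.
#' @return An object of class `convrel_isc`: the similarity `matrix`,
#'   `observed_median`, `observed_sd`, `boot_medians`, `p_value`, `B`,
#'   `seed`, and exclusion counts.
#' @export
bootstrap_null <- function(vectors, B = 10000, seed,
                           method = c("resample", "permute"),
                           min_shared = 3, small_sample_correction = FALSE) {
  method <- match.arg(method)
  if (B < 1) stop("B must be at least 1", call. = FALSE)
  if (missing(seed)) stop("a seed is required for reproducibility", call. = FALSE)
  m <- if (is.list(vectors)) do.call(cbind, vectors) else as.matrix(vectors)
  if (nrow(m) < 3) stop("response vectors must have length >= 3", call. = FALSE)
  mat <- pairwise_similarity(m, min_shared = min_shared)
  obs <- median_similarity(mat)
  boot <- withr::with_seed(seed, vapply(seq_len(B), function(b) {
    null_m <- resample_columns(m, method)
    median_similarity(pairwise_similarity(null_m, min_shared = min_shared))$median
  }, numeric(1)))
  p <- if (small_sample_correction) (1 + sum(boot >= obs$median)) / (B + 1)
  else mean(boot >= obs$median)
  structure(
    list(matrix = mat, observed_median = obs$median, observed_sd = obs$sd,
         n_pairs = obs$n_pairs, n_undefined = obs$n_undefined,
         boot_medians = boot, p_value = p, B = as.integer(B),
         seed = as.integer(seed), method = method),
    class = "convrel_isc"
  )
}

#' @export
print.convrel_isc <- function(x, ...) {
  cat("<convrel_isc> median r = ", format(round(x$observed_median, 3)),
      " (SD = ", format(round(x$observed_sd, 3)), ", ", x$n_pairs, " pairs)\n",
      "  p = ", format(x$p_value), " from B = ", x$B,
      " null iterations (", x$method, ", seed ", x$seed, ")\n", sep = "")
  if (x$n_undefined > 0) cat("  ", x$n_undefined, " undefined pair(s) excluded\n", sep = "")
  invisible(x)
}

#' Serialize an ISC result to JSON (plus optional matrix TSV)
#'
#' @param x A `convrel_isc` object.
#' @param path Output JSON path.
#' @param matrix_path Optional TSV path for the similarity matrix.
#' @return `path`, invisibly.
#' @export
write_isc <- function(x, path, matrix_path = NULL) {
  stopifnot(inherits(x, "convrel_isc"))
  jsonlite::write_json(
    list(observed_median = x$observed_median, observed_sd = x$observed_sd,
         p_value = x$p_value, B = x$B, seed = x$seed, method = x$method,
         n_pairs = x$n_pairs, n_undefined = x$n_undefined),
    path, auto_unbox = TRUE, digits = NA)
  if (!is.null(matrix_path)) {
    m <- x$matrix
    if (is.null(colnames(m))) {
      dimnames(m) <- list(paste0("p", seq_len(nrow(m))), paste0("p", seq_len(ncol(m))))
    }
    readr::write_tsv(tibble::as_tibble(m, rownames = "participant"),
                     matrix_path, progress = FALSE)
  }
  invisible(path)
}
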