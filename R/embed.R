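## Deterministic hashed bag-of-words embedder. Two independent polynomial
## rolling hashes over the token's characters give the bucket and the sign;
## all arithmetic stays below 2^53 so results are exact and identical across
## platforms.

token_hash <- function(token, base, modulus) {
  codes <- utf8ToInt(token)
  h <- 0
  for (code in codes) h <- (h * base + code) %% modulus
  h
}

#' Deterministic hashed bag-of-words sentence embedder
#'
#' The default embedding backend: each token is hashed into one of `dim`
#' buckets with a +/-1 sign from a second hash, and token counts are
#' accumulated. The result is a fixed-dimension sparse-ish vector whose
#' cosine similarity reflects token overlap between texts. The default
#' dimension of 512 mirrors common pre-trained sentence encoders. Embedding
#' the same text always yields bit-identical vectors — no model weights, no
#' randomness.
#'
#' Any backend with fields `name`, `dim`, and `embed(text) -> numeric(dim)`
#' satisfies the embedder contract; a pre-trained encoder can be plugged in
#' through the same interface.
#'
#' @param dim Positive embedding dimension (default 512).
#' @return A list of class `convrel_embedder` with `name`, `dim`, `embed`.
#' @export
hash_embedder <- function(dim = 512L) {
  dim <- as.integer(dim)
  stopifnot(dim >= 1)
  embed <- function(text) {
    tokens <- tokenize(paste(text, collapse = " "))
    v <- numeric(dim)
    for (tok in tokens) {
      bucket <- token_hash(tok, base = 31, modulus = 1048573) %% dim + 1
      sign <- if (token_hash(tok, base = 131, modulus = 524287) %% 2 == 0) 1 else -1
      v[bucket] <- v[bucket] + sign
    }
    v
  }
  structure(list(name = paste0("hash-bow-", dim), dim = dim, embed = embed),
            class = "convrel_embedder")
}

#' Cosine similarity between two vectors
#'
#' @param u,v Numeric vectors of equal length with non-zero norms.
#' @return The cosine of the angle between `u` and `v`, in \[-1, 1\].
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length", call. = FALSE)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("cosine similarity is undefined for a zero-norm vector", call. = FALSE)
  }
  sum(u * v) / (nu * nv)
}

#' Semantic similarity of a dyad's conversation
#'
#' Measures how similar the two sides of a dyadic conversation are. In
#' `pooled` mode (default) everything A said to B is concatenated into one
#' chunk, everything B said to A into another, and the cosine similarity of
#' the two chunk embeddings is returned — text chunks may span many
#' sentences. In `crosspair_mean` mode the cosine is averaged over all
#' (A-to-B sentence, B-to-A sentence) pairs instead. The score is undefined
#' (`NA`) unless both directions contain at least one utterance: one-sided
#' talk is the absence of a dyadic interaction, not an error.
#'
#' @param utterances A validated utterance tibble (any window).
#' @param dyad Length-2 character vector of contestant identifiers.
#' @param backend An embedder (see [hash_embedder()]).
#' @param mode `"pooled"` or `"crosspair_mean"`.
#' @return A similarity in \[-1, 1\], or `NA_real_` when undefined.
#' @export
dyad_similarity <- function(utterances, dyad, backend = hash_embedder(),
                            mode = c("pooled", "crosspair_mean")) {
  mode <- match.arg(mode)
  stopifnot(length(dyad) == 2)
  dy <- filter_dialogue(utterances, "specific", dyad = dyad)
  ab <- dy$text[dy$speaker == dyad[1]]
  ba <- dy$text[dy$speaker == dyad[2]]
  if (length(ab) == 0 || length(ba) == 0) return(NA_real_)
  if (mode == "pooled") {
    cosine_similarity(backend$embed(paste(ab, collapse = " ")),
                      backend$embed(paste(ba, collapse = " ")))
  } else {
    pairs <- expand.grid(i = seq_along(ab), j = seq_along(ba))
    ea <- lapply(ab, backend$embed)
    eb <- lapply(ba, backend$embed)
    mean(mapply(function(i, j) cosine_similarity(ea[[i]], eb[[j]]),
                pairs$i, pairs$j))
  }
}
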