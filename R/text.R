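# Pluggable text-encoder contract and the hashing reference encoder.
#
# The embedding model only requires a deterministic map text -> R^d_text.
# In production that slot is filled by a frozen pretrained language model;
# the signed-hashing bag-of-tokens encoder below is a lightweight,
# dependency-free reference implementation carrying enough lexical signal
# for retrieval and testing.

.tokenize <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

# deterministic 31-adic rolling hash, stable across platforms
.hash_token <- function(token, seed) {
  h <- (seed * 2654435761) %% 2147483647
  for (code in utf8ToInt(token)) h <- (h * 31 + code) %% 2147483647
  h
}

#' Signed-hashing text encoder
#'
#' Tokenizes on whitespace/punctuation, lower-cases, and hashes each token
#' into one of `d_text` signed buckets (feature hashing); the bucket vector
#' is L2-normalised. A bag-of-tokens map: word order is ignored, equal texts
#' always yield equal features.
#'
#' @param text character scalar.
#' @param d_text feature width (>= 8; default 768 to match a typical
#'   language-model feature size).
#' @param seed integer mixed into the hash, fixing the random projection.
#' @return Numeric vector of length `d_text`; the zero vector (padding kind)
#'   for empty text.
#' @export
hash_encode <- function(text, d_text = 768L, seed = 0L) {
  stopifnot(d_text >= 8L)
  v <- numeric(d_text)
  if (is.na(text)) return(v)
  toks <- .tokenize(text)
  if (!length(toks)) return(v)
  for (tok in toks) {
    h1 <- .hash_token(tok, seed)
    h2 <- .hash_token(tok, seed + 101L)
    b <- (h1 %% d_text) + 1L
    s <- if (h2 %% 2 == 0) 1 else -1
    v[b] <- v[b] + s
  }
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v <- v / nrm
  v
}

#' Construct a text encoder object
#'
#' The encoder contract used by the model: a list with `d_text` and
#' `encode(texts)` returning one feature row per text. Only the hashing
#' reference encoder is built in; any frozen external encoder satisfying
#' the contract can be plugged in via `encode_fun`.
#'
#' @param kind "hash" or "custom".
#' @param d_text feature width.
#' @param seed hashing seed.
#' @param encode_fun for `kind = "custom"`, a function(character) -> matrix.
#' @return An object of class `ed_text_encoder`.
#' @export
text_encoder <- function(kind = c("hash", "custom"), d_text = 768L, seed = 0L,
                         encode_fun = NULL) {
  kind <- match.arg(kind)
  enc <- if (kind == "hash") {
    function(texts) {
      out <- t(vapply(texts, hash_encode, numeric(d_text),
                      d_text = d_text, seed = seed))
      rownames(out) <- NULL
      out
    }
  } else {
    stopifnot(is.function(encode_fun))
    encode_fun
  }
  structure(list(kind = kind, d_text = as.integer(d_text), seed = seed,
                 encode = enc),
            class = "ed_text_encoder")
}

#' Average history features with padding
#'
#' The variable number of past-history features of one visit is reduced to
#' a single vector by the element-wise mean. A visit without history gets
#' the padding vector (all zeros) and a validity flag of 0 so the model can
#' mask the slot.
#'
#' @param features matrix with one feature per row (0 rows = no history),
#'   or a list of equal-length vectors.
#' @param padding padding vector (default zeros).
#' @return list with `feature` (vector) and `valid` (0 or 1).
#' @export
history_mean <- function(features, padding = NULL) {
  if (is.list(features) && !is.data.frame(features)) {
    d <- unique(vapply(features, length, 1L))
    if (length(d) > 1L) stop("DIM_MISMATCH: history features differ in length")
    features <- if (length(features)) do.call(rbind, features) else
      matrix(0, 0L, if (length(d)) d else length(padding))
  }
  if (is.null(padding)) padding <- numeric(ncol(features))
  if (length(padding) != ncol(features) && nrow(features) > 0L)
    stop("DIM_MISMATCH: padding length differs from feature width")
  if (nrow(features) == 0L) return(list(feature = padding, valid = 0L))
  list(feature = colMeans(features), valid = 1L)
}

#' Contrastive loss over paired text features
#'
#' NT-Xent loss over 2B features where (anchor_i, positive_i) are two views
#' of the same patient's text (for example chief complaint vs present
#' illness, or two history subsets) and every other feature in the batch is
#' a negative. Identical formula to [simclr_loss()] (shared implementation).
#'
#' @param anchor_feats B x d matrix.
#' @param positive_feats B x d matrix, row-aligned with `anchor_feats`.
#' @param temperature softmax temperature.
#' @return Scalar loss.
#' @export
text_pair_contrastive_loss <- function(anchor_feats, positive_feats,
                                       temperature = 0.5) {
  simclr_loss(anchor_feats, positive_feats, temperature)
}
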