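# Embedding index, cosine top-k retrieval, hit scoring, and 2-D maps.

#' Build an embedding index
#'
#' @param embeddings n x d matrix (no zero-norm rows).
#' @param visit_ids identifiers parallel to the rows (defaults to the
#'   matrix rownames).
#' @param labels optional per-entry label (for hit scoring).
#' @return An object of class `ed_index`.
#' @export
build_index <- function(embeddings, visit_ids = rownames(embeddings), labels = NULL) {
  embeddings <- as.matrix(embeddings)
  if (is.null(visit_ids)) stop("visit_ids required")
  if (length(visit_ids) != nrow(embeddings)) stop("one id per embedding row")
  nr <- sqrt(rowSums(embeddings^2))
  if (any(nr == 0)) stop("zero-norm embedding rows not allowed")
  structure(list(E = embeddings / nr, visit_ids = as.character(visit_ids),
                 labels = labels),
            class = "ed_index")
}

#' Retrieve the k most similar visits
#'
#' Exact brute-force cosine search: returns the `k` index entries with the
#' greatest cosine similarity to the query, in descending order;
#' similarity ties are broken by ascending visit id for determinism.
#'
#' @param index an `ed_index`.
#' @param q query embedding (non-zero vector of matching width).
#' @param k number of neighbours.
#' @return data.frame with columns `visit_id`, `similarity` (and `label`
#'   when the index has labels).
#' @export
query_topk <- function(index, q, k = 5L) {
  if (!inherits(index, "ed_index") || !nrow(index$E)) stop("empty index")
  stopifnot(k >= 1L, k <= nrow(index$E))
  q <- as.numeric(q)
  nq <- sqrt(sum(q^2))
  if (nq == 0) stop("zero-norm query")
  sim <- as.numeric(index$E %*% (q / nq))
  ord <- order(-sim, index$visit_ids)[seq_len(k)]
  out <- data.frame(visit_id = index$visit_ids[ord], similarity = sim[ord],
                    stringsAsFactors = FALSE)
  if (!is.null(index$labels)) out$label <- index$labels[ord]
  out
}

#' Top-5 hit score
#'
#' Number of the five retrieved entries whose label matches the query's
#' label (0-5): the label-based surrogate for a clinician's relevance
#' judgment of the retrieval list.
#'
#' @param retrieved_labels exactly five labels.
#' @param query_label the query's label.
#' @return Integer in 0..5.
#' @export
hit_score <- function(retrieved_labels, query_label) {
  if (length(retrieved_labels) != 5L) stop("exactly 5 retrieved labels required")
  sum(retrieved_labels == query_label)
}

#' Mean retrieval precision@5 against labels
#'
#' Convenience wrapper: each query embedding retrieves its top 5 among the
#' other entries (self excluded) and is scored by label agreement.
#'
#' @param embeddings n x d matrix with rownames.
#' @param labels per-row label.
#' @param n_queries number of (seeded) random queries.
#' @param seed RNG seed.
#' @return Mean hit score divided by 5, in [0, 1].
#' @export
retrieval_precision <- function(embeddings, labels, n_queries = 100L, seed = 1L) {
  set.seed(seed)
  qs <- sample.int(nrow(embeddings), min(n_queries, nrow(embeddings)))
  scores <- vapply(qs, function(i) {
    idx <- build_index(embeddings[-i, , drop = FALSE],
                       rownames(embeddings)[-i], labels[-i])
    top <- query_topk(idx, embeddings[i, ], 5L)
    hit_score(top$label, labels[i]) / 5
  }, numeric(1))
  mean(scores)
}

#' 2-D t-SNE projection
#'
#' Exact (quadratic) t-distributed stochastic neighbor embedding:
#' per-point bandwidths tuned to the target perplexity by bisection,
#' symmetrised input affinities, early exaggeration, and momentum gradient
#' descent on the Student-t low-dimensional affinities. Deterministic for
#' a fixed seed. Suitable for desk-scale n (a few thousand points).
#'
#' @param embeddings n x d matrix (n >= 5).
#' @param seed RNG seed for the initial layout.
#' @param perplexity effective neighbourhood size.
#' @param max_iter gradient-descent iterations.
#' @return n x 2 coordinate matrix.
#' @export
tsne_project <- function(embeddings, seed = 1L, perplexity = 30, max_iter = 400L) {
  X <- as.matrix(embeddings)
  n <- nrow(X)
  if (n < 5L) stop("need at least 5 points")
  perplexity <- min(perplexity, (n - 1) / 3)
  D <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D[i, -i]
    for (it in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      H <- log(sp) + beta * sum(di * p) / sp
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p / sp
  }
  P <- (P + t(P)) / (2 * n)
  P[P < 1e-12] <- 1e-12
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, 0, 1e-4), n, 2L)
  G <- matrix(0, n, 2L)
  gains <- matrix(1, n, 2L)
  for (iter in seq_len(max_iter)) {
    ex <- if (iter <= 100L) 4 else 1
    mom <- if (iter <= 250L) 0.5 else 0.8
    sq <- rowSums(Y^2)
    num <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < 1e-12] <- 1e-12
    L <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    G <- mom * G - 200 * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  Y
}

#' Plot a 2-D embedding map coloured by a covariate
#'
#' Companion visualisation for [tsne_project()]: colours points by a
#' demographic or clinical grouping (gender, age decade, triage level,
#' outcome, latent cluster, ...).
#'
#' @param coords n x 2 coordinates.
#' @param colour_by factor-like vector of length n.
#' @param main plot title.
#' @export
plot_embedding_map <- function(coords, colour_by, main = "embedding map") {
  f <- factor(colour_by)
  pal <- grDevices::hcl.colors(max(3L, nlevels(f)), "Dark 3")
  graphics::plot(coords[, 1L], coords[, 2L], col = pal[as.integer(f)],
                 pch = 16L, cex = 0.6, xlab = "dim 1", ylab = "dim 2",
                 main = main)
  graphics::legend("topright", legend = levels(f),
                   col = pal[seq_len(nlevels(f))], pch = 16L, cex = 0.7)
  invisible(NULL)
}
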