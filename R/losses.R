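# The three self-supervised pretraining objectives and their combination.

#' Deep InfoMax noise-contrastive loss
#'
#' Given the B x B matrix of discriminator probabilities `scores[i, j] =
#' p(eps_i | m_j)`, the loss is the mean binary cross-entropy over all B^2
#' pairs with target 1 on the diagonal (the embedding belongs to the visit)
#' and 0 off-diagonal. Minimising it maximises the mutual-information lower
#' bound: the loss tends to 0 only as diagonal scores tend to 1 and
#' off-diagonal scores to 0.
#'
#' @param scores B x B matrix of probabilities strictly inside (0, 1).
#' @return Scalar loss; `log(2)` when every score is 0.5.
#' @export
dim_nce_loss <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) != ncol(scores) || nrow(scores) < 2L)
    stop("scores must be a square matrix with B >= 2")
  if (any(scores <= 0) || any(scores >= 1))
    stop("scores must lie strictly inside (0, 1)")
  y <- diag(nrow(scores))
  -mean(y * log(scores) + (1 - y) * log(1 - scores))
}

#' SimCLR (NT-Xent) contrastive loss
#'
#' For the 2B embeddings formed by two augmented views of each batch item,
#' each anchor's positive is its other view and every remaining embedding a
#' negative; the loss is the mean softmax cross-entropy of temperature-scaled
#' cosine similarities. Invariant to rescaling of the embeddings (cosine) and
#' to permutations of the pair index.
#'
#' @param z,z_prime B x d matrices of paired embeddings (B >= 2).
#' @param temperature positive softmax temperature (tau).
#' @return Scalar loss.
#' @export
simclr_loss <- function(z, z_prime, temperature = 0.5) {
  z <- as.matrix(z); z_prime <- as.matrix(z_prime)
  stopifnot(temperature > 0, ncol(z) == ncol(z_prime))
  B <- nrow(z)
  if (B < 2L || nrow(z_prime) != B)
    stop("NEED_NEGATIVES: need B >= 2 aligned pairs")
  U <- rbind(z, z_prime)
  nr <- sqrt(rowSums(U^2))
  if (any(nr == 0)) stop("ZERO_VECTOR: zero-norm embedding")
  U <- U / nr
  S <- tcrossprod(U) / temperature
  diag(S) <- -Inf
  pos <- c(B + seq_len(B), seq_len(B))
  mx <- apply(S, 1L, max)
  lse <- log(rowSums(exp(S - mx))) + mx
  mean(lse - S[cbind(seq_len(2L * B), pos)])
}

#' Adversarial uniform-prior losses
#'
#' A linear domain discriminator L_DD (one linear layer + sigmoid over the
#' d_hidden input) is trained to tell Uniform[-1,1]^d prior draws (target 1)
#' from encoder embeddings (target 0); the encoder's generator objective is
#' the non-saturating form -log D(eps). At the adversarial equilibrium
#' (embedding distribution equal to the prior, chance-level discriminator)
#' the discriminator loss equals log(2).
#'
#' @param eps_batch B x d matrix of embeddings.
#' @param prior_batch B x d matrix of i.i.d. Uniform[-1,1] draws.
#' @param ldd list with `W` (d x 1) and `b` (scalar), the L_DD parameters.
#' @return list with `disc_loss` (trains only L_DD) and `gen_loss` (trains
#'   only the encoder).
#' @export
prior_adversarial_losses <- function(eps_batch, prior_batch, ldd) {
  eps_batch <- as.matrix(eps_batch); prior_batch <- as.matrix(prior_batch)
  stopifnot(ncol(eps_batch) == ncol(prior_batch),
            nrow(eps_batch) == nrow(prior_batch))
  W <- matrix(as.numeric(ldd$W), ncol = 1L); b <- as.numeric(ldd$b)
  d_eps <- stats::plogis(as.numeric(eps_batch %*% W) + b)
  d_pri <- stats::plogis(as.numeric(prior_batch %*% W) + b)
  list(disc_loss = -mean(c(log(d_pri), log(1 - d_eps))),
       gen_loss = -mean(log(d_eps)))
}

#' Combine the pretraining loss parts
#'
#' The encoder objective is `total = dim_nce + gamma * prior_gen + simclr`:
#' the DIM loss carries its gamma-weighted prior-matching term, and the
#' SimCLR loss is added on top. The discriminator-side prior loss is
#' optimised in the alternating adversarial step and never enters the
#' total.
#'
#' @param parts list with `dim_nce`, `prior_gen`, `simclr` and optionally
#'   `prior_disc`.
#' @param gamma weight of the generator-side prior term (default 0.1).
#' @return list of class `ed_loss_parts` with the components and `total`.
#' @export
total_pretrain_loss <- function(parts, gamma = 0.1) {
  total <- parts$dim_nce + gamma * parts$prior_gen + parts$simclr
  structure(list(dim_nce = parts$dim_nce, prior_gen = parts$prior_gen,
                 prior_disc = parts$prior_disc %||% NA_real_,
                 simclr = parts$simclr, gamma = gamma, total = total),
            class = "ed_loss_parts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
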