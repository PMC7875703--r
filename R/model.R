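# Transformer disease-embedding encoder and its projection heads.
#
# Architecture: the 15 structural fields are projected by an MLP (L_S) and
# the chief-complaint / mean-history text features by a shared MLP (L_B)
# into d_hidden-dimensional tokens; the sequence [CLS], M_S, M_CC, M_Hx
# (plus learned position and segment embeddings) is encoded by a post-norm
# Transformer stack; the embedding is the elementwise tanh of the final
# [CLS] row, bounding every coordinate in [-1, 1] so matching the
# Uniform[-1,1]^d prior is well-posed.

#' Model configuration
#'
#' Defaults mirror the full-scale model (12 layers, 12 heads, hidden size
#' 96, 768-dimensional text features). `preset = "small"` is the desk-scale
#' test configuration (hidden 32, 2 layers, 4 heads).
#'
#' @param d_hidden embedding width (divisible by `n_heads`).
#' @param n_layers,n_heads Transformer depth and head count.
#' @param d_text text-feature width fed to L_B.
#' @param history_mask_prob probability that augmentation hides the history
#'   slot (forces the attention mask bit to 0).
#' @param noise_fraction augmentation noise scale, in units of the per-field
#'   training SD.
#' @param dropout dropout rate during pretraining/finetuning.
#' @param d_ff feed-forward width (default 4 x d_hidden, BERT-style).
#' @param preset NULL or "small".
#' @return An object of class `ed_config`.
#' @export
ed_config <- function(d_hidden = 96L, n_layers = 12L, n_heads = 12L,
                      d_text = 768L, history_mask_prob = 0.15,
                      noise_fraction = 0.1, dropout = 0.1, d_ff = NULL,
                      preset = NULL) {
  if (identical(preset, "small")) {
    d_hidden <- 32L; n_layers <- 2L; n_heads <- 4L
  }
  if (is.null(d_ff)) d_ff <- 4L * d_hidden
  stopifnot(d_hidden %% n_heads == 0L)
  structure(list(d_hidden = as.integer(d_hidden), n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads), d_text = as.integer(d_text),
                 d_struct = 15L, history_mask_prob = history_mask_prob,
                 noise_fraction = noise_fraction, dropout = dropout,
                 d_ff = as.integer(d_ff)),
            class = "ed_config")
}

# flat named parameter list; names are dot-paths so optimizer state maps 1:1
ed_init_params <- function(config, seed = 1L, sd = 0.02) {
  set.seed(seed)
  d <- config$d_hidden
  p <- list()
  rn <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
  zr <- function(nc) matrix(0, 1L, nc)
  on1 <- function(nc) matrix(1, 1L, nc)
  p[["ls.W1"]] <- rn(config$d_struct, 64L); p[["ls.b1"]] <- zr(64L)
  p[["ls.W2"]] <- rn(64L, d);              p[["ls.b2"]] <- zr(d)
  p[["lb.W1"]] <- rn(config$d_text, 256L); p[["lb.b1"]] <- zr(256L)
  p[["lb.W2"]] <- rn(256L, d);             p[["lb.b2"]] <- zr(d)
  blocks <- function(prefix, n_tok) {
    p[[paste0(prefix, ".cls")]] <<- rn(1L, d)
    p[[paste0(prefix, ".pos")]] <<- rn(n_tok, d)
    p[[paste0(prefix, ".seg")]] <<- rn(2L, d)
    for (l in seq_len(config$n_layers)) {
      pre <- sprintf("%s.L%d.", prefix, l)
      for (w in c("Wq", "Wk", "Wv", "Wo")) p[[paste0(pre, w)]] <<- rn(d, d)
      for (b in c("bq", "bk", "bv", "bo")) p[[paste0(pre, b)]] <<- zr(d)
      p[[paste0(pre, "ln1g")]] <<- on1(d); p[[paste0(pre, "ln1b")]] <<- zr(d)
      p[[paste0(pre, "ffW1")]] <<- rn(d, config$d_ff); p[[paste0(pre, "ffb1")]] <<- zr(config$d_ff)
      p[[paste0(pre, "ffW2")]] <<- rn(config$d_ff, d); p[[paste0(pre, "ffb2")]] <<- zr(d)
      p[[paste0(pre, "ln2g")]] <<- on1(d); p[[paste0(pre, "ln2b")]] <<- zr(d)
    }
  }
  blocks("enc", 4L)
  blocks("disc", 6L)
  p[["disc.sep"]] <- rn(1L, d)
  p[["disc.outW"]] <- rn(d, 1L); p[["disc.outb"]] <- zr(1L)
  p[["ldd.W"]] <- rn(d, 1L); p[["ldd.b"]] <- zr(1L)
  p[["head.W1"]] <- rn(d, 32L); p[["head.b1"]] <- zr(32L)
  p[["head.W2"]] <- rn(32L, 1L); p[["head.b2"]] <- zr(1L)
  p
}

.group_names <- function(params, groups) {
  nm <- names(params)
  nm[grepl(paste0("^(", paste(groups, collapse = "|"), ")\\."), nm)]
}

# ---- tape forwards ---------------------------------------------------------

.tp_mlp2 <- function(tp, x, pid, prefix) {
  h <- tp_gelu(tp, tp_addrow(tp, tp_mm(tp, x, pid[[paste0(prefix, ".W1")]]),
                             pid[[paste0(prefix, ".b1")]]))
  tp_addrow(tp, tp_mm(tp, h, pid[[paste0(prefix, ".W2")]]),
            pid[[paste0(prefix, ".b2")]])
}

# post-norm Transformer stack over a token-major (n_tok*B) x d matrix
.tp_stack <- function(tp, x, pid, prefix, cfg, mask, n_tok, drop = NULL) {
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("%s.L%d.", prefix, l)
    q <- tp_addrow(tp, tp_mm(tp, x, pid[[paste0(pre, "Wq")]]), pid[[paste0(pre, "bq")]])
    k <- tp_addrow(tp, tp_mm(tp, x, pid[[paste0(pre, "Wk")]]), pid[[paste0(pre, "bk")]])
    v <- tp_addrow(tp, tp_mm(tp, x, pid[[paste0(pre, "Wv")]]), pid[[paste0(pre, "bv")]])
    a <- tp_mha(tp, q, k, v, mask, cfg$n_heads, n_tok)
    o <- tp_addrow(tp, tp_mm(tp, a, pid[[paste0(pre, "Wo")]]), pid[[paste0(pre, "bo")]])
    if (!is.null(drop)) o <- drop(o)
    x <- tp_layernorm(tp, tp_add(tp, x, o), pid[[paste0(pre, "ln1g")]], pid[[paste0(pre, "ln1b")]])
    f <- tp_gelu(tp, tp_addrow(tp, tp_mm(tp, x, pid[[paste0(pre, "ffW1")]]), pid[[paste0(pre, "ffb1")]]))
    f <- tp_addrow(tp, tp_mm(tp, f, pid[[paste0(pre, "ffW2")]]), pid[[paste0(pre, "ffb2")]])
    if (!is.null(drop)) f <- drop(f)
    x <- tp_layernorm(tp, tp_add(tp, x, f), pid[[paste0(pre, "ln2g")]], pid[[paste0(pre, "ln2b")]])
  }
  x
}

.tok_embed <- function(tp, tok, pid, prefix, pos_row, seg_level) {
  tok <- tp_addrow(tp, tok, tp_rows(tp, pid[[paste0(prefix, ".pos")]], pos_row))
  tp_addrow(tp, tok, tp_rows(tp, pid[[paste0(prefix, ".seg")]], seg_level + 1L))
}

# full encoder forward; returns node ids for eps and the projected tokens
.tp_encoder <- function(tp, pid, cfg, S, CC, HX, hx_valid, drop = NULL) {
  B <- nrow(S)
  s_id <- tp_const(tp, S)
  cc_id <- tp_const(tp, CC)
  hx_id <- tp_const(tp, HX)
  ms <- .tp_mlp2(tp, s_id, pid, "ls")
  mcc <- .tp_mlp2(tp, cc_id, pid, "lb")
  mhx <- .tp_mlp2(tp, hx_id, pid, "lb")
  toks <- list(.tok_embed(tp, tp_tile(tp, pid[["enc.cls"]], B), pid, "enc", 1L, 0L),
               .tok_embed(tp, ms, pid, "enc", 2L, 0L),
               .tok_embed(tp, mcc, pid, "enc", 3L, 0L),
               .tok_embed(tp, mhx, pid, "enc", 4L, 0L))
  x <- tp_rbind(tp, toks)
  mask <- cbind(1, 1, 1, as.numeric(hx_valid))
  x <- .tp_stack(tp, x, pid, "enc", cfg, mask, 4L, drop)
  eps <- tp_tanh(tp, tp_rows(tp, x, seq_len(B)))
  list(eps = eps, ms = ms, mcc = mcc, mhx = mhx)
}

# discriminator forward over rows of (eps, tokens) pairs; returns logit node
.tp_discriminator <- function(tp, pid, cfg, eps, ms, mcc, mhx, hx_valid, drop = NULL) {
  B <- nrow(tp_val(tp, eps))
  toks <- list(.tok_embed(tp, tp_tile(tp, pid[["disc.cls"]], B), pid, "disc", 1L, 0L),
               .tok_embed(tp, eps, pid, "disc", 2L, 0L),
               .tok_embed(tp, tp_tile(tp, pid[["disc.sep"]], B), pid, "disc", 3L, 1L),
               .tok_embed(tp, ms, pid, "disc", 4L, 1L),
               .tok_embed(tp, mcc, pid, "disc", 5L, 1L),
               .tok_embed(tp, mhx, pid, "disc", 6L, 1L))
  x <- tp_rbind(tp, toks)
  mask <- cbind(1, 1, 1, 1, 1, as.numeric(hx_valid))
  x <- .tp_stack(tp, x, pid, "disc", cfg, mask, 6L, drop)
  cls <- tp_rows(tp, x, seq_len(B))
  tp_addrow(tp, tp_mm(tp, cls, pid[["disc.outW"]]), pid[["disc.outb"]])
}

# ---- exported numeric surfaces --------------------------------------------

.const_pid <- function(tp, params) lapply(params, function(x) tp_const(tp, x))

#' Project structural vitals into token space
#'
#' Applies the structural MLP L_S (15 -> 64 -> d_hidden, GELU) to an
#' imputed structural vector or matrix.
#'
#' @param s length-15 vector or n x 15 matrix (no missing values).
#' @param params model parameters from the fitted model (`$params`).
#' @param config the model's `ed_config`.
#' @return n x d_hidden matrix.
#' @export
project_structural <- function(s, params, config) {
  if (is.null(dim(s))) s <- matrix(s, 1L)
  if (ncol(s) != config$d_struct) stop("expected ", config$d_struct, " structural fields")
  tp <- tp_new()
  pid <- .const_pid(tp, params[c("ls.W1", "ls.b1", "ls.W2", "ls.b2")])
  tp_val(tp, .tp_mlp2(tp, tp_const(tp, s), pid, "ls"))
}

#' Project a text feature into token space
#'
#' Applies the shared text MLP L_B (d_text -> 256 -> d_hidden, GELU); the
#' same network serves the chief-complaint and mean-history slots.
#'
#' @param f length-d_text vector or n x d_text matrix.
#' @inheritParams project_structural
#' @return n x d_hidden matrix.
#' @export
project_text <- function(f, params, config) {
  if (is.null(dim(f))) f <- matrix(f, 1L)
  if (ncol(f) != config$d_text) stop("expected d_text = ", config$d_text, " columns")
  tp <- tp_new()
  pid <- .const_pid(tp, params[c("lb.W1", "lb.b1", "lb.W2", "lb.b2")])
  tp_val(tp, .tp_mlp2(tp, tp_const(tp, f), pid, "lb"))
}

#' Assemble the encoder input sequence
#'
#' Builds the 4-token sequence [CLS], M_S, M_CC, M_Hx with position ids
#' 0..3, all segment ids 0, and attention mask (1, 1, 1, hx_valid): the
#' history slot is ignored whenever it holds padding.
#'
#' @param m_s,m_cc,m_hx n x d_hidden projected tokens.
#' @param hx_valid 0/1 vector: is the history slot real.
#' @inheritParams project_structural
#' @return list with `x` (token-major (4n) x d_hidden input embeddings:
#'   token + position + segment), `mask` (n x 4), `position_ids`,
#'   `segment_ids`.
#' @export
assemble_input <- function(m_s, m_cc, m_hx, hx_valid, params, config) {
  as_m <- function(v) if (is.null(dim(v))) matrix(v, 1L) else v
  m_s <- as_m(m_s); m_cc <- as_m(m_cc); m_hx <- as_m(m_hx)
  if (!all(c(ncol(m_s), ncol(m_cc), ncol(m_hx)) == config$d_hidden))
    stop("token width must equal d_hidden")
  B <- nrow(m_s)
  tp <- tp_new()
  pid <- .const_pid(tp, params[c("enc.cls", "enc.pos", "enc.seg")])
  toks <- list(.tok_embed(tp, tp_tile(tp, pid[["enc.cls"]], B), pid, "enc", 1L, 0L),
               .tok_embed(tp, tp_const(tp, m_s), pid, "enc", 2L, 0L),
               .tok_embed(tp, tp_const(tp, m_cc), pid, "enc", 3L, 0L),
               .tok_embed(tp, tp_const(tp, m_hx), pid, "enc", 4L, 0L))
  list(x = tp_val(tp, tp_rbind(tp, toks)),
       mask = cbind(1, 1, 1, as.numeric(hx_valid)),
       position_ids = 0:3, segment_ids = rep(0L, 4L))
}

#' Run the Transformer encoder on an assembled input
#'
#' @param assembled output of [assemble_input()].
#' @inheritParams project_structural
#' @return n x d_hidden embedding matrix; every coordinate lies in [-1, 1]
#'   (tanh of the final [CLS] row).
#' @export
embed_assembled <- function(assembled, params, config) {
  if (any(rowSums(assembled$mask) == 0)) stop("EMPTY_INPUT: attention mask is all zero")
  tp <- tp_new()
  pid <- .const_pid(tp, params)
  x <- tp_const(tp, assembled$x)
  x <- .tp_stack(tp, x, pid, "enc", config, assembled$mask, 4L)
  B <- nrow(assembled$mask)
  tp_val(tp, tp_tanh(tp, tp_rows(tp, x, seq_len(B))))
}

#' Discriminator score for an (embedding, input-tokens) pair
#'
#' The mutual-information discriminator: a Transformer (same architecture
#' as the encoder) over the sequence [CLS], embedding, [SEP], M_S, M_CC,
#' M_Hx with segment ids (0,0,1,1,1,1), read out as the sigmoid of a linear
#' map of the final [CLS] row. Estimates whether the embedding belongs to
#' the visit.
#'
#' @param eps n x d_hidden embeddings.
#' @param m_s,m_cc,m_hx n x d_hidden projected tokens (row-aligned pairs).
#' @param hx_valid 0/1 history-validity vector.
#' @inheritParams project_structural
#' @return Numeric vector of probabilities in (0, 1).
#' @export
dim_discriminator_score <- function(eps, m_s, m_cc, m_hx, hx_valid, params, config) {
  as_m <- function(v) if (is.null(dim(v))) matrix(v, 1L) else v
  eps <- as_m(eps)
  if (ncol(eps) != config$d_hidden) stop("embedding width must equal d_hidden")
  tp <- tp_new()
  pid <- .const_pid(tp, params)
  logit <- .tp_discriminator(tp, pid, config,
                             tp_const(tp, eps), tp_const(tp, as_m(m_s)),
                             tp_const(tp, as_m(m_cc)), tp_const(tp, as_m(m_hx)),
                             hx_valid)
  as.numeric(stats::plogis(tp_val(tp, logit)))
}

#' Augment a batch for contrastive training
#'
#' Two independent draws of this map give the SimCLR positive pair: (a)
#' additive Gaussian noise on the standardised structural matrix at scale
#' `noise_fraction` (per-field training SD units; the gender code is not
#' perturbed), and (b) with probability `history_mask_prob` the history
#' validity bit is forced to 0, hiding the history slot.
#'
#' @param batch list with `S` (n x 15 standardised structural matrix) and
#'   `hx_valid` (0/1 vector).
#' @param config `ed_config` supplying the augmentation rates.
#' @param seed optional local seed.
#' @return list with the augmented `S` and `hx_valid`.
#' @export
augment <- function(batch, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  S <- batch$S
  if (config$noise_fraction > 0) {
    noise <- matrix(stats::rnorm(length(S), 0, config$noise_fraction), nrow(S))
    noise[, colnames(S) == "gender"] <- 0
    S <- S + noise
  }
  hx <- batch$hx_valid
  if (config$history_mask_prob > 0)
    hx <- hx * (stats::runif(length(hx)) >= config$history_mask_prob)
  list(S = S, hx_valid = as.numeric(hx))
}
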