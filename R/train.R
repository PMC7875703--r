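# Pretraining loop (the model-fitting function), finetuning, and evaluation.

#' Training configuration
#'
#' Defaults follow the full-scale protocol (Adam, learning rate 1e-4,
#' minibatch 1024, gamma = 0.1). Desk-scale runs typically use
#' `batch_size = 64` and a larger learning rate.
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size (partial trailing batches are dropped:
#'   the contrastive losses need full batches of negatives).
#' @param epochs passes over the data.
#' @param seed integer seed controlling every random draw of the run.
#' @param gamma weight of the generator-side prior-matching term.
#' @param disc_steps_per_gen_step adversarial schedule: the domain
#'   discriminator is updated every batch, the encoder every k-th batch.
#' @param dim_negatives mismatched pairs sampled per anchor for the DIM
#'   noise-contrastive loss (subsampling of the B(B-1) off-diagonal pairs).
#' @param temperature SimCLR temperature tau.
#' @param use_dim,use_simclr,use_pretrain ablation switches; with
#'   `use_pretrain = FALSE` (or no objective enabled) the encoder keeps its
#'   random initialisation.
#' @return An object of class `ed_train_config`.
#' @export
ed_train_config <- function(learning_rate = 1e-4, batch_size = 1024L,
                            epochs = 10L, seed = 1L, gamma = 0.1,
                            disc_steps_per_gen_step = 1L, dim_negatives = 4L,
                            temperature = 0.5, use_dim = TRUE,
                            use_simclr = TRUE, use_pretrain = TRUE) {
  stopifnot(learning_rate > 0, batch_size >= 2L, temperature > 0)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 gamma = gamma, disc_steps_per_gen_step = as.integer(disc_steps_per_gen_step),
                 dim_negatives = as.integer(dim_negatives), temperature = temperature,
                 use_dim = isTRUE(use_dim), use_simclr = isTRUE(use_simclr),
                 use_pretrain = isTRUE(use_pretrain)),
            class = "ed_train_config")
}

# ---- Adam ------------------------------------------------------------------

.adam_new <- function() new.env(parent = emptyenv())

.adam_step <- function(st, params, grads, names, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- (st$t %||% 0L) + 1L
  t <- st$t
  for (nm in names) {
    g <- grads[[nm]]
    if (is.null(g)) next
    m <- st[[paste0("m.", nm)]] %||% array(0, dim(params[[nm]]))
    v <- st[[paste0("v.", nm)]] %||% array(0, dim(params[[nm]]))
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    st[[paste0("m.", nm)]] <- m
    st[[paste0("v.", nm)]] <- v
    mh <- m / (1 - b1^t); vh <- v / (1 - b2^t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  params
}

# ---- feature preparation ---------------------------------------------------

# standardised structural matrix + text features for a visit table
.prepare_features <- function(visits, stats, encoder) {
  S <- impute_and_perturb(vitals_matrix(visits), stats, 0)
  mu <- stats$mean[match(colnames(S), stats$field)]
  sd <- stats$sd[match(colnames(S), stats$field)]
  sd[is.na(sd) | sd == 0] <- 1
  S <- sweep(sweep(S, 2L, mu, "-"), 2L, sd, "/")
  colnames(S) <- vital_fields()

  hx_texts <- lapply(seq_len(nrow(visits)), function(i)
    select_history(visits$history[[i]], visits$triage_time[i]))
  all_texts <- unique(c(visits$chief_complaint, unlist(hx_texts)))
  all_texts <- all_texts[!is.na(all_texts)]
  feats <- encoder$encode(all_texts)
  lookup <- function(txt) feats[match(txt, all_texts), , drop = FALSE]
  CC <- lookup(visits$chief_complaint)
  CC[is.na(CC)] <- 0
  pad <- numeric(encoder$d_text)
  hx <- lapply(hx_texts, function(tt)
    history_mean(if (length(tt)) lookup(tt) else matrix(0, 0L, encoder$d_text), pad))
  HX <- do.call(rbind, lapply(hx, `[[`, "feature"))
  hx_valid <- vapply(hx, `[[`, 1L, "valid")
  list(S = S, CC = CC, HX = HX, hx_valid = as.numeric(hx_valid),
       visit_id = visits$visit_id)
}

# batch index sets: seeded shuffle, duplicates kept apart, partial batch dropped
.batch_plan <- function(keys, B) {
  n <- length(keys)
  perm <- sample.int(n)
  nb <- n %/% B
  if (nb == 0L) stop("batch_size exceeds the number of visits")
  for (b in seq_len(nb)) {
    lo <- (b - 1L) * B
    for (pos in seq_len(B)) {
      i <- lo + pos
      if (!keys[perm[i]] %in% keys[perm[lo + seq_len(pos - 1L)]]) next
      later <- if (lo + B < n) (lo + B + 1L):n else integer(0)
      ok <- later[!keys[perm[later]] %in% keys[perm[(lo + 1L):(lo + B)]]]
      if (length(ok)) {
        j <- ok[1L]
        tmp <- perm[i]; perm[i] <- perm[j]; perm[j] <- tmp
      }
    }
  }
  lapply(seq_len(nb), function(b) perm[((b - 1L) * B + 1L):(b * B)])
}

# ---- the fitting function --------------------------------------------------

#' Fit a self-supervised disease-concept embedding model
#'
#' Pretrains the Transformer encoder on a cleansed visit table without any
#' outcome labels. Each minibatch is augmented into two views (structural
#' noise + random history masking); the encoder is trained to minimise
#' `DIM noise-contrastive loss + gamma * prior-matching loss + SimCLR
#' loss`, while a linear domain discriminator is trained adversarially to
#' separate the embeddings from Uniform[-1,1]^d prior draws, pushing the
#' embedding distribution toward the uniform prior. The mutual-information
#' discriminator (a second Transformer over [CLS], embedding, [SEP] and the
#' input tokens) is trained jointly with the encoder on the
#' noise-contrastive objective.
#'
#' @param visits a cleansed, deduplicated visit table (the training split).
#' @param config model architecture, an [ed_config()].
#' @param train optimisation settings, an [ed_train_config()].
#' @param encoder text encoder contract, a [text_encoder()]; its `d_text`
#'   must match `config$d_text`. Encoder weights are frozen throughout.
#' @param stats training-split field statistics; computed from `visits`
#'   when NULL.
#' @return An object of class `edembed` with elements `params`, `config`,
#'   `train`, `stats`, `encoder`, `metrics` (per-step loss parts) and
#'   `pretrained`.
#' @seealso [predict.edembed()], [finetune()], [build_index()]
#' @export
edembed <- function(visits, config = ed_config(), train = ed_train_config(),
                    encoder = text_encoder("hash", d_text = config$d_text),
                    stats = NULL) {
  stopifnot(inherits(config, "ed_config"), inherits(train, "ed_train_config"))
  if (encoder$d_text != config$d_text)
    stop("encoder d_text (", encoder$d_text, ") != config d_text (", config$d_text, ")")
  set.seed(train$seed)
  if (is.null(stats)) stats <- cohort_stats(visits)
  feats <- .prepare_features(visits, stats, encoder)
  params <- ed_init_params(config, seed = train$seed)
  metrics <- NULL
  do_train <- train$use_pretrain && train$epochs > 0L &&
    (train$use_dim || train$use_simclr)
  if (do_train) {
    keys <- paste(apply(round(feats$S, 6), 1L, paste, collapse = ","),
                  visits$chief_complaint, feats$hx_valid)
    if (anyDuplicated(keys))
      warning("visits with identical model inputs found; they are kept in ",
              "separate minibatches (contrastive losses assume unique visits)")
    res <- .pretrain_loop(params, config, train, feats, keys)
    params <- res$params
    metrics <- res$metrics
  }
  structure(list(params = params, config = config, train = train,
                 stats = stats, encoder = encoder, metrics = metrics,
                 pretrained = do_train, n_visits = nrow(visits),
                 call = match.call()),
            class = "edembed")
}

.drop_fn <- function(tp, rate) {
  if (is.null(rate) || rate <= 0) return(NULL)
  function(x) {
    v <- tp_val(tp, x)
    mask <- (matrix(stats::runif(length(v)), nrow(v)) >= rate) / (1 - rate)
    tp_mul(tp, x, tp_const(tp, mask))
  }
}

.pretrain_loop <- function(params, cfg, train, feats, keys) {
  enc_names <- .group_names(params, c("ls", "lb", "enc"))
  disc_names <- .group_names(params, "disc")
  ldd_names <- .group_names(params, "ldd")
  st_model <- .adam_new(); st_ldd <- .adam_new()
  B <- train$batch_size
  d <- cfg$d_hidden
  metrics <- list()
  step <- 0L
  for (epoch in seq_len(train$epochs)) {
    for (idx in .batch_plan(keys, B)) {
      step <- step + 1L
      base <- list(S = feats$S[idx, , drop = FALSE], hx_valid = feats$hx_valid[idx])
      v1 <- augment(base, cfg)
      v2 <- augment(base, cfg)
      CC <- feats$CC[idx, , drop = FALSE]; HX <- feats$HX[idx, , drop = FALSE]

      tp <- tp_new(2048L)
      pid <- lapply(params, function(x) tp_param(tp, x))
      drop <- .drop_fn(tp, cfg$dropout)
      e1 <- .tp_encoder(tp, pid, cfg, v1$S, CC, HX, v1$hx_valid, drop)
      zero <- tp_const(tp, 0)
      dim_node <- zero; pg_node <- zero; pd_node <- NULL; sim_node <- zero

      if (train$use_dim) {
        K <- min(train$dim_negatives, B - 1L)
        negs <- unlist(lapply(seq_len(B), function(i)
          sample(seq_len(B)[-i], K)))
        ia <- c(seq_len(B), rep(seq_len(B), each = K))
        ja <- c(seq_len(B), negs)
        logit <- .tp_discriminator(tp, pid, cfg,
                                   tp_rows(tp, e1$eps, ia),
                                   tp_rows(tp, e1$ms, ja),
                                   tp_rows(tp, e1$mcc, ja),
                                   tp_rows(tp, e1$mhx, ja),
                                   v1$hx_valid[ja], drop)
        # class-balanced BCE: subsampling leaves 1 matched pair per K
        # mismatched ones, and an unweighted mean has a constant-predictor
        # saddle at the class prior; balancing restores the ln(2) saddle
        y_pair <- as.numeric(ia == ja)
        dim_node <- tp_bce_logits(tp, logit, y_pair,
                                  w = ifelse(y_pair == 1, K, 1))

        prior <- matrix(stats::runif(B * d, -1, 1), B, d)
        lg <- tp_addrow(tp, tp_mm(tp, e1$eps, pid[["ldd.W"]]), pid[["ldd.b"]])
        pg_node <- tp_bce_logits(tp, lg, rep(1, B))
        eps_det <- tp_const(tp, tp_val(tp, e1$eps))
        lp <- tp_addrow(tp, tp_mm(tp, tp_const(tp, prior), pid[["ldd.W"]]), pid[["ldd.b"]])
        le <- tp_addrow(tp, tp_mm(tp, eps_det, pid[["ldd.W"]]), pid[["ldd.b"]])
        pd_node <- tp_bce_logits(tp, tp_rbind(tp, list(lp, le)),
                                 c(rep(1, B), rep(0, B)))
      }
      if (train$use_simclr) {
        e2 <- .tp_encoder(tp, pid, cfg, v2$S, CC, HX, v2$hx_valid, drop)
        U <- tp_rownorm(tp, tp_rbind(tp, list(e1$eps, e2$eps)))
        S <- tp_smul(tp, tp_mm(tp, U, tp_t(tp, U)), 1 / train$temperature)
        pen <- matrix(0, 2L * B, 2L * B); diag(pen) <- -1e9
        S <- tp_add(tp, S, tp_const(tp, pen))
        sim_node <- tp_xent_rows(tp, S, c(B + seq_len(B), seq_len(B)))
      }
      total <- tp_add(tp, tp_add(tp, dim_node, tp_smul(tp, pg_node, train$gamma)),
                      sim_node)
      tv <- tp_val(tp, total)
      if (!is.finite(tv))
        stop("non-finite pretraining loss at step ", step,
             " (dim=", signif(tp_val(tp, dim_node), 4),
             ", simclr=", signif(tp_val(tp, sim_node), 4), ")")

      upd_encoder <- step %% train$disc_steps_per_gen_step == 0L
      g <- tp_grads_for(tp, total, pid)
      upd <- c(disc_names, if (upd_encoder) enc_names)
      params <- .adam_step(st_model, params, g, upd, train$learning_rate)
      if (!is.null(pd_node)) {
        gd <- tp_grads_for(tp, pd_node, pid[ldd_names])
        params <- .adam_step(st_ldd, params, gd, ldd_names, train$learning_rate)
      }
      metrics[[step]] <- data.frame(
        step = step, epoch = epoch,
        dim_nce = tp_val(tp, dim_node),
        prior_gen = if (train$use_dim) tp_val(tp, pg_node) else NA_real_,
        prior_disc = if (!is.null(pd_node)) tp_val(tp, pd_node) else NA_real_,
        simclr = if (train$use_simclr) tp_val(tp, sim_node) else NA_real_,
        total = tv)
    }
  }
  list(params = params, metrics = do.call(rbind, metrics))
}

# ---- prediction ------------------------------------------------------------

#' Embed visits with a fitted model
#'
#' @param object a fitted `edembed` model.
#' @param newdata a visit table.
#' @param ... unused.
#' @return n x d_hidden matrix of embeddings (rownames = visit ids); every
#'   coordinate lies in [-1, 1].
#' @export
predict.edembed <- function(object, newdata, ...) {
  feats <- .prepare_features(newdata, object$stats, object$encoder)
  eps <- .embed_features(object$params, object$config, feats)
  rownames(eps) <- feats$visit_id
  eps
}

.embed_features <- function(params, cfg, feats, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(nrow(feats$S))
  out <- matrix(0, length(idx), cfg$d_hidden)
  # chunked to keep tape size bounded
  chunks <- split(idx, ceiling(seq_along(idx) / 512))
  off <- 0L
  for (ch in chunks) {
    tp <- tp_new(1024L)
    pid <- .const_pid(tp, params)
    e <- .tp_encoder(tp, pid, cfg, feats$S[ch, , drop = FALSE],
                     feats$CC[ch, , drop = FALSE], feats$HX[ch, , drop = FALSE],
                     feats$hx_valid[ch])
    out[off + seq_along(ch), ] <- tp_val(tp, e$eps)
    off <- off + length(ch)
  }
  out
}

# ---- finetuning ------------------------------------------------------------

#' Finetune a pretrained embedding model for outcome classification
#'
#' @param object a fitted model.
#' @param ... passed to methods.
#' @export
finetune <- function(object, ...) UseMethod("finetune")

#' Finetune for the critical-care outcome
#'
#' Attaches the multilayer linear head FL_C to the encoder and trains with
#' class-weighted binary cross-entropy (positive-class weight n_neg/n_pos).
#' The encoder is unfrozen by default; `freeze_encoder = TRUE` trains the
#' head only. A validation fraction is held out for early stopping on
#' AUROC.
#'
#' @param object a fitted `edembed` model (pretrained or not: a model built
#'   with `use_pretrain = FALSE` gives the no-pretraining ablation).
#' @param visits labeled visit table.
#' @param labels 0/1 outcome vector; when NULL, computed by
#'   [label_critical_outcome()] on `visits`.
#' @param epochs,batch_size,learning_rate optimisation settings.
#' @param freeze_encoder train the head only.
#' @param val_fraction held-out fraction for early stopping; 0 disables
#'   validation entirely (all labels train, final parameters kept).
#' @param patience epochs without validation-AUROC improvement tolerated.
#' @param seed seed for shuffling/initial state.
#' @param ... unused.
#' @return An object of class `edembed_classifier`.
#' @export
finetune.edembed <- function(object, visits, labels = NULL, epochs = 10L,
                             batch_size = 64L, learning_rate = 1e-3,
                             freeze_encoder = FALSE, val_fraction = 0.15,
                             patience = 5L, seed = 1L, ...) {
  if (is.null(labels)) labels <- label_critical_outcome(visits)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("DEGENERATE_LABELS: both outcome classes are required")
  set.seed(seed)
  cfg <- object$config
  params <- object$params
  feats <- .prepare_features(visits, object$stats, object$encoder)
  n <- nrow(feats$S)
  # val_fraction = 0: train on every label, keep the final parameters
  # (early stopping needs a validation split with both classes, which a
  # small rare-outcome budget cannot spare)
  n_val <- if (val_fraction > 0) max(2L, round(val_fraction * n)) else 0L
  vix <- if (n_val > 0L) sample.int(n, n_val) else integer(0)
  tix <- setdiff(seq_len(n), vix)
  if (n_val > 0L &&
      (length(unique(labels[vix])) < 2L || length(unique(labels[tix])) < 2L)) {
    # rebalance: force one positive and one negative into each part
    pos <- which(labels == 1L); neg <- which(labels == 0L)
    vix <- unique(c(pos[1L], neg[1L], vix))
    tix <- setdiff(seq_len(n), vix)
  }
  pw <- sum(labels[tix] == 0L) / max(1L, sum(labels[tix] == 1L))
  upd_names <- c(.group_names(params, "head"),
                 if (!freeze_encoder) .group_names(params, c("ls", "lb", "enc")))
  st <- .adam_new()
  best <- list(auc = -Inf, params = params, epoch = 0L)
  hist <- list()
  # frozen encoder: embeddings do not change, compute them once
  eps_cache <- if (freeze_encoder) .embed_features(params, cfg, feats) else NULL
  for (epoch in seq_len(epochs)) {
    ord <- sample(tix)
    nb <- max(1L, length(ord) %/% batch_size)
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1L) * batch_size + 1L):min(b * batch_size, length(ord))]
      tp <- tp_new(1024L)
      pid <- lapply(params, function(x) tp_param(tp, x))
      drop <- .drop_fn(tp, cfg$dropout)
      eps_node <- if (freeze_encoder) {
        tp_const(tp, eps_cache[idx, , drop = FALSE])
      } else {
        .tp_encoder(tp, pid, cfg, feats$S[idx, , drop = FALSE],
                    feats$CC[idx, , drop = FALSE],
                    feats$HX[idx, , drop = FALSE], feats$hx_valid[idx], drop)$eps
      }
      h <- tp_gelu(tp, tp_addrow(tp, tp_mm(tp, eps_node, pid[["head.W1"]]), pid[["head.b1"]]))
      lg <- tp_addrow(tp, tp_mm(tp, h, pid[["head.W2"]]), pid[["head.b2"]])
      y <- labels[idx]
      loss <- tp_bce_logits(tp, lg, y, w = ifelse(y == 1L, pw, 1))
      g <- tp_grads_for(tp, loss, pid[upd_names])
      params <- .adam_step(st, params, g, upd_names, learning_rate)
    }
    if (n_val > 0L) {
      val_sc <- .head_scores(params, cfg, feats, vix)
      auc <- tryCatch(evaluate_auroc(val_sc, labels[vix]), error = function(e) NA_real_)
      hist[[epoch]] <- data.frame(epoch = epoch, val_auroc = auc)
      if (!is.na(auc) && auc > best$auc) best <- list(auc = auc, params = params, epoch = epoch)
      if (epoch - best$epoch >= patience) break
    }
  }
  if (epochs > 0L && best$auc > -Inf) params <- best$params
  structure(list(params = params, config = cfg, stats = object$stats,
                 encoder = object$encoder, pretrained = object$pretrained,
                 pos_weight = pw, val_auroc = best$auc,
                 history = do.call(rbind, hist), call = match.call()),
            class = "edembed_classifier")
}

.head_scores <- function(params, cfg, feats, idx) {
  eps <- .embed_features(params, cfg, feats, idx)
  h <- eps %*% params[["head.W1"]]
  h <- sweep(h, 2L, as.numeric(params[["head.b1"]]), "+")
  h <- h * stats::pnorm(h)
  as.numeric(stats::plogis(h %*% params[["head.W2"]] + as.numeric(params[["head.b2"]])))
}

#' Predict outcome probabilities
#'
#' @param object an `edembed_classifier`.
#' @param newdata a visit table.
#' @param ... unused.
#' @return Numeric vector of predicted critical-care-outcome probabilities.
#' @export
predict.edembed_classifier <- function(object, newdata, ...) {
  feats <- .prepare_features(newdata, object$stats, object$encoder)
  sc <- .head_scores(object$params, object$config, feats, seq_len(nrow(feats$S)))
  names(sc) <- feats$visit_id
  sc
}

# ---- evaluation ------------------------------------------------------------

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation with midranks for ties: the probability
#' that a uniformly chosen positive outscores a uniformly chosen negative
#' (ties counting one half).
#'
#' @param scores numeric predictions (any monotone scale).
#' @param labels 0/1 outcomes containing both classes.
#' @return AUROC in [0, 1].
#' @export
evaluate_auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stop("labels must contain both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}
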