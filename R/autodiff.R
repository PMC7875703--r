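# Minimal reverse-mode autodiff tape for the Transformer/loss machinery.
# Nodes are created eagerly (value computed at definition time); backward
# walks the tape in reverse and accumulates vector-Jacobian products.
# Only matrices (and length-1 numerics for losses) flow through the tape.
# Internal: not exported. Gradients are verified against finite differences
# in the test suite.

tp_new <- function(capacity = 512L) {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", capacity)
  tp$n <- 0L
  tp
}

tp_push <- function(tp, value, parents = integer(0), vjp = NULL, needs = FALSE) {
  # force every promise before claiming an id: evaluating a nested op call
  # pushes its own nodes first, and this node must come after all of them
  force(value); force(parents); force(vjp); force(needs)
  n <- tp$n + 1L
  if (n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[n]] <- list(value = value, parents = parents, vjp = vjp, needs = needs)
  tp$n <- n
  n
}

tp_val <- function(tp, i) {
  # force the id promise before touching tp$nodes: evaluating a nested op
  # call mutates the node list, and subscripting must see the fresh state
  force(i)
  tp$nodes[[i]]$value
}

tp_const <- function(tp, x) tp_push(tp, x)
tp_param <- function(tp, x) tp_push(tp, x, needs = TRUE)

.needs <- function(tp, ids) {
  for (i in ids) if (tp$nodes[[i]]$needs) return(TRUE)
  FALSE
}

# ---- elementwise / linear algebra primitives ------------------------------

tp_mm <- function(tp, a, b) {
  A <- tp_val(tp, a); B <- tp_val(tp, b)
  tp_push(tp, A %*% B, c(a, b),
          vjp = function(g, tp) list(g %*% t(B), crossprod(A, g)),
          needs = .needs(tp, c(a, b)))
}

tp_add <- function(tp, a, b) {
  tp_push(tp, tp_val(tp, a) + tp_val(tp, b), c(a, b),
          vjp = function(g, tp) list(g, g),
          needs = .needs(tp, c(a, b)))
}

# a: n x d, b: 1 x d bias row broadcast over rows
tp_addrow <- function(tp, a, b) {
  A <- tp_val(tp, a); B <- tp_val(tp, b)
  tp_push(tp, A + rep(as.numeric(B), each = nrow(A)), c(a, b),
          vjp = function(g, tp) list(g, matrix(colSums(g), 1L)),
          needs = .needs(tp, c(a, b)))
}

tp_sub <- function(tp, a, b) {
  tp_push(tp, tp_val(tp, a) - tp_val(tp, b), c(a, b),
          vjp = function(g, tp) list(g, -g),
          needs = .needs(tp, c(a, b)))
}

tp_mul <- function(tp, a, b) {
  A <- tp_val(tp, a); B <- tp_val(tp, b)
  tp_push(tp, A * B, c(a, b),
          vjp = function(g, tp) list(g * B, g * A),
          needs = .needs(tp, c(a, b)))
}

tp_smul <- function(tp, a, s) {
  tp_push(tp, tp_val(tp, a) * s, a,
          vjp = function(g, tp) list(g * s),
          needs = .needs(tp, a))
}

tp_t <- function(tp, a) {
  tp_push(tp, t(tp_val(tp, a)), a,
          vjp = function(g, tp) list(t(g)),
          needs = .needs(tp, a))
}

tp_tanh <- function(tp, a) {
  v <- tanh(tp_val(tp, a))
  tp_push(tp, v, a, vjp = function(g, tp) list(g * (1 - v^2)),
          needs = .needs(tp, a))
}

tp_sigmoid <- function(tp, a) {
  v <- stats::plogis(tp_val(tp, a))
  tp_push(tp, v, a, vjp = function(g, tp) list(g * v * (1 - v)),
          needs = .needs(tp, a))
}

# exact GELU: x * pnorm(x)
tp_gelu <- function(tp, a) {
  x <- tp_val(tp, a)
  ph <- stats::pnorm(x)
  tp_push(tp, x * ph, a,
          vjp = function(g, tp) list(g * (ph + x * stats::dnorm(x))),
          needs = .needs(tp, a))
}

tp_rows <- function(tp, a, idx) {
  A <- tp_val(tp, a)
  tp_push(tp, A[idx, , drop = FALSE], a,
          vjp = function(g, tp) {
            dA <- matrix(0, nrow(A), ncol(A))
            # idx may repeat; accumulate
            for (k in seq_along(idx)) dA[idx[k], ] <- dA[idx[k], ] + g[k, ]
            list(dA)
          },
          needs = .needs(tp, a))
}

# stack a list of n x d nodes row-wise (token-major blocks)
tp_rbind <- function(tp, ids) {
  vals <- lapply(ids, function(i) tp_val(tp, i))
  rs <- vapply(vals, nrow, 1L)
  tp_push(tp, do.call(rbind, vals), as.integer(ids),
          vjp = function(g, tp) {
            out <- vector("list", length(rs)); off <- 0L
            for (k in seq_along(rs)) {
              out[[k]] <- g[(off + 1L):(off + rs[k]), , drop = FALSE]
              off <- off + rs[k]
            }
            out
          },
          needs = .needs(tp, ids))
}

# broadcast a 1 x d row to n x d
tp_tile <- function(tp, a, n) {
  A <- tp_val(tp, a)
  tp_push(tp, matrix(as.numeric(A), n, length(A), byrow = TRUE), a,
          vjp = function(g, tp) list(matrix(colSums(g), 1L)),
          needs = .needs(tp, a))
}

tp_mean <- function(tp, a) {
  A <- tp_val(tp, a)
  tp_push(tp, mean(A), a,
          vjp = function(g, tp) list(array(g / length(A), dim(A))),
          needs = .needs(tp, a))
}

# ---- composite primitives with hand-written backward ----------------------

tp_layernorm <- function(tp, a, gain, bias, eps = 1e-5) {
  X <- tp_val(tp, a); G <- as.numeric(tp_val(tp, gain)); B <- as.numeric(tp_val(tp, bias))
  mu <- rowMeans(X)
  xc <- X - mu
  s <- sqrt(rowMeans(xc^2) + eps)
  xh <- xc / s
  n <- nrow(X)
  V <- xh * rep(G, each = n) + rep(B, each = n)
  tp_push(tp, V, c(a, gain, bias),
          vjp = function(g, tp) {
            dxh <- sweep(g, 2L, G, "*")
            m1 <- rowMeans(dxh)
            m2 <- rowMeans(dxh * xh)
            dX <- (dxh - m1 - xh * m2) / s
            list(dX, matrix(colSums(g * xh), 1L), matrix(colSums(g), 1L))
          },
          needs = .needs(tp, c(a, gain, bias)))
}

# Multi-head scaled-dot-product attention over fixed-length sequences.
# q, k, v: (n_tok * B) x d token-major (rows (t-1)*B + 1:B hold token t).
# mask: B x n_tok key-validity matrix (1 = attend, 0 = ignore).
tp_mha <- function(tp, q, k, v, mask, n_heads, n_tok) {
  Q <- tp_val(tp, q); K <- tp_val(tp, k); V <- tp_val(tp, v)
  d <- ncol(Q); dh <- d %/% n_heads
  B <- nrow(Q) %/% n_tok
  ri <- function(t) ((t - 1L) * B + 1L):(t * B)
  pen <- (mask - 1) * 1e9
  out <- matrix(0, nrow(Q), d)
  Astore <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    Qh <- Q[, cols, drop = FALSE]; Kh <- K[, cols, drop = FALSE]
    Vh <- V[, cols, drop = FALSE]
    Ah <- vector("list", n_tok)
    for (i in seq_len(n_tok)) {
      Qi <- Qh[ri(i), , drop = FALSE]
      S <- matrix(0, B, n_tok)
      for (j in seq_len(n_tok)) S[, j] <- rowSums(Qi * Kh[ri(j), , drop = FALSE])
      S <- S / sqrt(dh) + pen
      mxr <- S[, 1L]
      for (j in seq_len(n_tok)[-1L]) mxr <- pmax(mxr, S[, j])
      E <- exp(S - mxr)
      A <- E / rowSums(E)
      Ah[[i]] <- A
      Oi <- matrix(0, B, dh)
      for (j in seq_len(n_tok)) Oi <- Oi + A[, j] * Vh[ri(j), , drop = FALSE]
      out[ri(i), cols] <- Oi
    }
    Astore[[h]] <- Ah
  }
  tp_push(tp, out, c(q, k, v),
          vjp = function(g, tp) {
            dQ <- matrix(0, nrow(Q), d); dK <- dQ; dV <- dQ
            for (h in seq_len(n_heads)) {
              cols <- ((h - 1L) * dh + 1L):(h * dh)
              Qh <- Q[, cols, drop = FALSE]; Kh <- K[, cols, drop = FALSE]
              Vh <- V[, cols, drop = FALSE]
              for (i in seq_len(n_tok)) {
                gO <- g[ri(i), cols, drop = FALSE]
                A <- Astore[[h]][[i]]
                dA <- matrix(0, B, n_tok)
                for (j in seq_len(n_tok)) {
                  dV[ri(j), cols] <- dV[ri(j), cols] + A[, j] * gO
                  dA[, j] <- rowSums(gO * Vh[ri(j), , drop = FALSE])
                }
                dS <- (A * (dA - rowSums(dA * A))) / sqrt(dh)
                Qi <- Qh[ri(i), , drop = FALSE]
                dQi <- matrix(0, B, dh)
                for (j in seq_len(n_tok)) {
                  dQi <- dQi + dS[, j] * Kh[ri(j), , drop = FALSE]
                  dK[ri(j), cols] <- dK[ri(j), cols] + dS[, j] * Qi
                }
                dQ[ri(i), cols] <- dQ[ri(i), cols] + dQi
              }
            }
            list(dQ, dK, dV)
          },
          needs = .needs(tp, c(q, k, v)))
}

# rows L2-normalised; zero rows are an error upstream
tp_rownorm <- function(tp, a) {
  X <- tp_val(tp, a)
  nr <- sqrt(rowSums(X^2))
  U <- X / nr
  tp_push(tp, U, a,
          vjp = function(g, tp) list((g - U * rowSums(g * U)) / nr),
          needs = .needs(tp, a))
}

# mean over rows of [logsumexp(row) - row[pos]]; pos = 1-based column per row.
# Softmax cross-entropy against a one-hot target, numerically stable.
tp_xent_rows <- function(tp, a, pos) {
  S <- tp_val(tp, a)
  mx <- apply(S, 1L, max)
  E <- exp(S - mx)
  Z <- rowSums(E)
  P <- E / Z
  n <- nrow(S)
  picked <- S[cbind(seq_len(n), pos)]
  val <- mean(log(Z) + mx - picked)
  tp_push(tp, val, a,
          vjp = function(g, tp) {
            D <- P
            D[cbind(seq_len(n), pos)] <- D[cbind(seq_len(n), pos)] - 1
            list(g * D / n)
          },
          needs = .needs(tp, a))
}

# mean binary cross-entropy from logits; y in {0,1}, w optional per-row weight
tp_bce_logits <- function(tp, a, y, w = NULL) {
  L <- as.numeric(tp_val(tp, a))
  if (is.null(w)) w <- rep(1, length(L))
  sp <- ifelse(L > 0, L + log1p(exp(-L)), log1p(exp(L)))  # softplus(L)
  val <- sum(w * (sp - y * L)) / sum(w)
  tp_push(tp, val, a,
          vjp = function(g, tp) {
            d <- g * w * (stats::plogis(L) - y) / sum(w)
            list(matrix(d, ncol = 1L))
          },
          needs = .needs(tp, a))
}

# ---- backward --------------------------------------------------------------

tp_backward <- function(tp, loss) {
  grads <- vector("list", tp$n)
  grads[[loss]] <- 1
  for (i in seq.int(loss, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    nd <- tp$nodes[[i]]
    if (is.null(nd$vjp) || !nd$needs) next
    pg <- nd$vjp(g, tp)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      p <- ps[k]
      if (!tp$nodes[[p]]$needs) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  grads
}

# convenience: gradient of `loss` w.r.t. a named list of param node ids
tp_grads_for <- function(tp, loss, pidx) {
  grads <- tp_backward(tp, loss)
  out <- lapply(pidx, function(i) {
    g <- grads[[i]]
    if (is.null(g)) g <- array(0, dim(tp_val(tp, i)))
    g
  })
  names(out) <- names(pidx)
  out
}
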