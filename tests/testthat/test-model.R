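# Independent reference implementation of the encoder (plain per-visit
# loops, written directly from the architecture definition) used as the
# oracle for the vectorised forward pass.
ref_embed <- function(params, cfg, S, CC, HX, hx_valid) {
  gelu <- function(x) x * stats::pnorm(x)
  mlp <- function(x, pre) {
    h <- gelu(x %*% params[[paste0(pre, ".W1")]] +
                matrix(params[[paste0(pre, ".b1")]], nrow(x), ncol(params[[paste0(pre, ".b1")]]), byrow = TRUE))
    h %*% params[[paste0(pre, ".W2")]] +
      matrix(params[[paste0(pre, ".b2")]], nrow(h), ncol(params[[paste0(pre, ".b2")]]), byrow = TRUE)
  }
  ln <- function(x, g, b) {
    t(apply(x, 1L, function(r) {
      mu <- mean(r); s <- sqrt(mean((r - mu)^2) + 1e-5)
      (r - mu) / s * as.numeric(g) + as.numeric(b)
    }))
  }
  d <- cfg$d_hidden; H <- cfg$n_heads; dh <- d / H
  MS <- mlp(S, "ls"); MCC <- mlp(CC, "lb"); MHX <- mlp(HX, "lb")
  out <- matrix(0, nrow(S), d)
  for (b in seq_len(nrow(S))) {
    X <- rbind(params[["enc.cls"]], MS[b, ], MCC[b, ], MHX[b, ])
    X <- X + params[["enc.pos"]] +
      matrix(params[["enc.seg"]][1, ], 4L, d, byrow = TRUE)
    mask <- c(1, 1, 1, hx_valid[b])
    for (l in seq_len(cfg$n_layers)) {
      pre <- sprintf("enc.L%d.", l)
      Q <- X %*% params[[paste0(pre, "Wq")]] + matrix(params[[paste0(pre, "bq")]], 4, d, byrow = TRUE)
      K <- X %*% params[[paste0(pre, "Wk")]] + matrix(params[[paste0(pre, "bk")]], 4, d, byrow = TRUE)
      V <- X %*% params[[paste0(pre, "Wv")]] + matrix(params[[paste0(pre, "bv")]], 4, d, byrow = TRUE)
      O <- matrix(0, 4L, d)
      for (h in seq_len(H)) {
        cols <- ((h - 1) * dh + 1):(h * dh)
        sc <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dh)
        sc <- sc + matrix((mask - 1) * 1e9, 4L, 4L, byrow = TRUE)
        A <- t(apply(sc, 1L, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
        O[, cols] <- A %*% V[, cols, drop = FALSE]
      }
      X <- ln(X + O %*% params[[paste0(pre, "Wo")]] +
                matrix(params[[paste0(pre, "bo")]], 4, d, byrow = TRUE),
              params[[paste0(pre, "ln1g")]], params[[paste0(pre, "ln1b")]])
      FF <- gelu(X %*% params[[paste0(pre, "ffW1")]] +
                   matrix(params[[paste0(pre, "ffb1")]], 4, cfg$d_ff, byrow = TRUE)) %*%
        params[[paste0(pre, "ffW2")]] +
        matrix(params[[paste0(pre, "ffb2")]], 4, d, byrow = TRUE)
      X <- ln(X + FF, params[[paste0(pre, "ln2g")]], params[[paste0(pre, "ln2b")]])
    }
    out[b, ] <- tanh(X[1, ])
  }
  out
}

test_that("projection heads match an explicit matrix-product oracle", {
  cfg <- tiny_cfg()
  params <- ed_init_params(cfg, seed = 4, sd = 0.3)
  s <- matrix(stats::rnorm(2 * 15), 2L)
  want <- {
    h <- s %*% params[["ls.W1"]] + matrix(params[["ls.b1"]], 2, 64, byrow = TRUE)
    h <- h * stats::pnorm(h)
    h %*% params[["ls.W2"]] + matrix(params[["ls.b2"]], 2, 8, byrow = TRUE)
  }
  expect_equal(project_structural(s, params, cfg), want)
  expect_error(project_structural(matrix(0, 1, 9), params, cfg))

  # zero weights and biases give the zero vector
  p0 <- params
  for (nm in c("ls.W1", "ls.b1", "ls.W2", "ls.b2")) p0[[nm]][] <- 0
  expect_equal(project_structural(s, p0, cfg), matrix(0, 2, 8))

  # CC and Hx go through the same L_B network
  f <- matrix(stats::rnorm(12), 1L)
  expect_equal(project_text(f, params, cfg), project_text(f, params, cfg))
})

test_that("assembled input carries the mask, position and segment contract", {
  cfg <- tiny_cfg()
  params <- ed_init_params(cfg, seed = 4)
  m <- matrix(stats::rnorm(3 * 8), 3L)
  a1 <- assemble_input(m, m, m, c(1, 0, 1), params, cfg)
  expect_equal(a1$mask, cbind(1, 1, 1, c(1, 0, 1)))
  expect_equal(a1$position_ids, 0:3)
  expect_equal(a1$segment_ids, rep(0L, 4))
  # zero position/segment tables: rows reduce to the raw token embeddings
  p0 <- params; p0[["enc.pos"]][] <- 0; p0[["enc.seg"]][] <- 0
  a0 <- assemble_input(m, m, m, rep(1, 3), p0, cfg)
  expect_equal(a0$x[4:6, ], m)                      # M_S block
  expect_equal(a0$x[1, ], as.numeric(p0[["enc.cls"]]))
  expect_error(assemble_input(m[, 1:4], m, m, 1, params, cfg))
})

test_that("the vectorised encoder matches the per-visit reference oracle", {
  for (seed in 1:3) {
    cfg <- tiny_cfg()
    params <- ed_init_params(cfg, seed = seed, sd = 0.25)
    inp <- rand_inputs(cfg, B = 4L, seed = seed + 10)
    inp$hx <- c(1, 0, 1, 1)
    got <- fwd_eps(params, cfg, inp)
    want <- ref_embed(params, cfg, inp$S, inp$CC, inp$HX, inp$hx)
    expect_equal(got, want, tolerance = 1e-10)
    expect_true(all(abs(got) <= 1))                 # tanh bound
  }
})

test_that("masked history content never reaches the embedding or the score", {
  for (rep in 1:20) {
    cfg <- tiny_cfg()
    params <- ed_init_params(cfg, seed = 100 + rep, sd = 0.3)
    inp <- rand_inputs(cfg, B = 3L, seed = rep)
    inp$hx <- c(0, 0, 0)
    inp2 <- inp
    inp2$HX <- matrix(stats::rnorm(3 * cfg$d_text, sd = 5), 3L)
    expect_identical(fwd_eps(params, cfg, inp), fwd_eps(params, cfg, inp2))

    mhx1 <- project_text(inp$HX, params, cfg)
    mhx2 <- project_text(inp2$HX, params, cfg)
    eps <- fwd_eps(params, cfg, inp)
    ms <- project_structural(inp$S, params, cfg)
    mcc <- project_text(inp$CC, params, cfg)
    s1 <- dim_discriminator_score(eps, ms, mcc, mhx1, inp$hx, params, cfg)
    s2 <- dim_discriminator_score(eps, ms, mcc, mhx2, inp$hx, params, cfg)
    expect_identical(s1, s2)
    expect_true(all(s1 > 0 & s1 < 1))
  }
})

test_that("an unmasked history slot does change the embedding", {
  cfg <- tiny_cfg()
  params <- ed_init_params(cfg, seed = 9, sd = 0.3)
  inp <- rand_inputs(cfg, B = 2L, seed = 1)
  inp2 <- inp; inp2$HX <- inp$HX + 1
  expect_false(isTRUE(all.equal(fwd_eps(params, cfg, inp),
                                fwd_eps(params, cfg, inp2))))
})

test_that("position embeddings make the encoder order-sensitive", {
  # swapping the structural and chief-complaint slots changes the embedding
  cfg <- tiny_cfg()
  for (rep in 1:5) {
    params <- ed_init_params(cfg, seed = 200 + rep, sd = 0.3)
    m_s <- matrix(stats::rnorm(8), 1L); m_cc <- matrix(stats::rnorm(8), 1L)
    m_hx <- matrix(stats::rnorm(8), 1L)
    a1 <- assemble_input(m_s, m_cc, m_hx, 1, params, cfg)
    a2 <- assemble_input(m_cc, m_s, m_hx, 1, params, cfg)
    e1 <- embed_assembled(a1, params, cfg)
    e2 <- embed_assembled(a2, params, cfg)
    expect_false(isTRUE(all.equal(e1, e2)))
  }
})

test_that("embedding the same assembled input twice is deterministic", {
  cfg <- tiny_cfg()
  params <- ed_init_params(cfg, seed = 5)
  m <- matrix(stats::rnorm(2 * 8), 2L)
  a <- assemble_input(m, m, m, c(1, 1), params, cfg)
  expect_identical(embed_assembled(a, params, cfg), embed_assembled(a, params, cfg))
  a$mask <- matrix(0, 2, 4)
  expect_error(embed_assembled(a, params, cfg), "EMPTY_INPUT")
})

test_that("augmentation follows its configured rates", {
  cfg <- tiny_cfg(noise_fraction = 0, history_mask_prob = 0)
  batch <- list(S = matrix(stats::rnorm(20 * 15), 20,
                           dimnames = list(NULL, vital_fields())),
                hx_valid = rep(1, 20))
  expect_identical(augment(batch, cfg)$S, batch$S)            # identity
  cfg1 <- tiny_cfg(history_mask_prob = 1)
  expect_true(all(augment(batch, cfg1)$hx_valid == 0))

  cfg3 <- tiny_cfg(history_mask_prob = 0.3)
  big <- list(S = batch$S[rep(1, 10000), ], hx_valid = rep(1, 10000))
  masked <- 1 - augment(big, cfg3, seed = 42)$hx_valid
  expect_lt(abs(mean(masked) - 0.3), 0.02)

  cfgn <- tiny_cfg(noise_fraction = 0.25)
  aug <- augment(big, cfgn, seed = 43)
  expect_lt(abs(stats::sd(aug$S[, "sbp"] - big$S[, "sbp"]) - 0.25), 0.02)
  expect_identical(aug$S[, "gender"], big$S[, "gender"])      # gender fixed
})
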