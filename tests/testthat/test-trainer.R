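test_that("AUROC matches pair enumeration, handles ties, ignores monotone transforms", {
  expect_equal(evaluate_auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(evaluate_auroc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1.0)
  set.seed(21)
  sc <- stats::rnorm(4000); lab <- stats::rbinom(4000, 1, 0.5)
  expect_lt(abs(evaluate_auroc(sc, lab) - 0.5), 0.03)
  # invariance under strictly monotone transforms
  expect_equal(evaluate_auroc(exp(3 * sc), lab), evaluate_auroc(sc, lab))
  expect_equal(evaluate_auroc(rank(sc), lab), evaluate_auroc(sc, lab))
  # midrank tie handling agrees with the independent pROC implementation
  sc2 <- round(stats::rnorm(300), 1); lab2 <- stats::rbinom(300, 1, 0.3)
  expect_equal(evaluate_auroc(sc2, lab2),
               as.numeric(pROC::auc(pROC::roc(lab2, sc2, quiet = TRUE,
                                              direction = "<"))))
  expect_error(evaluate_auroc(c(1, 2), c(1, 1)), "both classes")
})

test_that("pretraining is reproducible and a no-objective run keeps the init", {
  co <- generate_cohort(cohort_config(n_visits = 128, seed = 3))
  cfg <- tiny_cfg(d_text = 16L)
  tr <- ed_train_config(batch_size = 32L, epochs = 2L, learning_rate = 1e-3,
                        seed = 5)
  enc <- text_encoder("hash", d_text = 16L)
  f1 <- edembed(co$visits, cfg, tr, enc)
  f2 <- edembed(co$visits, cfg, tr, enc)
  expect_identical(f1$metrics, f2$metrics)
  expect_identical(f1$params, f2$params)
  expect_true(all(is.finite(f1$metrics$total)))

  f0 <- edembed(co$visits, cfg,
                ed_train_config(batch_size = 32L, epochs = 2L, seed = 5,
                                use_dim = FALSE, use_simclr = FALSE), enc)
  expect_identical(f0$params, edembed:::ed_init_params(cfg, seed = 5L))
  expect_false(f0$pretrained)
})

test_that("ablation switches drop the matching loss parts", {
  co <- generate_cohort(cohort_config(n_visits = 96, seed = 4))
  cfg <- tiny_cfg(d_text = 16L)
  enc <- text_encoder("hash", d_text = 16L)
  fd <- edembed(co$visits, cfg,
                ed_train_config(batch_size = 32L, epochs = 1L, seed = 2,
                                use_simclr = FALSE), enc)
  expect_true(all(is.na(fd$metrics$simclr)))
  expect_false(anyNA(fd$metrics$dim_nce))
  fs <- edembed(co$visits, cfg,
                ed_train_config(batch_size = 32L, epochs = 1L, seed = 2,
                                use_dim = FALSE), enc)
  expect_true(all(is.na(fs$metrics$prior_disc)))
  expect_false(anyNA(fs$metrics$simclr))
})

test_that("finetuning learns a cluster-driven outcome and refuses one-class labels", {
  co <- generate_cohort(cohort_config(n_visits = 400, seed = 6,
                                      outcome_base_rate = 0.25,
                                      outcome_cluster_shift = c(-3, -1.5, 1.5, 3)))
  cfg <- tiny_cfg(d_text = 16L)
  enc <- text_encoder("hash", d_text = 16L)
  fit <- edembed(co$visits, cfg,
                 ed_train_config(batch_size = 64L, epochs = 4L,
                                 learning_rate = 1e-3, seed = 3), enc)
  lab <- label_critical_outcome(co$visits)
  clf <- finetune(fit, co$visits, lab, epochs = 5L, seed = 3)
  # held-out cohort from the same generator, different seed
  co2 <- generate_cohort(cohort_config(n_visits = 400, seed = 106,
                                       outcome_base_rate = 0.25,
                                       outcome_cluster_shift = c(-3, -1.5, 1.5, 3)))
  sc <- predict(clf, co2$visits)
  expect_gt(evaluate_auroc(sc, label_critical_outcome(co2$visits)), 0.8)

  expect_error(finetune(fit, co$visits, rep(1L, 400)), "DEGENERATE_LABELS")
})

test_that("a zero-epoch finetune scores with the untouched random head", {
  co <- generate_cohort(cohort_config(n_visits = 60, seed = 7,
                                      outcome_base_rate = 0.3))
  cfg <- tiny_cfg(d_text = 16L)
  fit <- edembed(co$visits, cfg,
                 ed_train_config(epochs = 0L, seed = 2, batch_size = 16L),
                 text_encoder("hash", d_text = 16L))
  clf <- finetune(fit, co$visits, label_critical_outcome(co$visits), epochs = 0L)
  expect_identical(clf$params[["head.W1"]], fit$params[["head.W1"]])
  expect_identical(clf$params[["enc.cls"]], fit$params[["enc.cls"]])
})
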