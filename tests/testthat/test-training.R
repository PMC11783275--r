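# Small shared fixture: a fast synthetic task (short sequences, low d).
tiny_task <- function(seed = 3, n_proteins = 6, n_variants = 36) {
  make_task(n_proteins = n_proteins, n_variants = n_variants,
            multi_point_fraction = 0.2, length_range = c(30L, 40L),
            embedder = embedder_mock(d = 8, k = 3, seed = 5), seed = seed)
}

test_that("reversibility augmentation doubles records and negates targets", {
  task <- tiny_task()
  ds <- stabemb_dataset(task$variants, task$sequences)
  n <- nrow(ds$records)
  aug <- augment_reverse(ds)
  expect_equal(nrow(aug$records), 2L * n)
  expect_equal(sum(aug$records$direction == "reverse"), n)
  expect_equal(aug$records$ddg[(n + 1):(2 * n)], -ds$records$ddg)
  # multiset of |targets| preserved
  expect_equal(sort(abs(aug$records$ddg[1:n])),
               sort(abs(aug$records$ddg[(n + 1):(2 * n)])))
  # each reverse record applied to its sequence restores the original
  for (i in c(1L, n)) {
    r <- aug$records[n + i, ]
    restored <- apply_variants(aug$sequences[[r$seq_id]], r$variant)
    orig <- aug$sequences[[aug$records$seq_id[i]]]
    expect_equal(restored$residues, orig$residues)
  }
  # idempotence guard and empty-set behaviour
  expect_error(augment_reverse(aug), "already contains reverse")
  empty <- ds; empty$records <- ds$records[0, ]
  expect_equal(nrow(augment_reverse(empty)$records), 0L)
})

test_that("mse loss matches its closed form", {
  expect_equal(mse_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(mse_loss(c(0, 2), c(1, 1)), 1)
  set.seed(1)
  y <- rnorm(10); p <- rnorm(10)
  perm <- sample(10)
  expect_equal(mse_loss(y[perm], p[perm]), mse_loss(y, p))
  expect_error(mse_loss(numeric(0), numeric(0)), "empty")
})

test_that("training is seed-reproducible and returns the argmin epoch", {
  task <- tiny_task()
  ctrl <- stabemb_control(batch_size = 16, epochs = 8, lr = 1e-3,
                          patience = 8, seed = 42)
  cfg <- ddg_config(NULL, m = 8, w = 5, h = 2, s = 16)
  fit1 <- stabemb(task$variants, task$sequences, embedder = task$embedder,
                  config = cfg, control = ctrl)
  fit2 <- stabemb(task$variants, task$sequences, embedder = task$embedder,
                  config = cfg, control = ctrl)
  expect_identical(fit1$log, fit2$log)
  expect_identical(fit1$params, fit2$params)

  # argmin contract: returned epoch's validation MSE is the log minimum
  expect_equal(fit1$best_val_mse, min(fit1$log$val_mse))
  expect_equal(fit1$log$val_mse[fit1$best_epoch], fit1$best_val_mse)

  # validation split is protein-grouped
  expect_true(all(fit1$val_proteins %in% task$variants$protein_id))
})

test_that("training loss decreases on a well-conditioned problem", {
  task <- tiny_task(seed = 9)
  fit <- stabemb(task$variants, task$sequences, embedder = task$embedder,
                 config = ddg_config(NULL, m = 8, w = 5, h = 2, s = 16),
                 control = stabemb_control(batch_size = 16, epochs = 10,
                                           lr = 1e-3, patience = 10,
                                           seed = 1))
  expect_lt(fit$log$train_mse[10], fit$log$train_mse[1])
})

test_that("fit object methods expose coefficients, residuals and summary", {
  task <- tiny_task(seed = 4)
  fit <- stabemb(task$variants, task$sequences, embedder = task$embedder,
                 config = ddg_config(NULL, m = 8, w = 5, h = 2, s = 16),
                 control = stabemb_control(batch_size = 16, epochs = 3,
                                           lr = 1e-3, patience = 3,
                                           seed = 2))
  expect_s3_class(coef(fit), "ddg_params")
  expect_equal(length(residuals(fit)), nrow(fit$records))
  expect_equal(residuals(fit), fit$records$ddg - fitted(fit))
  s <- summary(fit)
  expect_s3_class(s, "summary.stabemb")
  expect_output(print(s), "PCC")
  expect_output(print(fit), "best epoch")

  preds <- predict(fit, task$variants[1:4, ], task$sequences)
  expect_equal(nrow(preds), 4L)
  expect_true(all(is.finite(preds$ddg_pred)))
  # reverse predictions are produced from the mutated sequence
  both <- predict(fit, task$variants[1:2, ], task$sequences, reverse = TRUE)
  expect_equal(nrow(both), 4L)
  expect_equal(both$direction, c("direct", "direct", "reverse", "reverse"))
})
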