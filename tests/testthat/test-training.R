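test_that("label-smoothing cross-entropy reproduces worked values", {
  expect_equal(sce_loss(c(0.5, 0.5), 0, eps = 0), 0.693147, tolerance = 1e-6)
  expect_equal(sce_loss(c(1, 0), 0, eps = 0), 0, tolerance = 1e-9)
  expect_equal(sce_loss(c(0.8, 0.2), 0, eps = 0.2),
               0.8 * -log(0.8) + 0.2 * -log(0.2), tolerance = 1e-12)
  expect_equal(sce_loss(c(0.8, 0.2), 0, eps = 0.2), 0.50036, tolerance = 1e-4)
  expect_error(sce_loss(c(0.5, 0.5), 0, eps = 1), "eps")
  expect_error(sce_loss(c(0.5, 0.5), 0, eps = -0.1), "eps")
})

test_that("smoothing eps = 0 equals plain cross-entropy", {
  set.seed(3)
  for (rep in 1:20) {
    p <- runif(2, 0.01, 1)
    p <- p / sum(p)
    y <- sample(0:1, 1)
    expect_equal(sce_loss(p, y, eps = 0), -log(p[y + 1]), tolerance = 1e-12)
  }
})

test_that("the multi-task loss decomposes as 1*MSE + 10*SCE", {
  tasks <- default_tasks()
  set.seed(4)
  n <- 16
  pred <- list()
  targets <- list()
  for (t in c("loewe", "bliss", "zip", "hsa", "s")) {
    pred[[t]] <- rnorm(n, sd = 10)
    targets[[t]] <- rnorm(n, sd = 10)
  }
  for (t in c("synergy", "ddi")) {
    p <- matrix(runif(2 * n, 0.01, 1), n)
    pred[[t]] <- p / rowSums(p)
    targets[[t]] <- sample(0:1, n, replace = TRUE)
  }
  got <- total_loss(pred, targets, tasks, eps = 0.1)
  # independent recomputation
  expected <- 0
  for (t in c("loewe", "bliss", "zip", "hsa", "s")) {
    expected <- expected + 1 * mean((pred[[t]] - targets[[t]])^2)
  }
  for (t in c("synergy", "ddi")) {
    l <- 0
    for (i in seq_len(n)) {
      q <- if (targets[[t]][i] == 1) c(0.1, 0.9) else c(0.9, 0.1)
      l <- l - sum(q * log(pred[[t]][i, ]))
    }
    expected <- expected + 10 * l / n
  }
  expect_equal(got$total, expected, tolerance = 1e-10)
  # perfect predictions give zero loss at eps = 0
  perfect <- pred
  for (t in c("loewe", "bliss", "zip", "hsa", "s")) perfect[[t]] <- targets[[t]]
  for (t in c("synergy", "ddi")) {
    P <- matrix(0, n, 2)
    P[cbind(seq_len(n), targets[[t]] + 1)] <- 1
    perfect[[t]] <- P
  }
  expect_lt(total_loss(perfect, targets, tasks, eps = 0)$total, 1e-9)
  # single regression task with error 2 on one sample
  one <- list(task_spec("loewe", "regression"))
  expect_equal(total_loss(list(loewe = 3), list(loewe = 1), one)$total, 4)
  expect_error(total_loss(pred[-1], targets, tasks), "missing task")
})

test_that("order augmentation doubles records and is invertible", {
  co <- tiny_cohort(n_samples = 30, seed = 2)
  s <- co$dataset$samples
  aug <- augment_orders(s)
  expect_equal(nrow(aug), 2 * nrow(s))
  expect_equal(aug$drug_x[nrow(s) + 1], s$drug_y[1])
  expect_equal(aug$drug_y[nrow(s) + 1], s$drug_x[1])
  expect_equal(aug$loewe[nrow(s) + 1], s$loewe[1])
  key <- paste(pmin(aug$drug_x, aug$drug_y), pmax(aug$drug_x, aug$drug_y),
               aug$cell_line)
  expect_equal(length(unique(key)), length(unique(paste(
    pmin(s$drug_x, s$drug_y), pmax(s$drug_x, s$drug_y), s$cell_line))))
})

test_that("fold assignment partitions the samples evenly and reproducibly", {
  f <- make_folds(10, 5, seed = 3)
  expect_equal(as.integer(table(f)), rep(2L, 5))
  expect_identical(f, make_folds(10, 5, seed = 3))
  expect_false(identical(f, make_folds(10, 5, seed = 4)))
  expect_error(make_folds(3, 5), "at least")
  # union of test folds over the 5 iterations covers every sample exactly once
  f2 <- make_folds(23, 5, seed = 7)
  tested <- integer(0)
  for (i in 1:5) {
    roles <- demlr:::fold_roles(f2, i, 5)
    expect_length(intersect(roles$train, roles$val), 0)
    expect_length(intersect(roles$train, roles$test), 0)
    expect_length(intersect(roles$val, roles$test), 0)
    expect_equal(sort(c(roles$train, roles$val, roles$test)), 1:23)
    tested <- c(tested, roles$test)
  }
  expect_equal(sort(tested), 1:23)
})

small_train <- function(seed_cohort = 5, seed_train = 9, epochs = 4) {
  co <- tiny_cohort(n_samples = 60, seed = seed_cohort)
  cfg <- tiny_model_config(seed = 3)
  tc <- train_config(learning_rate = 1e-3, batch_size = 16, max_epochs = epochs,
                     patience = epochs, seed = seed_train)
  list(co = co, cfg = cfg,
       fit = train_deml(co$dataset, cfg, tc, split = list(train = 1:45, val = 46:60)))
}

test_that("training is deterministic under identical seeds", {
  a <- small_train()
  b <- small_train()
  expect_identical(a$fit$history, b$fit$history)
  expect_identical(a$fit$params, b$fit$params)
})

test_that("early stopping returns the best-validation parameters", {
  r <- small_train(epochs = 6)
  h <- r$fit$history
  expect_equal(r$fit$best_epoch, which.min(h$val_loss))
  expect_equal(r$fit$best_val_loss, min(h$val_loss))
  # the returned parameters reproduce the best epoch's validation loss
  co <- r$co
  val <- co$dataset$samples[46:60, ]
  pred <- predict_symmetrized(r$fit$params, r$cfg, val, co$dataset$store)
  vl <- total_loss(pred, demlr:::task_targets(val, r$cfg$tasks), r$cfg$tasks, 0.1)
  expect_equal(vl$total, r$fit$best_val_loss, tolerance = 1e-10)
  # stopping rule: the run never continues more than `patience` epochs
  # beyond the best epoch
  tc <- train_config(learning_rate = 1e-3, batch_size = 16, max_epochs = 50,
                     patience = 3, seed = 9)
  fit2 <- train_deml(co$dataset, r$cfg, tc, split = list(train = 1:45, val = 46:60))
  expect_lte(nrow(fit2$history), fit2$best_epoch + 3)
})

test_that("training rejects bad splits", {
  co <- tiny_cohort(n_samples = 30, seed = 5)
  cfg <- tiny_model_config()
  expect_error(train_deml(co$dataset, cfg, train_config(),
                          split = list(train = integer(0), val = 1:5)), "empty")
  expect_error(train_deml(co$dataset, cfg, train_config(),
                          split = list(train = 1:10, val = 5:15)), "overlap")
})

test_that("symmetrized prediction is invariant under drug-order swap", {
  co <- tiny_cohort(n_samples = 20, seed = 8)
  cfg <- tiny_model_config(seed = 13)
  params <- deml_init(cfg)
  s <- co$dataset$samples
  swapped <- s
  swapped$drug_x <- s$drug_y
  swapped$drug_y <- s$drug_x
  p1 <- predict_symmetrized(params, cfg, s, co$dataset$store)
  p2 <- predict_symmetrized(params, cfg, swapped, co$dataset$store)
  for (t in names(p1)) expect_equal(p1[[t]], p2[[t]], tolerance = 1e-12)
  # equals the hand-computed average of the two orders
  xb <- demlr:::batch_inputs(s, co$dataset$store)
  f1 <- deml_forward(params, cfg, xb$Dx, xb$Dy, xb$Cr)$pred
  f2 <- deml_forward(params, cfg, xb$Dy, xb$Dx, xb$Cr)$pred
  expect_equal(p1$loewe, (f1$loewe + f2$loewe) / 2, tolerance = 1e-12)
  expect_equal(p1$synergy, (f1$synergy + f2$synergy) / 2, tolerance = 1e-12)
  expect_lt(max(abs(rowSums(p1$synergy) - 1)), 1e-9)
})
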