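rand_inputs <- function(cfg, n = 3, seed = 1) {
  set.seed(seed)
  list(Dx = matrix(rnorm(n * cfg$p_d), n),
       Dy = matrix(rnorm(n * cfg$p_d), n),
       Cr = matrix(rnorm(n * cfg$p_c), n))
}

test_that("parameter initialization is deterministic and Xavier-scaled", {
  cfg <- tiny_model_config(seed = 5)
  p1 <- deml_init(cfg)
  p2 <- deml_init(cfg)
  expect_identical(p1, p2)
  W <- p1$experts[[1]]$layers[[1]]$W
  lim <- sqrt(6 / (nrow(W) + ncol(W)))
  expect_true(all(abs(W) <= lim))
  expect_gt(max(abs(W)), 0.5 * lim)  # spread over the Xavier range
})

test_that("composite blocks: identity map passes nonnegative input through", {
  d <- 4
  L <- identity_block(d)
  x <- c(0.5, 0, 2, 1)
  expect_equal(drop(mlp_layer(x, L)), x)
  # eval mode is deterministic even with a dropout-bearing spec
  L2 <- mlp_new(3, layer_spec(4, dropout_rate = 0.5))
  x2 <- matrix(rnorm(6), 2)
  expect_identical(mlp_layer(x2, L2, "eval"), mlp_layer(x2, L2, "eval"))
})

test_that("composite blocks match elementwise oracle recomputation", {
  set.seed(11)
  for (rep in 1:5) {
    spec <- layer_spec(sample(2:6, 1), use_batchnorm = sample(c(TRUE, FALSE), 1),
                       dropout_rate = 0.5,
                       norm_before_activation = sample(c(TRUE, FALSE), 1))
    L <- mlp_new(4, spec)
    if (spec$use_batchnorm) {  # non-trivial running statistics
      L$rmean <- rnorm(spec$width)
      L$rvar <- runif(spec$width, 0.5, 2)
      L$gamma <- runif(spec$width, 0.5, 2)
      L$beta <- rnorm(spec$width)
    }
    X <- matrix(rnorm(12), 3, 4)
    expect_lt(max(abs(mlp_layer(X, L, "eval") - oracle_block_eval(X, L))), 1e-6)
  }
})

test_that("gating weights form a simplex and reproduce softmax arithmetic", {
  cfg <- tiny_model_config(seed = 2)
  params <- deml_init(cfg)
  xi <- rand_inputs(cfg)
  W <- gate_weights("loewe", xi$Dx, xi$Dy, xi$Cr, params, cfg)
  expect_equal(dim(W), c(3, 6))
  expect_true(all(W >= 0))
  expect_lt(max(abs(rowSums(W) - 1)), 1e-6)
  # zero logits -> uniform 1/6
  params$gates$loewe$L2$W[] <- 0
  params$gates$loewe$L2$b[] <- 0
  W0 <- gate_weights("loewe", xi$Dx, xi$Dy, xi$Cr, params, cfg)
  expect_equal(unname(W0[1, ]), rep(1 / 6, 6), tolerance = 1e-12)
  # logits (0, ln 3) with two experts -> (0.25, 0.75)
  cfg2 <- tiny_model_config(expert_kinds = c(dense = 2L), seed = 2)
  p2 <- deml_init(cfg2)
  p2$gates$loewe$L2$W[] <- 0
  p2$gates$loewe$L2$b <- c(0, log(3))
  W2 <- gate_weights("loewe", xi$Dx[1, , drop = FALSE], xi$Dy[1, , drop = FALSE],
                     xi$Cr[1, , drop = FALSE], p2, cfg2)
  expect_equal(unname(W2[1, ]), c(0.25, 0.75), tolerance = 1e-12)
  expect_error(gate_weights("nope", xi$Dx, xi$Dy, xi$Cr, params, cfg), "unknown task")
})

test_that("fusion is the gated weighted sum of expert latents", {
  l1 <- c(2, 0); l2 <- c(0, 2)
  expect_equal(drop(fuse(list(l1, l2), c(0.5, 0.5))), c(1, 1))
  expect_equal(drop(fuse(list(l1, l2), c(1, 0))), l1)
  w <- c(0.3, 0.2, 0.5)
  same <- c(4, -1)
  expect_equal(drop(fuse(list(same, same, same), w)), same)
  expect_error(fuse(list(l1, l2), c(1, 0, 0)), "one weight per latent")
  expect_error(fuse(list(c(1, 2), c(1, 2, 3)), c(0.5, 0.5)), "widths differ")
})

test_that("bi-interaction arithmetic: identity towers give Oadd + Oproduct", {
  expert <- list(kind = "bi_interaction",
                 tower_x = list(identity_block(2)),
                 tower_y = list(identity_block(2)),
                 layer_add = identity_block(2),
                 layer_prod = identity_block(2))
  # a = [1, 2], b = [3, 4]: Oadd = [4, 6], Oproduct = [3, 8], out = [7, 14]
  out <- bi_interaction_expert(c(1, 2), c(3, 4), numeric(0), expert)
  expect_equal(drop(out), c(7, 14))
  zero <- bi_interaction_expert(c(0, 0), c(0, 0), numeric(0), expert)
  expect_equal(drop(zero), c(0, 0))
})

test_that("expert symmetry properties under drug swap", {
  cfg <- tiny_model_config(seed = 4)
  params <- deml_init(cfg)
  xi <- rand_inputs(cfg)
  dense <- params$experts[[1]]
  o1 <- dense_expert(xi$Dx, xi$Dy, xi$Cr, dense)
  o2 <- dense_expert(xi$Dy, xi$Dx, xi$Cr, dense)
  expect_gt(max(abs(o1 - o2)), 1e-6)  # concatenation is order-sensitive
  expect_equal(ncol(o1), cfg$d)
  # tying the two towers makes bi-additive and bi-interaction swap-invariant
  ba <- params$experts[[3]]
  ba$tower_y <- ba$tower_x
  expect_equal(bi_additive_expert(xi$Dx, xi$Dy, xi$Cr, ba),
               bi_additive_expert(xi$Dy, xi$Dx, xi$Cr, ba), tolerance = 1e-12)
  bi <- params$experts[[5]]
  bi$tower_y <- bi$tower_x
  expect_equal(bi_interaction_expert(xi$Dx, xi$Dy, xi$Cr, bi),
               bi_interaction_expert(xi$Dy, xi$Dx, xi$Cr, bi), tolerance = 1e-12)
})

test_that("forward pass emits the full task roster deterministically", {
  cfg <- tiny_model_config(dropout = 0.5, seed = 6)
  params <- deml_init(cfg)
  xi <- rand_inputs(cfg, n = 4)
  f1 <- deml_forward(params, cfg, xi$Dx, xi$Dy, xi$Cr, mode = "eval")
  f2 <- deml_forward(params, cfg, xi$Dx, xi$Dy, xi$Cr, mode = "eval")
  expect_identical(f1$pred, f2$pred)  # eval mode is pure
  expect_setequal(names(f1$pred), c("loewe", "bliss", "zip", "hsa", "s",
                                    "synergy", "ddi"))
  for (t in c("synergy", "ddi")) {
    P <- f1$pred[[t]]
    expect_equal(dim(P), c(4, 2))
    expect_true(all(P >= 0 & P <= 1))
    expect_lt(max(abs(rowSums(P) - 1)), 1e-6)
  }
  for (t in c("loewe", "bliss", "zip", "hsa", "s")) {
    expect_length(f1$pred[[t]], 4)
    expect_true(all(is.finite(f1$pred[[t]])))
  }
  expect_error(deml_forward(params, cfg, xi$Dx[, 1:3], xi$Dy, xi$Cr),
               "do not match")
})

test_that("one shared gate gives every task identical fusion weights", {
  cfg <- tiny_model_config(share_one_gate = TRUE, seed = 8)
  params <- deml_init(cfg)
  xi <- rand_inputs(cfg)
  f <- deml_forward(params, cfg, xi$Dx, xi$Dy, xi$Cr, mode = "eval")
  for (t in names(f$gate_weights)[-1]) {
    expect_identical(f$gate_weights[[t]], f$gate_weights[[1]])
  }
})

test_that("a one-hot gate routes a task through a single expert", {
  cfg <- tiny_model_config(seed = 9)
  params <- deml_init(cfg)
  k <- 4  # route loewe through expert 4 only
  params$gates$loewe$L2$W[] <- 0
  params$gates$loewe$L2$b <- c(0, 0, 0, 1000, 0, 0)
  xi <- rand_inputs(cfg)
  f <- deml_forward(params, cfg, xi$Dx, xi$Dy, xi$Cr, mode = "eval")
  latent_k <- bi_additive_expert(xi$Dx, xi$Dy, xi$Cr, params$experts[[k]])
  direct <- tower_predict(cfg$tasks[[1]], latent_k, params$towers$loewe)
  expect_equal(f$pred$loewe, direct, tolerance = 1e-10)
})

test_that("checkpoints reload bit-exactly with their configuration", {
  cfg <- tiny_model_config(seed = 10)
  params <- deml_init(cfg)
  f <- withr::local_tempfile(fileext = ".rds")
  save_deml(params, cfg, f)
  back <- load_deml(f)
  expect_identical(back$params, params)
  expect_equal(back$config$d, cfg$d)
  expect_equal(task_names(back$config$tasks), task_names(cfg$tasks))
  xi <- rand_inputs(cfg)
  expect_identical(
    deml_forward(params, cfg, xi$Dx, xi$Dy, xi$Cr)$pred,
    deml_forward(back$params, back$config, xi$Dx, xi$Dy, xi$Cr)$pred)
})
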