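# Independent step-by-step recomputations used as oracles. These deliberately
# use explicit elementwise loops and textbook formulas, never the package's
# own matrix code paths.

BN_EPS_ORACLE <- 1e-5

oracle_affine <- function(X, A) {
  n <- nrow(X); p <- ncol(A$W)
  out <- matrix(0, n, p)
  for (i in seq_len(n)) {
    for (j in seq_len(p)) {
      acc <- A$b[j]
      for (k in seq_len(ncol(X))) acc <- acc + X[i, k] * A$W[k, j]
      out[i, j] <- acc
    }
  }
  out
}

# eval-mode composite block: affine -> ReLU -> batch-norm (running stats);
# dropout is the identity in eval mode
oracle_block_eval <- function(X, L) {
  Z <- oracle_affine(X, L)
  spec <- L$spec
  stages <- if (spec$norm_before_activation) c("bn", "relu") else c("relu", "bn")
  cur <- Z
  for (st in stages) {
    if (st == "relu" && spec$use_activation) {
      cur <- apply(cur, c(1, 2), function(v) max(v, 0))
    } else if (st == "bn" && spec$use_batchnorm) {
      out <- cur
      for (j in seq_len(ncol(cur))) {
        for (i in seq_len(nrow(cur))) {
          xh <- (cur[i, j] - L$rmean[j]) / sqrt(L$rvar[j] + BN_EPS_ORACLE)
          out[i, j] <- L$gamma[j] * xh + L$beta[j]
        }
      }
      cur <- out
    }
  }
  cur
}

oracle_stack_eval <- function(X, layers) {
  for (L in layers) X <- oracle_block_eval(X, L)
  X
}

oracle_expert_eval <- function(Dx, Dy, Cr, expert) {
  if (expert$kind == "dense") {
    oracle_stack_eval(cbind(Dx, Dy, Cr), expert$layers)
  } else if (expert$kind == "bi_additive") {
    oracle_stack_eval(cbind(Dx, Cr), expert$tower_x) +
      oracle_stack_eval(cbind(Dy, Cr), expert$tower_y)
  } else {
    a <- oracle_stack_eval(cbind(Dx, Cr), expert$tower_x)
    b <- oracle_stack_eval(cbind(Dy, Cr), expert$tower_y)
    oracle_block_eval(a + b, expert$layer_add) +
      oracle_block_eval(a * b, expert$layer_prod)
  }
}

oracle_softmax_row <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

oracle_softmax_rows <- function(logits) {
  out <- logits
  for (i in seq_len(nrow(logits))) out[i, ] <- oracle_softmax_row(logits[i, ])
  out
}

oracle_gate_eval <- function(Dx, Dy, Cr, gate) {
  Z1 <- oracle_affine(cbind(Dx, Dy, Cr), gate$L1)
  H <- apply(Z1, c(1, 2), function(v) max(v, 0))
  oracle_softmax_rows(oracle_affine(H, gate$L2))
}

oracle_tower_eval <- function(Fused, tower, kind) {
  H <- oracle_stack_eval(Fused, tower$layers)
  out <- oracle_affine(H, tower$out)
  if (kind == "classification") oracle_softmax_rows(out)
  else out[, 1]
}

# average ranks computed from scratch (sort positions, means over ties)
oracle_ranks <- function(x) {
  n <- length(x)
  ord <- order(x)
  r <- numeric(n)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && x[ord[j + 1]] == x[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

oracle_spearman <- function(x, y) oracle_pearson(oracle_ranks(x), oracle_ranks(y))

# textbook rank-difference formula (valid without ties)
oracle_spearman_d2 <- function(x, y) {
  d <- oracle_ranks(x) - oracle_ranks(y)
  m <- length(x)
  1 - 6 * sum(d^2) / (m * (m^2 - 1))
}

# AUROC as the area under the ROC step curve (trapezoids handle ties)
oracle_auroc_curve <- function(labels, probs) {
  thr <- sort(unique(probs), decreasing = TRUE)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  tpr <- c(0, vapply(thr, function(t) sum(probs >= t & labels == 1) / n1, numeric(1)))
  fpr <- c(0, vapply(thr, function(t) sum(probs >= t & labels == 0) / n0, numeric(1)))
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# AUPR by explicit loop over distinct thresholds
oracle_aupr <- function(labels, probs) {
  thr <- sort(unique(probs), decreasing = TRUE)
  n1 <- sum(labels == 1)
  area <- 0
  prev_rec <- 0
  for (t in thr) {
    sel <- probs >= t
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / n1
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# ---------------------------------------------------------------------------
# fixture builders

tiny_cohort <- function(n_samples = 120, seed = 5, ...) {
  simulate_cohort(sim_config(n_drugs = 12, n_cells = 3, p_d = 6, p_c = 4,
                             latent_dim = 3, n_samples = n_samples,
                             seed = seed, ...))
}

tiny_model_config <- function(p_d = 6, p_c = 4, dropout = 0, ...) {
  deml_config(p_d = p_d, p_c = p_c, expert_widths = c(7, 5), gate_hidden = 6,
              tower_widths = c(5, 4), dropout_rate = dropout, ...)
}

# an identity composite block: unit diagonal affine map, no normalization,
# no dropout (exact identity on nonnegative inputs)
identity_block <- function(d) {
  list(W = diag(d), b = numeric(d),
       spec = layer_spec(d, use_activation = TRUE, use_batchnorm = FALSE,
                         dropout_rate = 0))
}

random_small_config <- function(seed) {
  set.seed(seed)
  kinds <- c(dense = sample(0:2, 1), bi_additive = sample(0:2, 1),
             bi_interaction = sample(0:2, 1))
  if (sum(kinds) == 0) kinds["dense"] <- 1L
  deml_config(
    p_d = sample(2:5, 1), p_c = sample(2:4, 1),
    expert_kinds = kinds,
    expert_widths = c(sample(3:16, 1), sample(2:8, 1)),
    gate_hidden = sample(2:16, 1),
    tower_widths = c(sample(2:16, 1), sample(2:16, 1)),
    tasks = list(task_spec("loewe", "regression"),
                 task_spec("synergy", "classification")),
    share_one_gate = sample(c(TRUE, FALSE), 1),
    dropout_rate = 0.5,  # inactive in eval mode
    use_batchnorm = sample(c(TRUE, FALSE), 1),
    norm_before_activation = sample(c(TRUE, FALSE), 1),
    seed = seed
  )
}
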