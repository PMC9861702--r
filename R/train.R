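# Multi-task objective, order-augmented Adam training with early stopping,
# five-fold cross-validation protocol.

LOGP_FLOOR <- 1e-12

#' Training configuration
#'
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size.
#' @param max_epochs epoch ceiling.
#' @param patience early stopping: training stops when the validation loss
#'   has not improved for this many consecutive epochs.
#' @param smoothing_eps label-smoothing mass moved off the true class in the
#'   classification losses.
#' @param optimizer only \code{"adam"} is available.
#' @param seed master seed for initial shuffling, per-epoch batch order and
#'   dropout masks.
#' @return list of class \code{"train_config"}.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 128L,
                         max_epochs = 1000L, patience = 100L,
                         smoothing_eps = 0.1, optimizer = "adam", seed = 1L) {
  stopifnot(learning_rate > 0, patience >= 1, batch_size >= 1,
            smoothing_eps >= 0, smoothing_eps < 1)
  optimizer <- match.arg(optimizer, "adam")
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 smoothing_eps = smoothing_eps, optimizer = optimizer,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Label-smoothing cross-entropy loss
#'
#' The target distribution places mass \code{1 - eps} on the true class and
#' spreads \code{eps} over the other classes; with \code{eps = 0} this is the
#' plain cross-entropy. Probabilities are floored at 1e-12 before the
#' logarithm.
#'
#' @param probs probability vector (one sample) or matrix (rows = samples),
#'   rows summing to 1.
#' @param true_class 0-based class index (vector for a batch).
#' @param eps smoothing parameter in [0, 1).
#' @return mean loss over the samples (nonnegative scalar).
#' @export
sce_loss <- function(probs, true_class, eps = 0.1) {
  if (eps < 0 || eps >= 1) stop("smoothing eps must be in [0, 1)")
  P <- as_batch(probs)
  C <- ncol(P)
  y <- as.integer(true_class) + 1L
  if (any(y < 1L | y > C)) stop("true_class out of range")
  Q <- matrix(eps / (C - 1), nrow(P), C)
  Q[cbind(seq_len(nrow(P)), y)] <- 1 - eps
  mean(-rowSums(Q * log(pmax(P, LOGP_FLOOR))))
}

# per-task losses on a prediction list; targets from the sample table
task_targets <- function(samples, tasks) {
  out <- list()
  for (t in tasks) {
    out[[t$name]] <- switch(t$name,
      synergy = samples$synergy_label,
      ddi = samples$ddi_label,
      samples[[t$name]])
    if (is.null(out[[t$name]]))
      stop(sprintf("no target column for task '%s'", t$name))
  }
  out
}

#' Weighted multi-task loss
#'
#' Sum over tasks of the per-task mean loss times the task's loss weight:
#' mean squared error for regression tasks (weight 1 by default) and
#' label-smoothing cross-entropy for classification tasks (weight 10 by
#' default).
#'
#' @param pred per-task prediction list as returned by
#'   \code{\link{deml_forward}}.
#' @param targets per-task list of target vectors (synergy scores, or 0/1
#'   labels for classification tasks).
#' @param tasks list of \code{\link{task_spec}}.
#' @param eps label-smoothing parameter.
#' @return list with \code{total} and named \code{per_task} losses (the
#'   per-task values are unweighted).
#' @export
total_loss <- function(pred, targets, tasks, eps = 0.1) {
  per_task <- numeric(0)
  total <- 0
  for (t in tasks) {
    p <- pred[[t$name]]
    if (is.null(p)) stop(sprintf("prediction bundle missing task '%s'", t$name))
    y <- targets[[t$name]]
    l <- if (t$kind == "regression") mean((p - y)^2) else sce_loss(p, y, eps)
    per_task[t$name] <- l
    total <- total + t$loss_weight * l
  }
  list(total = total, per_task = per_task)
}

# loss + gradient w.r.t. each tower's final linear output
loss_and_dpred <- function(pred, targets, tasks, eps) {
  dPred <- list()
  per_task <- numeric(0)
  total <- 0
  for (t in tasks) {
    y <- targets[[t$name]]
    n <- length(y)
    if (t$kind == "regression") {
      p <- pred[[t$name]]
      l <- mean((p - y)^2)
      dPred[[t$name]] <- matrix(t$loss_weight * 2 * (p - y) / n, ncol = 1)
    } else {
      P <- pred[[t$name]]
      C <- ncol(P)
      yi <- as.integer(y) + 1L
      Q <- matrix(eps / (C - 1), n, C)
      Q[cbind(seq_len(n), yi)] <- 1 - eps
      l <- mean(-rowSums(Q * log(pmax(P, LOGP_FLOOR))))
      # gradient through the softmax of the tower logits
      dPred[[t$name]] <- t$loss_weight * (P - Q) / n
    }
    per_task[t$name] <- l
    total <- total + t$loss_weight * l
  }
  list(total = total, per_task = per_task, dPred = dPred)
}

#' Duplicate training samples in both drug orders
#'
#' Each record is emitted twice, once as (x, y) and once as (y, x), with
#' identical targets. Applied to the training split only; test and validation
#' predictions instead average the two orders
#' (\code{\link{predict_symmetrized}}).
#'
#' @param samples combination data.frame.
#' @return data.frame with 2n rows.
#' @export
augment_orders <- function(samples) {
  swapped <- samples
  swapped$drug_x <- samples$drug_y
  swapped$drug_y <- samples$drug_x
  out <- rbind(samples, swapped)
  rownames(out) <- NULL
  out
}

#' Five-fold assignment
#'
#' Shuffles the samples and assigns near-equal folds (sizes differ by at most
#' one). In cross-validation iteration i, fold i is the test set, the next
#' fold cyclically is the validation set and the remaining folds train.
#'
#' @param n number of samples.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return integer vector of fold ids in 1..k.
#' @export
make_folds <- function(n, k = 5L, seed = 1L) {
  if (n < k) stop(sprintf("need at least %d samples for %d folds", k, k))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

fold_roles <- function(fold_id, iteration, k = max(fold_id)) {
  test <- iteration
  val <- iteration %% k + 1L
  list(train = which(!fold_id %in% c(test, val)),
       val = which(fold_id == val),
       test = which(fold_id == test))
}

# Adam update over a gradient tree mirroring the parameter tree.
adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  step <- function(p, g, m, v) {
    if (is.list(g)) {
      if (is.null(m)) m <- list()
      if (is.null(v)) v <- list()
      for (i in seq_along(g)) {
        nm <- names(g)[i]
        key <- if (!is.null(nm) && nzchar(nm)) nm else i
        if (identical(key, "kind")) next
        getk <- function(l) {
          if (is.character(key)) l[[key]]
          else if (key <= length(l)) l[[key]] else NULL
        }
        r <- step(p[[key]], g[[key]], getk(m), getk(v))
        p[[key]] <- r$p
        m[[key]] <- r$m
        v[[key]] <- r$v
      }
      list(p = p, m = m, v = v)
    } else {
      if (is.null(m)) { m <- 0 * g; v <- 0 * g }
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  if (is.null(state)) state <- list(m = list(), v = list())
  r <- step(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v))
}

#' Train the model on a train/validation split
#'
#' Runs Adam over shuffled mini-batches of the order-augmented training
#' records. After every epoch the validation loss is computed from
#' order-averaged, un-augmented predictions (mirroring test-time behaviour);
#' the parameters of the best-validation epoch are returned, and training
#' stops when the validation loss has not improved for \code{patience}
#' epochs or the epoch ceiling is reached.
#'
#' @param dataset a \code{\link{deml_dataset}}.
#' @param model_config a \code{\link{deml_config}}.
#' @param tc a \code{\link{train_config}}.
#' @param split list with integer index vectors \code{train} and \code{val}
#'   (disjoint).
#' @param verbose print per-epoch progress.
#' @return list with \code{params} (best-validation epoch), \code{history}
#'   (data.frame epoch / train_loss / val_loss plus per-task validation
#'   losses), \code{best_epoch}, \code{best_val_loss}.
#' @export
train_deml <- function(dataset, model_config, tc = train_config(),
                       split, verbose = FALSE) {
  if (length(split$train) == 0 || length(split$val) == 0)
    stop("empty train or validation split")
  if (length(intersect(split$train, split$val)))
    stop("train and validation splits overlap")
  store <- dataset$store
  tasks <- model_config$tasks
  train_samples <- augment_orders(dataset$samples[split$train, , drop = FALSE])
  val_samples <- dataset$samples[split$val, , drop = FALSE]
  val_targets <- task_targets(val_samples, tasks)

  params <- deml_init(model_config)
  state <- NULL
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  n_train <- nrow(train_samples)
  best_val <- Inf
  best_epoch <- 0L
  best_params <- params
  hist <- list()
  step_t <- 0L
  for (epoch in seq_len(tc$max_epochs)) {
    set.seed((tc$seed + 7919L * epoch) %% .Machine$integer.max)
    ord <- sample.int(n_train)
    batch_losses <- numeric(0)
    for (start in seq(1, n_train, by = tc$batch_size)) {
      idx <- ord[start:min(start + tc$batch_size - 1, n_train)]
      batch <- train_samples[idx, , drop = FALSE]
      xb <- batch_inputs(batch, store)
      fwd <- deml_forward(params, model_config, xb$Dx, xb$Dy, xb$Cr,
                          mode = "train", keep_cache = TRUE)
      params <- fwd$params  # refreshed batch-norm running statistics
      tg <- task_targets(batch, tasks)
      ld <- loss_and_dpred(fwd$pred, tg, tasks, tc$smoothing_eps)
      if (!is.finite(ld$total))
        stop(sprintf("non-finite training loss at epoch %d", epoch))
      grads <- deml_backward(ld$dPred, fwd, params, model_config)
      step_t <- step_t + 1L
      up <- adam_step(params, grads, state, tc$learning_rate, step_t)
      params <- up$params
      state <- up$state
      batch_losses <- c(batch_losses, ld$total)
    }
    vp <- predict_bundle(params, model_config, val_samples, store,
                         symmetrize = TRUE)
    vl <- total_loss(vp, val_targets, tasks, tc$smoothing_eps)
    if (!is.finite(vl$total))
      stop(sprintf("non-finite validation loss at epoch %d", epoch))
    hist[[epoch]] <- c(epoch = epoch, train_loss = mean(batch_losses),
                       val_loss = vl$total,
                       stats::setNames(vl$per_task, paste0("val_", names(vl$per_task))))
    if (vl$total < best_val) {
      best_val <- vl$total
      best_epoch <- epoch
      best_params <- params
    }
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f%s", epoch,
                      mean(batch_losses), vl$total,
                      if (best_epoch == epoch) " *" else ""))
    if (epoch - best_epoch >= tc$patience) break
  }
  history <- as.data.frame(do.call(rbind, hist))
  list(params = best_params, history = history,
       best_epoch = best_epoch, best_val_loss = best_val)
}

# per-task predictions for a sample table (optionally order-averaged)
predict_bundle <- function(params, config, samples, store, symmetrize = TRUE,
                           batch_size = 512L) {
  n <- nrow(samples)
  pred <- NULL
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    xb <- batch_inputs(samples[idx, , drop = FALSE], store)
    p1 <- deml_forward(params, config, xb$Dx, xb$Dy, xb$Cr, mode = "eval")$pred
    if (symmetrize) {
      p2 <- deml_forward(params, config, xb$Dy, xb$Dx, xb$Cr, mode = "eval")$pred
      p1 <- mapply(function(a, b) (a + b) / 2, p1, p2, SIMPLIFY = FALSE)
    }
    pred <- if (is.null(pred)) p1 else
      mapply(function(acc, new) if (is.matrix(acc)) rbind(acc, new) else c(acc, new),
             pred, p1, SIMPLIFY = FALSE)
  }
  pred
}

#' Order-averaged prediction for combination samples
#'
#' Runs the model in eval mode on both drug orders, (x, y) and (y, x), and
#' averages the two outputs per task; the result is invariant under swapping
#' the drugs of a sample. Averaged classification probabilities still sum
#' to one.
#'
#' @param params trained parameters.
#' @param config the model configuration.
#' @param samples combination data.frame.
#' @param store the \code{\link{feature_store}}.
#' @return per-task prediction list (regression: numeric vector;
#'   classification: n x 2 probability matrix).
#' @export
predict_symmetrized <- function(params, config, samples, store) {
  predict_bundle(params, config, samples, store, symmetrize = TRUE)
}

#' Five-fold cross-validation
#'
#' Shuffles the dataset into five folds; in each iteration three folds train,
#' one is used for early stopping and one is held out for testing, so that
#' every sample is tested exactly once across the five iterations. Test
#' predictions are order-averaged. Metrics are averaged across folds.
#'
#' @param dataset a \code{\link{deml_dataset}}.
#' @param model_config a \code{\link{deml_config}}.
#' @param tc a \code{\link{train_config}}.
#' @param k number of folds.
#' @param seed fold-assignment seed.
#' @param verbose print progress.
#' @return list with \code{fold_id}, per-fold \code{reports}, and
#'   \code{aggregate} (mean/variance per metric, see
#'   \code{\link{aggregate_cv}}).
#' @export
run_cv <- function(dataset, model_config, tc = train_config(), k = 5L,
                   seed = 1L, verbose = FALSE) {
  n <- nrow(dataset$samples)
  fold_id <- make_folds(n, k, seed)
  reports <- vector("list", k)
  for (i in seq_len(k)) {
    roles <- fold_roles(fold_id, i, k)
    fit <- train_deml(dataset, model_config, tc,
                      split = list(train = roles$train, val = roles$val),
                      verbose = verbose)
    test_samples <- dataset$samples[roles$test, , drop = FALSE]
    pred <- predict_symmetrized(fit$params, model_config, test_samples,
                                dataset$store)
    reports[[i]] <- evaluate_predictions(pred, test_samples, model_config$tasks)
    if (verbose) message(sprintf("fold %d/%d done (best epoch %d)", i, k, fit$best_epoch))
  }
  list(fold_id = fold_id, reports = reports, aggregate = aggregate_cv(reports))
}
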