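# User-facing fitting interface in the classic R modelling idiom: deml()
# fits the model and returns a classed object with the usual methods.

#' Fit the multi-task synergy/interaction model
#'
#' Trains the ensemble-based multi-task network on a combination dataset
#' with early stopping on a validation split, and returns a fitted-model
#' object supporting \code{predict}, \code{print}, \code{summary},
#' \code{plot}, \code{coef} and \code{residuals}.
#'
#' @param data a \code{\link{deml_dataset}} (combination samples plus their
#'   feature store).
#' @param model_config a \code{\link{deml_config}}; when omitted, one is
#'   built from the store's feature dimensions with default architecture.
#' @param train_cfg a \code{\link{train_config}}.
#' @param split optional list with integer index vectors \code{train} and
#'   \code{val}; by default a seeded 90/10 split.
#' @param verbose print per-epoch progress.
#' @return an object of class \code{"deml"}.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(sim_config(n_samples = 300, seed = 7))
#' cfg <- deml_config(p_d = cohort$dataset$store$p_d,
#'                    p_c = cohort$dataset$store$p_c,
#'                    expert_widths = c(32, 16), gate_hidden = 16,
#'                    tower_widths = c(16, 16), dropout_rate = 0.1)
#' fit <- deml(cohort$dataset, cfg, train_config(learning_rate = 1e-3,
#'                                               max_epochs = 5, patience = 5))
#' predict(fit, head(cohort$dataset$samples))
#' }
#' @export
deml <- function(data, model_config = NULL, train_cfg = train_config(),
                 split = NULL, verbose = FALSE) {
  if (!inherits(data, "deml_dataset")) stop("data must be a deml_dataset")
  if (is.null(model_config))
    model_config <- deml_config(p_d = data$store$p_d, p_c = data$store$p_c)
  if (model_config$p_d != data$store$p_d || model_config$p_c != data$store$p_c)
    stop("model_config feature dimensions do not match the store")
  n <- nrow(data$samples)
  if (is.null(split)) {
    idx <- with_seed(str_hash("holdout", seed = train_cfg$seed), sample.int(n))
    n_val <- max(1L, round(0.1 * n))
    split <- list(train = idx[-seq_len(n_val)], val = idx[seq_len(n_val)])
  }
  res <- train_deml(data, model_config, train_cfg, split, verbose = verbose)
  structure(list(params = res$params, model_config = model_config,
                 train_config = train_cfg, history = res$history,
                 best_epoch = res$best_epoch, best_val_loss = res$best_val_loss,
                 split = split, data = data),
            class = "deml")
}

#' Predict synergy scores and class probabilities for combinations
#'
#' Predictions are order-averaged by default: the model is evaluated on both
#' drug orders and the outputs are averaged, making the result invariant
#' under swapping \code{drug_x} and \code{drug_y}.
#'
#' @param object a fitted \code{"deml"} object.
#' @param newdata combination data.frame (columns \code{drug_x},
#'   \code{drug_y}, \code{cell_line}); defaults to the training data.
#' @param store feature store to resolve ids in; defaults to the fit's store.
#' @param symmetrize average the two drug orders.
#' @param ... unused.
#' @return data.frame with the id columns, one \code{pred_<task>} column per
#'   regression task and one \code{prob_<task>} (positive-class probability)
#'   column per classification task.
#' @export
predict.deml <- function(object, newdata = NULL, store = NULL,
                         symmetrize = TRUE, ...) {
  if (is.null(newdata)) newdata <- object$data$samples
  if (is.null(store)) store <- object$data$store
  pred <- predict_bundle(object$params, object$model_config, newdata, store,
                         symmetrize = symmetrize)
  out <- newdata[, c("drug_x", "drug_y", "cell_line"), drop = FALSE]
  for (t in object$model_config$tasks) {
    if (t$kind == "regression") out[[paste0("pred_", t$name)]] <- pred[[t$name]]
    else out[[paste0("prob_", t$name)]] <- pred[[t$name]][, 2]
  }
  rownames(out) <- NULL
  out
}

#' @export
print.deml <- function(x, ...) {
  cfg <- x$model_config
  roster <- paste(sprintf("%d %s", cfg$expert_kinds, names(cfg$expert_kinds)),
                  collapse = " + ")
  cat("Ensemble multi-task synergy/interaction model\n")
  cat(sprintf("  experts: %s (latent d = %d)\n", roster, cfg$d))
  cat(sprintf("  tasks: %s\n", paste(task_names(cfg$tasks), collapse = ", ")))
  cat(sprintf("  gating: %s\n",
              if (cfg$share_one_gate) "one shared gate" else "one gate per task"))
  cat(sprintf("  trained %d epochs; best validation loss %.4f at epoch %d\n",
              nrow(x$history), x$best_val_loss, x$best_epoch))
  invisible(x)
}

#' @export
summary.deml <- function(object, ...) {
  val <- object$data$samples[object$split$val, , drop = FALSE]
  pred <- predict_bundle(object$params, object$model_config, val,
                         object$data$store, symmetrize = TRUE)
  metrics <- evaluate_predictions(pred, val, object$model_config$tasks)
  structure(list(fit = object, val_metrics = metrics,
                 n_val = nrow(val)), class = "summary.deml")
}

#' @export
print.summary.deml <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\nValidation metrics (%d held-out samples, order-averaged):\n", x$n_val))
  for (t in names(x$val_metrics)) {
    v <- x$val_metrics[[t]]
    cat(sprintf("  %-8s %s\n", t,
                paste(sprintf("%s=%.4f", names(v), v), collapse = "  ")))
  }
  invisible(x)
}

#' @export
plot.deml <- function(x, ...) {
  h <- x$history
  rng <- range(c(h$train_loss, h$val_loss), finite = TRUE)
  graphics::plot(h$epoch, h$train_loss, type = "l", col = "steelblue",
                 xlab = "epoch", ylab = "loss", ylim = rng,
                 main = "Training history", ...)
  graphics::lines(h$epoch, h$val_loss, col = "firebrick")
  graphics::abline(v = x$best_epoch, lty = 3, col = "grey40")
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' @export
coef.deml <- function(object, ...) {
  flatten_params(object$params)
}

#' @export
residuals.deml <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data$samples
  pred <- predict_bundle(object$params, object$model_config, newdata,
                         object$data$store, symmetrize = TRUE)
  reg <- Filter(function(t) t$kind == "regression", object$model_config$tasks)
  out <- sapply(reg, function(t) newdata[[t$name]] - pred[[t$name]])
  colnames(out) <- vapply(reg, `[[`, character(1), "name")
  out
}
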