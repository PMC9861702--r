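# DEML computation graph: hybrid ensemble layer (dense, bi-additive and
# bi-interaction experts), per-task gating networks, and prediction towers.

#' Task specification
#'
#' @param name task name.
#' @param kind \code{"regression"} or \code{"classification"}.
#' @param loss_weight weight of this task's loss in the multi-task objective;
#'   defaults to 1 for regression and 10 for classification, balancing the
#'   0-1 probability scale of the classifiers against the synergy-score scale.
#' @return a list of class \code{"task_spec"}.
#' @export
task_spec <- function(name, kind = c("regression", "classification"),
                      loss_weight = NULL) {
  kind <- match.arg(kind)
  if (is.null(loss_weight)) loss_weight <- if (kind == "regression") 1 else 10
  structure(list(name = name, kind = kind, loss_weight = loss_weight),
            class = "task_spec")
}

#' Default seven-task roster
#'
#' Five synergy-score regression tasks (Loewe, Bliss, ZIP, HSA, S) plus the
#' synergy and adverse-DDI classification tasks.
#'
#' @return list of \code{\link{task_spec}} objects.
#' @export
default_tasks <- function() {
  c(lapply(REGRESSION_TASKS, task_spec, kind = "regression"),
    lapply(CLASSIFICATION_TASKS, task_spec, kind = "classification"))
}

#' Names of a task roster
#' @param tasks list of \code{\link{task_spec}} objects.
#' @return character vector of task names.
#' @export
task_names <- function(tasks) vapply(tasks, `[[`, character(1), "name")

#' Model configuration
#'
#' Defines the full architecture: expert roster (default two experts of each
#' of the three kinds, six in total), expert widths (the last width is the
#' shared latent dimension d), gating hidden width, tower widths and the task
#' roster. The gating output dimension always equals the number of experts M,
#' since the fusion softmax weights M expert outputs.
#'
#' @param p_d drug-descriptor dimension (541 at full scale).
#' @param p_c cell-line expression dimension (927 at full scale).
#' @param expert_kinds named integer vector of expert counts per kind
#'   (\code{dense}, \code{bi_additive}, \code{bi_interaction}).
#' @param expert_widths widths of the two expert layers; the last entry is
#'   the latent dimension d shared by all experts.
#' @param gate_hidden hidden width of each gating network.
#' @param tower_widths widths of the two tower layers before the final linear
#'   map.
#' @param tasks list of \code{\link{task_spec}}; defaults to the seven-task
#'   roster.
#' @param share_one_gate use one task-common gating network for every task
#'   instead of per-task gates.
#' @param dropout_rate dropout probability inside expert/tower blocks.
#' @param use_batchnorm apply batch normalization inside expert/tower blocks.
#' @param norm_before_activation see \code{\link{layer_spec}}.
#' @param seed seed for parameter initialization.
#' @return list of class \code{"deml_config"}.
#' @export
deml_config <- function(p_d = 541, p_c = 927,
                        expert_kinds = c(dense = 2L, bi_additive = 2L, bi_interaction = 2L),
                        expert_widths = c(4096L, 2048L),
                        gate_hidden = 4096L,
                        tower_widths = c(2048L, 2048L),
                        tasks = default_tasks(),
                        share_one_gate = FALSE,
                        dropout_rate = 0.5,
                        use_batchnorm = TRUE,
                        norm_before_activation = FALSE,
                        seed = 1L) {
  kinds <- c(dense = 0L, bi_additive = 0L, bi_interaction = 0L)
  kinds[names(expert_kinds)] <- as.integer(expert_kinds)
  if (sum(kinds) < 1) stop("at least one expert is required")
  if (length(tasks) < 1) stop("at least one task is required")
  nm <- task_names(tasks)
  if (anyDuplicated(nm)) stop("task names must be unique")
  structure(list(
    p_d = as.integer(p_d), p_c = as.integer(p_c),
    expert_kinds = kinds,
    expert_widths = as.integer(expert_widths),
    d = as.integer(expert_widths[length(expert_widths)]),
    gate_hidden = as.integer(gate_hidden),
    tower_widths = as.integer(tower_widths),
    tasks = tasks,
    share_one_gate = isTRUE(share_one_gate),
    dropout_rate = dropout_rate,
    use_batchnorm = isTRUE(use_batchnorm),
    norm_before_activation = isTRUE(norm_before_activation),
    seed = as.integer(seed)
  ), class = "deml_config")
}

n_experts <- function(config) sum(config$expert_kinds)

expert_roster <- function(config) {
  rep(names(config$expert_kinds), config$expert_kinds)
}

block_spec <- function(config, width) {
  layer_spec(width, use_activation = TRUE,
             use_batchnorm = config$use_batchnorm,
             dropout_rate = config$dropout_rate,
             norm_before_activation = config$norm_before_activation)
}

new_stack <- function(n_in, widths, config) {
  layers <- vector("list", length(widths))
  for (i in seq_along(widths)) {
    layers[[i]] <- mlp_new(n_in, block_spec(config, widths[i]))
    n_in <- widths[i]
  }
  layers
}

new_expert <- function(kind, config) {
  w <- config$expert_widths
  d <- config$d
  cat_all <- 2L * config$p_d + config$p_c
  cat_one <- config$p_d + config$p_c
  if (kind == "dense") {
    list(kind = kind, layers = new_stack(cat_all, w, config))
  } else if (kind == "bi_additive") {
    list(kind = kind,
         tower_x = new_stack(cat_one, w, config),
         tower_y = new_stack(cat_one, w, config))
  } else {
    list(kind = kind,
         tower_x = new_stack(cat_one, w, config),
         tower_y = new_stack(cat_one, w, config),
         layer_add = mlp_new(d, block_spec(config, d)),
         layer_prod = mlp_new(d, block_spec(config, d)))
  }
}

new_gate <- function(config) {
  cat_all <- 2L * config$p_d + config$p_c
  list(L1 = affine_new(cat_all, config$gate_hidden),
       L2 = affine_new(config$gate_hidden, n_experts(config)))
}

new_tower <- function(config, kind) {
  out_dim <- if (kind == "classification") 2L else 1L
  list(layers = new_stack(config$d, config$tower_widths, config),
       out = affine_new(config$tower_widths[length(config$tower_widths)], out_dim))
}

#' Initialize model parameters
#'
#' All affine maps use Xavier (Glorot) uniform initialization, seeded from
#' the configuration seed.
#'
#' @param config a \code{\link{deml_config}}.
#' @return nested parameter list with elements \code{experts}, \code{gates},
#'   \code{towers}.
#' @export
deml_init <- function(config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  experts <- lapply(expert_roster(config), new_expert, config = config)
  nm <- task_names(config$tasks)
  gates <- if (config$share_one_gate) {
    list(shared = new_gate(config))
  } else {
    stats::setNames(lapply(nm, function(t) new_gate(config)), nm)
  }
  towers <- stats::setNames(
    lapply(config$tasks, function(t) new_tower(config, t$kind)), nm)
  list(experts = experts, gates = gates, towers = towers)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# ---------------------------------------------------------------------------
# forward passes

stack_fwd <- function(X, layers, mode) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- mlp_fwd(X, layers[[i]], mode)
    X <- r$out
    caches[[i]] <- r$cache
    layers[[i]] <- r$layer
  }
  list(out = X, caches = caches, layers = layers)
}

stack_bwd <- function(dOut, caches, layers, need_dx = FALSE) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- mlp_bwd(dOut, caches[[i]], layers[[i]], need_dx = need_dx || i > 1)
    grads[[i]] <- r$grads
    dOut <- r$dX
  }
  list(dX = dOut, grads = grads)
}

expert_fwd <- function(Xb, expert, mode) {
  if (expert$kind == "dense") {
    r <- stack_fwd(Xb$cat_all, expert$layers, mode)
    expert$layers <- r$layers
    list(out = r$out, cache = list(dense = r$caches), expert = expert)
  } else if (expert$kind == "bi_additive") {
    rx <- stack_fwd(Xb$cat_x, expert$tower_x, mode)
    ry <- stack_fwd(Xb$cat_y, expert$tower_y, mode)
    expert$tower_x <- rx$layers
    expert$tower_y <- ry$layers
    list(out = rx$out + ry$out, cache = list(x = rx$caches, y = ry$caches),
         expert = expert)
  } else {
    rx <- stack_fwd(Xb$cat_x, expert$tower_x, mode)
    ry <- stack_fwd(Xb$cat_y, expert$tower_y, mode)
    a <- rx$out; b <- ry$out
    ra <- mlp_fwd(a + b, expert$layer_add, mode)
    rp <- mlp_fwd(a * b, expert$layer_prod, mode)
    expert$tower_x <- rx$layers
    expert$tower_y <- ry$layers
    expert$layer_add <- ra$layer
    expert$layer_prod <- rp$layer
    list(out = ra$out + rp$out,
         cache = list(x = rx$caches, y = ry$caches, a = a, b = b,
                      add = ra$cache, prod = rp$cache),
         expert = expert)
  }
}

expert_bwd <- function(dOut, cache, expert) {
  if (expert$kind == "dense") {
    r <- stack_bwd(dOut, cache$dense, expert$layers)
    list(grads = list(kind = expert$kind, layers = r$grads))
  } else if (expert$kind == "bi_additive") {
    rx <- stack_bwd(dOut, cache$x, expert$tower_x)
    ry <- stack_bwd(dOut, cache$y, expert$tower_y)
    list(grads = list(kind = expert$kind, tower_x = rx$grads, tower_y = ry$grads))
  } else {
    ra <- mlp_bwd(dOut, cache$add, expert$layer_add, need_dx = TRUE)
    rp <- mlp_bwd(dOut, cache$prod, expert$layer_prod, need_dx = TRUE)
    da <- ra$dX + rp$dX * cache$b
    db <- ra$dX + rp$dX * cache$a
    rx <- stack_bwd(da, cache$x, expert$tower_x)
    ry <- stack_bwd(db, cache$y, expert$tower_y)
    list(grads = list(kind = expert$kind, tower_x = rx$grads, tower_y = ry$grads,
                      layer_add = ra$grads, layer_prod = rp$grads))
  }
}

gate_fwd <- function(Xcat, gate) {
  r1 <- affine_fwd(Xcat, gate$L1)
  H <- pmax(r1$out, 0)
  r2 <- affine_fwd(H, gate$L2)
  W <- softmax_rows(r2$out)
  list(weights = W, cache = list(X = Xcat, Z1 = r1$out, H = H))
}

gate_bwd <- function(dW, W, cache, gate) {
  # softmax backward per row
  dlogits <- W * (dW - rowSums(dW * W))
  g2 <- list(W = crossprod(cache$H, dlogits), b = colSums(dlogits))
  dH <- dlogits %*% t(gate$L2$W)
  dZ1 <- dH * (cache$Z1 > 0)
  g1 <- list(W = crossprod(cache$X, dZ1), b = colSums(dZ1))
  list(L1 = g1, L2 = g2)
}

tower_fwd <- function(Fused, tower, kind, mode) {
  r <- stack_fwd(Fused, tower$layers, mode)
  ro <- affine_fwd(r$out, tower$out)
  tower$layers <- r$layers
  if (kind == "classification") {
    probs <- softmax_rows(ro$out)
    dimnames(probs) <- list(NULL, c("neg", "pos"))
    list(out = probs, logits = ro$out,
         cache = list(stack = r$caches, out_in = r$out), tower = tower)
  } else {
    list(out = unname(drop(ro$out)), cache = list(stack = r$caches, out_in = r$out),
         tower = tower)
  }
}

tower_bwd <- function(dOutLinear, cache, tower) {
  go <- list(W = crossprod(cache$out_in, dOutLinear), b = colSums(dOutLinear))
  dH <- dOutLinear %*% t(tower$out$W)
  r <- stack_bwd(dH, cache$stack, tower$layers, need_dx = TRUE)
  list(dFused = r$dX, grads = list(layers = r$grads, out = go))
}

prep_batch <- function(Dx, Dy, Cr) {
  list(cat_all = cbind(Dx, Dy, Cr), cat_x = cbind(Dx, Cr), cat_y = cbind(Dy, Cr))
}

#' Forward pass of the full model
#'
#' Runs every expert once on the batch, then for each task computes gating
#' weights over the expert latents, fuses them by weighted sum, and applies
#' the task's prediction tower. In eval mode the output is a deterministic
#' function of inputs and parameters.
#'
#' @param params parameters from \code{\link{deml_init}}.
#' @param config the \code{\link{deml_config}}.
#' @param Dx,Dy,Cr input batches (rows = samples): drug-x descriptors,
#'   drug-y descriptors, cell-line profile.
#' @param mode \code{"eval"} or \code{"train"}.
#' @param keep_cache keep intermediate activations (needed for the backward
#'   pass).
#' @return list with \code{pred} (per task: numeric vector for regression, or
#'   n x 2 probability matrix with columns \code{neg}, \code{pos} for
#'   classification), \code{gate_weights} per task, \code{params} (with
#'   refreshed batch-norm running statistics), and \code{cache} if requested.
#' @export
deml_forward <- function(params, config, Dx, Dy, Cr,
                         mode = c("eval", "train"), keep_cache = FALSE) {
  mode <- match.arg(mode)
  if (is.null(dim(Dx))) Dx <- matrix(Dx, nrow = 1)
  if (is.null(dim(Dy))) Dy <- matrix(Dy, nrow = 1)
  if (is.null(dim(Cr))) Cr <- matrix(Cr, nrow = 1)
  if (ncol(Dx) != config$p_d || ncol(Dy) != config$p_d || ncol(Cr) != config$p_c)
    stop(sprintf("input widths (%d, %d, %d) do not match config (p_d=%d, p_c=%d)",
                 ncol(Dx), ncol(Dy), ncol(Cr), config$p_d, config$p_c))
  Xb <- prep_batch(Dx, Dy, Cr)
  M <- n_experts(config)
  E <- vector("list", M)
  ec <- vector("list", M)
  for (m in seq_len(M)) {
    r <- expert_fwd(Xb, params$experts[[m]], mode)
    if (ncol(r$out) != config$d)
      stop(sprintf("expert %d produced latent width %d, expected d=%d",
                   m, ncol(r$out), config$d))
    E[[m]] <- r$out
    ec[[m]] <- r$cache
    params$experts[[m]] <- r$expert
  }
  nm <- task_names(config$tasks)
  pred <- list(); gw <- list(); gcache <- list(); tcache <- list()
  shared_gate <- NULL
  for (i in seq_along(config$tasks)) {
    t <- config$tasks[[i]]
    if (config$share_one_gate) {
      if (is.null(shared_gate)) shared_gate <- gate_fwd(Xb$cat_all, params$gates$shared)
      g <- shared_gate
    } else {
      g <- gate_fwd(Xb$cat_all, params$gates[[t$name]])
    }
    W <- g$weights
    Fused <- matrix(0, nrow(Dx), config$d)
    for (m in seq_len(M)) Fused <- Fused + W[, m] * E[[m]]
    tr <- tower_fwd(Fused, params$towers[[t$name]], t$kind, mode)
    params$towers[[t$name]] <- tr$tower
    pred[[t$name]] <- tr$out
    gw[[t$name]] <- W
    if (keep_cache) {
      gcache[[t$name]] <- g$cache
      tcache[[t$name]] <- tr$cache
    }
  }
  out <- list(pred = pred, gate_weights = gw, params = params)
  if (keep_cache) {
    out$cache <- list(Xb = Xb, E = E, expert_caches = ec,
                      gate_caches = gcache, tower_caches = tcache,
                      gate_weights = gw)
  }
  out
}

# Backward pass: dPred is a per-task list of gradients w.r.t. the tower's
# final *linear* output (n x 1 for regression, n x 2 logits for
# classification). Returns a gradient tree mirroring the parameter tree.
deml_backward <- function(dPred, fwd, params, config) {
  cache <- fwd$cache
  M <- n_experts(config)
  n <- nrow(cache$Xb$cat_all)
  dE <- lapply(seq_len(M), function(m) matrix(0, n, config$d))
  tower_grads <- list()
  gate_grads <- list()
  shared_acc <- NULL
  for (t in config$tasks) {
    tb <- tower_bwd(dPred[[t$name]], cache$tower_caches[[t$name]],
                    params$towers[[t$name]])
    tower_grads[[t$name]] <- tb$grads
    W <- cache$gate_weights[[t$name]]
    dW <- matrix(0, n, M)
    for (m in seq_len(M)) {
      dE[[m]] <- dE[[m]] + W[, m] * tb$dFused
      dW[, m] <- rowSums(tb$dFused * cache$E[[m]])
    }
    gate_name <- if (config$share_one_gate) "shared" else t$name
    gb <- gate_bwd(dW, W, cache$gate_caches[[t$name]], params$gates[[gate_name]])
    if (config$share_one_gate) {
      if (is.null(shared_acc)) shared_acc <- gb
      else shared_acc <- list(
        L1 = list(W = shared_acc$L1$W + gb$L1$W, b = shared_acc$L1$b + gb$L1$b),
        L2 = list(W = shared_acc$L2$W + gb$L2$W, b = shared_acc$L2$b + gb$L2$b))
    } else {
      gate_grads[[t$name]] <- gb
    }
  }
  if (config$share_one_gate) gate_grads <- list(shared = shared_acc)
  expert_grads <- vector("list", M)
  for (m in seq_len(M)) {
    expert_grads[[m]] <- expert_bwd(dE[[m]], cache$expert_caches[[m]],
                                    params$experts[[m]])$grads
  }
  list(experts = expert_grads, gates = gate_grads, towers = tower_grads)
}

# ---------------------------------------------------------------------------
# exported single-operation surfaces (used directly in tests and examples)

#' Expert subnetworks of the hybrid ensemble layer
#'
#' \code{dense_expert} concatenates the three inputs and applies two
#' composite blocks. \code{bi_additive_expert} runs drug-specific towers on
#' (dx, cr) and (dy, cr) and adds the outputs elementwise.
#' \code{bi_interaction_expert} additionally forms the elementwise product of
#' the two tower outputs, passes sum and product through separate single
#' blocks, and adds the results.
#'
#' @param dx,dy,cr input vectors or batch matrices.
#' @param params expert parameter list (an element of
#'   \code{deml_init(config)$experts} of the matching kind).
#' @param mode \code{"eval"} or \code{"train"}.
#' @return matrix of latent vectors (rows = samples, columns = latent dim d).
#' @export
dense_expert <- function(dx, dy, cr, params, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  stopifnot(params$kind == "dense")
  expert_fwd(prep_batch(as_batch(dx), as_batch(dy), as_batch(cr)), params, mode)$out
}

#' @rdname dense_expert
#' @export
bi_additive_expert <- function(dx, dy, cr, params, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  stopifnot(params$kind == "bi_additive")
  expert_fwd(prep_batch(as_batch(dx), as_batch(dy), as_batch(cr)), params, mode)$out
}

#' @rdname dense_expert
#' @export
bi_interaction_expert <- function(dx, dy, cr, params, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  stopifnot(params$kind == "bi_interaction")
  expert_fwd(prep_batch(as_batch(dx), as_batch(dy), as_batch(cr)), params, mode)$out
}

as_batch <- function(x) if (is.null(dim(x))) matrix(x, nrow = 1) else x

#' Gating weights over the experts for one task
#'
#' A two-layer network (affine + ReLU, then affine) on the concatenated
#' inputs followed by a row-wise softmax; the output is a probability vector
#' over the M experts for every sample.
#'
#' @param task task name.
#' @param dx,dy,cr input vectors or batch matrices.
#' @param params full parameter list from \code{\link{deml_init}}.
#' @param config the model configuration.
#' @return matrix (n x M) of nonnegative weights, each row summing to 1.
#' @export
gate_weights <- function(task, dx, dy, cr, params, config) {
  gate_name <- if (config$share_one_gate) "shared" else task
  if (!gate_name %in% names(params$gates))
    stop(sprintf("unknown task '%s' (registered: %s)", task,
                 paste(names(params$gates), collapse = ", ")))
  Xcat <- cbind(as_batch(dx), as_batch(dy), as_batch(cr))
  gate_fwd(Xcat, params$gates[[gate_name]])$weights
}

#' Fuse expert latents by gated weighted sum
#'
#' @param latents list of M latent matrices (or vectors) of equal width.
#' @param weights numeric vector of M simplex weights (single sample) or an
#'   n x M matrix.
#' @return fused latent matrix.
#' @export
fuse <- function(latents, weights) {
  latents <- lapply(latents, as_batch)
  if (is.null(dim(weights))) weights <- matrix(weights, nrow = nrow(latents[[1]]),
                                               ncol = length(weights), byrow = TRUE)
  if (length(latents) != ncol(weights)) stop("need one weight per latent")
  d <- unique(vapply(latents, ncol, integer(1)))
  if (length(d) != 1) stop("latent widths differ")
  out <- matrix(0, nrow(latents[[1]]), d)
  for (m in seq_along(latents)) out <- out + weights[, m] * latents[[m]]
  out
}

#' Prediction tower for one task
#'
#' Two composite blocks followed by a final linear map; classification
#' towers emit two logits converted by softmax to (negative, positive)
#' probabilities, regression towers emit a single value.
#'
#' @param task a \code{\link{task_spec}}.
#' @param fused fused latent vector or batch matrix.
#' @param params tower parameter list (an element of
#'   \code{deml_init(config)$towers}).
#' @param mode \code{"eval"} or \code{"train"}.
#' @return numeric vector (regression) or n x 2 probability matrix.
#' @export
tower_predict <- function(task, fused, params, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  tower_fwd(as_batch(fused), params, task$kind, mode)$out
}

# ---------------------------------------------------------------------------
# checkpointing

# flatten a parameter tree into arrays keyed by module path
flatten_params <- function(params, prefix = character()) {
  out <- list()
  for (i in seq_along(params)) {
    nm <- names(params)[i]
    label <- if (!is.null(nm) && nzchar(nm)) nm else as.character(i)
    el <- params[[i]]
    path <- c(prefix, label)
    if (is.list(el)) out <- c(out, flatten_params(el, path))
    else if (is.numeric(el)) out[[paste(path, collapse = "/")]] <- el
  }
  out
}

#' Save and load model checkpoints
#'
#' The checkpoint is a single file holding the parameters keyed by module
#' path together with the model configuration serialized as JSON; reload is
#' bit-exact.
#'
#' @param params parameter list (or a fitted \code{"deml"} object).
#' @param config model configuration (ignored when \code{params} is a fit).
#' @param path file path.
#' @export
save_deml <- function(params, config = NULL, path) {
  if (inherits(params, "deml")) {
    config <- params$model_config
    params <- params$params
  }
  cfg <- unclass(config)
  cfg$tasks <- lapply(cfg$tasks, unclass)
  obj <- list(format = "demlr-checkpoint", version = 1L,
              config_json = as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)),
              flat = flatten_params(params),
              params = params)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_deml
#' @return \code{load_deml} returns a list with \code{params} and \code{config}.
#' @export
load_deml <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "demlr-checkpoint")) stop("not a demlr checkpoint: ", path)
  cfg <- jsonlite::fromJSON(obj$config_json, simplifyDataFrame = FALSE)
  cfg$tasks <- lapply(cfg$tasks, function(t) structure(t, class = "task_spec"))
  cfg$expert_kinds <- unlist(cfg$expert_kinds)
  config <- structure(cfg, class = "deml_config")
  list(params = obj$params, config = config)
}
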