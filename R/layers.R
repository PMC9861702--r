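# Neural-network layer primitives: affine maps, the composite block
# linear -> ReLU -> batch-norm -> dropout, and their backward passes.
# Everything operates on row-major batches (n samples x features).

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# broadcast a length-p vector across the rows of an n x p matrix
rb_mul <- function(M, v) M * rep(v, each = nrow(M))
rb_add <- function(M, v) M + rep(v, each = nrow(M))

xavier_init <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

affine_new <- function(n_in, n_out) {
  list(W = xavier_init(n_in, n_out), b = numeric(n_out))
}

affine_fwd <- function(X, A) {
  list(out = rb_add(X %*% A$W, A$b), X = X)
}

affine_bwd <- function(dOut, cache, A, need_dx = TRUE) {
  list(dX = if (need_dx) dOut %*% t(A$W) else NULL,
       grads = list(W = crossprod(cache$X, dOut), b = colSums(dOut)))
}

#' Layer specification for composite network blocks
#'
#' One block is an affine map followed (by default) by ReLU activation,
#' batch normalization and dropout, in that order. Batch normalization uses
#' batch statistics in train mode and running statistics in eval mode;
#' dropout is active only in train mode (inverted dropout, so eval is the
#' identity). \code{norm_before_activation = TRUE} switches to the
#' conventional linear -> batch-norm -> ReLU -> dropout order.
#'
#' @param width output width of the block.
#' @param use_activation apply ReLU.
#' @param use_batchnorm apply batch normalization.
#' @param dropout_rate dropout probability in [0, 1).
#' @param norm_before_activation normalize before the ReLU instead of after.
#' @return a list of class \code{"layer_spec"}.
#' @export
layer_spec <- function(width, use_activation = TRUE, use_batchnorm = TRUE,
                       dropout_rate = 0.5, norm_before_activation = FALSE) {
  stopifnot(width >= 1, dropout_rate >= 0, dropout_rate < 1)
  structure(list(width = as.integer(width), use_activation = use_activation,
                 use_batchnorm = use_batchnorm, dropout_rate = dropout_rate,
                 norm_before_activation = norm_before_activation),
            class = "layer_spec")
}

mlp_new <- function(n_in, spec) {
  L <- list(W = xavier_init(n_in, spec$width), b = numeric(spec$width),
            spec = spec)
  if (spec$use_batchnorm) {
    L$gamma <- rep(1, spec$width)
    L$beta <- numeric(spec$width)
    L$rmean <- numeric(spec$width)
    L$rvar <- rep(1, spec$width)
  }
  L
}

bn_fwd <- function(H, L, mode) {
  n <- nrow(H)
  if (mode == "train" && n > 1) {
    mu <- colMeans(H)
    cent <- rb_add(H, -mu)
    v <- colMeans(cent^2)
    invstd <- 1 / sqrt(v + BN_EPS)
    xhat <- rb_mul(cent, invstd)
    L$rmean <- (1 - BN_MOMENTUM) * L$rmean + BN_MOMENTUM * mu
    L$rvar <- (1 - BN_MOMENTUM) * L$rvar + BN_MOMENTUM * v * n / (n - 1)
    list(out = rb_add(rb_mul(xhat, L$gamma), L$beta),
         xhat = xhat, invstd = invstd, layer = L)
  } else {
    invstd <- 1 / sqrt(L$rvar + BN_EPS)
    xhat <- rb_mul(rb_add(H, -L$rmean), invstd)
    list(out = rb_add(rb_mul(xhat, L$gamma), L$beta),
         xhat = xhat, invstd = invstd, layer = L)
  }
}

bn_bwd <- function(dY, cache, L) {
  n <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- rb_mul(dY, L$gamma)
  # standard batch-norm backward (train-mode batch statistics)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dH <- rb_mul(dxhat - rb_add(rb_mul(cache$xhat, s2 / n), s1 / n), cache$invstd)
  list(dH = dH, dgamma = dgamma, dbeta = dbeta)
}

# Forward pass of one composite block. Returns output, a cache for the
# backward pass, and the layer with refreshed batch-norm running statistics.
mlp_fwd <- function(X, L, mode = c("train", "eval")) {
  mode <- match.arg(mode)
  spec <- L$spec
  if (ncol(X) != nrow(L$W))
    stop(sprintf("layer expects input width %d, got %d", nrow(L$W), ncol(X)))
  Z <- rb_add(X %*% L$W, L$b)
  cache <- list(X = X, Z = Z, mode = mode)
  cur <- Z
  stages <- if (spec$norm_before_activation) c("bn", "relu") else c("relu", "bn")
  for (st in stages) {
    if (st == "relu" && spec$use_activation) {
      cache$relu_in <- cur
      cur <- pmax(cur, 0)
    } else if (st == "bn" && spec$use_batchnorm) {
      bn <- bn_fwd(cur, L, mode)
      cache$bn <- bn[c("xhat", "invstd")]
      cache$bn_train <- mode == "train" && nrow(cur) > 1
      L <- bn$layer
      cur <- bn$out
    }
  }
  if (spec$dropout_rate > 0 && mode == "train") {
    keep <- 1 - spec$dropout_rate
    mask <- matrix(runif(length(cur)) < keep, nrow(cur), ncol(cur)) / keep
    cache$mask <- mask
    cur <- cur * mask
  }
  list(out = cur, cache = cache, layer = L)
}

mlp_bwd <- function(dOut, cache, L, need_dx = TRUE) {
  spec <- L$spec
  grads <- list()
  d <- dOut
  if (!is.null(cache$mask)) d <- d * cache$mask
  stages <- if (spec$norm_before_activation) c("relu", "bn") else c("bn", "relu")
  for (st in stages) {
    if (st == "bn" && spec$use_batchnorm) {
      if (cache$bn_train) {
        bb <- bn_bwd(d, cache$bn, L)
        d <- bb$dH
        grads$gamma <- bb$dgamma
        grads$beta <- bb$dbeta
      } else {
        grads$gamma <- colSums(d * cache$bn$xhat)
        grads$beta <- colSums(d)
        d <- rb_mul(rb_mul(d, L$gamma), cache$bn$invstd)
      }
    } else if (st == "relu" && spec$use_activation) {
      d <- d * (cache$relu_in > 0)
    }
  }
  grads$W <- crossprod(cache$X, d)
  grads$b <- colSums(d)
  list(dX = if (need_dx) d %*% t(L$W) else NULL, grads = grads)
}

#' Apply one composite network block to a batch
#'
#' Exposed building block: affine map, then (by default) ReLU, batch
#' normalization and dropout. In eval mode the output is a deterministic
#' function of the input and parameters.
#'
#' @param x numeric vector (one sample) or matrix (batch of rows).
#' @param layer block parameters as created by the model initializer; a list
#'   with \code{W}, \code{b}, optional \code{gamma}/\code{beta}/running
#'   statistics, and a \code{spec} (\code{\link{layer_spec}}).
#' @param mode \code{"train"} or \code{"eval"}.
#' @return numeric matrix of block outputs (rows = samples).
#' @export
mlp_layer <- function(x, layer, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  mlp_fwd(x, layer, mode)$out
}

softmax_rows <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}
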