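# Minimal dense-network machinery (linear / batch-norm / leaky-ReLU /
# dropout layers, Adam) used by the siamese embedder. Matrices are row-major
# batches: one row per input vector. The per-element work is delegated to
# small C++ kernels (src/dense_ops.cpp); matrix products go through BLAS.

col_add <- function(X, v) cpp_col_add(X, v)
col_mul <- function(X, v) cpp_col_mul(X, v)

nn_linear <- function(n_in, n_out) {
  bound <- 1 / sqrt(n_in)
  list(kind = "linear",
       params = list(
         W = matrix(stats::runif(n_in * n_out, -bound, bound), n_in, n_out),
         b = stats::runif(n_out, -bound, bound)))
}

nn_bn <- function(dim, momentum = 0.1, eps = 1e-5) {
  list(kind = "bn", momentum = momentum, eps = eps,
       params = list(gamma = rep(1, dim), beta = rep(0, dim)),
       running_mean = rep(0, dim), running_var = rep(1, dim))
}

nn_lrelu <- function(slope = 0.01) list(kind = "lrelu", slope = slope, params = list())

nn_dropout <- function(p) list(kind = "dropout", p = p, params = list())

# Forward pass through a layer stack. In training mode batch-norm uses batch
# statistics (and updates running ones) and dropout draws masks from the R
# RNG; in eval mode batch-norm uses running statistics and dropout is the
# identity. Returns out, per-layer caches, and the (possibly updated) stack.
stack_forward <- function(stack, X, train) {
  caches <- vector("list", length(stack))
  for (i in seq_along(stack)) {
    layer <- stack[[i]]
    if (layer$kind == "linear") {
      caches[[i]] <- list(X = X)
      X <- col_add(X %*% layer$params$W, layer$params$b)
    } else if (layer$kind == "bn") {
      if (train) {
        r <- cpp_bn_train_forward(X, layer$params$gamma, layer$params$beta,
                                  layer$eps)
        layer$running_mean <- (1 - layer$momentum) * layer$running_mean +
          layer$momentum * r$mu
        layer$running_var <- (1 - layer$momentum) * layer$running_var +
          layer$momentum * r$var
        stack[[i]] <- layer
        caches[[i]] <- list(xhat = r$xhat, invstd = r$invstd, n = nrow(X))
        X <- r$out
      } else {
        invstd <- 1 / sqrt(layer$running_var + layer$eps)
        xhat <- cpp_col_scale_shift(X, invstd, -layer$running_mean * invstd)
        X <- cpp_col_scale_shift(xhat, layer$params$gamma, layer$params$beta)
      }
    } else if (layer$kind == "lrelu") {
      caches[[i]] <- list(pre = X)
      X <- cpp_lrelu(X, layer$slope)
    } else if (layer$kind == "dropout") {
      if (train && layer$p > 0) {
        r <- cpp_dropout(X, layer$p)
        caches[[i]] <- list(mask = r$mask)
        X <- r$out
      } else {
        caches[[i]] <- list(mask = NULL)
      }
    }
  }
  list(out = X, caches = caches, stack = stack)
}

# Backward pass (training mode only). Returns the gradient w.r.t. the stack
# input and per-layer parameter gradients in the same shape as `params`.
stack_backward <- function(stack, caches, dOut) {
  grads <- vector("list", length(stack))
  for (i in rev(seq_along(stack))) {
    layer <- stack[[i]]
    cache <- caches[[i]]
    if (layer$kind == "linear") {
      grads[[i]] <- list(W = crossprod(cache$X, dOut), b = colSums(dOut))
      dOut <- tcrossprod(dOut, layer$params$W)
    } else if (layer$kind == "bn") {
      r <- cpp_bn_backward(dOut, cache$xhat, cache$invstd, layer$params$gamma)
      grads[[i]] <- list(gamma = r$dgamma, beta = r$dbeta)
      dOut <- r$dX
    } else if (layer$kind == "lrelu") {
      dOut <- cpp_lrelu_grad(dOut, cache$pre, layer$slope)
      grads[[i]] <- list()
    } else if (layer$kind == "dropout") {
      if (!is.null(cache$mask)) dOut <- dOut * cache$mask
      grads[[i]] <- list()
    }
  }
  list(dX = dOut, grads = grads)
}

# Elementwise sum of two per-layer gradient lists.
add_grads <- function(a, b) {
  for (i in seq_along(a)) {
    for (nm in names(a[[i]])) a[[i]][[nm]] <- a[[i]][[nm]] + b[[i]][[nm]]
  }
  a
}

adam_init <- function(stack) {
  lapply(stack, function(layer) {
    lapply(layer$params, function(p) list(m = p * 0, v = p * 0))
  })
}

adam_step <- function(stack, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(stack)) {
    for (nm in names(stack[[i]]$params)) {
      st <- state[[i]][[nm]]
      r <- cpp_adam(stack[[i]]$params[[nm]], grads[[i]][[nm]], st$m, st$v,
                    lr, beta1, beta2, eps, bc1, bc2)
      state[[i]][[nm]] <- list(m = r$m, v = r$v)
      stack[[i]]$params[[nm]] <- r$p
    }
  }
  list(stack = stack, state = state)
}

n_stack_parameters <- function(stack) {
  sum(vapply(stack, function(l) sum(vapply(l$params, length, 1L)), 1))
}
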