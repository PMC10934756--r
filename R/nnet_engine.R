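# Minimal full-batch feed-forward engine used by both eye-state classifier
# variants. Hidden units are logistic sigmoids; the output layer is either a
# softmax (classification, cross-entropy loss) or a sigmoid (autoencoder
# reconstruction of [0,1] intensities, Bernoulli cross-entropy). Training is
# deterministic given the seed: seeded Glorot-uniform initialization followed
# by L-BFGS on the analytic gradient.

sigmoid <- function(z) 1 / (1 + exp(-z))

softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# layers: list of list(W = out x in, b = out)
netForward <- function(layers, X, outputType) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1L]] <- X
  nl <- length(layers)
  for (i in seq_len(nl)) {
    Z <- acts[[i]] %*% t(layers[[i]]$W) +
      matrix(layers[[i]]$b, nrow(X), length(layers[[i]]$b), byrow = TRUE)
    acts[[i + 1L]] <- if (i < nl) sigmoid(Z)
      else switch(outputType, softmax = softmaxRows(Z), sigmoid = sigmoid(Z))
  }
  acts
}

netInit <- function(sizes, seed) {
  withSeed(seed, {
    lapply(seq_len(length(sizes) - 1L), function(i) {
      fanIn <- sizes[i]; fanOut <- sizes[i + 1L]
      r <- sqrt(6 / (fanIn + fanOut))
      list(W = matrix(stats::runif(fanOut * fanIn, -r, r), fanOut, fanIn),
           b = rep(0, fanOut))
    })
  })
}

packParams <- function(layers)
  unlist(lapply(layers, function(l) c(l$W, l$b)), use.names = FALSE)

unpackParams <- function(theta, sizes) {
  layers <- vector("list", length(sizes) - 1L)
  pos <- 0L
  for (i in seq_along(layers)) {
    nw <- sizes[i + 1L] * sizes[i]
    layers[[i]] <- list(
      W = matrix(theta[pos + seq_len(nw)], sizes[i + 1L], sizes[i]),
      b = theta[pos + nw + seq_len(sizes[i + 1L])])
    pos <- pos + nw + sizes[i + 1L]
  }
  layers
}

# Cross-entropy loss (mean per sample) + L2 weight penalty, and its gradient
# by backpropagation. For both output types the output delta is (yhat - T).
netLossGrad <- function(theta, sizes, X, T, outputType, lambda,
                        wantGrad = TRUE) {
  layers <- unpackParams(theta, sizes)
  acts <- netForward(layers, X, outputType)
  n <- nrow(X)
  Y <- acts[[length(acts)]]
  eps <- 1e-12
  dataLoss <- if (outputType == "softmax") {
    -sum(T * log(Y + eps)) / n
  } else {
    -sum(T * log(Y + eps) + (1 - T) * log(1 - Y + eps)) / n
  }
  penalty <- lambda / 2 * sum(vapply(layers, function(l) sum(l$W^2),
                                     numeric(1)))
  loss <- dataLoss + penalty
  if (!wantGrad) return(loss)
  nl <- length(layers)
  grads <- vector("list", nl)
  delta <- (Y - T) / n
  for (i in rev(seq_len(nl))) {
    grads[[i]] <- list(W = t(delta) %*% acts[[i]] + lambda * layers[[i]]$W,
                       b = colSums(delta))
    if (i > 1L) {
      A <- acts[[i]]
      delta <- (delta %*% layers[[i]]$W) * A * (1 - A)
    }
  }
  list(loss = loss, grad = packParams(grads))
}

# Full-batch L-BFGS training of an arbitrary stack. Returns the layer list.
netTrain <- function(X, T, sizes, outputType, seed, lambda = 1e-4,
                     maxit = 500L, initLayers = NULL) {
  theta0 <- packParams(if (is.null(initLayers)) netInit(sizes, seed)
                       else initLayers)
  # optim evaluates fn and gr at the same point; share one forward/backward
  # pass between them
  cache <- new.env(parent = emptyenv())
  evalAt <- function(th) {
    if (is.null(cache$theta) || !identical(th, cache$theta)) {
      cache$res <- netLossGrad(th, sizes, X, T, outputType, lambda)
      cache$theta <- th
    }
    cache$res
  }
  fit <- stats::optim(theta0, function(th) evalAt(th)$loss,
                      function(th) evalAt(th)$grad, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  unpackParams(fit$par, sizes)
}

# Tied-architecture (encoder + decoder) autoencoder; returns the encoder
# layer plus pre/post reconstruction losses for training-progress checks.
trainAutoencoderLayer <- function(X, codeSize, seed, lambda = 1e-4,
                                  maxit = 100L) {
  sizes <- c(ncol(X), codeSize, ncol(X))
  init <- netInit(sizes, seed)
  lossBefore <- netLossGrad(packParams(init), sizes, X, X, "sigmoid",
                            lambda = 0, wantGrad = FALSE)
  layers <- netTrain(X, X, sizes, "sigmoid", seed, lambda, maxit,
                     initLayers = init)
  lossAfter <- netLossGrad(packParams(layers), sizes, X, X, "sigmoid",
                           lambda = 0, wantGrad = FALSE)
  list(encoder = layers[[1L]],
       codes = sigmoid(X %*% t(layers[[1L]]$W) +
                         matrix(layers[[1L]]$b, nrow(X), codeSize,
                                byrow = TRUE)),
       lossBefore = lossBefore, lossAfter = lossAfter)
}
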