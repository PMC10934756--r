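# Eye-state classifiers: the 2601-10-2 feed-forward network and the stacked
# autoencoder, plus evaluation utilities and the face-recognition channel
# score for fusion.

eyeStateClasses <- c("OPEN_OR_HALF", "CLOSED")

corpusMatrix <- function(images, requireLabels = TRUE) {
  X <- t(vapply(images, flattenRowMajor, numeric(2601)))
  labels <- vapply(images, imageLabel, character(1))
  if (requireLabels && any(is.na(labels)))
    stop("all images must be labeled")
  list(X = X, labels = labels)
}

checkTrainingSet <- function(labels) {
  tab <- table(factor(labels, levels = eyeStateClasses))
  if (any(tab < 2L))
    stop("training set must contain at least 2 samples of each class")
}

oneHot <- function(labels) {
  idx <- match(labels, eyeStateClasses)
  T <- matrix(0, length(labels), 2L)
  T[cbind(seq_along(labels), idx)] <- 1
  T
}

#' Train the one-hidden-layer eye-state network (2601-10-2)
#'
#' A feed-forward classifier with 2601 inputs (the flattened 51 x 51 eye
#' raster), 10 logistic hidden units, and a 2-way softmax output
#' (open-or-half vs. closed), trained full-batch on the cross-entropy
#' objective with a small L2 penalty. Weight initialization is seeded, so a
#' given (data, seed, hyperparameters) triple always yields the identical
#' model.
#'
#' @param images list of labeled \linkS4class{EyeImage}s (both classes
#'   present, at least 2 per class).
#' @param seed integer seed for weight initialization.
#' @param hidden hidden-layer width (default 10).
#' @param lambda L2 penalty (default 1e-4).
#' @param maxit optimizer iteration cap (default 500).
#' @return an \linkS4class{EyeStateModel} of variant \code{MLP_1H}.
#' @export
trainEyeStateMLP <- function(images, seed = 1L, hidden = 10L,
                             lambda = 1e-4, maxit = 500L) {
  if (!length(images)) stop("empty training set")
  cm <- corpusMatrix(images)
  checkTrainingSet(cm$labels)
  layers <- netTrain(cm$X, oneHot(cm$labels),
                     sizes = c(2601L, hidden, 2L), outputType = "softmax",
                     seed = seed, lambda = lambda, maxit = maxit)
  new("EyeStateModel", variant = "MLP_1H", layers = layers,
      trainingSeed = as.integer(seed), classes = eyeStateClasses)
}

#' Train the stacked-autoencoder eye-state network
#'
#' Greedy layer-wise pretraining followed by supervised fine-tuning: an
#' autoencoder with \code{hidden[1]} code units is trained to reconstruct
#' the 2601-pixel inputs; a second autoencoder with \code{hidden[2]} code
#' units is trained on the first layer's codes; a 2-way softmax layer is
#' trained on the second codes; the three encoders plus output layer are
#' then assembled into one network and fine-tuned end-to-end on the labels.
#' Deterministic given the seed.
#'
#' @inheritParams trainEyeStateMLP
#' @param hidden code-layer widths, default \code{c(100, 50)}.
#' @param pretrainMaxit iteration cap per pretraining stage (default 15;
#'   the codes only need to carry the class structure, not a polished
#'   reconstruction, before fine-tuning takes over).
#' @param maxit fine-tuning iteration cap (default 40).
#' @return an \linkS4class{EyeStateModel} of variant \code{STACKED_AE}.
#' @export
trainStackedAutoencoder <- function(images, seed = 1L, hidden = c(100L, 50L),
                                    lambda = 1e-4, pretrainMaxit = 15L,
                                    maxit = 40L) {
  if (!length(images)) stop("empty training set")
  cm <- corpusMatrix(images)
  checkTrainingSet(cm$labels)
  ae1 <- trainAutoencoderLayer(cm$X, hidden[1], seed = subSeed(seed, 1L),
                               lambda = lambda, maxit = pretrainMaxit)
  ae2 <- trainAutoencoderLayer(ae1$codes, hidden[2],
                               seed = subSeed(seed, 2L),
                               lambda = lambda, maxit = pretrainMaxit)
  top <- netTrain(ae2$codes, oneHot(cm$labels),
                  sizes = c(hidden[2], 2L), outputType = "softmax",
                  seed = subSeed(seed, 3L), lambda = lambda, maxit = maxit)
  assembled <- list(ae1$encoder, ae2$encoder, top[[1L]])
  sizes <- c(2601L, hidden, 2L)
  layers <- netTrain(cm$X, oneHot(cm$labels), sizes, "softmax",
                     seed = seed, lambda = lambda, maxit = maxit,
                     initLayers = assembled)
  new("EyeStateModel", variant = "STACKED_AE", layers = layers,
      trainingSeed = as.integer(seed), classes = eyeStateClasses)
}

#' Classify the eye state of one image
#'
#' @param model a trained \linkS4class{EyeStateModel}.
#' @param img an \linkS4class{EyeImage} with a 51 x 51 raster.
#' @return list with \code{label} and \code{confidence} (the winning softmax
#'   score; the two output scores always sum to 1).
#' @export
classifyEyeState <- function(model, img) {
  stopifnot(is(model, "EyeStateModel"))
  x <- matrix(flattenRowMajor(img), nrow = 1L)
  acts <- netForward(model@layers, x, "softmax")
  p <- acts[[length(acts)]][1L, ]
  i <- which.max(p)
  list(label = model@classes[i], confidence = p[i])
}

# Vectorized prediction over a corpus; returns a character vector of labels.
predictEyeStates <- function(model, images) {
  X <- t(vapply(images, flattenRowMajor, numeric(2601)))
  acts <- netForward(model@layers, X, "softmax")
  model@classes[max.col(acts[[length(acts)]], ties.method = "first")]
}

#' Evaluate a model on a labeled test set
#'
#' @param model a trained \linkS4class{EyeStateModel}.
#' @param images list of labeled \linkS4class{EyeImage}s.
#' @return a 2 x 2 confusion matrix (rows = actual class, columns =
#'   predicted class) with an \code{accuracy} attribute (trace / total).
#' @export
evaluateModel <- function(model, images) {
  cm <- corpusMatrix(images)
  pred <- predictEyeStates(model, images)
  conf <- table(actual = factor(cm$labels, levels = model@classes),
                predicted = factor(pred, levels = model@classes))
  conf <- unclass(conf)
  attr(conf, "accuracy") <- sum(diag(conf)) / sum(conf)
  conf
}

#' Face-recognition channel score for fuzzy fusion
#'
#' The fraction of frames within a window whose predicted eye state is
#' OPEN_OR_HALF: 1 means every frame showed open (or half-open) eyes.
#'
#' @param labels character vector of per-frame predicted labels.
#' @return a score in [0, 1].
#' @export
frChannelScore <- function(labels) {
  if (!length(labels)) stop("empty window: no frame predictions")
  if (!all(labels %in% eyeStateClasses))
    stop("labels must be OPEN_OR_HALF or CLOSED")
  mean(labels == "OPEN_OR_HALF")
}

#' Serialize or restore an eye-state model as JSON
#'
#' Weights are written as full-precision JSON numbers, so a written model
#' restores to an identical classifier.
#'
#' @param model an \linkS4class{EyeStateModel}.
#' @param path file path.
#' @return \code{readEyeStateModel}: the restored model;
#'   \code{writeEyeStateModel}: the path, invisibly.
#' @export
writeEyeStateModel <- function(model, path) {
  obj <- list(variant = model@variant, trainingSeed = model@trainingSeed,
              classes = model@classes,
              layers = lapply(model@layers, function(l)
                # weights stored flat in column-major order
                list(W = as.numeric(l$W), b = as.numeric(l$b),
                     dim = dim(l$W))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeEyeStateModel
#' @export
readEyeStateModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  layers <- lapply(obj$layers, function(l)
    list(W = matrix(as.numeric(l$W), l$dim[1], l$dim[2]),
         b = as.numeric(l$b)))
  new("EyeStateModel", variant = obj$variant, layers = layers,
      trainingSeed = as.integer(obj$trainingSeed),
      classes = as.character(obj$classes))
}
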