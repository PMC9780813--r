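# The compact CNN: 64x64x1 input; four convolutional blocks (3x3 kernels,
# biases, ReLU, 2x2 max pooling) with 64, 128, 256 and 64 filters and
# dropout 0.25 on blocks 1, 3 and 4; flatten; dense(8, ReLU); dense(1,
# sigmoid) with an L1 activity regularizer. Trained with Adam on binary
# cross-entropy. With unpadded (valid) convolutions the flattened feature
# has 2*2*64 = 256 elements and the network holds 519,249 parameters.

#' CNN architecture specification
#'
#' @param filters Filter counts of the four convolutional blocks.
#' @param kernel Convolution kernel side (square).
#' @param pool Max-pooling window side.
#' @param dropout Dropout rate per block (0 disables).
#' @param dense Width of the hidden dense layer.
#' @param padding `"valid"` (unpadded, default) or `"same"`.
#' @param inputSize Input image side length.
#' @param l1 L1 activity-regularizer coefficient on the output activation.
#' @return List of class `"ModelSpec"`.
#' @export
cnnModelSpec <- function(filters = c(64, 128, 256, 64), kernel = 3,
                         pool = 2, dropout = c(0.25, 0, 0.25, 0.25),
                         dense = 8, padding = c("valid", "same"),
                         inputSize = 64, l1 = 1e-4) {
  padding <- match.arg(padding)
  stopifnot(length(filters) == length(dropout))
  structure(list(filters = as.integer(filters), kernel = as.integer(kernel),
                 pool = as.integer(pool), dropout = dropout,
                 dense = as.integer(dense), padding = padding,
                 inputSize = as.integer(inputSize), l1 = l1),
            class = "ModelSpec")
}

# spatial side lengths after each conv+pool block; errors if the image
# collapses before the last block
.spatialSizes <- function(spec) {
  s <- spec$inputSize
  if (!length(spec$filters)) return(integer(0))
  sizes <- integer(length(spec$filters))
  for (i in seq_along(spec$filters)) {
    if (spec$padding == "valid") {
      if (s < spec$kernel)
        stop("input size ", spec$inputSize, " too small for ",
             length(spec$filters), " conv/pool stages")
      s <- s - spec$kernel + 1L
    }
    s <- s %/% spec$pool
    if (s < 1L)
      stop("input size ", spec$inputSize, " too small for ",
           length(spec$filters), " conv/pool stages")
    sizes[i] <- s
  }
  sizes
}

#' Closed-form trainable-parameter count
#'
#' Pure function of the architecture: for each convolutional block
#' `kernel^2 * c_in * c_out + c_out`, plus the two dense layers on the
#' flattened feature. Independent of any realized weights.
#'
#' @param spec A [cnnModelSpec()] (or a built model, whose spec is used).
#' @return Integer parameter count.
#' @examples
#' countParameters(cnnModelSpec())                    # 519249
#' round(countParameters(cnnModelSpec()) / 1e6, 2)    # 0.52 million
#' @export
countParameters <- function(spec) {
  if (inherits(spec, "CnnModel")) spec <- spec$spec
  sizes <- .spatialSizes(spec)
  if (length(spec$filters)) {
    cin <- c(1L, spec$filters[-length(spec$filters)])
    convP <- sum(spec$kernel^2 * cin * spec$filters + spec$filters)
    flat <- sizes[length(sizes)]^2 * spec$filters[length(spec$filters)]
  } else {
    convP <- 0L                     # dense path on the flattened input
    flat <- spec$inputSize^2
  }
  as.integer(convP + (flat * spec$dense + spec$dense) +
               (spec$dense * 1L + 1L))
}

# Glorot-uniform sample with the given fan-in/fan-out
.glorot <- function(dims, fanIn, fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

#' Build (initialize) the CNN
#'
#' Realizes the architecture as weight tensors with seeded Glorot-uniform
#' initialization and zero biases. The realized parameter total always
#' equals [countParameters()] of the spec.
#'
#' @param spec A [cnnModelSpec()].
#' @param seed Integer seed for weight initialization.
#' @return List of class `"CnnModel"` with elements `spec`, `conv` (list of
#'   `W`/`b` per block), `dense1`, `dense2`, and `nParams`.
#' @export
buildModel <- function(spec = cnnModelSpec(), seed = 1) {
  sizes <- .spatialSizes(spec)
  cin <- c(1L, spec$filters[-length(spec$filters)])
  k <- spec$kernel
  model <- .withSeed(seed, {
    conv <- vector("list", length(spec$filters))
    for (i in seq_along(spec$filters)) {
      conv[[i]] <- list(
        W = .glorot(c(k, k, cin[i], spec$filters[i]),
                    k^2 * cin[i], k^2 * spec$filters[i]),
        b = numeric(spec$filters[i]))
    }
    flat <- sizes[length(sizes)]^2 * spec$filters[length(spec$filters)]
    list(spec = spec, conv = conv,
         dense1 = list(W = matrix(runif(spec$dense * flat,
                                        -sqrt(6 / (flat + spec$dense)),
                                        sqrt(6 / (flat + spec$dense))),
                                  spec$dense, flat),
                       b = numeric(spec$dense)),
         dense2 = list(W = matrix(runif(spec$dense,
                                        -sqrt(6 / (spec$dense + 1)),
                                        sqrt(6 / (spec$dense + 1))),
                                  1, spec$dense),
                       b = 0))
  })
  model$nParams <- as.integer(
    sum(vapply(model$conv, function(l) length(l$W) + length(l$b), 0)) +
      length(model$dense1$W) + length(model$dense1$b) +
      length(model$dense2$W) + length(model$dense2$b))
  class(model) <- "CnnModel"
  model
}

#' @export
print.CnnModel <- function(x, ...) {
  cat("CnnModel:", paste(x$spec$filters, collapse = "-"),
      "conv filters,", x$spec$padding, "padding,",
      format(x$nParams, big.mark = ","), "parameters\n")
  invisible(x)
}

# zero-pad H and W dims for 'same' convolution
.padSame <- function(x, k) {
  p <- (k - 1L) %/% 2L
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  out
}

.relu <- function(z) z * (z > 0)

# forward pass; keeps caches for backprop when training = TRUE
.cnnForward <- function(model, x, training = FALSE, dropSeedOffset = 0L) {
  spec <- model$spec
  caches <- list()
  a <- x
  for (i in seq_along(model$conv)) {
    xin <- if (spec$padding == "same") .padSame(a, spec$kernel) else a
    r <- conv_forward(xin, model$conv[[i]]$W, model$conv[[i]]$b,
                      relu = TRUE)
    pl <- maxpool_forward(r, spec$pool)
    p <- pl$out
    mask <- NULL
    if (training && spec$dropout[i] > 0) {
      keep <- 1 - spec$dropout[i]
      mask <- array((runif(length(p)) < keep) / keep, dim = dim(p))
      p <- p * mask
    }
    caches[[i]] <- list(xin = xin, idx = pl$idx, poolOut = pl$out,
                        mask = mask, rdim = dim(r))
    a <- p
  }
  flatDim <- prod(dim(a)[1:3])
  B <- dim(a)[4]
  f <- matrix(a, flatDim, B)
  z1 <- model$dense1$W %*% f + model$dense1$b
  a1 <- .relu(z1)
  z2 <- model$dense2$W %*% a1 + model$dense2$b
  prob <- 1 / (1 + exp(-z2))
  list(prob = as.numeric(prob), caches = caches, f = f, z1 = z1, a1 = a1,
       pooledDim = dim(a))
}

# backward pass; returns gradients in the same structure as the parameters
.cnnBackward <- function(model, fw, y) {
  spec <- model$spec
  B <- length(y)
  prob <- fw$prob
  # d(mean BCE)/dz2 plus the L1 activity-regularizer term (sigmoid > 0)
  dz2 <- matrix((prob - y) / B + (spec$l1 / B) * prob * (1 - prob), 1, B)
  g <- list()
  g$dense2 <- list(W = dz2 %*% t(fw$a1), b = sum(dz2))
  da1 <- t(model$dense2$W) %*% dz2
  dz1 <- da1 * (fw$z1 > 0)
  g$dense1 <- list(W = dz1 %*% t(fw$f), b = rowSums(dz1))
  df <- t(model$dense1$W) %*% dz1
  da <- array(df, fw$pooledDim)
  g$conv <- vector("list", length(model$conv))
  for (i in rev(seq_along(model$conv))) {
    cache <- fw$caches[[i]]
    if (!is.null(cache$mask)) da <- da * cache$mask
    # scatter through the pooling argmax; the ReLU mask is applied there
    dz <- maxpool_backward(cache$idx, da, cache$poolOut,
                           as.integer(cache$rdim))
    gr <- conv_backward(cache$xin, model$conv[[i]]$W, dz)
    g$conv[[i]] <- list(W = gr$dw, b = gr$db)
    da <- gr$dx
    if (spec$padding == "same") {
      p <- (spec$kernel - 1L) %/% 2L
      d <- dim(da)
      da <- da[p + seq_len(d[1] - 2L * p), p + seq_len(d[2] - 2L * p), , ,
               drop = FALSE]
    }
  }
  g
}

#' Training configuration
#'
#' Defaults are the documented full-run settings (binary cross-entropy,
#' Adam, learning rate 0.001, batch 256, 500 epochs, 10 steps per epoch);
#' tests and the desk-scale experiments pass smaller values.
#'
#' @param lr Learning rate (> 0).
#' @param batchSize Mini-batch size.
#' @param epochs Number of epochs.
#' @param stepsPerEpoch Optimizer steps per epoch; `NULL` means one full
#'   pass over the training data.
#' @param seed Integer seed controlling initialization order, shuffling and
#'   dropout.
#' @return List of class `"TrainConfig"`.
#' @export
trainConfig <- function(lr = 0.001, batchSize = 256, epochs = 500,
                        stepsPerEpoch = 10, seed = 1) {
  if (lr <= 0) stop("learning rate must be > 0")
  if (batchSize < 1 || epochs < 1 ||
      (!is.null(stepsPerEpoch) && stepsPerEpoch < 1))
    stop("batchSize, epochs and stepsPerEpoch must be >= 1")
  structure(list(lr = lr, batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs),
                 stepsPerEpoch = if (is.null(stepsPerEpoch)) NULL
                                 else as.integer(stepsPerEpoch),
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

# convert a list of 0..255 integer image matrices to a (H, W, 1, B) array
# scaled to [0, 1]
.imagesToArray <- function(images) {
  d <- dim(images[[1L]])
  array(unlist(images, use.names = FALSE) / 255, c(d[1], d[2], 1L,
                                                   length(images)))
}

# binary labels from a LabeledImageSet: ASMI (abnormal) = 1, NORM = 0
.setToXY <- function(set) {
  list(x = .imagesToArray(set@images),
       y = as.numeric(set@meta$class == "ASMI"))
}

.adamInit <- function(model) {
  list(m = rapply(model[c("conv", "dense1", "dense2")],
                  function(v) v * 0, how = "replace"),
       v = rapply(model[c("conv", "dense1", "dense2")],
                  function(v) v * 0, how = "replace"),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one Adam step over the nested parameter/gradient lists
.adamStep <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(par, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    par <- par - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(par, m, v)
  }
  for (i in seq_along(model$conv)) {
    for (nm in c("W", "b")) {
      r <- upd(model$conv[[i]][[nm]], grads$conv[[i]][[nm]],
               state$m$conv[[i]][[nm]], state$v$conv[[i]][[nm]])
      model$conv[[i]][[nm]] <- r[[1]]
      state$m$conv[[i]][[nm]] <- r[[2]]
      state$v$conv[[i]][[nm]] <- r[[3]]
    }
  }
  for (lay in c("dense1", "dense2")) {
    for (nm in c("W", "b")) {
      r <- upd(model[[lay]][[nm]], grads[[lay]][[nm]],
               state$m[[lay]][[nm]], state$v[[lay]][[nm]])
      model[[lay]][[nm]] <- r[[1]]
      state$m[[lay]][[nm]] <- r[[2]]
      state$v[[lay]][[nm]] <- r[[3]]
    }
  }
  list(model = model, state = state)
}

.bceLoss <- function(prob, y, l1) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p)) + l1 * sum(abs(prob)) /
    length(y)
}

#' Predict class probabilities
#'
#' @param model A trained (or freshly built) `"CnnModel"`.
#' @param images A [LabeledImageSet-class] or list of image matrices.
#' @param batchSize Forward-pass batch size.
#' @return Numeric vector of sigmoid outputs in (0, 1).
#' @export
predictProbs <- function(model, images, batchSize = 64) {
  if (is(images, "LabeledImageSet")) images <- images@images
  n <- length(images)
  probs <- numeric(n)
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    x <- .imagesToArray(images[idx])
    probs[idx] <- .cnnForward(model, x, training = FALSE)$prob
  }
  probs
}

#' Train the CNN
#'
#' Seeded mini-batch Adam on binary cross-entropy (plus the L1 activity
#' penalty on the sigmoid output). The positive class is ASMI. History
#' records per-epoch training loss and validation accuracy; final metrics
#' are computed on the validation set at threshold 0.5.
#'
#' @param model A `"CnnModel"` from [buildModel()].
#' @param train,validation [LabeledImageSet-class] objects (non-empty,
#'   images matching the model's input size).
#' @param config A [trainConfig()].
#' @return List with `model` (trained), `history` (`data.frame` epoch,
#'   loss, val_accuracy) and `metrics` (see [evaluateModel()]).
#' @export
trainModel <- function(model, train, validation, config = trainConfig()) {
  tr <- .setToXY(train)
  va <- .setToXY(validation)
  if (!length(tr$y) || !length(va$y)) stop("empty train or validation set")
  d <- dim(tr$x)
  if (d[1] != model$spec$inputSize || d[2] != model$spec$inputSize)
    stop("image size ", d[1], "x", d[2], " does not match model input ",
         model$spec$inputSize)
  n <- length(tr$y)
  state <- .adamInit(model)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_accuracy = numeric(0))
  model <- .withSeed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(n)
      steps <- config$stepsPerEpoch %||% ceiling(n / config$batchSize)
      need <- steps * config$batchSize
      ord <- rep_len(ord, max(need, length(ord)))[seq_len(need)]
      lossAcc <- 0
      for (s in seq_len(steps)) {
        idx <- ord[(s - 1L) * config$batchSize + seq_len(config$batchSize)]
        xb <- tr$x[, , , idx, drop = FALSE]
        yb <- tr$y[idx]
        fw <- .cnnForward(model, xb, training = TRUE)
        lossAcc <- lossAcc + .bceLoss(fw$prob, yb, model$spec$l1)
        g <- .cnnBackward(model, fw, yb)
        r <- .adamStep(model, g, state, config$lr)
        model <- r$model
        state <- r$state
      }
      valProb <- .cnnForward(model, va$x, training = FALSE)$prob
      valAcc <- mean((valProb >= 0.5) == (va$y == 1))
      history[nrow(history) + 1L, ] <- list(epoch, lossAcc / steps, valAcc)
    }
    model
  })
  valProb <- .cnnForward(model, va$x, training = FALSE)$prob
  list(model = model, history = history,
       metrics = evaluateModel(valProb, va$y))
}

#' Evaluate binary predictions
#'
#' Thresholds probabilities at 0.5 and reports accuracy, sensitivity
#' (recall of the positive class), specificity, precision, mean binary
#' cross-entropy loss, and the confusion counts. Rates with a zero
#' denominator are reported as `NA`.
#'
#' @param probs Numeric vector of predicted probabilities.
#' @param labels Binary labels (0/1), same length.
#' @param threshold Decision threshold (default 0.5).
#' @return List of class `"EvalMetrics"` with `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `loss`, `tp`, `fp`, `tn`, `fn`.
#' @export
evaluateModel <- function(probs, labels, threshold = 0.5) {
  if (length(probs) != length(labels))
    stop("predictions and labels differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    accuracy = (tp + tn) / length(labels),
    sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp),
    precision = rate(tp, tp + fp),
    loss = .bceLoss(pmin(pmax(probs, 0), 1), labels, 0),
    tp = tp, fp = fp, tn = tn, fn = fn), class = "EvalMetrics")
}

#' @export
print.EvalMetrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | sensitivity %s | specificity %s | precision %s | loss %.4f\n",
    x$accuracy, format(x$sensitivity), format(x$specificity),
    format(x$precision), x$loss))
  cat(sprintf("confusion: TP %d FP %d TN %d FN %d\n", x$tp, x$fp, x$tn,
              x$fn))
  invisible(x)
}
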