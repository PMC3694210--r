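# Deep networks with unsupervised pretraining: a stack of restricted
# Boltzmann machines (Gaussian-visible/logistic-hidden at the bottom,
# logistic/logistic above) trained greedily by contrastive divergence, then
# unrolled into a feed-forward net with a linear-regression or softmax output
# layer and fine-tuned by mini-batch back-propagation with momentum. Both the
# acoustic-to-articulatory / acoustic-to-acoustic mappings (linear output)
# and the phone classifier (softmax output) use this machinery.

#' Network specification
#'
#' @param input input dimension.
#' @param hidden integer vector of exactly three hidden-layer sizes.
#' @param output output dimension.
#' @param output_kind `"linear"` (regression) or `"softmax"` (classifier).
#' @return object of class `net_spec`.
#' @export
net_spec <- function(input, hidden, output,
                     output_kind = c("linear", "softmax")) {
  output_kind <- match.arg(output_kind)
  hidden <- as.integer(hidden)
  if (length(hidden) != 3L) stop("exactly 3 hidden layers are required")
  if (any(c(input, hidden, output) < 1)) stop("layer sizes must be positive")
  structure(list(input = as.integer(input), hidden = hidden,
                 output = as.integer(output), output_kind = output_kind),
            class = "net_spec")
}

#' Training configuration
#'
#' Defaults are conventional desk-scale settings for contrastive-divergence
#' pretraining and momentum back-propagation; all can be overridden.
#'
#' @param pretrain_epochs RBM epochs per layer (default 20).
#' @param finetune_epochs back-propagation epochs (default 50).
#' @param lr_pretrain learning rate for binary-binary RBMs (default 0.01).
#' @param lr_gaussian learning rate for the Gaussian-visible RBM
#'   (default 0.001).
#' @param lr_finetune back-propagation learning rate (default 0.1).
#' @param lr_decay multiplicative per-epoch decay of the fine-tuning rate
#'   (default 0.98).
#' @param weight_decay L2 penalty coefficient applied to all weights during
#'   fine-tuning (default 1e-4, the classical small weight cost; biases are
#'   not penalized).
#' @param momentum momentum coefficient (default 0.9).
#' @param batch_size mini-batch size (default 32).
#' @param cd_steps contrastive-divergence steps (default 1).
#' @param seed RNG seed governing initialization, sampling and shuffling.
#' @param standardize z-score inputs (and regression outputs) before
#'   training (default TRUE).
#' @return object of class `train_config`.
#' @export
train_config <- function(pretrain_epochs = 20, finetune_epochs = 50,
                         lr_pretrain = 0.01, lr_gaussian = 0.001,
                         lr_finetune = 0.1, lr_decay = 0.98,
                         weight_decay = 1e-4, momentum = 0.9,
                         batch_size = 32, cd_steps = 1, seed = 1,
                         standardize = TRUE) {
  if (pretrain_epochs < 0 || finetune_epochs < 0) stop("epochs must be >= 0")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (cd_steps < 1) stop("cd_steps must be >= 1")
  structure(list(pretrain_epochs = pretrain_epochs,
                 finetune_epochs = finetune_epochs,
                 lr_pretrain = lr_pretrain, lr_gaussian = lr_gaussian,
                 lr_finetune = lr_finetune, lr_decay = lr_decay,
                 weight_decay = weight_decay, momentum = momentum,
                 batch_size = batch_size, cd_steps = cd_steps,
                 seed = as.integer(seed), standardize = standardize),
            class = "train_config")
}

logistic <- function(x) 1 / (1 + exp(-x))

# Greedy CD training of one RBM. v: n x nv data (standardized for the
# Gaussian-visible bottom layer). Returns weights, biases and the per-epoch
# mean squared reconstruction error.
rbm_train <- function(v, n_hidden, gaussian_visible, lr, config) {
  nv <- ncol(v); n <- nrow(v)
  # Glorot-style scale adjusted for logistic units: keeps activations out of
  # the saturated and the collapsed-constant regimes through the stack.
  W <- matrix(stats::rnorm(nv * n_hidden, sd = 4 * sqrt(2 / (nv + n_hidden))),
              nv, n_hidden)
  b_h <- numeric(n_hidden)
  b_v <- numeric(nv)
  vW <- matrix(0, nv, n_hidden); vb_h <- numeric(n_hidden); vb_v <- numeric(nv)
  recon_log <- numeric(0)
  if (config$pretrain_epochs == 0) {
    return(list(W = W, b_h = b_h, b_v = b_v, recon = recon_log))
  }
  for (epoch in seq_len(config$pretrain_epochs)) {
    ord <- sample.int(n)
    se <- 0
    for (i0 in seq(1, n, by = config$batch_size)) {
      idx <- ord[i0:min(n, i0 + config$batch_size - 1)]
      v0 <- v[idx, , drop = FALSE]
      nb <- nrow(v0)
      h_p <- logistic(sweep(v0 %*% W, 2, b_h, "+"))
      h_s <- (matrix(stats::runif(nb * n_hidden), nb) < h_p) * 1
      vk <- v0; hk_p <- h_p; hk_s <- h_s
      for (s in seq_len(config$cd_steps)) {
        vk <- sweep(hk_s %*% t(W), 2, b_v, "+")
        if (!gaussian_visible) vk <- logistic(vk)
        hk_p <- logistic(sweep(vk %*% W, 2, b_h, "+"))
        if (s < config$cd_steps)
          hk_s <- (matrix(stats::runif(nb * n_hidden), nb) < hk_p) * 1
      }
      gW <- (crossprod(v0, h_p) - crossprod(vk, hk_p)) / nb
      gb_v <- colMeans(v0 - vk)
      gb_h <- colMeans(h_p - hk_p)
      vW <- config$momentum * vW + lr * gW
      vb_v <- config$momentum * vb_v + lr * gb_v
      vb_h <- config$momentum * vb_h + lr * gb_h
      W <- W + vW; b_v <- b_v + vb_v; b_h <- b_h + vb_h
      se <- se + sum((v0 - vk)^2)
    }
    recon_log <- c(recon_log, se / (n * nv))
  }
  list(W = W, b_h = b_h, b_v = b_v, recon = recon_log)
}

#' Greedy layer-wise pretraining of the RBM stack
#'
#' The bottom machine has Gaussian visible units (inputs must be
#' standardized) and logistic hidden units; the machines above are
#' logistic-logistic. Each is trained by CD-`cd_steps` on the deterministic
#' hidden probabilities of the machine below. With `pretrain_epochs = 0` the
#' seeded random initialization is returned untouched.
#'
#' @param inputs standardized n x d input matrix.
#' @param spec a [net_spec()].
#' @param config a [train_config()].
#' @return list with `weights`, `biases` (3 each, input side up) and
#'   `recon_log` (per-layer, per-epoch mean squared reconstruction error).
#' @export
pretrain_stack <- function(inputs, spec, config) {
  inputs <- as.matrix(inputs)
  if (!all(is.finite(inputs))) stop("non-finite inputs")
  if (nrow(inputs) < 1) stop("need at least one sample")
  if (ncol(inputs) != spec$input) stop("input dimension mismatch")
  set.seed(config$seed)
  weights <- vector("list", 3); biases <- vector("list", 3)
  recon_log <- vector("list", 3)
  h <- inputs
  for (l in 1:3) {
    gaussian <- (l == 1L)
    lr <- if (gaussian) config$lr_gaussian else config$lr_pretrain
    rbm <- rbm_train(h, spec$hidden[l], gaussian, lr, config)
    weights[[l]] <- rbm$W
    biases[[l]] <- rbm$b_h
    recon_log[[l]] <- rbm$recon
    h <- logistic(sweep(h %*% rbm$W, 2, rbm$b_h, "+"))
  }
  list(weights = weights, biases = biases, recon_log = recon_log)
}

# Forward pass through the unrolled net on standardized inputs. Returns
# activations per layer; output on the standardized / probability scale.
forward_pass <- function(weights, biases, x, output_kind) {
  a <- vector("list", 4)
  h <- x
  for (l in 1:3) {
    h <- logistic(sweep(h %*% weights[[l]], 2, biases[[l]], "+"))
    a[[l]] <- h
  }
  z <- sweep(h %*% weights[[4]], 2, biases[[4]], "+")
  if (output_kind == "softmax") {
    z <- z - apply(z, 1, max)
    e <- exp(z)
    a[[4]] <- e / rowSums(e)
  } else {
    a[[4]] <- z
  }
  a
}

# Loss and gradients of the unrolled net on standardized data.
# linear: L = 0.5 * sum((yhat - y)^2) / n ; softmax: mean cross-entropy.
nn_loss_grad <- function(weights, biases, x, y, output_kind) {
  n <- nrow(x)
  a <- forward_pass(weights, biases, x, output_kind)
  yhat <- a[[4]]
  if (output_kind == "linear") {
    loss <- 0.5 * sum((yhat - y)^2) / n
    delta <- (yhat - y) / n
  } else {
    loss <- -sum(y * log(pmax(yhat, 1e-300))) / n
    delta <- (yhat - y) / n
  }
  gw <- vector("list", 4); gb <- vector("list", 4)
  acts <- list(x, a[[1]], a[[2]], a[[3]])
  for (l in 4:1) {
    gw[[l]] <- crossprod(acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(weights[[l]])) * acts[[l]] * (1 - acts[[l]])
    }
  }
  list(loss = loss, gw = gw, gb = gb)
}

#' Fine-tune a pretrained stack by back-propagation
#'
#' Unrolls the stack into a deterministic feed-forward net, adds a linear
#' (regression) or softmax (classification) output layer, and minimizes mean
#' squared error / cross-entropy by mini-batch gradient descent with
#' momentum. With `finetune_epochs = 0` the pretrained weights and the
#' seeded random output layer are returned untouched.
#'
#' @param pretrained result of [pretrain_stack()].
#' @param inputs standardized n x d inputs.
#' @param targets standardized targets (linear) or one-hot label matrix
#'   (softmax).
#' @param spec,config see [pretrain_stack()].
#' @return list with `weights`, `biases` (4 each) and `loss_log`
#'   (full-data loss at epoch 0 and after each epoch).
#' @export
finetune <- function(pretrained, inputs, targets, spec, config) {
  inputs <- as.matrix(inputs); targets <- as.matrix(targets)
  if (nrow(inputs) != nrow(targets)) stop("row counts of inputs and targets differ")
  if (ncol(targets) != spec$output) stop("target dimension mismatch")
  n <- nrow(inputs)
  weights <- c(pretrained$weights,
               list(matrix(stats::rnorm(
                 spec$hidden[3] * spec$output,
                 sd = sqrt(2 / (spec$hidden[3] + spec$output))),
                 spec$hidden[3], spec$output)))
  biases <- c(pretrained$biases, list(numeric(spec$output)))
  loss_log <- nn_loss_grad(weights, biases, inputs, targets,
                           spec$output_kind)$loss
  if (config$finetune_epochs > 0) {
    vW <- lapply(weights, function(w) w * 0)
    vb <- lapply(biases, function(b) b * 0)
    decay <- if (is.null(config$lr_decay)) 1 else config$lr_decay
    for (epoch in seq_len(config$finetune_epochs)) {
      lr <- config$lr_finetune * decay^(epoch - 1)
      ord <- sample.int(n)
      for (i0 in seq(1, n, by = config$batch_size)) {
        idx <- ord[i0:min(n, i0 + config$batch_size - 1)]
        g <- nn_loss_grad(weights, biases,
                          inputs[idx, , drop = FALSE],
                          targets[idx, , drop = FALSE], spec$output_kind)
        wd <- if (is.null(config$weight_decay)) 0 else config$weight_decay
        for (l in 1:4) {
          vW[[l]] <- config$momentum * vW[[l]] -
            lr * (g$gw[[l]] + wd * weights[[l]])
          vb[[l]] <- config$momentum * vb[[l]] - lr * g$gb[[l]]
          weights[[l]] <- weights[[l]] + vW[[l]]
          biases[[l]] <- biases[[l]] + vb[[l]]
        }
      }
      loss_log <- c(loss_log,
                    nn_loss_grad(weights, biases, inputs, targets,
                                 spec$output_kind)$loss)
    }
  }
  list(weights = weights, biases = biases, loss_log = loss_log)
}

standardize_fit <- function(x, what = "input") {
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  if (nrow(x) == 1) sd_ <- rep(1, ncol(x))
  zero <- which(sd_ == 0 | !is.finite(sd_))
  if (length(zero))
    stop("zero-variance ", what, " dimension(s): ",
         paste(utils::head(zero, 5), collapse = ", "))
  list(center = mu, scale = sd_)
}

apply_standardize <- function(x, st) {
  sweep(sweep(x, 2, st$center, "-"), 2, st$scale, "/")
}

#' Train a deep network end to end
#'
#' Standardizes inputs (and regression targets), pretrains the RBM stack,
#' fine-tunes by back-propagation, and packages the result with its
#' standardization statistics. Deterministic given `config$seed`.
#'
#' @param x n x d input matrix.
#' @param y n x k numeric target matrix (linear) or factor/character labels
#'   (softmax; converted to one-hot over `levels`).
#' @param spec a [net_spec()]; for softmax, `spec$output` must equal the
#'   number of label levels.
#' @param config a [train_config()].
#' @param levels label levels for softmax (defaults to sorted unique labels);
#'   classifier output columns follow this order.
#' @return object of class `trained_net`.
#' @export
train_dnn <- function(x, y, spec, config, levels = NULL) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite inputs")
  if (ncol(x) != spec$input) stop("input dimension mismatch")
  x_st <- if (config$standardize) standardize_fit(x, "input") else
    list(center = rep(0, ncol(x)), scale = rep(1, ncol(x)))
  xs <- apply_standardize(x, x_st)
  if (spec$output_kind == "softmax") {
    if (is.null(levels)) levels <- sort(unique(as.character(y)))
    bad <- setdiff(as.character(y), levels)
    if (length(bad)) stop("label(s) outside inventory: ",
                          paste(unique(bad), collapse = ", "))
    if (length(levels) != spec$output)
      stop("spec output size does not match number of label levels")
    ys <- outer(as.character(y), levels, "==") * 1
    y_st <- NULL
  } else {
    y <- as.matrix(y)
    if (nrow(y) != nrow(x)) stop("row counts of x and y differ")
    y_st <- if (config$standardize) standardize_fit(y, "output") else
      list(center = rep(0, ncol(y)), scale = rep(1, ncol(y)))
    ys <- apply_standardize(y, y_st)
  }
  pre <- pretrain_stack(xs, spec, config)
  ft <- finetune(pre, xs, ys, spec, config)
  structure(
    list(spec = spec, weights = ft$weights, biases = ft$biases,
         x_standardize = x_st, y_standardize = y_st, levels = levels,
         log = list(recon = pre$recon_log, loss = ft$loss_log),
         config = config),
    class = "trained_net")
}

#' @export
print.trained_net <- function(x, ...) {
  cat(sprintf("<trained_net> %d-%s-%d (%s); final loss %.4g\n",
              x$spec$input, paste(x$spec$hidden, collapse = "-"),
              x$spec$output, x$spec$output_kind,
              utils::tail(x$log$loss, 1)))
  invisible(x)
}

#' Predict from a trained deep network
#'
#' Applies the stored input standardization, runs the forward pass, and (for
#' regression) inverts the output standardization. Softmax rows sum to one.
#'
#' @param object a `trained_net`.
#' @param newdata matrix (or vector, taken as one row) of inputs.
#' @param ... unused.
#' @return matrix of predictions (regression scale, or class probabilities).
#' @export
predict.trained_net <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$spec$input)
    stop("input dimension mismatch: expected ", object$spec$input,
         ", got ", ncol(newdata))
  xs <- apply_standardize(newdata, object$x_standardize)
  out <- forward_pass(object$weights, object$biases, xs,
                      object$spec$output_kind)[[4]]
  if (object$spec$output_kind == "linear" && !is.null(object$y_standardize)) {
    out <- sweep(sweep(out, 2, object$y_standardize$scale, "*"), 2,
                 object$y_standardize$center, "+")
  }
  if (object$spec$output_kind == "softmax" && !is.null(object$levels))
    colnames(out) <- object$levels
  out
}

#' Classify inputs with a softmax network
#'
#' Argmax over class probabilities; ties break toward the lowest class index
#' (the first level).
#'
#' @param net a softmax `trained_net`.
#' @param x input matrix.
#' @return character vector of predicted labels.
#' @export
classify_dnn <- function(net, x) {
  if (net$spec$output_kind != "softmax") stop("not a classifier network")
  p <- predict(net, x)
  net$levels[apply(p, 1, which.max)]
}

#' Save / load a trained network
#'
#' Plain-text serialization (dput with hexadecimal numerics), so round-trips
#' are bit-exact.
#'
#' @param net a `trained_net`.
#' @param path file path.
#' @return `path` / the restored `trained_net`.
#' @export
save_trained_net <- function(net, path) {
  dput(unclass(net), file = path,
       control = c("keepNA", "keepInteger", "niceNames", "showAttributes",
                   "hexNumeric"))
  invisible(path)
}

#' @rdname save_trained_net
#' @export
load_trained_net <- function(path) {
  obj <- dget(path)
  class(obj$spec) <- "net_spec"
  class(obj$config) <- "train_config"
  structure(obj, class = "trained_net")
}
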