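#' Training configuration for the image classifier
#'
#' Optimiser and schedule settings: Adam with initial learning rate 1e-4,
#' batch size 128, at most 20 epochs, and early stopping on validation loss
#' (patience 3 validation checks, one check per epoch, best weights
#' restored). `batch_size` and `initial_lr` are meant to be adapted when
#' training the small scratch backbones at desk scale (see the package
#' vignette); the defaults are the settings used with pretrained backbones.
#'
#' @param backbone One of `"tiny-test-cnn"`, `"small-cnn"`, `"googlenet"`,
#'   `"resnet18"`, `"resnet50"`. The two scratch backbones train offline;
#'   the pretrained names require a weights file this package does not bundle
#'   and currently raise an informative error.
#' @param n_classes Number of output classes.
#' @param initial_lr Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience in validation checks.
#' @param freeze_features Train only the final dense head.
#' @param seed Integer seed controlling initialisation and batch shuffling.
#' @return Object of class `train_config`.
#' @export
train_config <- function(backbone = "tiny-test-cnn", n_classes = 2,
                         initial_lr = 1e-4, batch_size = 128,
                         max_epochs = 20, patience = 3,
                         freeze_features = FALSE, seed = 1L) {
  if (max_epochs < 1) stop("max_epochs must be >= 1")
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(backbone = backbone, n_classes = as.integer(n_classes),
                 optimizer = "adam", initial_lr = initial_lr,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 freeze_features = freeze_features,
                 seed = as.integer(seed)),
            class = "train_config")
}

# ---- backbone definitions ------------------------------------------------

# Scratch backbones operate on a 32 x 32 grayscale reduction of the
# 224 x 224 x 3 input (luminance then 7 x 7 average pooling), keeping the
# published input contract while staying trainable on one CPU.
backbone_layers <- function(backbone, n_classes) {
  switch(backbone,
    "tiny-test-cnn" = list(
      list(type = "conv", k = 5, out_c = 8),
      list(type = "relu"),
      list(type = "maxpool"),
      list(type = "conv", k = 3, out_c = 16),
      list(type = "relu"),
      list(type = "maxpool"),
      list(type = "dense", out = n_classes)
    ),
    "small-cnn" = list(
      list(type = "conv", k = 5, out_c = 12),
      list(type = "relu"),
      list(type = "maxpool"),
      list(type = "conv", k = 3, out_c = 24),
      list(type = "relu"),
      list(type = "maxpool"),
      list(type = "conv", k = 3, out_c = 32),
      list(type = "relu"),
      list(type = "dense", out = n_classes)
    ),
    "googlenet" = ,
    "resnet18" = ,
    "resnet50" = stop(
      "backbone '", backbone, "' needs pretrained weights, which are not ",
      "bundled with the package; use a scratch backbone ('tiny-test-cnn' ",
      "or 'small-cnn') or supply weights through your own loader"
    ),
    stop("unknown backbone: ", backbone)
  )
}

# 7x -> 1 average-pooling operator, 32 x 224.
gray_pool_op <- local({
  P <- NULL
  function() {
    if (is.null(P)) P <<- kronecker(diag(32), matrix(1 / 7, 1, 7))
    P
  }
})

# 224 x 224 x 3 integer image -> standardised 32 x 32 grayscale matrix.
input_transform <- function(img) {
  img <- unclass(img)
  d <- dim(img)
  if (length(d) != 3L || d[1] != 224L || d[2] != 224L || d[3] != 3L) {
    stop("images must be 224 x 224 x 3")
  }
  g <- (0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]) / 255
  P <- gray_pool_op()
  g <- P %*% g %*% t(P)
  s <- stats::sd(g)
  if (s > 0) (g - mean(g)) / s else g * 0
}

# Walk the layer list once to size every parameter tensor.
layer_shapes <- function(layers, in_dim = c(32, 32, 1)) {
  dims <- list()
  cur <- in_dim
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    dims[[i]] <- list(in_dim = cur)
    if (l$type == "conv") {
      cur <- c(cur[1] - l$k + 1L, cur[2] - l$k + 1L, l$out_c)
    } else if (l$type == "maxpool") {
      cur <- c(cur[1] %/% 2L, cur[2] %/% 2L, cur[3])
    } else if (l$type == "dense") {
      cur <- c(l$out)
    }
    dims[[i]]$out_dim <- cur
  }
  dims
}

# im2col gather index (K x P) for a conv layer.
conv_index <- function(in_dim, k) {
  H <- in_dim[1]; W <- in_dim[2]; C <- in_dim[3]
  oh <- H - k + 1L; ow <- W - k + 1L
  off <- expand.grid(a = 0:(k - 1L), b = 0:(k - 1L), cc = 0:(C - 1L))
  pos <- expand.grid(i = seq_len(oh), j = seq_len(ow))
  idx <- outer(seq_len(nrow(off)), seq_len(nrow(pos)), function(ko, po) {
    (pos$i[po] + off$a[ko]) +
      (pos$j[po] + off$b[ko] - 1L) * H +
      off$cc[ko] * H * W
  })
  storage.mode(idx) <- "integer"
  idx
}

#' Build an image classification model
#'
#' Constructs a convolutional network with a 2-output fully connected head
#' followed by softmax, accepting 224 x 224 x 3 images. Scratch backbones
#' are initialised randomly (He initialisation, seeded); the pretrained
#' backbone names raise an error because their weights are not bundled.
#'
#' @param cfg A [train_config()].
#' @return Object of class `ppg_cnn`.
#' @export
#' @examples
#' model <- build_model(train_config(backbone = "tiny-test-cnn"))
#' img <- array(sample(0:255, 224 * 224 * 3, TRUE), c(224, 224, 3))
#' predict(model, list(img))
build_model <- function(cfg) {
  layers <- backbone_layers(cfg$backbone, cfg$n_classes)
  dims <- layer_shapes(layers)
  set.seed(cfg$seed)
  params <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      K <- l$k * l$k * dims[[i]]$in_dim[3]
      params[[i]] <- list(
        W = matrix(stats::rnorm(K * l$out_c, 0, sqrt(2 / K)), K, l$out_c),
        b = numeric(l$out_c)
      )
    } else if (l$type == "dense") {
      D <- prod(dims[[i]]$in_dim)
      params[[i]] <- list(
        W = matrix(stats::rnorm(D * l$out, 0, sqrt(2 / D)), D, l$out),
        b = numeric(l$out)
      )
    }
  }
  idx <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    if (layers[[i]]$type == "conv") {
      idx[[i]] <- conv_index(dims[[i]]$in_dim, layers[[i]]$k)
    }
  }
  structure(list(backbone = cfg$backbone, n_classes = cfg$n_classes,
                 layers = layers, dims = dims, params = params,
                 conv_idx = idx, cfg = cfg),
            class = "ppg_cnn")
}

#' @export
print.ppg_cnn <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) {
    if (is.null(p)) 0L else length(p$W) + length(p$b)
  }, integer(1)))
  cat("<ppg_cnn> backbone ", x$backbone, ", ", x$n_classes,
      " classes, ", np, " trainable parameters\n", sep = "")
  invisible(x)
}

# ---- forward / backward --------------------------------------------------

conv_forward <- function(x, in_dim, idx, W, b, batch) {
  K <- nrow(idx); P <- ncol(idx)
  Xf <- matrix(x, nrow = batch)
  M <- matrix(aperm(array(Xf[, as.vector(idx)], c(batch, K, P)), c(1, 3, 2)),
              batch * P, K)
  Z <- M %*% W
  Z <- sweep(Z, 2, b, "+")
  list(out = array(Z, c(batch, P %/% 1, ncol(W))), M = M)
}

conv_backward <- function(dZ, M, idx, W, in_dim, batch) {
  K <- nrow(idx); P <- ncol(idx); F_ <- ncol(W)
  dZm <- matrix(dZ, batch * P, F_)
  dW <- crossprod(M, dZm)
  db <- colSums(dZm)
  dM <- array(dZm %*% t(W), c(batch, P, K))
  dXf <- matrix(0, batch, prod(in_dim))
  for (k in seq_len(K)) {
    cols <- idx[k, ]
    dXf[, cols] <- dXf[, cols] + dM[, , k]
  }
  list(dX = dXf, dW = dW, db = db)
}

maxpool_forward <- function(x, in_dim, batch) {
  H <- in_dim[1]; W <- in_dim[2]; C <- in_dim[3]
  xa <- array(x, c(batch, H, W, C))
  oi <- seq(1L, H, by = 2L); oj <- seq(1L, W, by = 2L)
  cand <- list(xa[, oi, oj, , drop = FALSE], xa[, oi + 1L, oj, , drop = FALSE],
               xa[, oi, oj + 1L, , drop = FALSE],
               xa[, oi + 1L, oj + 1L, , drop = FALSE])
  out <- pmax(cand[[1]], cand[[2]], cand[[3]], cand[[4]])
  list(out = out, cand = cand)
}

maxpool_backward <- function(dOut, fwd, in_dim, batch) {
  H <- in_dim[1]; W <- in_dim[2]; C <- in_dim[3]
  dX <- array(0, c(batch, H, W, C))
  oi <- seq(1L, H, by = 2L); oj <- seq(1L, W, by = 2L)
  assigned <- array(FALSE, dim(dOut))
  sub <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (m in 1:4) {
    take <- (fwd$cand[[m]] == fwd$out) & !assigned
    assigned <- assigned | take
    dX[, oi + sub[[m]][1], oj + sub[[m]][2], ] <-
      dX[, oi + sub[[m]][1], oj + sub[[m]][2], ] + dOut * take
  }
  dX
}

model_forward <- function(model, X, keep_cache = FALSE) {
  batch <- nrow(X)
  a <- X  # batch x 1024 (32 x 32 x 1, column-major)
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    ind <- model$dims[[i]]$in_dim
    if (l$type == "conv") {
      fw <- conv_forward(a, ind, model$conv_idx[[i]], model$params[[i]]$W,
                         model$params[[i]]$b, batch)
      if (keep_cache) caches[[i]] <- fw["M"]
      a <- matrix(fw$out, nrow = batch)
    } else if (l$type == "relu") {
      if (keep_cache) caches[[i]] <- list(mask = a > 0)
      a <- pmax(a, 0)
    } else if (l$type == "maxpool") {
      fw <- maxpool_forward(a, ind, batch)
      if (keep_cache) caches[[i]] <- fw
      a <- matrix(fw$out, nrow = batch)
    } else if (l$type == "dense") {
      if (keep_cache) caches[[i]] <- list(X = a)
      a <- sweep(a %*% model$params[[i]]$W, 2, model$params[[i]]$b, "+")
    }
  }
  z <- a - apply(a, 1, max)
  probs <- exp(z) / rowSums(exp(z))
  list(logits = a, probs = probs, caches = caches)
}

model_backward <- function(model, fwd, X, y_onehot) {
  batch <- nrow(X)
  grads <- vector("list", length(model$layers))
  d <- (fwd$probs - y_onehot) / batch
  for (i in rev(seq_along(model$layers))) {
    l <- model$layers[[i]]
    ind <- model$dims[[i]]$in_dim
    if (l$type == "dense") {
      Xin <- fwd$caches[[i]]$X
      grads[[i]] <- list(dW = crossprod(Xin, d),
                         db = colSums(d))
      d <- d %*% t(model$params[[i]]$W)
    } else if (l$type == "maxpool") {
      dOut <- array(d, dim(fwd$caches[[i]]$out))
      d <- matrix(maxpool_backward(dOut, fwd$caches[[i]], ind, batch),
                  nrow = batch)
    } else if (l$type == "relu") {
      d <- d * fwd$caches[[i]]$mask
    } else if (l$type == "conv") {
      od <- model$dims[[i]]$out_dim
      dZ <- array(d, c(batch, od[1] * od[2], od[3]))
      bw <- conv_backward(dZ, fwd$caches[[i]]$M, model$conv_idx[[i]],
                          model$params[[i]]$W, ind, batch)
      grads[[i]] <- bw[c("dW", "db")]
      d <- bw$dX
    }
  }
  grads
}

# ---- images in ------------------------------------------------------------

# Accepts an image manifest tibble (image or image_path column), a list of
# pixel arrays, or a single array; returns batch x 1024 feature matrix.
images_to_features <- function(images) {
  if (is.array(images) && length(dim(images)) == 3L) images <- list(images)
  if (is.data.frame(images)) {
    images <- if ("image" %in% names(images)) {
      images$image
    } else if ("image_path" %in% names(images)) {
      purrr::map(images$image_path, read_scalogram_png)
    } else {
      stop("image manifest needs an 'image' or 'image_path' column")
    }
  }
  t(vapply(images, function(im) as.vector(input_transform(im)),
           numeric(32 * 32)))
}

manifest_labels <- function(manifest) {
  factor(as.character(manifest$label), levels = c("NTS", "HTS"))
}

# ---- training -------------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) return(NULL)
    list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0)
  })
}

adam_step <- function(params, grads, state, lr, t, freeze_until = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(params)) {
    if (is.null(params[[i]]) || is.null(grads[[i]]) || i <= freeze_until) next
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * grads[[i]]$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * grads[[i]]$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * grads[[i]]$db
    s$vb <- beta2 * s$vb + (1 - beta2) * grads[[i]]$db^2
    mhW <- s$mW / (1 - beta1^t); vhW <- s$vW / (1 - beta2^t)
    mhb <- s$mb / (1 - beta1^t); vhb <- s$vb / (1 - beta2^t)
    params[[i]]$W <- params[[i]]$W - lr * mhW / (sqrt(vhW) + eps)
    params[[i]]$b <- params[[i]]$b - lr * mhb / (sqrt(vhb) + eps)
    state[[i]] <- s
  }
  list(params = params, state = state)
}

eval_loss_acc <- function(model, X, y) {
  n <- nrow(X)
  probs <- matrix(0, n, model$n_classes)
  for (from in seq(1, n, by = 256)) {
    to <- min(from + 255, n)
    probs[from:to, ] <- model_forward(model, X[from:to, , drop = FALSE])$probs
  }
  yi <- as.integer(y)
  loss <- -mean(log(pmax(probs[cbind(seq_len(n), yi)], 1e-12)))
  pred <- ifelse(probs[, 2] > probs[, 1], 2L, 1L)  # tie -> NTS
  list(loss = loss, acc = mean(pred == yi), probs = probs)
}

#' Train a model on a calibration split
#'
#' Mini-batch Adam on softmax cross-entropy over the split's training
#' images, with one validation check per epoch. Early stopping halts
#' training after `patience` checks without a new best validation loss and
#' restores the best-so-far weights. Deterministic for a fixed seed.
#'
#' @param model A `ppg_cnn` from [build_model()].
#' @param split A `calibration_split`, or a list with elements `train` and
#'   `val`, each an image manifest tibble with `label` and `image`/
#'   `image_path` columns.
#' @param cfg A [train_config()].
#' @return Object of class `ppg_cnn_fit`: the trained `model`, a per-check
#'   `history` tibble, `epochs_completed`, `stop_reason` (`"early_stop"` or
#'   `"max_epochs"`), and `best_val_loss`.
#' @export
train_model <- function(model, split, cfg = model$cfg) {
  if (nrow(split$train) == 0L) stop("training set is empty")
  has_val <- nrow(split$val) > 0L
  if (!has_val) {
    warning("validation set is empty; training without early stopping")
  }
  Xtr <- images_to_features(split$train)
  ytr <- manifest_labels(split$train)
  if (has_val) {
    Xva <- images_to_features(split$val)
    yva <- manifest_labels(split$val)
  }

  set.seed(cfg$seed)
  params <- model$params
  state <- adam_init(params)
  n <- nrow(Xtr)
  onehot <- diag(model$n_classes)[as.integer(ytr), , drop = FALSE]
  freeze_until <- if (isTRUE(cfg$freeze_features)) {
    length(model$layers) - 1L
  } else 0L

  best <- list(loss = Inf, params = params, epoch = 0L)
  bad_checks <- 0L
  stop_reason <- "max_epochs"
  hist <- list()
  t_adam <- 0L

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0
    for (from in seq(1, n, by = cfg$batch_size)) {
      bi <- ord[from:min(from + cfg$batch_size - 1, n)]
      model$params <- params
      fwd <- model_forward(model, Xtr[bi, , drop = FALSE], keep_cache = TRUE)
      yi <- as.integer(ytr[bi])
      ep_loss <- ep_loss -
        sum(log(pmax(fwd$probs[cbind(seq_along(bi), yi)], 1e-12)))
      ep_correct <- ep_correct +
        sum(ifelse(fwd$probs[, 2] > fwd$probs[, 1], 2L, 1L) == yi)
      grads <- model_backward(model, fwd, Xtr[bi, , drop = FALSE],
                              onehot[bi, , drop = FALSE])
      t_adam <- t_adam + 1L
      upd <- adam_step(params, grads, state, cfg$initial_lr, t_adam,
                       freeze_until)
      params <- upd$params; state <- upd$state
    }
    model$params <- params
    row <- tibble::tibble(epoch = epoch,
                          train_loss = ep_loss / n,
                          train_acc = ep_correct / n,
                          val_loss = NA_real_, val_acc = NA_real_)
    if (has_val) {
      va <- eval_loss_acc(model, Xva, yva)
      row$val_loss <- va$loss; row$val_acc <- va$acc
      if (va$loss < best$loss) {
        best <- list(loss = va$loss, params = params, epoch = epoch)
        bad_checks <- 0L
      } else {
        bad_checks <- bad_checks + 1L
      }
    }
    hist[[epoch]] <- row
    if (has_val && bad_checks >= cfg$patience) {
      stop_reason <- "early_stop"
      break
    }
  }

  if (has_val) model$params <- best$params
  fit <- list(model = model,
              history = dplyr::bind_rows(hist),
              epochs_completed = length(hist),
              stop_reason = stop_reason,
              best_val_loss = if (has_val) best$loss else NA_real_,
              best_epoch = if (has_val) best$epoch else NA_integer_,
              cfg = cfg)
  class(fit) <- "ppg_cnn_fit"
  fit
}

#' @export
print.ppg_cnn_fit <- function(x, ...) {
  cat("<ppg_cnn_fit> ", x$model$backbone, ": ", x$epochs_completed,
      " epoch(s), stop: ", x$stop_reason,
      if (!is.na(x$best_val_loss)) {
        sprintf(", best val loss %.4f (epoch %d)", x$best_val_loss, x$best_epoch)
      }, "\n", sep = "")
  invisible(x)
}

#' Predict hypertension labels for images
#'
#' @param object A `ppg_cnn` or `ppg_cnn_fit`.
#' @param images An image manifest tibble, list of 224 x 224 x 3 arrays, or
#'   a single array.
#' @param ... Ignored.
#' @return Tibble with `label` (factor NTS/HTS; probability ties resolve to
#'   NTS), `p_nts`, `p_hts`.
#' @export
predict.ppg_cnn <- function(object, images, ...) {
  X <- images_to_features(images)
  res <- eval_loss_acc(object, X,
                       factor(rep("NTS", nrow(X)), c("NTS", "HTS")))
  tibble::tibble(
    label = factor(ifelse(res$probs[, 2] > res$probs[, 1], "HTS", "NTS"),
                   levels = c("NTS", "HTS")),
    p_nts = res$probs[, 1],
    p_hts = res$probs[, 2]
  )
}

#' @rdname predict.ppg_cnn
#' @export
predict.ppg_cnn_fit <- function(object, images, ...) {
  predict(object$model, images, ...)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-check training history of a fitted classifier
#'
#' @param x A `ppg_cnn_fit`.
#' @param ... Ignored.
#' @return Tibble with one row per validation check: `epoch`, `train_loss`,
#'   `train_acc`, `val_loss`, `val_acc`.
#' @export
tidy.ppg_cnn_fit <- function(x, ...) x$history

#' One-row summary of a fitted classifier
#'
#' @param x A `ppg_cnn_fit`.
#' @param ... Ignored.
#' @return Tibble: `backbone`, `epochs_completed`, `stop_reason`,
#'   `best_epoch`, `best_val_loss`, `final_val_acc`.
#' @export
glance.ppg_cnn_fit <- function(x, ...) {
  h <- x$history
  va <- if (nrow(h) && !all(is.na(h$val_acc))) {
    h$val_acc[match(x$best_epoch, h$epoch)]
  } else NA_real_
  tibble::tibble(backbone = x$model$backbone,
                 epochs_completed = x$epochs_completed,
                 stop_reason = x$stop_reason,
                 best_epoch = x$best_epoch,
                 best_val_loss = x$best_val_loss,
                 final_val_acc = va)
}

#' Plot training history
#'
#' @param object A `ppg_cnn_fit`.
#' @param ... Ignored.
#' @return A ggplot of training/validation loss and accuracy per epoch.
#' @export
autoplot.ppg_cnn_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"epoch",
                              names_to = c("set", "metric"), names_sep = "_")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Save / load a trained classifier as plain text
#'
#' Writes the architecture, configuration, and all weights as JSON.
#'
#' @param fit A `ppg_cnn_fit`.
#' @param path Output path.
#' @return `path` invisibly, or the restored `ppg_cnn_fit`.
#' @export
write_model_checkpoint <- function(fit, path) {
  payload <- list(
    backbone = fit$model$backbone,
    n_classes = fit$model$n_classes,
    cfg = unclass(fit$cfg),
    epochs_completed = fit$epochs_completed,
    stop_reason = fit$stop_reason,
    params = {
      keep <- which(!vapply(fit$model$params, is.null, logical(1)))
      stats::setNames(lapply(keep, function(i) {
        p <- fit$model$params[[i]]
        list(W = as.vector(p$W), dims = dim(p$W), b = p$b)
      }), as.character(keep))
    },
    history = fit$history
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_checkpoint
#' @export
read_model_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(train_config, payload$cfg[names(payload$cfg) != "optimizer"])
  model <- build_model(cfg)
  for (key in names(payload$params)) {
    i <- as.integer(key)
    p <- payload$params[[key]]
    model$params[[i]]$W <- matrix(p$W, p$dims[1], p$dims[2])
    model$params[[i]]$b <- p$b
  }
  fit <- list(model = model,
              history = tibble::as_tibble(payload$history),
              epochs_completed = payload$epochs_completed,
              stop_reason = payload$stop_reason,
              best_val_loss = NA_real_, best_epoch = NA_integer_, cfg = cfg)
  class(fit) <- "ppg_cnn_fit"
  fit
}
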