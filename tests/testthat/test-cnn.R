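test_that("models expose the 2-class softmax contract on 224x224x3 input", {
  set.seed(1)
  img <- array(sample(0:255, 224 * 224 * 3, TRUE), c(224, 224, 3))
  for (bb in c("tiny-test-cnn", "small-cnn")) {
    model <- build_model(train_config(backbone = bb, seed = 2))
    p <- predict(model, list(img))
    expect_equal(nrow(p), 1)
    expect_true(all(is.finite(c(p$p_nts, p$p_hts))))
    expect_equal(p$p_nts + p$p_hts, 1, tolerance = 1e-9)
    expect_true(p$label %in% c("NTS", "HTS"))
  }
  expect_error(build_model(train_config(backbone = "nope")), "unknown backbone")
  expect_error(build_model(train_config(backbone = "resnet18")), "weights")
  expect_error(predict(build_model(train_config()),
                       list(array(0L, c(100, 100, 3)))), "224")
})

test_that("predictions are argmax labels with probabilities summing to one", {
  set.seed(4)
  imgs <- lapply(1:6, function(i) array(sample(0:255, 224 * 224 * 3, TRUE),
                                        c(224, 224, 3)))
  model <- build_model(train_config(seed = 3))
  p <- predict(model, imgs)
  expect_equal(nrow(p), 6)
  expect_equal(p$p_nts + p$p_hts, rep(1, 6), tolerance = 1e-5)
  expect_equal(as.character(p$label),
               ifelse(p$p_hts > p$p_nts, "HTS", "NTS"))
})

test_that("analytic gradients match finite differences on a tiny batch", {
  cfg <- train_config(backbone = "tiny-test-cnn", seed = 5)
  model <- build_model(cfg)
  set.seed(6)
  X <- matrix(stats::rnorm(3 * 1024), 3, 1024)
  y <- c(1L, 2L, 1L)
  onehot <- diag(2)[y, ]
  loss_at <- function(m) {
    p <- ppgcalib:::model_forward(m, X)$probs
    -mean(log(p[cbind(1:3, y)]))
  }
  fwd <- ppgcalib:::model_forward(model, X, keep_cache = TRUE)
  grads <- ppgcalib:::model_backward(model, fwd, X, onehot)
  eps <- 1e-5
  for (li in c(1, 4, 7)) {  # conv1, conv2, dense
    for (probe in list(c(1, 1), c(2, 2))) {
      m2 <- model
      m2$params[[li]]$W[probe[1], probe[2]] <-
        m2$params[[li]]$W[probe[1], probe[2]] + eps
      num <- (loss_at(m2) - loss_at(model)) / eps
      expect_equal(num, grads[[li]]$dW[probe[1], probe[2]], tolerance = 1e-3)
    }
  }
})

test_that("trivially separable image classes are learned to perfection", {
  man <- band_manifest(20, seed = 10)
  # linear separability oracle on raw pixels: centroid classifier
  feats <- t(vapply(man$image, function(im) {
    as.vector(ppgcalib:::input_transform(im))
  }, numeric(1024)))
  cn <- colMeans(feats[man$label == "NTS", ])
  ch <- colMeans(feats[man$label == "HTS", ])
  pred0 <- ifelse(rowSums((feats - matrix(cn, 40, 1024, TRUE))^2) <
                    rowSums((feats - matrix(ch, 40, 1024, TRUE))^2),
                  "NTS", "HTS")
  expect_equal(mean(pred0 == man$label), 1)

  cfg <- train_config(initial_lr = 3e-3, batch_size = 16, max_epochs = 8,
                      seed = 1)
  split <- list(train = man[c(1:15, 21:35), ], val = man[c(16:20, 36:40), ])
  fit <- train_model(build_model(cfg), split, cfg)
  expect_lte(fit$epochs_completed, 20)
  h <- tidy(fit)
  expect_equal(max(h$train_acc), 1)
  expect_equal(glance(fit)$final_val_acc, 1)
})

test_that("training is deterministic for a fixed seed", {
  man <- band_manifest(8, seed = 2)
  split <- list(train = man[c(1:6, 9:14), ], val = man[c(7:8, 15:16), ])
  cfg <- train_config(initial_lr = 3e-3, batch_size = 8, max_epochs = 3,
                      seed = 7)
  f1 <- train_model(build_model(cfg), split, cfg)
  f2 <- train_model(build_model(cfg), split, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("early stopping restores the best validation checkpoint", {
  man <- band_manifest(10, seed = 5)
  # make validation labels adversarial so validation loss soon degrades
  val <- man[c(1:4, 11:14), ]
  val$label <- factor(rev(as.character(val$label)), c("NTS", "HTS"))
  split <- list(train = man[c(5:10, 15:20), ], val = val)
  cfg <- train_config(initial_lr = 5e-3, batch_size = 8, max_epochs = 20,
                      patience = 2, seed = 8)
  fit <- train_model(build_model(cfg), split, cfg)
  expect_equal(fit$stop_reason, "early_stop")
  expect_lt(fit$epochs_completed, 20)
  h <- tidy(fit)
  expect_equal(fit$best_val_loss, min(h$val_loss))
  # the restored weights reproduce the best validation loss
  X <- ppgcalib:::images_to_features(split$val)
  y <- ppgcalib:::manifest_labels(split$val)
  ev <- ppgcalib:::eval_loss_acc(fit$model, X, y)
  expect_equal(ev$loss, fit$best_val_loss, tolerance = 1e-9)
})

test_that("degenerate splits error or warn as promised", {
  man <- band_manifest(4, seed = 3)
  expect_error(train_model(build_model(train_config()),
                           list(train = man[0, ], val = man)), "empty")
  cfg <- train_config(max_epochs = 1, batch_size = 4, seed = 1)
  expect_warning(fit <- train_model(build_model(cfg),
                                    list(train = man, val = man[0, ]), cfg),
                 "without early stopping")
  expect_equal(fit$stop_reason, "max_epochs")
})

test_that("a fitted model survives a text checkpoint round trip", {
  man <- band_manifest(6, seed = 9)
  split <- list(train = man[c(1:4, 7:10), ], val = man[c(5:6, 11:12), ])
  cfg <- train_config(initial_lr = 3e-3, batch_size = 4, max_epochs = 2,
                      seed = 11)
  fit <- train_model(build_model(cfg), split, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_checkpoint(fit, path)
  back <- read_model_checkpoint(path)
  p1 <- predict(fit, man[1:4, ])
  p2 <- predict(back, man[1:4, ])
  expect_equal(p1$p_hts, p2$p_hts, tolerance = 1e-12)
  expect_equal(back$epochs_completed, fit$epochs_completed)
})
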