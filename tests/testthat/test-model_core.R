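test_that("model construction is deterministic and well-formed", {
  m1 <- build_model(64, 3, seed = 5)
  m2 <- build_model(64, 3, seed = 5)
  expect_identical(get_params(m1), get_params(m2))
  m3 <- build_model(64, 3, seed = 6)
  expect_false(identical(get_params(m1), get_params(m3)))

  # sections appear in backbone -> neck -> head order
  secs <- vapply(m1$layers, `[[`, "", "section")
  expect_identical(secs, secs[order(match(secs, c("backbone", "neck", "head")))])
  # at least 6 prunable residual blocks
  expect_gte(sum(vapply(m1$layers, function(l) l$type == "resblock", TRUE)), 6)
  # parameter count equals the summed tensor sizes
  expect_equal(param_count(m1),
               sum(vapply(m1$layers, function(l)
                 length(l$W) + length(l$b), 0)))
})

test_that("forward pass yields probabilities for any configured size", {
  for (sz in c(16, 32, 64)) {
    m <- build_model(sz, 3, seed = 2)
    x <- array(runif(2 * sz * sz * 3), c(2, sz, sz, 3))
    p <- model_predict(m, list(x = x, y = c(0, 1)))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("analytic gradients match central finite differences", {
  m <- build_model(16, 3, seed = 3)
  set.seed(5)
  xs <- array(runif(4 * 16 * 16 * 3), c(4, 16, 16, 3))
  ys <- c(0, 1, 1, 0)
  lg <- fedlhe:::model_loss_grads(m, xs, ys)
  flat <- unlist(lapply(seq_along(m$layers), function(li) {
    g <- lg$grads[[li]]
    if (is.null(g)) numeric(0) else c(as.numeric(g$W), g$b)
  }))
  p <- get_params(m)
  num_loss <- function(pp) {
    pr <- as.numeric(fedlhe:::model_forward(set_params(m, pp), xs)$out)
    pc <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    -mean(ys * log(pc) + (1 - ys) * log(1 - pc))
  }
  eps <- 1e-6
  set.seed(6)
  for (j in sample(length(p), 12)) {
    pp <- p; pp[j] <- pp[j] + eps; up <- num_loss(pp)
    pp[j] <- pp[j] - 2 * eps; dn <- num_loss(pp)
    num <- (up - dn) / (2 * eps)
    expect_lt(abs(flat[j] - num), 1e-6 + 1e-4 * abs(num))
  }
})

test_that("training is deterministic given seed and data order", {
  b <- tiny_bundle()
  m <- build_model(32, 3, seed = 1)
  cfg <- train_config(epochs = 2, seed = 9)
  t1 <- train_local(m, b$train, cfg, val = image_set_to_batch(b$val))
  t2 <- train_local(m, b$train, cfg, val = image_set_to_batch(b$val))
  expect_identical(t1$history, t2$history)
  expect_identical(get_params(t1$model), get_params(t2$model))
})

test_that("zero epochs change nothing and produce an empty history", {
  b <- tiny_bundle()
  m <- build_model(32, 3, seed = 1)
  tr <- train_local(m, b$train, train_config(epochs = 0))
  expect_identical(get_params(tr$model), get_params(m))
  expect_equal(nrow(tr$history), 0)
})

test_that("a single-class shard warns but still trains", {
  b <- tiny_bundle()
  labs <- vapply(b$train$images, `[[`, 0, "label")
  one_class <- fedlhe:::subset_image_set(b$train, which(labs == 1)[1:20])
  m <- build_model(32, 3, seed = 1)
  expect_warning(train_local(m, one_class, train_config(epochs = 1)),
                 "single class")
})

test_that("frozen backbone tensors are bit-unchanged by training", {
  b <- tiny_bundle()
  m <- freeze_backbone(build_model(32, 3, seed = 3))
  expect_identical(m, freeze_backbone(m))  # idempotent
  backbone_before <- lapply(Filter(function(l) l$section == "backbone",
                                   m$layers), `[[`, "W")
  tr <- train_local(m, b$train, train_config(epochs = 1, seed = 2))
  backbone_after <- lapply(Filter(function(l) l$section == "backbone",
                                  tr$model$layers), `[[`, "W")
  expect_identical(backbone_before, backbone_after)
  # neck/head did move
  expect_false(identical(get_params(m), get_params(tr$model)))
  # trainable count drops by exactly the backbone size
  backbone_size <- sum(vapply(m$layers, function(l)
    if (l$section == "backbone" && !is.null(l$W)) length(l$W) + length(l$b)
    else 0, 0))
  expect_equal(param_count(m) - param_count(m, trainable_only = TRUE),
               backbone_size)
  expect_equal(param_count(unfreeze_backbone(m), trainable_only = TRUE),
               param_count(m))
})

test_that("loss decreases on a separable shard for small learning rates", {
  wins <- 0
  for (seed in 1:3) {
    b <- generate_dataset(120, image_size = 32, seed = seed)
    m <- build_model(32, 3, seed = seed)
    tr <- train_local(m, b$train, train_config(epochs = 3, lr = 0.005,
                                               seed = seed))
    if (tr$history$loss[3] < tr$history$loss[1]) wins <- wins + 1
  }
  expect_gte(wins, 2)
})

test_that("classification metrics come from the exact contingency", {
  # all correct
  r <- classification_report(c(0.9, 0.1, 0.8, 0.2), c(1, 0, 1, 0))
  expect_equal(r$accuracy, 1)
  expect_equal(r$f1, 1)
  # TP=9 FP=1 FN=3 TN=7
  preds <- c(rep(1, 9), rep(1, 1), rep(0, 3), rep(0, 7))
  labels <- c(rep(1, 9), rep(0, 1), rep(1, 3), rep(0, 7))
  r <- classification_report(preds, labels)
  expect_equal(r$precision, 0.9)
  expect_equal(r$recall, 0.75)
  expect_equal(round(r$f1, 4), 0.8182)
  # degenerate: no positives anywhere
  r0 <- classification_report(rep(0, 5), rep(0, 5))
  expect_equal(r0$precision, 0)
  expect_equal(r0$recall, 0)
  expect_true(all(c("precision", "recall") %in% r0$degenerate))
  expect_equal(r0$accuracy, 1)
  expect_error(evaluate(build_model(16, 3, 1),
                        list(x = array(0, c(0, 16, 16, 3)), y = numeric(0))),
               "empty")
})

test_that("classification_report agrees with an independent implementation", {
  skip_if_not_installed("caret")
  set.seed(77)
  for (rep in 1:100) {
    n <- sample(10:60, 1)
    y <- sample(0:1, n, replace = TRUE)
    yhat <- sample(0:1, n, replace = TRUE)
    if (sum(yhat) == 0 || sum(yhat) == n || length(unique(y)) < 2) next
    r <- classification_report(yhat, y)
    cm <- caret::confusionMatrix(factor(yhat, levels = c(0, 1)),
                                 factor(y, levels = c(0, 1)),
                                 positive = "1", mode = "prec_recall")
    expect_equal(r$accuracy, unname(cm$overall["Accuracy"]))
    expect_equal(r$precision, unname(cm$byClass["Precision"]))
    expect_equal(r$recall, unname(cm$byClass["Recall"]))
    # caret reports NaN where this package flags a zero denominator
    if (is.finite(cm$byClass["F1"]))
      expect_equal(r$f1, unname(cm$byClass["F1"]))
  }
})

test_that("parameter vector extraction and insertion are exact inverses", {
  m <- build_model(32, 3, seed = 4)
  p <- get_params(m)
  m2 <- set_params(m, p)
  expect_identical(get_params(m2), p)
  p2 <- p + 0.25
  expect_equal(get_params(set_params(m, p2)), p2)
  expect_error(set_params(m, p[-1]), "length|too short")
  # trainable-only round-trip under a frozen backbone
  mf <- freeze_backbone(m)
  pt <- get_params(mf, trainable_only = TRUE)
  expect_lt(length(pt), length(p))
  expect_identical(get_params(set_params(mf, pt, trainable_only = TRUE),
                              trainable_only = TRUE), pt)
})

test_that("checkpoints reproduce the model bit-exactly", {
  b <- tiny_bundle()
  m <- train_local(build_model(32, 3, seed = 8), b$train,
                   train_config(epochs = 1, seed = 8))$model
  f <- withr::local_tempfile(fileext = ".txt")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(get_params(m2), get_params(m))
  x <- array(runif(3 * 32 * 32 * 3), c(3, 32, 32, 3))
  expect_identical(model_predict(m2, list(x = x, y = rep(0, 3))),
                   model_predict(m, list(x = x, y = rep(0, 3))))
})
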