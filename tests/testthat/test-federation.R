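test_that("fedavrg computes the sample-weighted mean", {
  u <- function(id, n, w) client_update(id, n, params = w)
  # single client: identity
  expect_identical(fedavrg(list(u(1, 7, c(0.1, -0.2)))), c(0.1, -0.2))
  # sizes 1 and 3, params 2 and 6 -> 5
  expect_equal(fedavrg(list(u(1, 1, 2), u(2, 3, 6))), 5)
  # equal sizes -> arithmetic mean
  expect_equal(fedavrg(list(u(1, 4, 1), u(2, 4, 2), u(3, 4, 3))), 2)
  expect_error(fedavrg(list()), "at least one")
  expect_error(fedavrg(list(u(1, 1, c(1, 2)), u("bad", 1, 1))),
               "client\\(s\\): bad")
})

test_that("fedavrg is idempotent, permutation-stable and convex", {
  set.seed(61)
  w <- rnorm(40)
  ups <- lapply(1:5, function(j) client_update(j, j, params = w))
  expect_identical(fedavrg(ups), w)  # identical inputs: bit-exact
  ups2 <- lapply(1:5, function(j)
    client_update(j, sample(1:50, 1), params = rnorm(40)))
  g <- fedavrg(ups2)
  gp <- fedavrg(rev(ups2))
  expect_equal(g, gp, tolerance = 1e-12)
  lo <- do.call(pmin, lapply(ups2, `[[`, "params"))
  hi <- do.call(pmax, lapply(ups2, `[[`, "params"))
  eps <- 1e-12
  expect_true(all(g >= lo - eps & g <= hi + eps))
})

test_that("encrypted aggregation matches the plaintext path", {
  kp <- he_keygen(bit_length = 32, seed = 71)
  codec <- fp_codec(16, 8, headroom = 50)
  # five clients with identical weight 0.2 and equal sizes
  ups <- lapply(1:5, function(j)
    client_update(j, 8, payload = encrypt_update(rep(0.2, 10), 8, kp, codec)))
  agg <- encrypted_aggregate(ups, kp, codec)
  expect_equal(agg, rep(0.2, 10), tolerance = 1 / codec$scale)
  # sizes 1 and 3 with weights 2 and 6 -> 5 within a quantum
  ups2 <- list(
    client_update(1, 1, payload = encrypt_update(2, 1, kp, codec)),
    client_update(2, 3, payload = encrypt_update(6, 3, kp, codec)))
  expect_equal(encrypted_aggregate(ups2, kp, codec), 5,
               tolerance = 2^-16)
  # mixed keys are rejected
  kp2 <- he_keygen(bit_length = 32, seed = 72)
  ups3 <- list(
    client_update(1, 1, payload = encrypt_update(1, 1, kp, codec)),
    client_update(2, 1, payload = encrypt_update(1, 1, kp2, codec)))
  expect_error(encrypted_aggregate(ups3, kp, codec), "different keys")
  # exceeding the headroom is an overflow error, not silent wraparound
  big <- list(client_update(1, 60,
                            payload = encrypt_update(1, 60, kp, codec)))
  expect_error(encrypted_aggregate(big, kp, codec), "headroom exceeded")
})

test_that("encrypted and plaintext aggregation agree within the stated bound", {
  kp <- he_keygen(bit_length = 32, seed = 73)
  codec <- fp_codec(16, 8, headroom = 400)
  set.seed(62)
  for (rep in 1:30) {
    ns <- sample(10:70, 5)
    ws <- lapply(1:5, function(j) runif(25, -4, 4))
    plain <- fedavrg(Map(function(j, w) client_update(j, ns[j], params = w),
                         1:5, ws))
    enc <- encrypted_aggregate(
      Map(function(j, w) client_update(
        j, ns[j], payload = encrypt_update(w, ns[j], kp, codec)), 1:5, ws),
      kp, codec)
    bound <- 5 / (2 * codec$scale * sum(ns))
    expect_lte(max(abs(enc - plain)), bound)
  }
})

test_that("client selection is deterministic and sized by the floor rule", {
  expect_equal(select_clients(5, 1), 1:5)
  s1 <- select_clients(10, 0.5, seed = 3, round_index = 2)
  s2 <- select_clients(10, 0.5, seed = 3, round_index = 2)
  expect_identical(s1, s2)
  expect_equal(length(s1), 5)
  expect_equal(length(select_clients(5, 0.6, seed = 1)), 3)
  expect_equal(length(select_clients(5, 0.1, seed = 1)), 1)  # min 1
  expect_error(select_clients(5, 0), "0 clients|\\(0, 1\\]")
  # different rounds draw different subsets (with high probability)
  draws <- vapply(1:8, function(r)
    paste(select_clients(10, 0.3, seed = 3, round_index = r),
          collapse = ","), "")
  expect_gt(length(unique(draws)), 1)
})

test_that("identical shards make the aggregate equal each client exactly", {
  b <- tiny_bundle(n = 120, image_size = 32, seed = 51)
  labs <- vapply(b$train$images, `[[`, 0, "label")
  idx <- c(which(labs == 0)[1:12], which(labs == 1)[1:20])
  one <- fedlhe:::subset_image_set(b$train, idx)
  shards <- lapply(1:5, function(j)
    structure(list(client_id = j, data = one, indices = idx, n = length(idx),
                   spec = NULL), class = "client_shard"))
  cfg <- fedl_config(rounds = 1, local_epochs = 1, encryption = FALSE,
                     balance_shards = FALSE, seed = 5)
  fit <- fedl(b, cfg, shards = shards)
  # reproduce one client's local training
  template <- build_model(32, 3, seed = fedlhe:::derive_seed(5, 11))
  tc <- train_config(epochs = 1, batch_size = 32, lr = 0.01,
                     seed = fedlhe:::derive_seed(5, 500, 1))
  local <- train_local(template, one, tc)
  expect_identical(coef(fit), get_params(local$model))
})

test_that("one-client federation is exactly local training", {
  b <- tiny_bundle(n = 100, image_size = 32, seed = 52)
  shards <- partition_iid(b, 1, seed = 1)
  cfg <- fedl_config(n_clients = 1, rounds = 1, local_epochs = 2,
                     encryption = FALSE, balance_shards = FALSE, seed = 9)
  fit <- fedl(b, cfg, shards = shards)
  template <- build_model(32, 3, seed = fedlhe:::derive_seed(9, 11))
  tc <- train_config(epochs = 2, batch_size = 32, lr = 0.01,
                     seed = fedlhe:::derive_seed(9, 500, 1))
  local <- train_local(template, shards[[1]], tc)
  expect_identical(coef(fit), get_params(local$model))
})

test_that("zero rounds leave the initial state and an empty history", {
  b <- tiny_bundle(n = 100, image_size = 32, seed = 53)
  cfg <- fedl_config(rounds = 0, encryption = FALSE, balance_shards = FALSE,
                     seed = 2)
  fit <- fedl(b, cfg)
  expect_equal(nrow(fit$history), 0)
  expect_identical(coef(fit),
                   get_params(build_model(32, 3,
                                          seed = fedlhe:::derive_seed(2, 11))))
})

test_that("fedl objects expose the standard methods", {
  b <- tiny_bundle(n = 120, image_size = 32, seed = 54)
  cfg <- fedl_config(rounds = 2, local_epochs = 1, encryption = FALSE,
                     balance_shards = FALSE, seed = 3)
  fit <- fedl(b, cfg)
  expect_s3_class(fit, "fedl")
  expect_output(print(fit), "Federated two-class classifier")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.fedl")
  expect_equal(nrow(sm$global), 2)
  expect_length(coef(fit), param_count(fit$model))
  p <- predict(fit, b$test)
  expect_true(all(p >= 0 & p <= 1))
  cls <- predict(fit, b$test, type = "class")
  expect_true(all(cls %in% 0:1))
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
  # round logs have one row per selected client plus one global row
  expect_equal(sum(fit$history$round == 1),
               length(fit$client_sizes) + 1)
})

test_that("the encrypted request channel returns the model's prediction", {
  b <- tiny_bundle(n = 100, image_size = 32, seed = 55)
  cfg <- fedl_config(rounds = 1, local_epochs = 1, encryption = FALSE,
                     balance_shards = FALSE, seed = 4)
  fit <- fedl(b, cfg)
  img <- b$test$images[[1]]
  resp <- encrypted_request(fit, img, session_seed = 11)
  direct <- predict(fit, fedlhe:::new_image_set(list(img)))
  expect_equal(resp$prob, direct, tolerance = 1e-12)
  expect_true(resp$class %in% c("benign", "malignant"))
})
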