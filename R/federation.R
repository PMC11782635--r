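# Federated averaging with optional homomorphically encrypted aggregation.
#
# Each communication round broadcasts the global parameter vector, trains
# every selected client locally for G epochs, uploads the last-epoch
# weights, and aggregates them by sample-size-weighted averaging. Under
# encryption the clients quantize the pre-scaled vector n_i * w_i to the
# fixed-point code, pack it into coefficient slots and encrypt; the server
# folds the ciphertexts with homomorphic addition only, decrypts the single
# aggregate, divides by the total sample count and dequantizes. The server
# never sees an individual client's update in the clear.

#' A client's per-round update
#'
#' @param client_id Client identifier.
#' @param n_samples Local sample count (> 0); the averaging weight.
#' @param params Plaintext parameter vector (plaintext mode).
#' @param payload A `packed_ct` (encrypted mode).
#' @param metrics Optional named list of local metrics.
#' @export
client_update <- function(client_id, n_samples, params = NULL,
                          payload = NULL, metrics = NULL) {
  if (n_samples <= 0) stop("n_samples must be positive")
  structure(list(client_id = client_id, n_samples = n_samples,
                 params = params, payload = payload, metrics = metrics),
            class = "client_update")
}

#' Sample-size-weighted federated averaging (plaintext)
#'
#' Computes the per-coordinate weighted mean `sum_i (n_i / N) w_i` with
#' `N = sum_i n_i`, anchored at the first update so that averaging identical
#' vectors reproduces them bit-exactly. The result is a convex combination
#' of the client vectors.
#'
#' @param updates Non-empty list of [client_update()]s carrying `params` of
#'   equal length.
#' @return The aggregated parameter vector.
#' @export
fedavrg <- function(updates) {
  if (!is.list(updates) || length(updates) == 0)
    stop("fedavrg needs at least one client update")
  lens <- vapply(updates, function(u) length(u$params), 0L)
  if (any(lens != lens[1])) {
    bad <- vapply(updates[lens != lens[1]], function(u)
      as.character(u$client_id), "")
    stop("parameter vectors differ in length for client(s): ",
         paste(bad, collapse = ", "))
  }
  ns <- vapply(updates, `[[`, 0, "n_samples")
  N <- sum(ns)
  base <- updates[[1]]$params
  acc <- base
  if (length(updates) > 1)
    for (j in 2:length(updates))
      acc <- acc + (ns[j] / N) * (updates[[j]]$params - base)
  acc
}

#' Quantize, pre-scale and encrypt a client update
#'
#' The client clips its parameter vector to the codec range, quantizes the
#' pre-scaled value `round(n_i * w * scale) + n_i * offset`, and encrypts
#' the packed result. Pre-scaling by the integer sample count keeps the
#' weighted average compatible with addition-only aggregation.
#'
#' @param params Parameter vector.
#' @param n_samples Client sample count.
#' @param key `he_keypair` (public part used).
#' @param codec An [fp_codec()]; its headroom must cover the total sample
#'   count of the federation.
#' @param slot_count Packing slots per ciphertext.
#' @export
encrypt_update <- function(params, n_samples, key, codec, slot_count = 64) {
  q <- federation_plain_modulus(codec)
  wc <- pmin(pmax(params, -codec$clip), codec$clip)
  v <- round(wc * n_samples * codec$scale) + n_samples * codec$offset
  packed_encrypt(v, key, slot_count = slot_count, q = q)
}

#' Plaintext modulus sized for pre-scaled aggregation
#'
#' Smallest prime exceeding `headroom * (2 * offset + 1)`, so the sum of
#' `headroom` pre-scaled quantized samples cannot wrap.
#' @param codec An [fp_codec()].
#' @export
federation_plain_modulus <- function(codec) {
  default_plain_modulus(codec$headroom, 2 * codec$offset)
}

#' Aggregate encrypted client updates
#'
#' Folds the packed ciphertexts with homomorphic addition (no individual
#' decryption), decrypts only the aggregate, divides by the total sample
#' count and dequantizes. Agreement with the plaintext [fedavrg()] is within
#' `n_clients / (2 * scale * N)` per coordinate.
#'
#' @param updates List of [client_update()]s carrying `payload`.
#' @param key The `he_keypair` (private part needed for the single
#'   aggregate decryption).
#' @param codec The [fp_codec()] the clients used.
#' @return The aggregated (decrypted, dequantized) parameter vector.
#' @export
encrypted_aggregate <- function(updates, key, codec) {
  if (!is.list(updates) || length(updates) == 0)
    stop("need at least one encrypted update")
  ns <- vapply(updates, `[[`, 0, "n_samples")
  N <- sum(ns)
  if (N > codec$headroom)
    stop("codec headroom exceeded before aggregation: total sample count ",
         N, " > headroom ", codec$headroom,
         " (the quantized sum could overflow)")
  payloads <- lapply(updates, `[[`, "payload")
  mods <- vapply(payloads, `[[`, "", "n")
  if (length(unique(mods)) != 1)
    stop("encrypted updates are under different keys")
  total <- payloads[[1]]
  if (length(payloads) > 1)
    for (j in 2:length(payloads)) total <- packed_add(total, payloads[[j]])
  sums <- packed_decrypt(total, key, reduce = FALSE)
  (sums / N - codec$offset) / codec$scale
}

#' Random client selection
#'
#' Sampling without replacement of `max(1, floor(fraction * n_available))`
#' clients, deterministic per `(seed, round_index)`.
#' @param n_available Number of clients.
#' @param fraction Participation fraction in `(0, 1]`.
#' @param seed Integer seed.
#' @param round_index Communication round (varies the draw).
#' @export
select_clients <- function(n_available, fraction = 1, seed = 1,
                           round_index = 0) {
  if (fraction <= 0 || fraction > 1)
    stop("client fraction must be in (0, 1]; got a selection of 0 clients")
  m <- max(1L, floor(fraction * n_available))
  if (m == n_available) return(seq_len(n_available))
  sort(with_seed(derive_seed(seed, 300, round_index),
                 sample.int(n_available, m)))
}

# ---- the federated experiment ------------------------------------------

#' Federation configuration
#'
#' Defaults mirror the experiment hyperparameters: 5 clients, batch size
#' 32, Adam at learning rate 0.01, random client selection with full
#' participation, FedAvrg aggregation, encryption on. Desk-scale defaults
#' use 10 rounds of 2 local epochs.
#'
#' @param n_clients Number of clients.
#' @param rounds Communication rounds.
#' @param local_epochs Local epochs G per round.
#' @param batch_size Minibatch size.
#' @param lr Learning rate.
#' @param encryption Encrypt uploads with the additive scheme.
#' @param client_fraction Fraction of clients selected per round.
#' @param seed Master seed; every random stream derives from it.
#' @param scale_bits,clip Fixed-point codec geometry.
#' @param slot_count Packing slots per ciphertext.
#' @param key_bits Bits per prime of the generated key pair.
#' @param balance_shards Oversample each shard's minority class by
#'   augmentation before training.
#' @param best_weights `"last"` keeps the final round's global weights;
#'   `"best_val"` keeps the round with the best global validation accuracy.
#' @export
fedl_config <- function(n_clients = 5, rounds = 10, local_epochs = 2,
                        batch_size = 32, lr = 0.01, encryption = TRUE,
                        client_fraction = 1, seed = 1, scale_bits = 16,
                        clip = 8, slot_count = 64, key_bits = 32,
                        balance_shards = TRUE,
                        best_weights = c("last", "best_val")) {
  stopifnot(n_clients >= 1, rounds >= 0, local_epochs >= 1, batch_size >= 1)
  structure(list(n_clients = n_clients, rounds = rounds,
                 local_epochs = local_epochs, batch_size = batch_size,
                 lr = lr, encryption = encryption,
                 client_fraction = client_fraction, seed = seed,
                 scale_bits = scale_bits, clip = clip,
                 slot_count = slot_count, key_bits = key_bits,
                 balance_shards = balance_shards,
                 best_weights = match.arg(best_weights)),
            class = "fedl_config")
}

# Internal: assemble the mutable federation state.
fedl_state <- function(template, keypair, codec, val, config) {
  structure(list(round_index = 0L, template = template,
                 global_params = get_params(template), keypair = keypair,
                 codec = codec, val = val, config = config,
                 history = list()), class = "fedl_state")
}

#' Run one communication round
#'
#' Broadcast the global parameters, train each selected client for G local
#' epochs, upload (encrypted) last-epoch weights, aggregate, update the
#' global model and log metrics. A failing client aborts the round with its
#' id named; no partial aggregation occurs.
#'
#' @param state A `fedl_state` (built internally by [fedl()]).
#' @param shards List of `client_shard`s, parallel to the client ids.
#' @param config A [fedl_config()].
#' @return `list(state, round_log)`.
#' @export
run_round <- function(state, shards, config) {
  r <- state$round_index + 1L
  sel <- select_clients(length(shards), config$client_fraction,
                        config$seed, r)
  train_seed <- derive_seed(config$seed, 500, r)
  updates <- vector("list", length(sel))
  rows <- list()
  for (si in seq_along(sel)) {
    shard <- shards[[sel[si]]]
    res <- tryCatch({
      model <- set_params(state$template, state$global_params)
      tc <- train_config(epochs = config$local_epochs,
                         batch_size = config$batch_size, lr = config$lr,
                         seed = train_seed)
      train_local(model, shard, tc)
    }, error = function(e)
      stop("round ", r, " aborted: client ", shard$client_id,
           " failed (", conditionMessage(e), ")", call. = FALSE))
    params_i <- get_params(res$model)
    last <- res$history[nrow(res$history), ]
    cval <- evaluate(res$model, state$val)
    last$val_acc <- cval$accuracy
    last$val_loss <- cval$loss
    n_i <- length(shard$data)
    upd <- client_update(shard$client_id, n_i, params = params_i,
                         metrics = as.list(last))
    if (config$encryption)
      upd$payload <- encrypt_update(params_i, n_i, state$keypair,
                                    state$codec, config$slot_count)
    updates[[si]] <- upd
    rows[[length(rows) + 1]] <- data.frame(
      round = r, client_id = as.character(shard$client_id), n = n_i,
      acc = last$acc, loss = last$loss, val_acc = last$val_acc,
      val_loss = last$val_loss)
  }
  state$global_params <- if (config$encryption)
    encrypted_aggregate(updates, state$keypair, state$codec)
  else fedavrg(updates)
  gmodel <- set_params(state$template, state$global_params)
  gev <- evaluate(gmodel, state$val)
  rows[[length(rows) + 1]] <- data.frame(
    round = r, client_id = "global", n = sum(vapply(updates, `[[`, 0,
                                                    "n_samples")),
    acc = NA_real_, loss = NA_real_, val_acc = gev$accuracy,
    val_loss = gev$loss)
  log <- do.call(rbind, rows)
  state$round_index <- r
  state$history[[r]] <- log
  list(state = state, round_log = log)
}

#' Fit a federated model on a dataset bundle
#'
#' The main entry point: prepares non-IID client shards (unless supplied),
#' generates the key pair and codec, and runs the configured number of
#' communication rounds of (optionally encrypted) federated averaging.
#'
#' @param bundle A `dataset_bundle` from [generate_dataset()].
#' @param config A [fedl_config()].
#' @param shards Optional list of `client_shard`s; by default the train
#'   split is partitioned with [partition_noniid()] (5 clients) or
#'   [partition_iid()] otherwise.
#' @param model Optional initial `layered_model` template.
#' @return An object of class `fedl` with `print`, `summary`, `coef`,
#'   `predict` and `plot` methods.
#' @examples
#' \donttest{
#' bundle <- generate_dataset(300, image_size = 32, seed = 1)
#' fit <- fedl(bundle, fedl_config(rounds = 2, key_bits = 16, seed = 1))
#' print(fit)
#' }
#' @export
fedl <- function(bundle, config = fedl_config(), shards = NULL,
                 model = NULL) {
  stopifnot(inherits(bundle, "dataset_bundle"), inherits(config, "fedl_config"))
  if (is.null(shards)) {
    shards <- if (config$n_clients == 5)
      partition_noniid(bundle, seed = derive_seed(config$seed, 21))
    else partition_iid(bundle, config$n_clients,
                       seed = derive_seed(config$seed, 21))
  }
  if (config$balance_shards)
    shards <- lapply(seq_along(shards), function(j)
      augment_minority(shards[[j]], seed = derive_seed(config$seed, 33, j)))
  image_size <- dim(bundle$val$images[[1]]$pixels)[1]
  if (is.null(model))
    model <- build_model(image_size = image_size, channels = 3,
                         seed = derive_seed(config$seed, 11))
  keypair <- he_keygen(bit_length = config$key_bits,
                       seed = derive_seed(config$seed, 7))
  total_n <- sum(vapply(shards, function(s) length(s$data), 0))
  codec <- fp_codec(scale_bits = config$scale_bits, clip = config$clip,
                    headroom = max(total_n, config$n_clients))
  val <- image_set_to_batch(bundle$val)
  state <- fedl_state(model, keypair, codec, val, config)
  best <- list(acc = -Inf, params = state$global_params, round = 0L)
  for (r in seq_len(config$rounds)) {
    out <- run_round(state, shards, config)
    state <- out$state
    g <- out$round_log[out$round_log$client_id == "global", ]
    if (g$val_acc > best$acc)
      best <- list(acc = g$val_acc, params = state$global_params, round = r)
  }
  final_params <- if (config$best_weights == "best_val" &&
                        config$rounds > 0) best$params else state$global_params
  history <- if (length(state$history)) do.call(rbind, state$history) else
    data.frame(round = integer(0), client_id = character(0), n = integer(0),
               acc = numeric(0), loss = numeric(0), val_acc = numeric(0),
               val_loss = numeric(0))
  structure(list(
    model = set_params(model, final_params),
    global_params = final_params,
    history = history,
    config = config,
    keypair = keypair,
    codec = codec,
    client_sizes = stats::setNames(
      vapply(shards, function(s) length(s$data), 0),
      vapply(shards, function(s) as.character(s$client_id), "")),
    best = best,
    rounds_run = state$round_index
  ), class = "fedl")
}

# ---- encrypted request channel -----------------------------------------

#' Serve a prediction request over the encrypted channel
#'
#' Demonstrates the request path: the user wraps a symmetric session key
#' with the public exponent, encrypts the image payload with the 4-round
#' block transform, and receives the prediction back over the same channel.
#' Runs entirely in-process.
#'
#' @param fit A fitted [fedl()] object.
#' @param image A `synth_image` or pixel array matching the model input.
#' @param session_seed Seed for the session key and nonce.
#' @return Decrypted response: a list with the predicted probability and
#'   class.
#' @export
encrypted_request <- function(fit, image, session_seed = 1) {
  stopifnot(inherits(fit, "fedl"))
  px <- if (inherits(image, "synth_image")) image$pixels else image
  session <- with_seed(session_seed, sample.int(2^30, 2))
  wrapped <- wrap_session_key(session[1], fit$keypair)
  ks <- derive_round_keys(session[1], session[2])
  req <- encrypt_payload(writeBin(as.numeric(px), raw(), size = 8,
                                  endian = "little"),
                         ks, nonce_seed = session_seed)
  # server side: unwrap the session key, decrypt, predict, re-encrypt
  s_key <- as.numeric(unwrap_session_key(wrapped, fit$keypair))
  ks_srv <- derive_round_keys(s_key, session[2])
  bytes <- decrypt_payload(req, ks_srv)
  arr <- array(readBin(bytes, "numeric", n = length(bytes) / 8, size = 8,
                       endian = "little"), dim(px))
  prob <- model_predict(fit$model, list(x = array(arr, c(1, dim(arr))),
                                        y = 0))
  resp <- encrypt_payload(writeBin(prob, raw(), size = 8, endian = "little"),
                          ks_srv, nonce_seed = session_seed + 1)
  p <- readBin(decrypt_payload(resp, ks), "numeric", 1, size = 8,
               endian = "little")
  list(prob = p, class = ifelse(p >= 0.5, "malignant", "benign"))
}
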