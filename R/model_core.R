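# Surrogate layered detector-classifier standing in for a pruned YOLO-style
# network: a backbone of residual 3x3 convolution blocks over a fixed
# average-pool stem, a global-average-pool + dense neck, and a single
# sigmoid head. Sections appear in backbone -> neck -> head order; residual
# blocks carry keep-flags so whole hidden layers can be pruned, with the
# skip path keeping the forward function defined. All tensor work is plain
# im2col matrix algebra, which keeps training deterministic given the seed.

# ---- tensor primitives --------------------------------------------------

# 3x3 same-padding convolution via im2col; the patch gather and the
# gradient scatter run in compiled code (src/conv_kernels.cpp).
.im2col <- function(x) {
  d <- dim(x)
  cpp_im2col(x, d[1], d[2], d[3], d[4])
}

.col2im <- function(dcols, dims) {
  cpp_col2im(dcols, dims[1], dims[2], dims[3], dims[4])
}

# Average-pool the input down to a 16x16 grid and centre pixel values
# around 0 (inputs arrive scaled to [0, 1]).
.stem_grid <- 16L

.stem_pool <- function(x, p) {
  if (p == 1) return(x - 0.5)
  g <- .stem_grid
  d <- dim(x); N <- d[1]; C <- d[4]
  hc <- g * p
  x <- x[, seq_len(hc), seq_len(hc), , drop = FALSE]
  a <- array(x, c(N, p, g, p, g, C))
  m <- aperm(a, c(1, 3, 5, 6, 2, 4))
  array(rowMeans(matrix(m, N * g * g * C, p * p)), c(N, g, g, C)) - 0.5
}

.sigmoid <- function(s) 1 / (1 + exp(-s))

# ---- model construction -------------------------------------------------

#' Build the surrogate layered classifier
#'
#' Architecture: fixed average-pool stem reducing the input to a 16x16 grid,
#' a 3x3 convolution into `width` channels, `n_blocks` prunable residual
#' blocks `y = x + relu(conv3x3(x))` (the backbone), a global-average-pool
#' plus dense neck, and a one-unit sigmoid head. Initialization is He-scaled
#' and fully determined by `seed`.
#'
#' @param image_size Input side length in pixels (>= 16).
#' @param channels Input channels (3 for RGB).
#' @param seed Integer seed for the deterministic initialization.
#' @param width Backbone channel width.
#' @param n_blocks Number of residual blocks (the prunable hidden layers).
#' @param neck_units Units of the dense neck layer.
#' @return Object of class `layered_model`.
#' @export
build_model <- function(image_size = 64, channels = 3, seed = 1,
                        width = 8, n_blocks = 8, neck_units = 16) {
  if (image_size < 16) stop("image_size must be at least 16")
  p <- image_size %/% .stem_grid
  layers <- list()
  add <- function(ly) layers[[length(layers) + 1]] <<- ly
  mk <- function(name, section, type, W = NULL, b = NULL, extra = list()) {
    c(list(name = name, section = section, type = type, W = W, b = b,
           keep = TRUE, trainable = TRUE), extra)
  }
  with_seed(seed, {
    add(mk("stem_pool", "backbone", "pool", extra = list(factor = p)))
    W <- matrix(stats::rnorm(9 * channels * width, sd = sqrt(2 / (9 * channels))),
                9 * channels, width)
    add(mk("conv_in", "backbone", "conv", W, numeric(width)))
    for (j in seq_len(n_blocks)) {
      # residual branches start small so the stacked skip sums stay in a
      # well-conditioned range and the head is not born saturated
      W <- matrix(stats::rnorm(9 * width * width,
                               sd = sqrt(2 / (9 * width)) / 4),
                  9 * width, width)
      add(mk(sprintf("resblock%02d", j), "backbone", "resblock", W,
             numeric(width)))
    }
    add(mk("neck_gap", "neck", "gap"))
    W <- matrix(stats::rnorm(width * neck_units, sd = sqrt(1 / width)),
                width, neck_units)
    add(mk("neck_dense", "neck", "dense", W, numeric(neck_units),
           extra = list(act = "relu")))
    W <- matrix(stats::rnorm(neck_units, sd = sqrt(1 / neck_units) / 4),
                neck_units, 1)
    add(mk("head", "head", "dense", W, numeric(1),
           extra = list(act = "sigmoid")))
  })
  structure(list(layers = layers, image_size = image_size,
                 channels = channels, width = width, n_blocks = n_blocks,
                 neck_units = neck_units, seed = seed),
            class = "layered_model")
}

#' Total parameter count of the kept layers
#' @param model A `layered_model`.
#' @param trainable_only Count only trainable layers.
#' @export
param_count <- function(model, trainable_only = FALSE) {
  sum(vapply(model$layers, function(ly) {
    if (!ly$keep || is.null(ly$W)) return(0)
    if (trainable_only && !ly$trainable) return(0)
    length(ly$W) + length(ly$b)
  }, 0))
}

#' @export
print.layered_model <- function(x, ...) {
  cat("Surrogate layered classifier (", x$image_size, "x", x$image_size, "x",
      x$channels, " input)\n", sep = "")
  for (ly in x$layers) {
    cat(sprintf("  %-12s %-8s %-8s %s%s\n", ly$name, ly$section, ly$type,
                if (is.null(ly$W)) "-" else
                  paste0(length(ly$W) + length(ly$b), " params"),
                paste0(if (!ly$keep) " [pruned]" else "",
                       if (!ly$trainable) " [frozen]" else "")))
  }
  cat("  kept parameters:", param_count(x), "\n")
  invisible(x)
}

# ---- forward / backward -------------------------------------------------

model_forward <- function(model, x, want_cache = FALSE) {
  caches <- if (want_cache) vector("list", length(model$layers)) else NULL
  for (li in seq_along(model$layers)) {
    ly <- model$layers[[li]]
    if (!ly$keep) next
    if (ly$type == "pool") {
      x <- .stem_pool(x, ly$factor)
    } else if (ly$type == "conv") {
      cols <- .im2col(x)
      z <- cols %*% ly$W
      z <- z + rep(ly$b, each = nrow(z))
      a <- pmax(z, 0)
      if (want_cache) caches[[li]] <- list(cols = cols, mask = z > 0,
                                           dims = dim(x))
      x <- array(a, c(dim(x)[1:3], ncol(ly$W)))
    } else if (ly$type == "resblock") {
      cols <- .im2col(x)
      z <- cols %*% ly$W
      z <- z + rep(ly$b, each = nrow(z))
      a <- pmax(z, 0)
      if (want_cache) caches[[li]] <- list(cols = cols, mask = z > 0,
                                           dims = dim(x))
      x <- x + array(a, dim(x))
    } else if (ly$type == "gap") {
      d <- dim(x)
      if (want_cache) caches[[li]] <- list(dims = d)
      x <- matrix(rowMeans(matrix(aperm(x, c(1, 4, 2, 3)),
                                  d[1] * d[4], d[2] * d[3])), d[1], d[4])
    } else if (ly$type == "dense") {
      z <- x %*% ly$W
      z <- z + rep(ly$b, each = nrow(z))
      if (want_cache) caches[[li]] <- list(input = x, z = z)
      x <- switch(ly$act, relu = pmax(z, 0), sigmoid = .sigmoid(z), z)
    } else stop("unknown layer type: ", ly$type)
  }
  list(out = x, caches = caches)
}

# Binary cross entropy with the probabilities clamped away from 0/1 for the
# reported loss; the gradient uses the exact (p - y) form.
.bce <- function(p, y) {
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(pc) + (1 - y) * log(1 - pc))
}

model_loss_grads <- function(model, x, y) {
  fw <- model_forward(model, x, want_cache = TRUE)
  p <- as.numeric(fw$out)
  n <- length(y)
  grads <- vector("list", length(model$layers))
  delta <- NULL  # gradient flowing backwards
  dscore <- matrix((p - y) / n, n, 1)
  delta <- dscore
  for (li in rev(seq_along(model$layers))) {
    ly <- model$layers[[li]]
    if (!ly$keep) next
    cache <- fw$caches[[li]]
    if (ly$type == "dense") {
      if (identical(ly$act, "relu")) delta <- delta * (cache$z > 0)
      grads[[li]] <- list(W = crossprod(cache$input, delta),
                          b = colSums(delta))
      delta <- delta %*% t(ly$W)
    } else if (ly$type == "gap") {
      d <- cache$dims
      dx <- array(0, d)
      hw <- d[2] * d[3]
      for (cc in seq_len(d[4])) dx[, , , cc] <- delta[, cc] / hw
      delta <- dx
    } else if (ly$type == "resblock") {
      dz <- matrix(delta, nrow = prod(cache$dims[1:3])) * cache$mask
      grads[[li]] <- list(W = crossprod(cache$cols, dz), b = colSums(dz))
      dcols <- dz %*% t(ly$W)
      delta <- delta + .col2im(dcols, cache$dims)
    } else if (ly$type == "conv") {
      dz <- matrix(delta, nrow = prod(cache$dims[1:3])) * cache$mask
      grads[[li]] <- list(W = crossprod(cache$cols, dz), b = colSums(dz))
      dcols <- dz %*% t(ly$W)
      delta <- .col2im(dcols, cache$dims)
    } else if (ly$type == "pool") {
      break  # no parameters upstream of the stem
    }
  }
  list(loss = .bce(p, y), prob = p, grads = grads)
}

# ---- training -----------------------------------------------------------

#' Local training configuration
#'
#' Mirrors the experiment hyperparameters: Adam, binary cross entropy,
#' batch size 32, learning rate 0.01 for standard training and 0.0032 for
#' post-prune transfer fine-tuning.
#'
#' @param epochs Local epochs.
#' @param batch_size Minibatch size.
#' @param lr Learning rate (0.01 default; use 0.0032 when fine-tuning).
#' @param seed Seed controlling shuffling (and hence the whole run).
#' @param threshold Decision threshold on the sigmoid output.
#' @export
train_config <- function(epochs = 2, batch_size = 32, lr = 0.01, seed = 1,
                         threshold = 0.5) {
  stopifnot(epochs >= 0, batch_size >= 1, lr > 0)
  structure(list(epochs = epochs, batch_size = batch_size, lr = lr,
                 seed = seed, threshold = threshold,
                 beta1 = 0.9, beta2 = 0.999, eps = 1e-8),
            class = "train_config")
}

.adam_init <- function(model) {
  lapply(model$layers, function(ly) {
    if (is.null(ly$W)) return(NULL)
    list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0)
  })
}

.adam_step <- function(model, grads, state, t, config) {
  b1 <- config$beta1; b2 <- config$beta2; eps <- config$eps; lr <- config$lr
  for (li in seq_along(model$layers)) {
    ly <- model$layers[[li]]
    if (is.null(ly$W) || !ly$keep || !ly$trainable || is.null(grads[[li]]))
      next
    st <- state[[li]]
    g <- grads[[li]]
    st$mW <- b1 * st$mW + (1 - b1) * g$W
    st$vW <- b2 * st$vW + (1 - b2) * g$W^2
    st$mb <- b1 * st$mb + (1 - b1) * g$b
    st$vb <- b2 * st$vb + (1 - b2) * g$b^2
    corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
    ly$W <- ly$W - lr * (st$mW / corr1) / (sqrt(st$vW / corr2) + eps)
    ly$b <- ly$b - lr * (st$mb / corr1) / (sqrt(st$vb / corr2) + eps)
    model$layers[[li]] <- ly
    state[[li]] <- st
  }
  list(model = model, state = state)
}

# Coerce the various dataset containers to a plain list(x = array, y).
as_batch <- function(data) {
  if (is.list(data) && !is.null(data$x) && !is.null(data$y)) return(data)
  if (inherits(data, "image_set")) return(image_set_to_batch(data))
  if (inherits(data, "client_shard")) return(image_set_to_batch(data$data))
  stop("cannot interpret this object as a dataset")
}

#' Train a model on a local shard
#'
#' Minibatch Adam on binary cross entropy for the configured number of
#' epochs. Frozen (non-trainable) layers are left bit-unchanged. The
#' reported per-epoch training metrics are averaged over the minibatches as
#' seen during the epoch; validation metrics come from a full pass over
#' `val` when provided.
#'
#' @param model A `layered_model`.
#' @param shard Training data: a `client_shard`, an `image_set`, or a
#'   `list(x = N x H x W x C array, y = 0/1 labels)`.
#' @param config A [train_config()].
#' @param val Optional validation data in any of the same forms.
#' @return `list(model, history)` with one history row per epoch
#'   (`epoch, acc, loss, val_acc, val_loss`).
#' @export
train_local <- function(model, shard, config = train_config(), val = NULL) {
  data <- as_batch(shard)
  n <- length(data$y)
  if (n == 0) stop("empty training shard")
  if (length(unique(data$y)) < 2)
    warning("training shard contains a single class; proceeding (binary ",
            "cross entropy remains defined)")
  vdata <- if (!is.null(val)) as_batch(val)
  history <- data.frame(epoch = integer(0), acc = numeric(0),
                        loss = numeric(0), val_acc = numeric(0),
                        val_loss = numeric(0))
  if (config$epochs == 0) return(list(model = model, history = history))
  state <- .adam_init(model)
  t <- 0
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      idx <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        bi <- idx[start:min(start + config$batch_size - 1, n)]
        xb <- data$x[bi, , , , drop = FALSE]
        yb <- data$y[bi]
        lg <- model_loss_grads(model, xb, yb)
        t <- t + 1
        upd <- .adam_step(model, lg$grads, state, t, config)
        model <- upd$model; state <- upd$state
        ep_loss <- ep_loss + lg$loss * length(bi)
        ep_correct <- ep_correct +
          sum((lg$prob >= config$threshold) == (yb == 1))
      }
      row <- data.frame(epoch = ep, acc = ep_correct / n, loss = ep_loss / n,
                        val_acc = NA_real_, val_loss = NA_real_)
      if (!is.null(vdata)) {
        ev <- evaluate(model, vdata, threshold = config$threshold)
        row$val_acc <- ev$accuracy; row$val_loss <- ev$loss
      }
      history <- rbind(history, row)
    }
  })
  list(model = model, history = history)
}

#' Freeze or unfreeze the backbone section
#'
#' Frozen layers are excluded from gradient updates (their tensors stay
#' bit-identical through training); the neck and head are unaffected.
#' Idempotent and reversible.
#' @param model A `layered_model`.
#' @export
freeze_backbone <- function(model) {
  for (li in seq_along(model$layers))
    if (model$layers[[li]]$section == "backbone")
      model$layers[[li]]$trainable <- FALSE
  model
}

#' @rdname freeze_backbone
#' @export
unfreeze_backbone <- function(model) {
  for (li in seq_along(model$layers))
    if (model$layers[[li]]$section == "backbone")
      model$layers[[li]]$trainable <- TRUE
  model
}

# ---- evaluation ---------------------------------------------------------

#' Predict class probabilities
#' @param model A `layered_model`.
#' @param data Dataset in any form accepted by [train_local()].
#' @param chunk Evaluation batch size.
#' @export
model_predict <- function(model, data, chunk = 256) {
  d <- as_batch(data)
  n <- dim(d$x)[1]
  probs <- numeric(n)
  for (start in seq(1, n, by = chunk)) {
    bi <- start:min(start + chunk - 1, n)
    probs[bi] <- as.numeric(model_forward(model,
                                          d$x[bi, , , , drop = FALSE])$out)
  }
  probs
}

#' Evaluate a model on a labelled dataset
#'
#' @param model A `layered_model`.
#' @param data Labelled dataset.
#' @param threshold Decision threshold on the sigmoid output.
#' @return Object of class `eval_report`: accuracy, loss (binary cross
#'   entropy), precision, recall, f1 and the contingency counts.
#' @export
evaluate <- function(model, data, threshold = 0.5) {
  d <- as_batch(data)
  if (length(d$y) == 0) stop("cannot evaluate on an empty dataset")
  probs <- model_predict(model, d)
  rep <- classification_report(probs, d$y, threshold = threshold)
  rep$loss <- .bce(probs, d$y)
  rep
}

#' Classification metrics from the 2x2 contingency
#'
#' Precision is the fraction of positive (malignant) predictions that are
#' correct, recall the fraction of positive cases found, and F1 their
#' harmonic mean `2PR/(P+R)`. Zero-denominator cases return 0 and are
#' flagged in `$degenerate`.
#'
#' @param preds Probabilities (thresholded at `threshold`) or 0/1 labels.
#' @param labels True 0/1 labels.
#' @param threshold Decision threshold.
#' @return Object of class `eval_report`.
#' @export
classification_report <- function(preds, labels, threshold = 0.5) {
  if (length(preds) != length(labels)) stop("preds and labels differ in length")
  yhat <- as.numeric(preds >= threshold)
  y <- as.numeric(labels)
  tp <- sum(yhat == 1 & y == 1); fp <- sum(yhat == 1 & y == 0)
  fn <- sum(yhat == 0 & y == 1); tn <- sum(yhat == 0 & y == 0)
  degenerate <- character(0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    degenerate <- c(degenerate, "precision"); 0 }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    degenerate <- c(degenerate, "recall"); 0 }
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else {
      degenerate <- c(degenerate, "f1"); 0 }
  structure(list(accuracy = (tp + tn) / length(y), precision = precision,
                 recall = recall, f1 = f1, tp = tp, fp = fp, fn = fn,
                 tn = tn, degenerate = degenerate, loss = NA_real_),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f  loss %s  precision %.4f  recall %.4f  f1 %.4f\n",
              x$accuracy, ifelse(is.na(x$loss), "NA", sprintf("%.4f", x$loss)),
              x$precision, x$recall, x$f1))
  if (length(x$degenerate))
    cat("  zero-denominator (flagged 0):",
        paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

# ---- parameter vector interface ----------------------------------------

#' Extract / insert the flat parameter vector
#'
#' Concatenates `W` then `b` of every kept layer (optionally only trainable
#' layers), in architectural order. [set_params()] is the exact inverse.
#' @param model A `layered_model`.
#' @param trainable_only Restrict to trainable layers.
#' @export
get_params <- function(model, trainable_only = FALSE) {
  unlist(lapply(model$layers, function(ly) {
    if (!ly$keep || is.null(ly$W)) return(numeric(0))
    if (trainable_only && !ly$trainable) return(numeric(0))
    c(as.numeric(ly$W), ly$b)
  }))
}

#' @rdname get_params
#' @param params Numeric vector from [get_params()] with matching layout.
#' @export
set_params <- function(model, params, trainable_only = FALSE) {
  pos <- 0
  for (li in seq_along(model$layers)) {
    ly <- model$layers[[li]]
    if (!ly$keep || is.null(ly$W)) next
    if (trainable_only && !ly$trainable) next
    nw <- length(ly$W); nb <- length(ly$b)
    if (pos + nw + nb > length(params))
      stop("parameter vector too short for this model")
    ly$W <- matrix(params[pos + seq_len(nw)], nrow(ly$W), ncol(ly$W))
    ly$b <- params[pos + nw + seq_len(nb)]
    pos <- pos + nw + nb
    model$layers[[li]] <- ly
  }
  if (pos != length(params))
    stop("parameter vector length ", length(params),
         " does not match the model's ", pos, " parameters")
  model
}

# ---- checkpoints --------------------------------------------------------

#' Save / load a model checkpoint as structured text
#'
#' Layer names, sections, shapes, keep/trainable flags and tensors written
#' with 17 significant digits, which round-trips doubles exactly.
#' @param model A `layered_model`.
#' @param path File path.
#' @export
save_checkpoint <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("fedlhe-model image_size=%d channels=%d width=%d n_blocks=%d neck_units=%d seed=%d",
                     model$image_size, model$channels, model$width,
                     model$n_blocks, model$neck_units, model$seed), con)
  for (ly in model$layers) {
    extra <- if (ly$type == "pool") sprintf(" factor=%d", ly$factor)
             else if (ly$type == "dense") sprintf(" act=%s", ly$act)
             else ""
    writeLines(sprintf("layer %s %s %s keep=%d trainable=%d%s", ly$name,
                       ly$section, ly$type, as.integer(ly$keep),
                       as.integer(ly$trainable), extra), con)
    if (!is.null(ly$W)) {
      writeLines(sprintf("W %d %d", nrow(ly$W), ncol(ly$W)), con)
      writeLines(paste(sprintf("%.17g", ly$W), collapse = " "), con)
      writeLines(sprintf("b %d", length(ly$b)), con)
      writeLines(paste(sprintf("%.17g", ly$b), collapse = " "), con)
    }
  }
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "fedlhe-model"))
    stop("not a model checkpoint: ", path)
  meta <- as.list(stats::setNames(
    as.integer(sub(".*=", "", strsplit(lines[1], " ")[[1]][-1])),
    sub("=.*", "", strsplit(lines[1], " ")[[1]][-1])))
  model <- build_model(meta$image_size, meta$channels, meta$seed,
                       meta$width, meta$n_blocks, meta$neck_units)
  li <- 0; j <- 2
  while (j <= length(lines)) {
    parts <- strsplit(lines[j], " ", fixed = TRUE)[[1]]
    if (parts[1] != "layer") stop("malformed checkpoint at line ", j)
    li <- li + 1
    ly <- model$layers[[li]]
    if (ly$name != parts[2])
      stop("checkpoint layer order mismatch: expected ", ly$name,
           ", found ", parts[2])
    kv <- grep("=", parts, value = TRUE)
    flags <- stats::setNames(sub(".*=", "", kv), sub("=.*", "", kv))
    ly$keep <- flags[["keep"]] == "1"
    ly$trainable <- flags[["trainable"]] == "1"
    j <- j + 1
    if (!is.null(ly$W)) {
      wd <- as.integer(strsplit(lines[j], " ")[[1]][2:3])
      ly$W <- matrix(as.numeric(strsplit(lines[j + 1], " ")[[1]]),
                     wd[1], wd[2])
      bd <- as.integer(strsplit(lines[j + 2], " ")[[1]][2])
      ly$b <- as.numeric(strsplit(lines[j + 3], " ")[[1]])[seq_len(bd)]
      j <- j + 4
    }
    model$layers[[li]] <- ly
  }
  model
}
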