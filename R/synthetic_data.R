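# Synthetic two-class histopathology-like image generator and partitioner.
#
# Benign images carry few, small, round, regular cell-cluster blobs on a
# pink-hued textured background; malignant images carry many, larger,
# eccentric, ragged-edged blobs with darker colour and higher chroma
# variance. Blob scale grows with the magnification tag, and every blob
# contributes a normalized bounding box, so the data mimic the structure
# (not the histology) of a two-class, four-magnification microscopy corpus
# at a benign:malignant ratio of 2480:5429 by default.

.mag_levels <- c(40L, 100L, 200L, 400L)

# Per-class magnification mix of the emulated corpus (counts by level).
magnification_table <- function() {
  matrix(c(652, 644, 588, 588,       # benign 40/100/200/400
           1370, 1437, 1390, 1232),  # malignant
         nrow = 2, byrow = TRUE,
         dimnames = list(c("benign", "malignant"), .mag_levels))
}

# ---- containers ---------------------------------------------------------

new_synth_image <- function(pixels, label, magnification, boxes, id,
                            synthetic = FALSE) {
  structure(list(pixels = pixels, label = label,
                 magnification = magnification, boxes = boxes, id = id,
                 synthetic = synthetic), class = "synth_image")
}

new_image_set <- function(images) {
  structure(list(images = images), class = "image_set")
}

#' @export
length.image_set <- function(x) length(x$images)

set_labels <- function(set) vapply(set$images, `[[`, 0, "label")
set_mags <- function(set) vapply(set$images, `[[`, 0L, "magnification")
set_ids <- function(set) vapply(set$images, `[[`, "", "id")

subset_image_set <- function(set, idx) new_image_set(set$images[idx])

#' Convert an image set to a dense training batch
#' @param set An `image_set`.
#' @return `list(x = N x H x W x 3 array, y = labels)`.
#' @export
image_set_to_batch <- function(set) {
  n <- length(set$images)
  if (n == 0) stop("empty image set")
  d <- dim(set$images[[1]]$pixels)
  x <- array(0, c(n, d))
  for (j in seq_len(n)) x[j, , , ] <- set$images[[j]]$pixels
  list(x = x, y = set_labels(set))
}

# ---- image synthesis ----------------------------------------------------

.blob_params <- function(label, magf, size) {
  sc <- magf * size / 64
  if (label == 0) {
    list(k = sample(1:3, 1),
         r_lo = 2.5 * sc, r_hi = 4.5 * sc,
         ecc_lo = 1.0, ecc_hi = 1.15,
         amp_lo = 0.0, amp_hi = 0.05,
         col = c(0.62, 0.42, 0.68), col_sd = 0.02,
         alpha_lo = 0.55, alpha_hi = 0.70)
  } else {
    list(k = sample(4:9, 1),
         r_lo = 4.0 * sc, r_hi = 7.5 * sc,
         ecc_lo = 1.3, ecc_hi = 2.2,
         amp_lo = 0.15, amp_hi = 0.35,
         col = c(0.38, 0.12, 0.48), col_sd = 0.07,
         alpha_lo = 0.75, alpha_hi = 0.92)
  }
}

.gen_image <- function(label, mag, size, id) {
  magf <- c(`40` = 0.7, `100` = 1.0, `200` = 1.4, `400` = 1.9)[[as.character(mag)]]
  base <- c(0.93, 0.81, 0.88) + stats::rnorm(3, 0, 0.015)
  tex <- bilinear_resize(matrix(stats::runif(64, -1, 1), 8, 8), size, size) * 0.04
  px <- array(0, c(size, size, 3))
  for (ch in 1:3)
    px[, , ch] <- base[ch] + tex +
      matrix(stats::rnorm(size * size, 0, 0.015), size, size)
  pp <- .blob_params(label, magf, size)
  X <- matrix(seq_len(size), size, size, byrow = TRUE)
  Y <- matrix(seq_len(size), size, size)
  boxes <- matrix(numeric(0), 0, 5)
  for (bl in seq_len(pp$k)) {
    cx <- stats::runif(1, 0.18, 0.82) * size
    cy <- stats::runif(1, 0.18, 0.82) * size
    r <- stats::runif(1, pp$r_lo, pp$r_hi)
    ecc <- stats::runif(1, pp$ecc_lo, pp$ecc_hi)
    ang <- stats::runif(1, 0, pi)
    amp <- stats::runif(1, pp$amp_lo, pp$amp_hi)
    nl1 <- sample(3:7, 1); ph1 <- stats::runif(1, 0, 2 * pi)
    nl2 <- sample(8:13, 1); ph2 <- stats::runif(1, 0, 2 * pi)
    colr <- pmin(pmax(pp$col + stats::rnorm(3, 0, pp$col_sd), 0), 1)
    alpha <- stats::runif(1, pp$alpha_lo, pp$alpha_hi)
    a_ax <- r * sqrt(ecc); b_ax <- r / sqrt(ecc)
    dx <- X - cx; dy <- Y - cy
    u <- (dx * cos(ang) + dy * sin(ang)) / a_ax
    v <- (-dx * sin(ang) + dy * cos(ang)) / b_ax
    d <- sqrt(u^2 + v^2)
    theta <- atan2(dy, dx)
    mod <- 1 + amp * (0.6 * sin(nl1 * theta + ph1) +
                        0.4 * sin(nl2 * theta + ph2))
    deff <- d / pmax(mod, 0.4)
    apx <- alpha * pmin(pmax((1.15 - deff) / 0.3, 0), 1)
    for (ch in 1:3) px[, , ch] <- px[, , ch] * (1 - apx) + colr[ch] * apx
    ex <- sqrt((a_ax * cos(ang))^2 + (b_ax * sin(ang))^2) * (1 + amp) * 1.15
    ey <- sqrt((a_ax * sin(ang))^2 + (b_ax * cos(ang))^2) * (1 + amp) * 1.15
    x1 <- max((cx - ex) / size, 0); x2 <- min((cx + ex) / size, 1)
    y1 <- max((cy - ey) / size, 0); y2 <- min((cy + ey) / size, 1)
    boxes <- rbind(boxes, c(label, (x1 + x2) / 2, (y1 + y2) / 2,
                            x2 - x1, y2 - y1))
  }
  colnames(boxes) <- c("class", "cx", "cy", "w", "h")
  px <- round(pmin(pmax(px, 0), 1) * 255) / 255  # exact PNG round-trip
  new_synth_image(px, label, as.integer(mag), boxes, id)
}

#' Class counts under the package's rounding rule
#'
#' The minority class receives the floor of its expected count; the
#' majority class receives the remainder.
#' @param n_images Total images.
#' @param benign_fraction Benign fraction in `[0, 1]`.
#' @export
class_counts <- function(n_images, benign_fraction) {
  if (benign_fraction < 0 || benign_fraction > 1)
    stop("benign_fraction must be in [0, 1]")
  if (benign_fraction <= 0.5) {
    nb <- floor(benign_fraction * n_images)
  } else {
    nb <- n_images - floor((1 - benign_fraction) * n_images)
  }
  c(benign = as.integer(nb), malignant = as.integer(n_images - nb))
}

#' Generate a synthetic two-class image dataset
#'
#' Draws labels at the requested benign fraction, assigns magnification tags
#' at the per-class mix of the emulated corpus, renders each image, and
#' returns stratified 80/10/10 train/validation/test splits. Fully
#' deterministic for a given seed.
#'
#' @param n_images Total number of images (>= 10).
#' @param benign_fraction Benign class fraction; defaults to 2480/7909.
#' @param image_size Side length in pixels.
#' @param seed Integer seed.
#' @return A `dataset_bundle` with `train`, `val`, `test` image sets.
#' @export
generate_dataset <- function(n_images, benign_fraction = 2480 / 7909,
                             image_size = 64, seed = 1) {
  if (n_images < 10) stop("n_images must be at least 10")
  cc <- class_counts(n_images, benign_fraction)
  with_seed(seed, {
    labels <- sample(rep(c(0L, 1L), cc))
    mt <- magnification_table()
    mags <- integer(n_images)
    for (cl in 0:1) {
      idx <- which(labels == cl)
      mags[idx] <- sample(.mag_levels, length(idx), replace = TRUE,
                          prob = mt[cl + 1, ] / sum(mt[cl + 1, ]))
    }
    images <- vector("list", n_images)
    for (j in seq_len(n_images))
      images[[j]] <- .gen_image(labels[j], mags[j], image_size,
                                sprintf("img%05d", j))
  })
  full <- new_image_set(images)
  bundle <- split_80_10_10(full, seed = derive_seed(seed, 101))
  bundle$class_counts <- cc
  bundle$seed <- seed
  bundle
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat("Synthetic dataset bundle\n")
  for (sp in c("train", "val", "test")) {
    s <- x[[sp]]
    cat(sprintf("  %-5s: %4d images (%d benign / %d malignant)\n", sp,
                length(s), sum(set_labels(s) == 0), sum(set_labels(s) == 1)))
  }
  invisible(x)
}

# ---- splits and partitions ---------------------------------------------

#' Stratified 80/10/10 train/validation/test split
#'
#' Per class, `floor(0.1 * n_class)` images go to test and the same number
#' to validation; the remainder trains. Deterministic per seed; the three
#' splits are disjoint and cover the input exactly.
#'
#' @param set An `image_set` (or `dataset_bundle` whose splits are pooled
#'   first).
#' @param seed Integer seed.
#' @export
split_80_10_10 <- function(set, seed = 1) {
  if (inherits(set, "dataset_bundle"))
    set <- new_image_set(c(set$train$images, set$val$images, set$test$images))
  n <- length(set)
  if (n < 10) stop("need at least 10 images to split")
  labels <- set_labels(set)
  test_idx <- integer(0); val_idx <- integer(0)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      nt <- floor(0.1 * length(idx))
      pick <- sample(idx, 2 * nt)
      test_idx <- c(test_idx, pick[seq_len(nt)])
      val_idx <- c(val_idx, pick[nt + seq_len(nt)])
    }
  })
  train_idx <- setdiff(seq_len(n), c(test_idx, val_idx))
  structure(list(train = subset_image_set(set, sort(train_idx)),
                 val = subset_image_set(set, sort(val_idx)),
                 test = subset_image_set(set, sort(test_idx)),
                 seed = seed), class = "dataset_bundle")
}

#' Default five-client non-IID shard specification
#'
#' Encodes the heterogeneous hospital scenario numerically: client 1
#' majority-benign (0.7), client 2 majority-malignant (benign 0.2), client 3
#' balanced but low magnifications only (40x/100x), client 4 balanced but
#' high magnifications only (200x/400x), client 5 a half-size, highly
#' unbalanced shard (benign 0.85).
#' @export
default_shard_specs <- function() {
  list(
    list(client_id = 3L, benign_fraction = 0.5, mags = c(40L, 100L), rel_size = 1),
    list(client_id = 4L, benign_fraction = 0.5, mags = c(200L, 400L), rel_size = 1),
    list(client_id = 1L, benign_fraction = 0.7, mags = NULL, rel_size = 1),
    list(client_id = 2L, benign_fraction = 0.2, mags = NULL, rel_size = 1),
    list(client_id = 5L, benign_fraction = 0.85, mags = NULL, rel_size = 0.5)
  )
}

.spec_counts <- function(spec, s) {
  size <- max(1L, round(spec$rel_size * s))
  nb <- round(spec$benign_fraction * size)
  c(size = size, nb = nb, nm = size - nb)
}

.noniid_feasible <- function(specs, s, avail) {
  # avail: matrix [class (1=benign,2=malignant)] x [mag level]
  pool <- avail
  for (spec in specs) {
    ct <- .spec_counts(spec, s)
    cols <- if (is.null(spec$mags)) seq_len(ncol(pool)) else
      match(spec$mags, .mag_levels)
    if (sum(pool[1, cols]) < ct["nb"] || sum(pool[2, cols]) < ct["nm"])
      return(FALSE)
    # remove greedily from the restricted columns (proportionally)
    for (cl in 1:2) {
      need <- if (cl == 1) ct[["nb"]] else ct[["nm"]]
      for (co in cols) {
        take <- min(need, pool[cl, co])
        pool[cl, co] <- pool[cl, co] - take
        need <- need - take
      }
    }
  }
  TRUE
}

#' Partition the training split into non-IID client shards
#'
#' Stratified exact draws: each shard receives exactly
#' `round(benign_fraction * size)` benign images, drawn without replacement
#' from the magnification strata its spec allows. Shards are pairwise
#' disjoint; images not claimed by any shard are returned in the
#' `unassigned` attribute, so shards plus the unassigned pool account for
#' the train split exactly. When `size` is not given in the specs a common
#' base size is chosen as the largest feasible one.
#'
#' @param bundle A `dataset_bundle` (only the train split is sharded).
#' @param shard_specs List of specs (see [default_shard_specs()]); each may
#'   carry `size` to fix its shard size directly.
#' @param seed Integer seed.
#' @return List of `client_shard` objects (ordered by client id) with
#'   attribute `unassigned` (indices into the train split).
#' @export
partition_noniid <- function(bundle, shard_specs = default_shard_specs(),
                             seed = 1) {
  train <- bundle$train
  labels <- set_labels(train)
  mags <- set_mags(train)
  avail <- matrix(0L, 2, length(.mag_levels),
                  dimnames = list(c("benign", "malignant"), .mag_levels))
  for (cl in 0:1) for (mi in seq_along(.mag_levels))
    avail[cl + 1, mi] <- sum(labels == cl & mags == .mag_levels[mi])
  has_sizes <- all(vapply(shard_specs, function(s) !is.null(s$size), TRUE))
  if (!has_sizes) {
    lo <- 1L; hi <- length(train)
    if (!.noniid_feasible(shard_specs, lo, avail))
      stop("train split too small for the shard specification")
    while (lo < hi) {  # binary search for the largest feasible base size
      mid <- (lo + hi + 1L) %/% 2L
      if (.noniid_feasible(shard_specs, mid, avail)) lo <- mid else hi <- mid - 1L
    }
    s_base <- lo
  }
  remaining <- rep(TRUE, length(train))
  shards <- list()
  with_seed(seed, {
    for (spec in shard_specs) {
      if (!is.null(spec$size)) {
        size <- spec$size
        nb <- round(spec$benign_fraction * size); nm <- size - nb
      } else {
        ct <- .spec_counts(spec, s_base)
        nb <- ct[["nb"]]; nm <- ct[["nm"]]
      }
      ok_mag <- if (is.null(spec$mags)) rep(TRUE, length(train)) else
        mags %in% spec$mags
      idx <- integer(0)
      for (cl in 0:1) {
        need <- if (cl == 0) nb else nm
        pool <- which(remaining & ok_mag & labels == cl)
        if (length(pool) < need)
          stop(sprintf(
            "infeasible shard spec for client %d: needs %d %s image(s) %s but only %d remain",
            spec$client_id, need, c("benign", "malignant")[cl + 1],
            if (is.null(spec$mags)) "" else
              paste0("at magnification ", paste(spec$mags, collapse = "/")),
            length(pool)))
        take <- if (length(pool) == 1) pool else sample(pool, need)
        take <- take[seq_len(need)]
        idx <- c(idx, take)
        remaining[take] <- FALSE
      }
      idx <- sort(idx)
      shards[[length(shards) + 1]] <- structure(
        list(client_id = spec$client_id, data = subset_image_set(train, idx),
             indices = idx, n = length(idx), spec = spec),
        class = "client_shard")
    }
  })
  ord <- order(vapply(shards, `[[`, 0L, "client_id"))
  shards <- shards[ord]
  attr(shards, "unassigned") <- which(remaining)
  shards
}

#' Partition the training split into IID client shards
#'
#' Random shuffle, then near-equal contiguous slices (the first shards take
#' the remainder); disjoint and covering.
#' @param bundle A `dataset_bundle`.
#' @param n_clients Number of clients.
#' @param seed Integer seed.
#' @export
partition_iid <- function(bundle, n_clients = 5, seed = 1) {
  train <- bundle$train
  n <- length(train)
  if (n_clients < 1 || n_clients > n) stop("invalid number of clients")
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% n_clients, n_clients)
  extra <- n %% n_clients
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  shards <- list()
  pos <- 0
  for (j in seq_len(n_clients)) {
    idx <- sort(perm[pos + seq_len(sizes[j])])
    pos <- pos + sizes[j]
    shards[[j]] <- structure(
      list(client_id = j, data = subset_image_set(train, idx),
           indices = idx, n = length(idx), spec = NULL),
      class = "client_shard")
  }
  attr(shards, "unassigned") <- integer(0)
  shards
}

#' Oversample the minority class of a shard by augmentation
#'
#' Augmented copies (marked `synthetic = TRUE`) of randomly drawn
#' minority-class images are appended until the minority fraction reaches
#' `target_balance`.
#' @param shard A `client_shard`.
#' @param seed Integer seed.
#' @param target_balance Desired minority fraction (0.5 = balanced).
#' @export
augment_minority <- function(shard, seed = 1, target_balance = 0.5) {
  stopifnot(inherits(shard, "client_shard"))
  labels <- set_labels(shard$data)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n0 == n1 || n0 == 0 || n1 == 0) return(shard)
  minority <- if (n0 < n1) 0 else 1
  n_min <- min(n0, n1); n_maj <- max(n0, n1)
  # minority fraction after adding k copies: (n_min + k) / (n + k)
  k <- max(0, ceiling((target_balance * (n_min + n_maj) - n_min) /
                        (1 - target_balance)))
  if (k == 0) return(shard)
  pool <- which(labels == minority)
  images <- shard$data$images
  with_seed(seed, {
    picks <- sample(pool, k, replace = TRUE)
    for (j in seq_len(k)) {
      img <- augment(images[[picks[j]]], seed = NULL)
      img$synthetic <- TRUE
      img$id <- sprintf("%s_aug%03d", img$id, j)
      images[[length(images) + 1]] <- img
    }
  })
  shard$data <- new_image_set(images)
  shard$n <- length(images)
  shard
}

# ---- preprocessing and augmentation ------------------------------------

#' Resize an image to the model's input dimension
#'
#' Bilinear resampling at pixel centres; pixel values stay in `[0, 1]`.
#' Normalized bounding boxes are unaffected by resizing.
#' @param image A `synth_image` or an H x W x C array.
#' @param target_size Output side length.
#' @export
preprocess <- function(image, target_size = 64) {
  px <- if (inherits(image, "synth_image")) image$pixels else image
  out <- pmin(pmax(bilinear_resize(px, target_size), 0), 1)
  if (inherits(image, "synth_image")) {
    image$pixels <- out
    image
  } else out
}

.rot90_pixels <- function(px) {
  h <- dim(px)[1]
  aperm(px[, h:1, , drop = FALSE], c(2, 1, 3))
}

.rot90_boxes <- function(b) {
  if (nrow(b) == 0) return(b)
  cbind(class = b[, 1], cx = b[, 3], cy = 1 - b[, 2], w = b[, 5], h = b[, 4])
}

.apply_transform <- function(img, op, scale_f = 1) {
  px <- img$pixels; b <- img$boxes
  if (op %in% c("rot90", "rot180", "rot270")) {
    k <- match(op, c("rot90", "rot180", "rot270"))
    for (j in seq_len(k)) { px <- .rot90_pixels(px); b <- .rot90_boxes(b) }
  } else if (op == "hflip") {
    px <- px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
    if (nrow(b)) b[, 2] <- 1 - b[, 2]
  } else if (op == "vflip") {
    px <- px[rev(seq_len(dim(px)[1])), , , drop = FALSE]
    if (nrow(b)) b[, 3] <- 1 - b[, 3]
  } else if (op == "scale") {
    h <- dim(px)[1]; w <- dim(px)[2]
    cyx <- (h + 1) / 2; cxx <- (w + 1) / 2
    ys <- cyx + (seq_len(h) - cyx) / scale_f
    xs <- cxx + (seq_len(w) - cxx) / scale_f
    px <- pmin(pmax(bilinear_sample(px, ys, xs), 0), 1)
    if (nrow(b)) {
      b[, 2] <- 0.5 + (b[, 2] - 0.5) * scale_f
      b[, 3] <- 0.5 + (b[, 3] - 0.5) * scale_f
      b[, 4] <- b[, 4] * scale_f
      b[, 5] <- b[, 5] * scale_f
      x1 <- pmin(pmax(b[, 2] - b[, 4] / 2, 0), 1)
      x2 <- pmin(pmax(b[, 2] + b[, 4] / 2, 0), 1)
      y1 <- pmin(pmax(b[, 3] - b[, 5] / 2, 0), 1)
      y2 <- pmin(pmax(b[, 3] + b[, 5] / 2, 0), 1)
      b <- cbind(class = b[, 1], cx = (x1 + x2) / 2, cy = (y1 + y2) / 2,
                 w = x2 - x1, h = y2 - y1)
      b <- b[b[, 4] > 0 & b[, 5] > 0, , drop = FALSE]
    }
  } else stop("unknown transform: ", op)
  img$pixels <- px
  img$boxes <- b
  img
}

#' Randomly augment an image
#'
#' A seeded choice among 90-degree rotations, horizontal/vertical flips and
#' a central scale of +/-10%, with bounding boxes transformed consistently.
#' @param image A `synth_image`.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @export
augment <- function(image, seed = NULL) {
  stopifnot(inherits(image, "synth_image"))
  with_seed(seed, {
    op <- sample(c("rot90", "rot180", "rot270", "hflip", "vflip", "scale"), 1)
    f <- stats::runif(1, 0.9, 1.1)
    .apply_transform(image, op, scale_f = f)
  })
}

# ---- YOLO label files ---------------------------------------------------

#' Write / read YOLO-format label files
#'
#' One line per box, `class cx cy w h`, centre/size normalized to `[0, 1]`
#' with six decimals; reading the file back recovers the boxes at that
#' precision. Malformed lines and out-of-range coordinates raise errors
#' naming the offending line.
#' @param image A `synth_image`, or a boxes matrix (columns class, cx, cy,
#'   w, h).
#' @param path Output path.
#' @export
write_yolo_labels <- function(image, path) {
  b <- if (inherits(image, "synth_image")) image$boxes else image
  if (is.null(dim(b))) b <- matrix(b, ncol = 5, byrow = TRUE)
  lines <- if (nrow(b) == 0) character(0) else
    sprintf("%d %.6f %.6f %.6f %.6f", as.integer(b[, 1]), b[, 2], b[, 3],
            b[, 4], b[, 5])
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_yolo_labels
#' @export
read_yolo_labels <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(matrix(numeric(0), 0, 5,
                  dimnames = list(NULL, c("class", "cx", "cy", "w", "h"))))
  out <- matrix(0, length(lines), 5,
                dimnames = list(NULL, c("class", "cx", "cy", "w", "h")))
  for (j in seq_along(lines)) {
    parts <- suppressWarnings(as.numeric(strsplit(trimws(lines[j]), "\\s+")[[1]]))
    if (length(parts) != 5 || anyNA(parts))
      stop("malformed YOLO label at line ", j, " of ", path)
    if (any(parts[2:5] < 0) || any(parts[2:5] > 1))
      stop("out-of-range box coordinate at line ", j, " of ", path,
           " (must be normalized to [0, 1])")
    out[j, ] <- parts
  }
  out
}

# ---- on-disk layout -----------------------------------------------------

#' Write a dataset bundle to disk
#'
#' Layout: `images/<split>/<class>/<id>.png`, `labels/<split>/<id>.txt`
#' (YOLO format) and a `manifest.csv` with columns id, split, label,
#' magnification, synthetic. PNG writes round-trip bit-exactly because
#' generated pixels sit on the 8-bit grid.
#' @param bundle A `dataset_bundle`.
#' @param dir Output directory.
#' @export
write_dataset <- function(bundle, dir) {
  rows <- list()
  for (sp in c("train", "val", "test")) {
    set <- bundle[[sp]]
    for (img in set$images) {
      cls_dir <- file.path(dir, "images", sp, c("benign", "malignant")[img$label + 1])
      dir.create(cls_dir, recursive = TRUE, showWarnings = FALSE)
      lab_dir <- file.path(dir, "labels", sp)
      dir.create(lab_dir, recursive = TRUE, showWarnings = FALSE)
      png::writePNG(img$pixels, file.path(cls_dir, paste0(img$id, ".png")))
      write_yolo_labels(img, file.path(lab_dir, paste0(img$id, ".txt")))
      rows[[length(rows) + 1]] <- data.frame(
        id = img$id, split = sp, label = img$label,
        magnification = img$magnification,
        synthetic = isTRUE(img$synthetic))
    }
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Load a dataset directory written by [write_dataset()]
#'
#' Also serves as the loader stub for real two-class image corpora arranged
#' in the same `images/<split>/<class>/` layout with a manifest; it has only
#' been exercised against synthetic data.
#' @param dir Dataset directory.
#' @export
load_image_dir <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  splits <- list()
  for (sp in c("train", "val", "test")) {
    rows <- man[man$split == sp, , drop = FALSE]
    images <- vector("list", nrow(rows))
    for (j in seq_len(nrow(rows))) {
      r <- rows[j, ]
      cls <- c("benign", "malignant")[r$label + 1]
      px <- png::readPNG(file.path(dir, "images", sp, cls,
                                   paste0(r$id, ".png")))
      lab_path <- file.path(dir, "labels", sp, paste0(r$id, ".txt"))
      boxes <- if (file.exists(lab_path)) read_yolo_labels(lab_path) else
        matrix(numeric(0), 0, 5)
      images[[j]] <- new_synth_image(px, r$label, r$magnification, boxes,
                                     r$id, isTRUE(r$synthetic))
    }
    splits[[sp]] <- new_image_set(images)
  }
  structure(list(train = splits$train, val = splits$val, test = splits$test,
                 seed = NA_integer_), class = "dataset_bundle")
}
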