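test_that("class counts follow the floor-minority rounding rule", {
  expect_equal(class_counts(1000, 2480 / 7909),
               c(benign = 313L, malignant = 687L))
  expect_equal(class_counts(10, 1), c(benign = 10L, malignant = 0L))
  expect_equal(class_counts(10, 0), c(benign = 0L, malignant = 10L))
  expect_equal(class_counts(10, 0.7), c(benign = 7L, malignant = 3L))
  expect_error(class_counts(10, 1.2), "\\[0, 1\\]")
})

test_that("generation is deterministic and structurally sound", {
  b1 <- generate_dataset(40, image_size = 32, seed = 5)
  b2 <- generate_dataset(40, image_size = 32, seed = 5)
  expect_identical(b1$train$images[[1]]$pixels, b2$train$images[[1]]$pixels)
  expect_identical(lapply(b1$val$images, `[[`, "id"),
                   lapply(b2$val$images, `[[`, "id"))
  b3 <- generate_dataset(40, image_size = 32, seed = 6)
  expect_false(identical(b1$train$images[[1]]$pixels,
                         b3$train$images[[1]]$pixels))
  all_imgs <- c(b1$train$images, b1$val$images, b1$test$images)
  for (img in all_imgs[1:10]) {
    expect_true(all(img$pixels >= 0 & img$pixels <= 1))
    expect_true(img$magnification %in% c(40, 100, 200, 400))
    expect_true(all(img$boxes[, 2:5] >= 0 & img$boxes[, 2:5] <= 1))
    expect_true(nrow(img$boxes) >= 1)
  }
  # benign images carry fewer blobs than malignant ones on average
  labs <- vapply(all_imgs, `[[`, 0, "label")
  nb <- vapply(all_imgs, function(i) nrow(i$boxes), 0)
  expect_lt(mean(nb[labs == 0]), mean(nb[labs == 1]))
  # all-benign generation
  bb <- generate_dataset(20, benign_fraction = 1, image_size = 16, seed = 1)
  expect_true(all(vapply(c(bb$train$images, bb$val$images, bb$test$images),
                         `[[`, 0, "label") == 0))
})

test_that("80/10/10 split counts are exact under the floor rule", {
  b <- generate_dataset(100, benign_fraction = 0.5, image_size = 16, seed = 2)
  expect_equal(length(b$train), 80)
  expect_equal(length(b$val), 10)
  expect_equal(length(b$test), 10)

  # corpus-scale stub: 7909 images at the 2480:5429 class balance
  labels <- rep(c(0L, 1L), c(2480, 5429))
  big <- stub_image_set(labels)
  sp <- split_80_10_10(big, seed = 3)
  expect_equal(length(sp$test), 790)
  expect_equal(length(sp$val), 790)
  expect_equal(length(sp$train), 6329)
  # stratified: class fractions within one sample of the full set's
  full_frac <- 2480 / 7909
  for (s in list(sp$train, sp$val, sp$test)) {
    labs <- vapply(s$images, `[[`, 0, "label")
    expect_lte(abs(sum(labs == 0) - full_frac * length(labs)), 1)
  }
  # disjoint and covering
  ids <- c(vapply(sp$train$images, `[[`, "", "id"),
           vapply(sp$val$images, `[[`, "", "id"),
           vapply(sp$test$images, `[[`, "", "id"))
  expect_equal(sort(ids), sort(vapply(big$images, `[[`, "", "id")))
})

test_that("YOLO label files round-trip at six decimals", {
  f <- withr::local_tempfile(fileext = ".txt")
  write_yolo_labels(matrix(c(1, 0.5, 0.5, 0.2, 0.3), 1), f)
  expect_equal(readLines(f), "1 0.500000 0.500000 0.200000 0.300000")
  b <- read_yolo_labels(f)
  expect_equal(unname(b[1, ]), c(1, 0.5, 0.5, 0.2, 0.3))
  # empty list -> empty file -> empty matrix
  write_yolo_labels(matrix(numeric(0), 0, 5), f)
  expect_equal(nrow(read_yolo_labels(f)), 0)
  # round-trip of random boxes at the stated precision
  set.seed(9)
  boxes <- cbind(sample(0:1, 7, TRUE), matrix(round(runif(28), 6), 7))
  write_yolo_labels(boxes, f)
  expect_equal(unname(read_yolo_labels(f)), unname(boxes))
  # out-of-range coordinate errors with the line number
  writeLines(c("0 0.5 0.5 0.1 0.1", "1 1.500000 0.5 0.1 0.1"), f)
  expect_error(read_yolo_labels(f), "line 2")
  writeLines("0 0.5 oops 0.1 0.1", f)
  expect_error(read_yolo_labels(f), "malformed.*line 1")
})

test_that("preprocess resizes bilinearly and is the identity at same size", {
  b <- generate_dataset(12, image_size = 32, seed = 4)
  img <- b$train$images[[1]]
  same <- preprocess(img, 32)
  expect_equal(same$pixels, img$pixels, tolerance = 1e-12)
  small <- preprocess(img, 16)
  expect_equal(dim(small$pixels), c(16, 16, 3))
  expect_true(all(small$pixels >= 0 & small$pixels <= 1))
})

test_that("flips are involutions and rotation maps boxes correctly", {
  b <- generate_dataset(12, image_size = 32, seed = 8)
  img <- b$train$images[[1]]
  h2 <- fedlhe:::.apply_transform(fedlhe:::.apply_transform(img, "hflip"),
                                  "hflip")
  expect_identical(h2$pixels, img$pixels)
  expect_equal(h2$boxes, img$boxes)
  v2 <- fedlhe:::.apply_transform(fedlhe:::.apply_transform(img, "vflip"),
                                  "vflip")
  expect_identical(v2$pixels, img$pixels)

  # 90-degree rotation: (cx, cy) -> (cy, 1 - cx), (w, h) -> (h, w)
  r <- fedlhe:::.apply_transform(img, "rot90")
  expect_equal(unname(r$boxes[, 2]), unname(img$boxes[, 3]))
  expect_equal(unname(r$boxes[, 3]), unname(1 - img$boxes[, 2]))
  expect_equal(unname(r$boxes[, 4]), unname(img$boxes[, 5]))
  # pixels follow the same map: a marked pixel lands where the box map says
  mk <- img
  mk$pixels[] <- 0
  mk$pixels[5, 20, 1] <- 1   # row y, col x
  rk <- fedlhe:::.apply_transform(mk, "rot90")
  pos <- which(rk$pixels[, , 1] == 1, arr.ind = TRUE)
  h <- 32
  expect_equal(unname(pos[1, "col"]), 5)        # x' = y
  expect_equal(unname(pos[1, "row"]), h + 1 - 20)  # y' = 1 - x
  # four rotations compose to the identity
  r4 <- img
  for (j in 1:4) r4 <- fedlhe:::.apply_transform(r4, "rot90")
  expect_identical(r4$pixels, img$pixels)
  expect_equal(r4$boxes, img$boxes)
})

test_that("augmentation is seeded and keeps invariants", {
  b <- generate_dataset(12, image_size = 32, seed = 3)
  img <- b$train$images[[1]]
  a1 <- augment(img, seed = 42)
  a2 <- augment(img, seed = 42)
  expect_identical(a1$pixels, a2$pixels)
  expect_true(all(a1$pixels >= 0 & a1$pixels <= 1))
  if (nrow(a1$boxes))
    expect_true(all(a1$boxes[, 2:5] >= 0 & a1$boxes[, 2:5] <= 1))
})

test_that("IID partitioning gives near-equal disjoint covering shards", {
  labels <- rep(c(0L, 1L), 50)
  set100 <- stub_image_set(labels)
  bundle <- list(train = set100)
  class(bundle) <- "dataset_bundle"
  shards <- partition_iid(bundle, 5, seed = 2)
  expect_equal(vapply(shards, function(s) s$n, 0), rep(20, 5))
  idx <- unlist(lapply(shards, `[[`, "indices"))
  expect_equal(sort(idx), 1:100)  # disjoint and covering
})

test_that("non-IID shards honour class and magnification specs exactly", {
  b <- generate_dataset(600, image_size = 16, seed = 12)
  shards <- partition_noniid(b, seed = 4)
  ids <- vapply(shards, `[[`, 0L, "client_id")
  expect_equal(ids, 1:5)
  fr <- function(s) mean(vapply(s$data$images, `[[`, 0, "label") == 0)
  specs <- list(`1` = 0.7, `2` = 0.2, `3` = 0.5, `4` = 0.5, `5` = 0.85)
  for (s in shards) {
    want <- specs[[as.character(s$client_id)]]
    got_benign <- sum(vapply(s$data$images, `[[`, 0, "label") == 0)
    expect_equal(got_benign, round(want * s$n),
                 label = sprintf("client %d benign count", s$client_id))
  }
  expect_true(all(vapply(shards[[3]]$data$images, `[[`, 0L,
                         "magnification") %in% c(40L, 100L)))
  expect_true(all(vapply(shards[[4]]$data$images, `[[`, 0L,
                         "magnification") %in% c(200L, 400L)))
  # client 5 is half the base size
  expect_equal(shards[[5]]$n, round(0.5 * shards[[1]]$n))
  # disjoint; together with the unassigned pool they cover train exactly
  idx <- unlist(lapply(shards, `[[`, "indices"))
  expect_equal(length(idx), length(unique(idx)))
  expect_equal(sort(c(idx, attr(shards, "unassigned"))),
               seq_len(length(b$train)))
})

test_that("infeasible shard specs error with the deficit named", {
  labels <- rep(c(0L, 1L), c(5, 95))
  b <- list(train = stub_image_set(labels))
  class(b) <- "dataset_bundle"
  specs <- list(list(client_id = 1L, benign_fraction = 0.9, mags = NULL,
                     rel_size = 1, size = 50))
  expect_error(partition_noniid(b, specs, seed = 1),
               "needs 45 benign")
})

test_that("minority oversampling balances a shard and marks copies", {
  b <- generate_dataset(120, image_size = 16, seed = 21)
  shards <- partition_noniid(b, seed = 5)
  sh <- shards[[2]]  # benign 0.2: strongly malignant-skewed
  bal <- augment_minority(sh, seed = 6, target_balance = 0.5)
  labs <- vapply(bal$data$images, `[[`, 0, "label")
  expect_gte(mean(labs == 0), 0.5 - 1 / length(labs))
  synth <- vapply(bal$data$images, function(i) isTRUE(i$synthetic), TRUE)
  expect_true(any(synth))
  expect_true(all(vapply(bal$data$images[synth], `[[`, 0, "label") == 0))
  # deterministic
  bal2 <- augment_minority(sh, seed = 6, target_balance = 0.5)
  expect_identical(vapply(bal2$data$images, `[[`, "", "id"),
                   vapply(bal$data$images, `[[`, "", "id"))
})

test_that("dataset directories round-trip through PNG and label files", {
  b <- generate_dataset(15, image_size = 16, seed = 31)
  dir <- withr::local_tempdir()
  write_dataset(b, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  b2 <- load_image_dir(dir)
  for (sp in c("train", "val", "test")) {
    expect_equal(length(b2[[sp]]), length(b[[sp]]))
    ids <- vapply(b[[sp]]$images, `[[`, "", "id")
    ids2 <- vapply(b2[[sp]]$images, `[[`, "", "id")
    o <- match(ids, ids2)
    for (j in seq_along(ids)) {
      expect_identical(b2[[sp]]$images[[o[j]]]$pixels,
                       b[[sp]]$images[[j]]$pixels)
      if (nrow(b[[sp]]$images[[j]]$boxes))
        expect_true(max(abs(b2[[sp]]$images[[o[j]]]$boxes -
                              b[[sp]]$images[[j]]$boxes)) <= 5e-7)
    }
  }
})
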