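test_that("dataset splitting is exhaustive, disjoint, sized and seeded", {
  recs <- data.frame(id = 1:515)
  sp <- split_dataset(recs, 0.8, seed = 1)
  expect_equal(nrow(sp$train), 412)
  expect_equal(nrow(sp$test), 103)
  expect_setequal(c(sp$train$id, sp$test$id), 1:515)

  s1 <- split_dataset(as.list(1:10), 0.8, seed = 1)
  s2 <- split_dataset(as.list(1:10), 0.8, seed = 2)
  expect_equal(length(s1$train), 8)
  expect_equal(length(s2$test), 2)
  expect_false(identical(s1$train, s2$train))
  expect_identical(split_dataset(as.list(1:10), 0.8, seed = 1), s1)

  expect_error(split_dataset(data.frame(id = 1)), "at least 2")
  # round(0.8 * 2) = 2 would leave an empty test set
  expect_error(split_dataset(data.frame(id = 1:2), 0.8), "empty")
})

test_that("dice and iou follow their definitions on counted masks", {
  a <- matrix(0, 20, 20); b <- matrix(0, 20, 20)
  a[1:10, 1:10] <- 255            # |A| = 100
  b[6:15, 1:10] <- 255            # |B| = 100, |A n B| = 50
  expect_equal(dice(a, b), 0.5)
  expect_equal(iou(a, b, "foreground"), 50 / 150)
  expect_equal(dice(a, a), 1)
  expect_equal(iou(a, a), 1)
  expect_equal(miou(a, a), 1)

  d <- matrix(0, 20, 20); d[11:20, 11:20] <- 255
  expect_equal(dice(a, d), 0)
  expect_equal(iou(a, d, "foreground"), 0)

  # complement masks share no foreground
  p <- matrix(0, 2, 2); q <- matrix(255, 2, 2); p[1, 1] <- 255; q[1, 1] <- 0
  expect_equal(iou(p, q, "foreground"), 0)

  # both-empty class scores 1
  z <- matrix(0, 4, 4)
  expect_equal(dice(z, z), 1)
  expect_equal(iou(z, z, "foreground"), 1)

  expect_error(dice(a, matrix(0, 10, 10)), "mismatch")
  bad <- a; bad[1, 1] <- 7
  expect_error(dice(bad, a), "0 and 255")
})

test_that("dice and iou satisfy their algebraic identities", {
  for (s in 1:20) {
    a <- random_mask(10, 0.4, seed = s)
    b <- random_mask(10, 0.4, seed = 100 + s)
    d <- dice(a, b); i <- iou(a, b, "foreground")
    expect_equal(d, dice(b, a))
    expect_equal(d, 2 * i / (1 + i), tolerance = 1e-12)
    expect_lte(i, d + 1e-12)
    expect_equal(miou(a, b),
                 (iou(a, b, "foreground") + iou(a, b, "background")) / 2)
  }
})

test_that("training validates its inputs", {
  expect_error(train_seg(list()), "no training pairs")
  cfg <- seg_train_config(epochs = 1, base_channels = 4, depth = 2,
                          image_size = 16)
  face <- matrix(0.5, 16, 16)
  expect_error(train_seg(list(list(face = face, mask = matrix(0, 8, 8))),
                         cfg), "mismatch")
  badmask <- matrix(3, 16, 16)
  expect_error(train_seg(list(list(face = face, mask = badmask)), cfg),
               "0 and 255")
  expect_error(seg_train_config(learning_rate = 0), "learning_rate")
})

test_that("prediction thresholding is monotone and binary", {
  set.seed(3)
  cfg <- seg_train_config(epochs = 1, learning_rate = 1e-3, base_channels = 4,
                          depth = 2, image_size = 32, seed = 4)
  face <- matrix(runif(32 * 32), 32, 32)
  mask <- matrix(0, 32, 32); mask[10:20, 10:20] <- 255
  m <- train_seg(list(list(face = face, mask = mask)), cfg)
  pr <- predict_prob(m, face)
  expect_true(all(pr >= 0 & pr <= 1))
  m3 <- predict_mask(m, face, threshold = 0.3)
  m5 <- predict_mask(m, face, threshold = 0.5)
  m7 <- predict_mask(m, face, threshold = 0.7)
  expect_true(all(m5[m7 == 255] == 255))
  expect_true(all(m3[m5 == 255] == 255))
  expect_true(all(m5 %in% c(0, 255)))
  expect_error(predict_mask(m, matrix(0.5, 16, 16)), "image_size")
})

test_that("training reduces the loss and improves Dice on fixtures", {
  pairs <- make_seg_pairs(4, size = 64, seed = 5)
  cfg <- seg_train_config(epochs = 8, learning_rate = 3e-4,
                          base_channels = 8, depth = 2, image_size = 64,
                          seed = 1)
  m <- train_seg(pairs, cfg, val_pairs = pairs[1])
  expect_equal(nrow(m$history), 8)
  expect_lt(tail(m$history$loss, 1), m$history$loss[1])
  expect_gte(tail(m$history$val_dice, 1), m$history$val_dice[1])
  # determinism under identical config and seed
  m2 <- train_seg(pairs, cfg)
  expect_identical(m$params, m2$params)
})

test_that("input sizes not divisible by 2^depth are padded transparently", {
  set.seed(5)
  cfg <- seg_train_config(epochs = 1, learning_rate = 5e-4, base_channels = 4,
                          depth = 2, image_size = 30, seed = 2)
  face <- matrix(runif(30 * 30), 30, 30)
  mask <- matrix(0, 30, 30); mask[10:20, 8:22] <- 255
  m <- train_seg(list(list(face = face, mask = mask)), cfg)
  pr <- predict_prob(m, face)
  expect_equal(dim(pr), c(30, 30))
  expect_true(all(predict_mask(m, face) %in% c(0, 255)))
})

test_that("checkpoints round-trip through save/load", {
  pairs <- make_seg_pairs(1, size = 32, seed = 2)
  cfg <- seg_train_config(epochs = 1, learning_rate = 3e-4, base_channels = 4,
                          depth = 2, image_size = 32, seed = 1)
  m <- train_seg(pairs, cfg)
  f <- withr::local_tempfile(fileext = ".ckpt")
  save_seg_model(m, f)
  m2 <- load_seg_model(f)
  expect_identical(predict_mask(m2, pairs[[1]]$face),
                   predict_mask(m, pairs[[1]]$face))
})
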