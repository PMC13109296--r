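test_that("manifest reading validates structure and bounds", {
  dir <- tempdir()
  p <- file.path(dir, "man.csv")
  df <- data.frame(series_id = rep(c("A", "B"), each = 3),
                   frame_index = rep(1:3, 2), stage = c(1, 1, 2, 3, 3, 4),
                   path = sprintf("img%d.png", 1:6))
  utils::write.csv(df, p, row.names = FALSE)
  expect_equal(nrow(read_manifest(p)), 6)
  # empty file with header -> empty records
  utils::write.csv(df[0, ], p, row.names = FALSE)
  expect_equal(nrow(read_manifest(p)), 0)
  # stage out of bounds names the row
  df2 <- df; df2$stage[4] <- 9
  utils::write.csv(df2, p, row.names = FALSE)
  expect_error(read_manifest(p), "row 4.*9")
  # duplicate key names the row
  df3 <- df; df3$frame_index[2] <- 1
  utils::write.csv(df3, p, row.names = FALSE)
  expect_error(read_manifest(p), "duplicate")
  # missing column
  utils::write.csv(df[, -3], p, row.names = FALSE)
  expect_error(read_manifest(p), "stage")
})

make_records <- function(n_series, L, size = 8) {
  recs <- do.call(rbind, lapply(seq_len(n_series), function(i)
    data.frame(series_id = sprintf("S%02d", i), frame_index = seq_len(L),
               stage = pmin(1L + (i - 1L) %% 8L, 8L),
               path = sprintf("S%02d_%d", i, seq_len(L)))))
  imgs <- stats::setNames(
    lapply(seq_len(nrow(recs)), function(i)
      array(runif(size * size * 3), c(size, size, 3))),
    recs$path)
  list(records = recs, images = imgs)
}

test_that("series assembly enforces length policy and final-frame labels", {
  set.seed(1)
  d <- make_records(10, 30)
  samples <- assemble_series(d$records, L = 30, images = d$images)
  expect_length(samples, 10)
  expect_equal(samples[[1]]$label, samples[[1]]$stage[30])
  # a short series is excluded under the default policy, with a warning
  short <- d$records[-2, ]   # S01 loses frame 2
  expect_warning(kept <- assemble_series(short, L = 30, images = d$images),
                 "S01")
  expect_length(kept, 9)
  # pad policy duplicates the earliest frame at the front
  padded <- assemble_series(short, L = 30, images = d$images, policy = "pad")
  expect_length(padded, 10)
  s1 <- padded[[1]]
  expect_length(s1$images, 30)
  expect_identical(s1$images[[1]], s1$images[[2]])  # frame 1 repeated
  expect_equal(s1$frame_index[1], s1$frame_index[2])
})

test_that("series-level splits have exact sizes, purity and determinism", {
  set.seed(2)
  d <- make_records(10, 2)
  samples <- assemble_series(d$records, L = 2, images = d$images)
  sp <- split_series(samples, split_spec(seed = 4))
  expect_equal(vapply(sp[c("train", "val", "test")], length, integer(1)),
               c(train = 6L, val = 2L, test = 2L))
  # no series straddles splits
  ids <- lapply(sp[c("train", "val", "test")], function(x)
    vapply(x, function(s) s$series_id, character(1)))
  expect_length(intersect(ids$train, ids$val), 0)
  expect_length(intersect(ids$train, ids$test), 0)
  expect_length(intersect(ids$val, ids$test), 0)
  # deterministic given the seed
  sp2 <- split_series(samples, split_spec(seed = 4))
  expect_identical(sp$assignments, sp2$assignments)
  # everything to train under (1, 0, 0)
  all_train <- split_series(samples, split_spec(c(1, 0, 0), seed = 1))
  expect_length(all_train$train, 10)
  expect_error(split_series(samples[1:2], split_spec(seed = 1)), "at least 3")
})

test_that("splits are stratified when counts permit", {
  set.seed(3)
  # 40 series, 5 per stage: each split should see every stage
  recs <- do.call(rbind, lapply(1:40, function(i)
    data.frame(series_id = sprintf("S%02d", i), frame_index = 1L,
               stage = 1L + (i - 1L) %/% 5L, path = sprintf("p%d", i))))
  imgs <- stats::setNames(lapply(1:40, function(i) array(0.5, c(8, 8, 3))),
                          recs$path)
  samples <- assemble_series(recs, L = 1, images = imgs)
  sp <- split_series(samples, split_spec(seed = 9))
  for (part in sp[c("train", "val", "test")]) {
    labs <- vapply(part, function(s) s$label, integer(1))
    expect_setequal(unique(labs), 1:8)
  }
})

test_that("augmentation preserves labels, counts and temporal coherence", {
  set.seed(4)
  d <- make_records(6, 5, size = 12)
  samples <- assemble_series(d$records, L = 5, images = d$images)
  pol <- augmentation_policy(expansion_factor = 3, seed = 2)
  aug <- augment_training_set(samples, pol)
  expect_length(aug, 18)      # factor x originals
  # factor 1 is the identity
  expect_identical(augment_training_set(samples,
                                        augmentation_policy(expansion_factor = 1)),
                   samples)
  # per-stage counts scale exactly by the factor
  lab <- function(x) table(factor(vapply(x, function(s) s$label, integer(1)),
                                  levels = 1:8))
  expect_equal(as.integer(lab(aug)), 3L * as.integer(lab(samples)))
  # augmented copies keep label and frame count of their source
  copies <- aug[vapply(aug, function(s) isTRUE(s$augmented), logical(1))]
  expect_length(copies, 12)
  for (cp in copies) {
    src <- samples[[which(vapply(samples, function(s)
      s$series_id == cp$source_id, logical(1)))]]
    expect_equal(cp$label, src$label)
    expect_length(cp$images, length(src$images))
  }
  # the same geometric transform is applied to every frame of a series:
  # a flip applied per-series means frame-wise flip equals the copy
  expect_error(augmentation_policy(ops = "sharpen"), "unknown augmentation")
})

test_that("augmentation ops behave geometrically", {
  img <- array(runif(12 * 12 * 3), c(12, 12, 3))
  expect_identical(phenodistill:::img_flip_h(phenodistill:::img_flip_h(img)), img)
  expect_equal(phenodistill:::img_rotate(img, 0), img, tolerance = 1e-12)
  bright <- phenodistill:::img_brightness(img, 1.5)
  expect_true(all(bright <= 1) && all(bright >= img - 1e-12))
})

test_that("dataset summary mirrors the per-stage accounting table", {
  set.seed(6)
  d <- make_records(16, 2)
  samples <- assemble_series(d$records, L = 2, images = d$images)
  sp <- split_series(samples, split_spec(seed = 1))
  aug <- augment_training_set(sp$train, augmentation_policy(expansion_factor = 3,
                                                            seed = 1))
  summ <- dataset_summary(aug, sp$val, sp$test)
  expect_equal(nrow(summ), 9)
  expect_equal(summ$stage[9], "ALL")
  expect_equal(summ$train_after_aug, 3L * summ$train_before_aug)
  expect_equal(summ$overall, summ$train_after_aug + summ$val + summ$test)
  # empty splits give an all-zero table
  empty <- dataset_summary(list(), list(), list())
  expect_true(all(empty$overall == 0))
})
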