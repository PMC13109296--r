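test_that("student forward honors the shape and determinism contracts", {
  cfg <- tiny_backbone()
  st <- build_student(cfg, seed = 2)
  img <- rand_image(seed = 5)
  fw <- student_forward(st, img, taps = TRUE)
  expect_length(fw$logits, 8)
  expect_true(all(is.finite(fw$logits)))
  expect_length(fw$attention, 5)
  expect_equal(vapply(fw$attention, function(m) m$layer_index, integer(1)), 1:5)
  # tap resolutions halve after the stem
  expect_equal(dim(fw$attention[[1]]$map), c(16, 16))
  expect_equal(dim(fw$attention[[2]]$map), c(8, 8))
  # same seed, same initial parameters
  st2 <- build_student(cfg, seed = 2)
  expect_identical(st$store$params, st2$store$params)
  expect_false(identical(st$store$params,
                         build_student(cfg, seed = 3)$store$params))
  # eval-mode forwards are dropout-free and identical
  expect_identical(student_forward(st, img)$logits,
                   student_forward(st, img)$logits)
  expect_error(backbone_config("mini", dropout = 1.2), "dropout")
})

test_that("teacher handles arbitrary lengths and is order-sensitive", {
  cfg <- tiny_backbone()
  te <- build_teacher(cfg, seed = 2)
  ser <- rand_series(L = 4, seed = 9)
  out <- teacher_forward(te, ser, taps = TRUE)
  expect_length(out$logits, 8)
  expect_length(out$attention, 5)
  # degenerate single-frame series still works
  out1 <- teacher_forward(te, ser[1])
  expect_length(out1$logits, 8)
  expect_error(teacher_forward(te, list()), "empty")
  # permuting frames changes the output
  perm <- teacher_forward(te, ser[c(3, 1, 2, 4)])
  expect_gt(max(abs(out$logits - perm$logits)), 1e-10)
  # teacher strictly extends the student architecture
  st <- build_student(cfg, seed = 2)
  expect_gt(phenodistill:::param_count(te$store),
            phenodistill:::param_count(st$store))
})

test_that("the shared backbone is weight-tied between per-frame and standalone use", {
  cfg <- tiny_backbone()
  te <- build_teacher(cfg, seed = 6)
  ser <- rand_series(L = 3, seed = 2)
  x <- phenodistill:::stack_series(list(structure(list(images = ser),
                                                  class = "pd_series")))
  fw <- phenodistill:::teacher_forward_raw(te, x, S = 1, L = 3)
  solo <- phenodistill:::seq_forward(te$layers,
                                     phenodistill:::stack_images(ser[2]),
                                     te$store, FALSE, FALSE)
  feat_solo <- phenodistill:::global_avgpool(solo$y)
  # one parameter store serves both paths; numerical agreement is limited
  # only by BLAS accumulation order across batch shapes
  expect_equal(unname(fw$feats[2, ]), unname(as.numeric(feat_solo)),
               tolerance = 1e-12)
})

test_that("attention maps follow the sum-of-squares + L2 normalization definition", {
  # all-zero activation passes through, unnormalized
  z <- attention_from_activation(array(0, c(3, 3, 4)))
  expect_false(z$normalized)
  expect_true(all(z$map == 0))
  # single channel: map is the (normalized) elementwise square
  M <- matrix(c(1, 2, 0, 3), 2, 2)
  a1 <- attention_from_activation(array(M, c(2, 2, 1)))
  expect_true(a1$normalized)
  expect_equal(a1$map, M^2 / sqrt(sum(M^4)), tolerance = 1e-12)
  expect_equal(sqrt(sum(a1$map^2)), 1, tolerance = 1e-6)
  # invariance to positive rescaling of the activation
  set.seed(3)
  act <- array(rnorm(4 * 4 * 6), c(4, 4, 6))
  expect_equal(attention_from_activation(act)$map,
               attention_from_activation(2 * act)$map, tolerance = 1e-12)
  # strictly positive wherever any channel is nonzero
  act2 <- array(0, c(2, 2, 3)); act2[1, 1, 2] <- 0.3
  m2 <- attention_from_activation(act2)
  expect_gt(m2$map[1, 1], 0)
  expect_equal(sum(m2$map > 0), 1)
  expect_error(attention_from_activation(array(Inf, c(2, 2, 1))), "finite")
})

test_that("the full-depth preset builds with the expected parameter budget", {
  r50 <- build_student(backbone_config("resnet50", input_size = 32L), seed = 1)
  n <- phenodistill:::param_count(r50$store)
  expect_gte(n, 23e6)
  expect_lte(n, 30e6)
  fw <- student_forward(r50, rand_image(32, seed = 4), taps = TRUE)
  expect_length(fw$logits, 8)
  expect_length(fw$attention, 5)
  rep <- complexity_report(r50)
  expect_equal(rep$parameters[rep$component == "TOTAL"], n)
})

test_that("complexity report decomposes additively", {
  te <- build_teacher(tiny_backbone(), seed = 1)
  rep <- complexity_report(te)
  expect_setequal(rep$component, c("backbone", "lstm", "head", "TOTAL"))
  expect_equal(sum(rep$parameters[rep$component != "TOTAL"]),
               rep$parameters[rep$component == "TOTAL"])
})

test_that("checkpoints round-trip bitwise and validate their header", {
  te <- build_teacher(tiny_backbone(), seed = 8)
  p <- file.path(tempdir(), "teacher.ckpt")
  save_checkpoint(te, p)
  back <- load_checkpoint(p)
  expect_identical(back$store$params, te$store$params)
  ser <- rand_series(L = 2, seed = 1)
  expect_identical(teacher_forward(back, ser)$logits,
                   teacher_forward(te, ser)$logits)
  saveRDS(list(format = "other"), p)
  expect_error(load_checkpoint(p), "checkpoint")
})
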