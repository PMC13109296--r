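# Tiny-scale training smoke tests: 12 series x 4 frames at 16 px, 1-3
# epochs. The statistical benchmark lives in test-acceptance.R.

sp_cache <- NULL
get_sp <- function() {
  if (is.null(sp_cache)) sp_cache <<- tiny_split(seed = 7)
  sp_cache
}

test_that("teacher training logs one record per epoch and is seed-deterministic", {
  sp <- get_sp()
  cfg1 <- train_config(epochs = 1L, seed = 3)
  mc <- tiny_backbone()
  f1 <- train_teacher(sp$train, sp$val, cfg1, mc)
  expect_equal(nrow(f1$log), 1)
  expect_named(f1$log, c("epoch", "loss", "val_OA", "val_MAE"))
  f2 <- train_teacher(sp$train, sp$val, cfg1, mc)
  expect_identical(f1$log, f2$log)               # same seed, same losses
  expect_identical(f1$model$store$params, f2$model$store$params)
  f3 <- train_teacher(sp$train, sp$val, train_config(epochs = 1L, seed = 4), mc)
  expect_false(identical(f1$log$loss, f3$log$loss))
  expect_error(train_teacher(list(), sp$val, cfg1, mc), "empty")
})

test_that("teacher supervision is normalized, causal and cached", {
  sp <- get_sp()
  mc <- tiny_backbone()
  tt <- train_teacher(sp$train, sp$val, train_config(epochs = 1L, seed = 1), mc)
  s <- sp$train[[1]]
  cfg <- loss_config()
  sv <- teacher_supervision(tt$model, s, cfg = cfg)
  expect_equal(sum(sv$p), 1, tolerance = 1e-9)
  expect_length(sv$attention, 5)
  # t = L equals the full-series forward
  full <- teacher_forward(tt$model, s$images)
  expect_equal(sv$logits, full$logits, tolerance = 1e-12)
  # truncation changes the soft label in general
  sv2 <- teacher_supervision(tt$model, s, t = 2L, cfg = cfg)
  expect_false(isTRUE(all.equal(sv$logits, sv2$logits, tolerance = 1e-10)))
  # cache hit returns bit-identical arrays (memory and disk)
  cache_dir <- file.path(tempdir(), "supcache")
  sv_a <- teacher_supervision(tt$model, s, cfg = cfg, cache_dir = cache_dir)
  sv_b <- teacher_supervision(tt$model, s, cfg = cfg, cache_dir = cache_dir)
  expect_identical(sv_a, sv_b)
  expect_error(teacher_supervision(tt$model, s, t = 99L), "out of range")
})

test_that("student modes implement the component contracts", {
  sp <- get_sp()
  mc <- tiny_backbone()
  tt <- train_teacher(sp$train, sp$val, train_config(epochs = 1L, seed = 1), mc)
  cfg <- train_config(epochs = 2L, seed = 5)

  base <- train_student(sp$train, sp$val, NULL, cfg, mode = "baseline",
                        model_config = mc)
  # baseline loss is plain hard cross-entropy at every step
  expect_true(all(base$step_log$L_soft == 0))
  expect_true(all(base$step_log$L_attention == 0))
  expect_equal(base$step_log$L_total, base$step_log$L_hard, tolerance = 1e-12)

  kd <- train_student(sp$train, sp$val, tt$model, cfg, mode = "kd",
                      model_config = mc)
  expect_true(all(kd$step_log$L_attention == 0))
  expect_true(all(kd$step_log$L_soft > 0))
  expect_false(any(is.na(kd$log$val_KL)))

  kdat <- train_student(sp$train, sp$val, tt$model, cfg, mode = "kd_at",
                        model_config = mc)
  expect_true(all(kdat$step_log$L_attention > 0))
  expect_equal(kdat$step_log$L_total,
               0.7 * kdat$step_log$L_soft + 0.3 * kdat$step_log$L_hard +
                 0.001 * kdat$step_log$L_attention, tolerance = 1e-9)

  # teacher parameters are bitwise unchanged by student training
  before <- phenodistill:::copy_params(tt$model)
  kd2 <- train_student(sp$train, sp$val, tt$model, cfg, mode = "kd_at",
                       model_config = mc)
  expect_identical(before$params, tt$model$store$params)

  # determinism of the full student path
  kd3 <- train_student(sp$train, sp$val, tt$model, cfg, mode = "kd_at",
                       model_config = mc)
  expect_identical(kd2$log, kd3$log)
})

test_that("shared init makes arms differ only by loss configuration", {
  sp <- get_sp()
  mc <- tiny_backbone()
  init <- phenodistill:::copy_params(build_student(mc, seed = 5))
  cfg <- train_config(epochs = 1L, seed = 5)
  a <- train_student(sp$train, sp$val, NULL, cfg, mode = "baseline",
                     model_config = mc, init = init)
  b <- train_student(sp$train, sp$val, NULL, cfg, mode = "baseline",
                     model_config = mc, init = init)
  expect_identical(a$model$store$params, b$model$store$params)
})

test_that("the all-frames sampling policy multiplies the sample count", {
  sp <- get_sp()
  mc <- tiny_backbone()
  tt <- train_teacher(sp$train, sp$val, train_config(epochs = 1L, seed = 1), mc)
  cfg <- train_config(epochs = 1L, seed = 2, batch_size = 64L,
                      student_sample = "all_frames")
  fit <- train_student(sp$train, sp$val, tt$model, cfg, mode = "kd",
                       model_config = mc)
  L <- length(sp$train[[1]]$images)
  expect_equal(nrow(fit$step_log), ceiling(length(sp$train) * L / 64))
})

test_that("divergence aborts with a diagnostic", {
  sp <- get_sp()
  mc <- tiny_backbone()
  # a non-finite parameter state must be caught at the first loss
  bad <- phenodistill:::copy_params(build_student(mc, seed = 1))
  bad$params[[1]][1] <- NaN
  expect_error(train_student(sp$train, sp$val, NULL,
                             train_config(epochs = 1L, seed = 1),
                             mode = "baseline", model_config = mc,
                             init = bad),
               "diverged")
})
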