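#' Training configuration
#'
#' Defaults follow the study setup: Adam, batch size 16, learning rate
#' 1e-4, dropout 0.3.
#'
#' @param batch_size minibatch size (series for the teacher, frames for the
#'   student).
#' @param lr Adam learning rate.
#' @param epochs number of epochs (>= 1).
#' @param dropout dropout rate before the classification layer.
#' @param seed integer seed governing initialization, shuffling and dropout.
#' @param loss a [loss_config()].
#' @param student_sample `"final_frame"` (one student sample per series,
#'   default) or `"all_frames"` (every frame is a sample, supervised by the
#'   causally truncated series).
#' @return an object of class `pd_train_config`.
#' @export
train_config <- function(batch_size = 16L, lr = 1e-4, epochs = 10L,
                         dropout = 0.3, seed = 1L, loss = loss_config(),
                         student_sample = c("final_frame", "all_frames")) {
  if (epochs < 1L) stopf("epochs must be >= 1")
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 optimizer = "adam", epochs = as.integer(epochs),
                 dropout = dropout, seed = as.integer(seed), loss = loss,
                 student_sample = match.arg(student_sample)),
            class = "pd_train_config")
}

onehot_rows <- function(y, n) {
  M <- matrix(0, length(y), n)
  M[cbind(seq_along(y), y)] <- 1
  M
}

# stack the frames of several series into one (H,W,S*L,3) batch,
# frame index fastest
stack_series <- function(samples) {
  imgs <- unlist(lapply(samples, function(s) s$images), recursive = FALSE)
  stack_images(imgs)
}

check_finite_loss <- function(loss, what) {
  if (!is.finite(loss))
    stopf("%s diverged: non-finite loss (%g); lower the learning rate or check inputs",
          what, loss)
}

## ---- prediction -----------------------------------------------------------

#' Predict stages with a trained teacher
#'
#' @param model a teacher `pd_model`.
#' @param samples list of `pd_series`.
#' @param chunk series per forward chunk (memory control).
#' @return integer vector of predicted stages.
#' @export
predict_teacher <- function(model, samples, chunk = 32L) {
  preds <- integer(length(samples))
  i <- 1L
  while (i <= length(samples)) {
    j <- min(i + chunk - 1L, length(samples))
    batch <- samples[i:j]
    L <- length(batch[[1]]$images)
    fw <- teacher_forward_raw(model, stack_series(batch), S = length(batch),
                              L = L, training = FALSE)
    preds[i:j] <- max.col(fw$logits, ties.method = "first")
    i <- j + 1L
  }
  preds
}

#' Predict stages with a trained student (final frame of each series)
#'
#' @param model a student `pd_model`.
#' @param samples list of `pd_series` (their final frames are classified) or
#'   a list of images.
#' @param chunk images per forward chunk.
#' @return integer vector of predicted stages.
#' @export
predict_student <- function(model, samples, chunk = 256L) {
  imgs <- lapply(samples, function(s)
    if (inherits(s, "pd_series")) s$images[[length(s$images)]] else s)
  preds <- integer(length(imgs))
  i <- 1L
  while (i <= length(imgs)) {
    j <- min(i + chunk - 1L, length(imgs))
    fw <- student_forward_raw(model, stack_images(imgs[i:j]), training = FALSE)
    preds[i:j] <- max.col(fw$logits, ties.method = "first")
    i <- j + 1L
  }
  preds
}

## ---- teacher training ------------------------------------------------------

#' Train the teacher on image series with hard labels
#'
#' Minimizes the cross-entropy of the final-state classification over
#' ordered frame series using Adam. Deterministic given `(config, data,
#' seed)`. The returned model carries the parameters of the epoch with the
#' best validation overall accuracy (ties broken by lower MAE).
#'
#' @param train,val lists of `pd_series`.
#' @param config a [train_config()].
#' @param model_config a [backbone_config()].
#' @param hidden LSTM hidden size (default: preset-dependent).
#' @param verbose print per-epoch progress.
#' @return a list with `model`, `log` (one row per epoch: loss, val_OA,
#'   val_MAE), and `best_epoch`.
#' @export
train_teacher <- function(train, val, config = train_config(),
                          model_config = backbone_config(), hidden = NULL,
                          verbose = FALSE) {
  if (length(train) == 0L || length(val) == 0L) stopf("empty train or val split")
  model_config$dropout <- config$dropout
  model <- build_teacher(model_config, hidden = hidden, seed = config$seed)
  opt <- adam_init(model$store)
  n <- length(train)
  labels <- vapply(train, function(s) s$label, integer(1))
  val_labels <- vapply(val, function(s) s$label, integer(1))
  L <- length(train[[1]]$images)
  log <- vector("list", config$epochs)
  best <- list(OA = -Inf, MAE = Inf, epoch = 0L, snap = NULL)
  set.seed(substream_seed(config$seed, 7L))
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    tot <- 0
    i <- 1L
    while (i <= n) {
      j <- min(i + config$batch_size - 1L, n)
      ix <- ord[i:j]
      S <- length(ix)
      x <- stack_series(train[ix])
      fw <- teacher_forward_raw(model, x, S = S, L = L, training = TRUE,
                                keep = TRUE)
      q <- softmax_rows(fw$logits)
      y <- labels[ix]
      loss <- -mean(log(pmax(q[cbind(seq_len(S), y)], .log_eps)))
      check_finite_loss(loss, "teacher training")
      tot <- tot + loss * S
      dZ <- (q - onehot_rows(y, ncol(q))) / S
      grads <- new_grads(model$store)
      ## head
      grads$g[[model$head$W]] <- crossprod(fw$drop$y, dZ)
      grads$g[[model$head$b]] <- colSums(dZ)
      dfeat <- dZ %*% t(model$store$params[[model$head$W]])
      if (!is.null(fw$drop$mask)) dfeat <- dfeat * fw$drop$mask
      ## recurrent head
      dfeats <- lstm_backward(model$store, model$lstm, dfeat, fw$feats,
                              fw$lstm$caches, S, L, grads)
      ## backbone
      dx <- global_avgpool_backward(dfeats, fw$last_dim)
      seq_backward(model$layers, dx, x, fw$run$outs, fw$run$caches,
                   model$store, grads)
      opt <- adam_step(model$store, grads, opt, config$lr)
      i <- j + 1L
    }
    pred <- predict_teacher(model, val)
    rep <- metric_report(val_labels, pred)
    log[[ep]] <- data.frame(epoch = ep, loss = tot / n, val_OA = rep$OA,
                            val_MAE = rep$MAE)
    if (rep$OA > best$OA || (rep$OA == best$OA && rep$MAE < best$MAE)) {
      best <- list(OA = rep$OA, MAE = rep$MAE, epoch = ep,
                   snap = copy_params(model))
    }
    if (verbose)
      message(sprintf("teacher epoch %d: loss %.4f val OA %.3f", ep,
                      tot / n, rep$OA))
  }
  model <- restore_params(model, best$snap)
  list(model = model, log = do.call(rbind, log), best_epoch = best$epoch)
}

## ---- teacher supervision ---------------------------------------------------

#' Soft label and attention maps from a frozen teacher
#'
#' Forwards the series truncated at frame `t` (frames `1..t`, so no future
#' information leaks into mid-series supervision) and returns the
#' temperature-softened probability vector together with the five attention
#' maps of frame `t`. Results are cached (in memory, and on disk under
#' `cache_dir` when given) keyed by `(series_id, t)`, so repeated student
#' epochs reuse them.
#'
#' @param teacher a trained teacher `pd_model`.
#' @param sample a `pd_series`.
#' @param t truncation frame (default: the full series length).
#' @param cfg a [loss_config()] providing the temperature.
#' @param cache_dir optional directory for on-disk caching.
#' @return a list with `p` (probability vector summing to 1), `attention`
#'   (list of 5 `pd_attention_map`), `logits`.
#' @export
teacher_supervision <- function(teacher, sample, t = NULL,
                                cfg = loss_config(), cache_dir = NULL) {
  L <- length(sample$images)
  t <- t %||% L
  if (t < 1L || t > L) stopf("t = %d out of range 1..%d", t, L)
  key <- sprintf("%s|t=%d|T=%g", sample$series_id, t, cfg$temperature)
  mem <- .pkg_env$supervision_cache
  if (is.null(mem)) {
    mem <- new.env(parent = emptyenv())
    .pkg_env$supervision_cache <- mem
  }
  if (!is.null(mem[[key]])) return(mem[[key]])
  if (!is.null(cache_dir)) {
    f <- file.path(cache_dir, paste0(digest::digest(key), ".rds"))
    if (file.exists(f)) {
      out <- readRDS(f)
      mem[[key]] <- out
      return(out)
    }
  }
  fw <- teacher_forward(teacher, sample$images[seq_len(t)], taps = TRUE)
  out <- list(p = softened_probabilities(fw$logits, cfg$temperature),
              attention = fw$attention, logits = fw$logits)
  mem[[key]] <- out
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(out, file.path(cache_dir, paste0(digest::digest(key), ".rds")))
  }
  out
}

# batched supervision over many samples at the full series length:
# returns soft-label matrix and per-sample attention maps (only the
# requested layers, to bound memory)
supervise_batch <- function(teacher, samples, cfg, layers = integer(0),
                            chunk = 32L) {
  n <- length(samples)
  P <- matrix(0, n, teacher$config$n_stages_out)
  maps <- if (length(layers)) vector("list", n) else NULL
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    batch <- samples[i:j]
    L <- length(batch[[1]]$images)
    fw <- teacher_forward_raw(teacher, stack_series(batch), S = length(batch),
                              L = L, training = FALSE)
    P[i:j, ] <- t(apply(fw$logits, 1L, softened_probabilities,
                        temperature = cfg$temperature))
    if (length(layers)) {
      for (b in seq_along(batch)) {
        frame_b <- (b - 1L) * L + L   # final frame of series b
        mm <- vector("list", 5L)
        for (l in layers) {
          act <- fw$taps[[l]][, , frame_b, , drop = FALSE]
          act <- array(act, dim(act)[c(1, 2, 4)])
          mm[[l]] <- attention_from_activation(act, layer_index = l)
        }
        maps[[i + b - 1L]] <- mm
      }
    }
    i <- j + 1L
  }
  list(P = P, maps = maps)
}

## ---- student training ------------------------------------------------------

mode_loss_config <- function(mode, loss) {
  switch(mode,
    baseline = loss_config(temperature = loss$temperature, alpha = 0, beta = 0,
                           transfer_layers = loss$transfer_layers,
                           scale_soft_by_T2 = loss$scale_soft_by_T2),
    kd = loss_config(temperature = loss$temperature, alpha = loss$alpha,
                     beta = 0, transfer_layers = loss$transfer_layers,
                     scale_soft_by_T2 = loss$scale_soft_by_T2),
    kd_at = loss,
    stopf("unknown training mode '%s'", mode))
}

#' Train the student against a frozen teacher
#'
#' Minimizes the combined objective on single frames (by default the final
#' frame of each training series, so student and teacher sample counts
#' align). Three modes support the component ablation: `"baseline"` (hard
#' labels only, `alpha = 0, beta = 0`), `"kd"` (`beta = 0`), and `"kd_at"`
#' (the full objective). The teacher is only read, never updated.
#'
#' @param train,val lists of `pd_series`.
#' @param teacher a trained teacher `pd_model` (ignored in `"baseline"`
#'   mode, may be `NULL` there).
#' @param config a [train_config()].
#' @param mode `"baseline"`, `"kd"` or `"kd_at"`.
#' @param model_config a [backbone_config()].
#' @param init optional parameter snapshot (from an untrained student built
#'   with the same config) so ablation arms share initial weights.
#' @param verbose print per-epoch progress.
#' @return a list with `model`, `log` (per-epoch loss breakdown, val_OA,
#'   val_MAE, val_KL), `step_log`, and `best_epoch`.
#' @export
train_student <- function(train, val, teacher, config = train_config(),
                          mode = c("kd_at", "kd", "baseline"),
                          model_config = backbone_config(), init = NULL,
                          verbose = FALSE) {
  mode <- match.arg(mode)
  if (length(train) == 0L || length(val) == 0L) stopf("empty train or val split")
  cfg <- mode_loss_config(mode, config$loss)
  needs_teacher <- cfg$alpha > 0 || cfg$beta > 0
  if (needs_teacher && is.null(teacher)) stopf("mode '%s' needs a teacher", mode)
  model_config$dropout <- config$dropout
  model <- build_student(model_config, seed = config$seed)
  if (!is.null(init)) model <- restore_params(model, init)
  teacher_snap <- if (needs_teacher) copy_params(teacher) else NULL
  opt <- adam_init(model$store)

  ## expand to (image, hard label, series, t) student samples
  if (config$student_sample == "final_frame") {
    imgs <- lapply(train, function(s) s$images[[length(s$images)]])
    hard <- vapply(train, function(s) s$label, integer(1))
    sup_idx <- seq_along(train); sup_t <- NULL
  } else {
    imgs <- list(); hard <- integer(0); sup_idx <- integer(0); sup_t <- integer(0)
    for (si in seq_along(train)) {
      s <- train[[si]]
      for (t in seq_along(s$images)) {
        imgs[[length(imgs) + 1L]] <- s$images[[t]]
        hard <- c(hard, s$stage[t])
        sup_idx <- c(sup_idx, si); sup_t <- c(sup_t, t)
      }
    }
  }
  n <- length(imgs)
  nk <- model$config$n_stages_out
  layers <- if (cfg$beta > 0) cfg$transfer_layers else integer(0)

  ## teacher supervision, computed once and reused every epoch
  P <- NULL; tmaps <- NULL; Pval <- NULL
  if (needs_teacher) {
    if (config$student_sample == "final_frame") {
      sup <- supervise_batch(teacher, train, cfg, layers)
      P <- sup$P; tmaps <- sup$maps
    } else {
      P <- matrix(0, n, nk)
      tmaps <- if (length(layers)) vector("list", n) else NULL
      for (k in seq_len(n)) {
        sv <- teacher_supervision(teacher, train[[sup_idx[k]]], t = sup_t[k],
                                  cfg = cfg)
        P[k, ] <- sv$p
        if (length(layers)) tmaps[[k]] <- sv$attention
      }
    }
    Pval <- supervise_batch(teacher, val, cfg, integer(0))$P
  }
  val_labels <- vapply(val, function(s) s$label, integer(1))

  log <- vector("list", config$epochs)
  steps <- list()
  best <- list(OA = -Inf, MAE = Inf, epoch = 0L, snap = NULL)
  step_id <- 0L
  set.seed(substream_seed(config$seed, 11L))
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_sum <- c(L_soft = 0, L_hard = 0, L_attention = 0, L_total = 0)
    i <- 1L
    while (i <= n) {
      j <- min(i + config$batch_size - 1L, n)
      ix <- ord[i:j]
      B <- length(ix)
      x <- stack_images(imgs[ix])
      fw <- student_forward_raw(model, x, training = TRUE, keep = TRUE)
      Z <- fw$logits
      q1 <- softmax_rows(Z, 1)
      y <- hard[ix]
      Lh <- -mean(log(pmax(q1[cbind(seq_len(B), y)], .log_eps)))
      dZ <- (1 - cfg$alpha) * (q1 - onehot_rows(y, nk)) / B
      Ls <- 0
      if (cfg$alpha > 0) {
        qT <- softmax_rows(Z, cfg$temperature)
        pT <- P[ix, , drop = FALSE]
        Ls <- -mean(rowSums(pT * log(pmax(qT, .log_eps))))
        soft_scale <- if (cfg$scale_soft_by_T2) cfg$temperature else 1 / cfg$temperature
        if (cfg$scale_soft_by_T2) Ls <- Ls * cfg$temperature^2
        dZ <- dZ + cfg$alpha * soft_scale * (qT - pT) / B
      }
      La <- 0
      tap_grads <- NULL
      if (cfg$beta > 0) {
        tap_grads <- vector("list", 5L)
        for (l in layers)
          tap_grads[[l]] <- array(0, dim(fw$taps[[l]]))
        for (b in seq_len(B)) {
          tm <- tmaps[[ix[b]]]
          for (l in layers) {
            act <- fw$taps[[l]][, , b, , drop = FALSE]
            act <- array(act, dim(act)[c(1, 2, 4)])
            smap <- attention_from_activation(act, layer_index = l)
            La <- La + sqrt(sum((smap$map - tm[[l]]$map)^2))
            ga <- attention_grad_activation(act, tm[[l]]) * (cfg$beta / B)
            tap_grads[[l]][, , b, ] <- ga
          }
        }
        La <- La / B
      }
      total <- cfg$alpha * Ls + (1 - cfg$alpha) * Lh + cfg$beta * La
      check_finite_loss(total, "student training")
      grads <- new_grads(model$store)
      grads$g[[model$head$W]] <- crossprod(fw$drop$y, dZ)
      grads$g[[model$head$b]] <- colSums(dZ)
      dfeat <- dZ %*% t(model$store$params[[model$head$W]])
      if (!is.null(fw$drop$mask)) dfeat <- dfeat * fw$drop$mask
      dx <- global_avgpool_backward(dfeat, fw$last_dim)
      seq_backward(model$layers, dx, x, fw$run$outs, fw$run$caches,
                   model$store, grads, tap_grads = tap_grads,
                   tap_at = model$tap_at)
      opt <- adam_step(model$store, grads, opt, config$lr)
      step_id <- step_id + 1L
      steps[[step_id]] <- data.frame(step = step_id, L_soft = Ls, L_hard = Lh,
                                     L_attention = La, L_total = total)
      w <- B / n
      ep_sum <- ep_sum + c(Ls, Lh, La, total) * w
      i <- j + 1L
    }
    pred <- predict_student(model, val)
    rep <- metric_report(val_labels, pred)
    val_KL <- NA_real_
    if (needs_teacher) {
      fwv <- student_forward_raw(model, stack_images(
        lapply(val, function(s) s$images[[length(s$images)]])), training = FALSE)
      qTv <- softmax_rows(fwv$logits, cfg$temperature)
      val_KL <- mean(rowSums(Pval * (log(pmax(Pval, .log_eps)) -
                                       log(pmax(qTv, .log_eps)))))
    }
    log[[ep]] <- data.frame(epoch = ep, L_soft = ep_sum[1], L_hard = ep_sum[2],
                            L_attention = ep_sum[3], L_total = ep_sum[4],
                            val_OA = rep$OA, val_MAE = rep$MAE, val_KL = val_KL)
    if (rep$OA > best$OA || (rep$OA == best$OA && rep$MAE < best$MAE)) {
      best <- list(OA = rep$OA, MAE = rep$MAE, epoch = ep,
                   snap = copy_params(model))
    }
    if (verbose)
      message(sprintf("student[%s] epoch %d: total %.4f val OA %.3f", mode,
                      ep, ep_sum[4], rep$OA))
  }
  if (needs_teacher) {
    now <- copy_params(teacher)
    stopifnot(identical(teacher_snap$params, now$params))
  }
  model <- restore_params(model, best$snap)
  rownames_log <- do.call(rbind, log)
  rownames(rownames_log) <- NULL
  list(model = model, log = rownames_log, step_log = do.call(rbind, steps),
       best_epoch = best$epoch, mode = mode)
}

#' Evaluate a trained model on a list of series samples
#'
#' @param model a `pd_model` (student or teacher).
#' @param samples list of `pd_series`.
#' @return a `pd_metric_report`.
#' @export
evaluate_model <- function(model, samples) {
  y <- vapply(samples, function(s) s$label, integer(1))
  pred <- if (model$type == "teacher") predict_teacher(model, samples)
  else predict_student(model, samples)
  metric_report(y, pred)
}
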