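#' Backbone configuration
#'
#' Describes the convolutional backbone shared by the teacher and the
#' student. Both presets expose exactly five attention tap points (the stem
#' output plus the four subsequent stages), mirroring the five layers whose
#' attention maps are transferred and visualized.
#'
#' @param preset `"mini"` (a five-stage CNN that trains on one CPU in
#'   minutes) or `"resnet50"` (the full bottleneck architecture; buildable
#'   and runnable, intended for parameter accounting and full-scale runs).
#' @param n_stages_out number of output classes (the 8 phenological stages).
#' @param dropout dropout rate applied to the pooled feature before the
#'   classification layer (default 0.3).
#' @param input_size expected square input resolution in pixels.
#' @param widths per-tap channel widths for the mini preset.
#' @return an object of class `pd_backbone_config`.
#' @export
backbone_config <- function(preset = c("mini", "resnet50"), n_stages_out = 8L,
                            dropout = 0.3, input_size = 32L,
                            widths = c(8L, 16L, 32L, 64L, 128L)) {
  preset <- match.arg(preset)
  if (dropout < 0 || dropout >= 1) stopf("dropout must be in [0, 1)")
  if (preset == "mini" && length(widths) != 5L)
    stopf("mini preset needs exactly 5 channel widths (got %d)", length(widths))
  structure(list(preset = preset, n_stages_out = as.integer(n_stages_out),
                 dropout = dropout, input_size = as.integer(input_size),
                 widths = as.integer(widths)),
            class = "pd_backbone_config")
}

build_backbone <- function(store, config) {
  if (config$preset == "mini") {
    w <- config$widths
    layers <- list(
      nn_conv(store, 3L, w[1]), nn_relu(),
      nn_conv(store, w[1], w[2]), nn_relu(), nn_avgpool2(),
      nn_conv(store, w[2], w[3]), nn_relu(), nn_avgpool2(),
      nn_conv(store, w[3], w[4]), nn_relu(), nn_avgpool2(),
      nn_conv(store, w[4], w[5]), nn_relu(), nn_avgpool2())
    list(layers = layers, tap_at = c(2L, 5L, 8L, 11L, 14L), out_ch = w[5])
  } else {
    bottleneck <- function(c_in, mid, c_out, stride) {
      body <- list(nn_conv(store, c_in, mid, k = 1L), nn_bn(store, mid),
                   nn_relu(),
                   nn_conv(store, mid, mid, k = 3L, stride = stride),
                   nn_bn(store, mid), nn_relu(),
                   nn_conv(store, mid, c_out, k = 1L), nn_bn(store, c_out))
      shortcut <- if (c_in != c_out || stride != 1L)
        list(nn_conv(store, c_in, c_out, k = 1L, stride = stride),
             nn_bn(store, c_out)) else NULL
      nn_block(body, shortcut)
    }
    stage <- function(c_in, mid, c_out, n, stride) {
      out <- list(bottleneck(c_in, mid, c_out, stride))
      for (i in seq_len(n - 1L)) out <- c(out, list(bottleneck(c_out, mid, c_out, 1L)))
      out
    }
    layers <- c(list(nn_conv(store, 3L, 64L, k = 7L, stride = 2L),
                     nn_bn(store, 64L), nn_relu(), nn_maxpool3()),
                stage(64L, 64L, 256L, 3L, 1L),
                stage(256L, 128L, 512L, 4L, 2L),
                stage(512L, 256L, 1024L, 6L, 2L),
                stage(1024L, 512L, 2048L, 3L, 2L))
    # taps: stem relu (3), then the last block of each stage
    list(layers = layers, tap_at = c(3L, 7L, 11L, 17L, 20L), out_ch = 2048L)
  }
}

param_count <- function(store, names = NULL) {
  nms <- names %||% names(store$params)
  sum(vapply(store$params[nms], length, numeric(1)))
}

#' Build the single-image student model
#'
#' The student is the backbone alone: one image in, 8-class logits out,
#' with the five tap activations available for attention transfer and
#' visualization.
#'
#' @param config a [backbone_config()].
#' @param seed integer seed for weight initialization; two builds with the
#'   same seed have identical initial parameters.
#' @return an object of class `pd_model` (type `"student"`).
#' @export
build_student <- function(config = backbone_config(), seed = 1L) {
  if (!inherits(config, "pd_backbone_config")) stopf("config must be a pd_backbone_config")
  with_seed(seed, {
    store <- new_param_store()
    bb <- build_backbone(store, config)
    bb_params <- names(store$params)
    Wf <- matrix(stats::rnorm(bb$out_ch * config$n_stages_out,
                              sd = sqrt(1 / bb$out_ch)),
                 bb$out_ch, config$n_stages_out)
    head <- list(W = add_param(store, Wf),
                 b = add_param(store, numeric(config$n_stages_out)))
    structure(list(type = "student", preset = config$preset, config = config,
                   store = store, layers = bb$layers, tap_at = bb$tap_at,
                   out_ch = bb$out_ch, head = head, seed = seed,
                   components = list(backbone = bb_params,
                                     head = setdiff(names(store$params), bb_params))),
              class = "pd_model")
  })
}

#' Build the image-series teacher model
#'
#' The teacher applies the same backbone to every frame of an ordered image
#' series and summarizes the per-frame features with a single-layer LSTM;
#' the final hidden state is classified into the 8 stages. Per-frame
#' attention maps are exposed at the same five tap points as the student.
#'
#' @param config a [backbone_config()].
#' @param hidden LSTM hidden size (>= 1); default 128 for the mini preset,
#'   512 for resnet50.
#' @param seed integer seed for weight initialization.
#' @return an object of class `pd_model` (type `"teacher"`).
#' @export
build_teacher <- function(config = backbone_config(), hidden = NULL, seed = 1L) {
  if (!inherits(config, "pd_backbone_config")) stopf("config must be a pd_backbone_config")
  hidden <- hidden %||% (if (config$preset == "mini") 128L else 512L)
  if (hidden < 1L) stopf("hidden size must be >= 1 (got %d)", hidden)
  with_seed(seed, {
    store <- new_param_store()
    bb <- build_backbone(store, config)
    bb_params <- names(store$params)
    C <- bb$out_ch; h <- as.integer(hidden)
    sdx <- sqrt(1 / C); sdh <- sqrt(1 / h)
    b0 <- numeric(4L * h)
    b0[(h + 1L):(2L * h)] <- 1  # forget-gate bias
    lstm <- list(Wx = add_param(store, matrix(stats::rnorm(C * 4L * h, sd = sdx), C, 4L * h)),
                 Wh = add_param(store, matrix(stats::rnorm(h * 4L * h, sd = sdh), h, 4L * h)),
                 b = add_param(store, b0), hidden = h)
    lstm_params <- setdiff(names(store$params), bb_params)
    Wf <- matrix(stats::rnorm(h * config$n_stages_out, sd = sqrt(1 / h)),
                 h, config$n_stages_out)
    head <- list(W = add_param(store, Wf),
                 b = add_param(store, numeric(config$n_stages_out)))
    structure(list(type = "teacher", preset = config$preset, config = config,
                   store = store, layers = bb$layers, tap_at = bb$tap_at,
                   out_ch = bb$out_ch, lstm = lstm, head = head, seed = seed,
                   components = list(backbone = bb_params, lstm = lstm_params,
                                     head = setdiff(names(store$params),
                                                    c(bb_params, lstm_params)))),
              class = "pd_model")
  })
}

#' @export
print.pd_model <- function(x, ...) {
  cat(sprintf("<pd_model %s/%s: %s parameters, 5 attention taps>\n",
              x$type, x$preset,
              format(param_count(x$store), big.mark = ",")))
  invisible(x)
}

## ---- forward passes -------------------------------------------------------

# stack a list of H x W x 3 images into the (H, W, B, C) batch layout
stack_images <- function(images) {
  if (is.array(images) && length(dim(images)) == 3L) images <- list(images)
  d <- dim(images[[1]])
  B <- length(images)
  x <- array(unlist(images, use.names = FALSE), c(d[1], d[2], d[3], B))
  aperm(x, c(1, 2, 4, 3))
}

dropout_forward <- function(feat, rate, training) {
  if (!training || rate <= 0) return(list(y = feat, mask = NULL))
  mask <- matrix((stats::runif(length(feat)) >= rate) / (1 - rate),
                 nrow(feat), ncol(feat))
  list(y = feat * mask, mask = mask)
}

# low-level student forward: images already stacked to (H,W,B,C)
student_forward_raw <- function(model, x, training = FALSE, keep = FALSE) {
  run <- seq_forward(model$layers, x, model$store, training, keep = keep)
  taps <- run$outs[model$tap_at]
  feat0 <- global_avgpool(run$y)
  dp <- dropout_forward(feat0, model$config$dropout, training)
  logits <- dp$y %*% model$store$params[[model$head$W]] +
    rep(model$store$params[[model$head$b]], each = nrow(dp$y))
  list(logits = logits, taps = taps, feat = feat0, drop = dp,
       run = if (keep) run else NULL, last_dim = dim(run$y))
}

# low-level teacher forward: x holds S series of L frames each,
# batch index b = (s-1)*L + t
teacher_forward_raw <- function(model, x, S, L, training = FALSE, keep = FALSE) {
  run <- seq_forward(model$layers, x, model$store, training, keep = keep)
  taps <- run$outs[model$tap_at]
  feats <- global_avgpool(run$y)   # (S*L) x C
  lf <- lstm_forward(model$store, model$lstm, feats, S, L, keep)
  dp <- dropout_forward(lf$H, model$config$dropout, training)
  logits <- dp$y %*% model$store$params[[model$head$W]] +
    rep(model$store$params[[model$head$b]], each = S)
  list(logits = logits, taps = taps, feats = feats, lstm = lf, drop = dp,
       run = if (keep) run else NULL, last_dim = dim(run$y))
}

lstm_forward <- function(store, lstm, feats, S, L, keep = FALSE) {
  h <- lstm$hidden
  Wx <- store$params[[lstm$Wx]]; Wh <- store$params[[lstm$Wh]]
  b <- store$params[[lstm$b]]
  H <- matrix(0, S, h); Cs <- matrix(0, S, h)
  caches <- if (keep) vector("list", L) else NULL
  for (t in seq_len(L)) {
    idx <- t + L * (seq_len(S) - 1L)
    X <- feats[idx, , drop = FALSE]
    G <- X %*% Wx + H %*% Wh + rep(b, each = S)
    gi <- sigm(G[, seq_len(h), drop = FALSE])
    gf <- sigm(G[, h + seq_len(h), drop = FALSE])
    gg <- tanh(G[, 2L * h + seq_len(h), drop = FALSE])
    go <- sigm(G[, 3L * h + seq_len(h), drop = FALSE])
    Cnew <- gf * Cs + gi * gg
    tc <- tanh(Cnew)
    Hnew <- go * tc
    if (keep) caches[[t]] <- list(i = gi, f = gf, g = gg, o = go,
                                  Cprev = Cs, tc = tc, Hprev = H, idx = idx)
    Cs <- Cnew; H <- Hnew
  }
  list(H = H, C = Cs, caches = caches)
}

lstm_backward <- function(store, lstm, dH, feats, caches, S, L, grads) {
  h <- lstm$hidden
  Wx <- store$params[[lstm$Wx]]; Wh <- store$params[[lstm$Wh]]
  dC <- matrix(0, S, h)
  dfeats <- matrix(0, nrow(feats), ncol(feats))
  for (t in rev(seq_len(L))) {
    ch <- caches[[t]]
    do <- dH * ch$tc * ch$o * (1 - ch$o)
    dC <- dC + dH * ch$o * (1 - ch$tc^2)
    di <- dC * ch$g * ch$i * (1 - ch$i)
    df <- dC * ch$Cprev * ch$f * (1 - ch$f)
    dg <- dC * ch$i * (1 - ch$g^2)
    dG <- cbind(di, df, dg, do)
    X <- feats[ch$idx, , drop = FALSE]
    grads$g[[lstm$Wx]] <- grads$g[[lstm$Wx]] + crossprod(X, dG)
    grads$g[[lstm$Wh]] <- grads$g[[lstm$Wh]] + crossprod(ch$Hprev, dG)
    grads$g[[lstm$b]] <- grads$g[[lstm$b]] + colSums(dG)
    dfeats[ch$idx, ] <- dG %*% t(Wx)
    dH <- dG %*% t(Wh)
    dC <- dC * ch$f
  }
  dfeats
}

## ---- public forward API ---------------------------------------------------

#' Forward an image (or images) through the student
#'
#' @param model a student `pd_model`.
#' @param images one `H x W x 3` array or a list of them.
#' @param taps if `TRUE`, also return the five per-layer attention maps
#'   (for a single image).
#' @return a list with `logits` (matrix, one row per image) and, when
#'   requested, `attention` (list of 5 [attention maps][attention_from_activation]).
#' @export
student_forward <- function(model, images, taps = FALSE) {
  if (model$type != "student") stopf("model is not a student")
  x <- stack_images(images)
  fw <- student_forward_raw(model, x, training = FALSE)
  out <- list(logits = fw$logits)
  if (taps) out$attention <- taps_to_maps(fw$taps, sample = 1L)
  out
}

#' Forward an ordered frame series through the teacher
#'
#' @param model a teacher `pd_model`.
#' @param series a list of `H x W x 3` arrays, temporally ordered
#'   (length L >= 1).
#' @param taps if `TRUE`, also return the final frame's five attention maps.
#' @return a list with `logits` (length-8 vector) and optionally `attention`.
#' @export
teacher_forward <- function(model, series, taps = FALSE) {
  if (model$type != "teacher") stopf("model is not a teacher")
  if (is.array(series) && length(dim(series)) == 3L) series <- list(series)
  if (length(series) == 0L) stopf("empty series")
  L <- length(series)
  x <- stack_images(series)
  fw <- teacher_forward_raw(model, x, S = 1L, L = L, training = FALSE)
  out <- list(logits = drop(fw$logits))
  if (taps) out$attention <- taps_to_maps(fw$taps, sample = L)
  out
}

# extract one sample's attention maps from batched tap activations
taps_to_maps <- function(taps, sample) {
  lapply(seq_along(taps), function(i) {
    act <- taps[[i]][, , sample, , drop = FALSE]
    act <- array(act, dim(act)[c(1, 2, 4)])
    attention_from_activation(act, layer_index = i)
  })
}

#' Compute a spatial attention map from a convolutional activation
#'
#' Collapses the channel dimension of an activation by summing squared
#' channel values at every spatial position, then L2-normalizes the
#' flattened map. An all-zero activation passes through unchanged with the
#' `normalized` flag set to `FALSE`. After normalization the map is
#' invariant to positive rescaling of the activation.
#'
#' @param activation numeric array `H x W x C` (a matrix is treated as
#'   `H x W x 1`).
#' @param layer_index optional tap index 1..5, recorded on the result.
#' @return an object of class `pd_attention_map`: a list with `layer_index`,
#'   `map` (`H x W`, non-negative) and `normalized` (logical).
#' @export
attention_from_activation <- function(activation, layer_index = NA_integer_) {
  if (is.matrix(activation)) activation <- array(activation, c(dim(activation), 1L))
  if (length(dim(activation)) != 3L) stopf("activation must be H x W x C")
  if (!all(is.finite(activation))) stopf("activation must be finite")
  d <- dim(activation)
  m <- matrix(activation^2, d[1] * d[2], d[3])
  map <- matrix(rowSums(m), d[1], d[2])
  nrm <- sqrt(sum(map^2))
  normalized <- nrm > 0
  if (normalized) map <- map / nrm
  structure(list(layer_index = as.integer(layer_index), map = map,
                 normalized = normalized),
            class = "pd_attention_map")
}

## ---- complexity & checkpoints ---------------------------------------------

#' Parameter-count report per submodule
#'
#' @param model a `pd_model`.
#' @return a data.frame with columns `component` and `parameters`, plus a
#'   `TOTAL` row.
#' @export
complexity_report <- function(model) {
  rows <- lapply(names(model$components), function(nm) {
    data.frame(component = nm,
               parameters = param_count(model$store, model$components[[nm]]))
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(component = "TOTAL",
                        parameters = param_count(model$store)))
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry a versioned header, the build configuration and all
#' parameters and running statistics, so a round-trip reproduces the model
#' exactly.
#'
#' @param model a `pd_model`.
#' @param path file path.
#' @return `path` invisibly (`save_checkpoint`); the restored `pd_model`
#'   (`load_checkpoint`).
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(format = "phenodistill-checkpoint", version = 1L,
              type = model$type, preset = model$preset, config = model$config,
              hidden = if (!is.null(model$lstm)) model$lstm$hidden else NULL,
              seed = model$seed,
              params = model$store$params, state = model$store$state,
              config_hash = digest::digest(model$config))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stopf("checkpoint not found: %s", path)
  obj <- readRDS(path)
  if (!identical(obj$format, "phenodistill-checkpoint"))
    stopf("not a phenodistill checkpoint: %s", path)
  if (obj$version != 1L) stopf("unsupported checkpoint version %s", obj$version)
  model <- if (obj$type == "student") build_student(obj$config, seed = obj$seed)
  else build_teacher(obj$config, hidden = obj$hidden, seed = obj$seed)
  model$store$params <- obj$params
  model$store$state <- obj$state
  model
}

# deep copy of parameters (stores are environments, so models otherwise alias)
copy_params <- function(model) list(params = model$store$params,
                                    state = model$store$state)
restore_params <- function(model, snap) {
  model$store$params <- snap$params
  model$store$state <- snap$state
  model
}
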