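#' Read and validate a frame manifest
#'
#' The manifest is a CSV with header `series_id,frame_index,stage,path`,
#' one row per frame. Stages must lie in 1..8 and `(series_id,
#' frame_index)` must be unique; violations raise an error naming the
#' offending row.
#'
#' @param path manifest CSV path.
#' @return a data.frame of validated frame records.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("series_id", "frame_index", "stage", "path")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stopf("manifest %s is missing column(s): %s", path,
          paste(missing, collapse = ", "))
  if (nrow(df) == 0L) return(df[, need])
  bad <- which(!(df$stage %in% 1:8))
  if (length(bad))
    stopf("manifest row %d: stage %s outside 1..8", bad[1], df$stage[bad[1]])
  key <- paste(df$series_id, df$frame_index)
  dup <- which(duplicated(key))
  if (length(dup))
    stopf("manifest row %d: duplicate (series_id, frame_index) = (%s, %s)",
          dup[1], df$series_id[dup[1]], df$frame_index[dup[1]])
  df[, need]
}

#' Assemble frame records into ordered series samples
#'
#' Groups records by `series_id` and sorts by `frame_index`. Series whose
#' frame count differs from `L` are rejected with a warning (default
#' policy) or padded to length `L` by repeating the earliest frame at the
#' front (`policy = "pad"`; series longer than `L` are always rejected).
#' Each sample's label is the stage of its final frame: the temporal head
#' summarizes the history to classify the *current* state, so the latest
#' frame is the natural target.
#'
#' @param records frame records (from [read_manifest()] or a `pd_data`).
#' @param L required series length (default 30).
#' @param policy `"reject"` or `"pad"` for series shorter than `L`.
#' @param images named list of image arrays keyed by `path`, or `NULL` to
#'   read them from disk via [read_png()] relative to `root`.
#' @param root directory against which manifest paths are resolved.
#' @param label `"final_frame"` (default) or `"majority"` stage.
#' @return a list of `pd_series` samples: each a list with `series_id`,
#'   `frame_index`, `stage` (per frame), `label`, and `images` (list of
#'   `H x W x 3` arrays, one per frame).
#' @export
assemble_series <- function(records, L = 30L, policy = c("reject", "pad"),
                            images = NULL, root = NULL,
                            label = c("final_frame", "majority")) {
  policy <- match.arg(policy)
  label <- match.arg(label)
  if (L < 1L) stopf("L must be >= 1")
  if (inherits(records, "pd_data")) {
    images <- images %||% records$images
    records <- records$records
  }
  get_img <- function(p) {
    if (!is.null(images)) {
      img <- images[[p]]
      if (is.null(img)) stopf("image %s not found in image store", p)
      img
    } else read_png(if (is.null(root)) p else file.path(root, p))
  }
  out <- list()
  for (sid in unique(records$series_id)) {
    rows <- records[records$series_id == sid, , drop = FALSE]
    rows <- rows[order(rows$frame_index), , drop = FALSE]
    if (nrow(rows) != L) {
      if (policy == "reject" || nrow(rows) > L) {
        warning(sprintf("series %s has %d frames (need %d); excluded",
                        sid, nrow(rows), L), call. = FALSE)
        next
      }
      pad <- rows[rep(1L, L - nrow(rows)), , drop = FALSE]
      rows <- rbind(pad, rows)
    }
    stages <- as.integer(rows$stage)
    lab <- if (label == "final_frame") stages[length(stages)] else {
      tab <- table(stages)
      as.integer(names(tab)[which.max(tab)])
    }
    out[[length(out) + 1L]] <- structure(
      list(series_id = sid, frame_index = rows$frame_index, stage = stages,
           label = lab, images = lapply(rows$path, get_img)),
      class = "pd_series")
  }
  out
}

#' Series-level split specification
#'
#' @param ratios three non-negative train/validation/test fractions summing
#'   to 1 (default 0.6/0.2/0.2).
#' @param seed integer seed for the shuffle.
#' @return an object of class `pd_split_spec`.
#' @export
split_spec <- function(ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  if (length(ratios) != 3L || any(ratios < 0))
    stopf("ratios must be three non-negative numbers")
  if (abs(sum(ratios) - 1) > 1e-9) stopf("ratios must sum to 1")
  structure(list(ratios = ratios, seed = as.integer(seed)),
            class = "pd_split_spec")
}

# largest-remainder allocation of `target` units across strata of sizes
# `avail`, capped by availability
.allocate <- function(avail, target) {
  if (target <= 0 || sum(avail) == 0) return(integer(length(avail)))
  share <- avail / sum(avail) * target
  base <- pmin(floor(share), avail)
  left <- target - sum(base)
  if (left > 0) {
    room <- avail - base
    ord <- order(share - floor(share), decreasing = TRUE)
    for (i in ord) {
      if (left == 0) break
      if (room[i] > 0) { base[i] <- base[i] + 1L; left <- left - 1L }
    }
  }
  as.integer(base)
}

#' Split series samples into train/validation/test at the series level
#'
#' The partition is by `series_id` (no series straddles splits) and
#' stratified by label, so every stage reaches every split when counts
#' permit. Overall sizes are `round(n * ratio)` for validation and test
#' with the remainder to train; allocation across label strata uses largest
#' remainders. Deterministic given the seed in `spec`.
#'
#' @param samples list of `pd_series`.
#' @param spec a [split_spec()].
#' @return a list with elements `train`, `val`, `test` (lists of
#'   `pd_series`) and `assignments` (data.frame `series_id,split`).
#' @export
split_series <- function(samples, spec = split_spec()) {
  n <- length(samples)
  if (n < 3L && all(spec$ratios > 0))
    stopf("need at least 3 series for a three-way split (got %d)", n)
  labels <- vapply(samples, function(s) s$label, integer(1))
  n_val <- round(n * spec$ratios[2])
  n_test <- round(n * spec$ratios[3])
  strata <- split(seq_len(n), labels)
  ord <- with_seed(spec$seed, lapply(strata, function(ix) ix[sample.int(length(ix))]))
  avail <- vapply(ord, length, integer(1))
  a_val <- .allocate(avail, n_val)
  # remaining availability for test
  a_test <- .allocate(avail - a_val, n_test)
  assign <- rep("train", n)
  for (k in seq_along(ord)) {
    ix <- ord[[k]]
    if (a_val[k] > 0) assign[ix[seq_len(a_val[k])]] <- "val"
    if (a_test[k] > 0) assign[ix[a_val[k] + seq_len(a_test[k])]] <- "test"
  }
  ids <- vapply(samples, function(s) s$series_id, character(1))
  list(train = samples[assign == "train"],
       val = samples[assign == "val"],
       test = samples[assign == "test"],
       assignments = data.frame(series_id = ids, split = assign,
                                stringsAsFactors = FALSE))
}

#' Augmentation policy for training series
#'
#' @param ops ordered subset of `c("brightness", "flip", "rotation")`.
#' @param expansion_factor integer >= 1; the augmented set holds
#'   `expansion_factor` times the original samples (originals plus
#'   `expansion_factor - 1` augmented copies each).
#' @param brightness_range multiplicative brightness half-range (default
#'   0.2, i.e. factors in `[0.8, 1.2]`).
#' @param rotation_range rotation half-range in degrees (default 15).
#' @param seed integer seed.
#' @return an object of class `pd_augmentation_policy`.
#' @export
augmentation_policy <- function(ops = c("brightness", "flip", "rotation"),
                                expansion_factor = 3L, brightness_range = 0.2,
                                rotation_range = 15, seed = 1L) {
  known <- c("brightness", "flip", "rotation")
  bad <- setdiff(ops, known)
  if (length(bad)) stopf("unknown augmentation op: %s", paste(bad, collapse = ", "))
  if (expansion_factor < 1L) stopf("expansion_factor must be >= 1")
  structure(list(ops = ops, expansion_factor = as.integer(expansion_factor),
                 brightness_range = brightness_range,
                 rotation_range = rotation_range, seed = as.integer(seed)),
            class = "pd_augmentation_policy")
}

img_flip_h <- function(img) img[, rev(seq_len(dim(img)[2])), , drop = FALSE]

img_brightness <- function(img, factor) clamp(img * factor, 0, 1)

# rotate about the image center by `deg` degrees, bilinear sampling with
# edge clamping (matches the replicate padding used elsewhere)
img_rotate <- function(img, deg) {
  d <- dim(img); H <- d[1]; W <- d[2]
  th <- deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- rep(seq_len(H), times = W) - cy
  xx <- rep(seq_len(W), each = H) - cx
  sy <- cy + yy * cos(th) - xx * sin(th)
  sx <- cx + yy * sin(th) + xx * cos(th)
  y0 <- clamp(floor(sy), 1, H); y1 <- clamp(y0 + 1, 1, H)
  x0 <- clamp(floor(sx), 1, W); x1 <- clamp(x0 + 1, 1, W)
  fy <- clamp(sy - y0, 0, 1); fx <- clamp(sx - x0, 0, 1)
  out <- array(0, d)
  for (ch in seq_len(d[3])) {
    p <- img[, , ch]
    v <- (1 - fy) * (1 - fx) * p[cbind(y0, x0)] +
      fy * (1 - fx) * p[cbind(y1, x0)] +
      (1 - fy) * fx * p[cbind(y0, x1)] +
      fy * fx * p[cbind(y1, x1)]
    out[, , ch] <- v
  }
  out
}

#' Expand a training set by temporally coherent augmentation
#'
#' Returns the originals plus `expansion_factor - 1` augmented copies of
#' every series. Each copy draws one brightness factor, one flip decision
#' and one rotation angle and applies them identically to every frame, so
#' an augmented series remains a temporally coherent input for the teacher.
#' Labels and frame counts are preserved; per-stage counts scale exactly by
#' the factor.
#'
#' @param train list of `pd_series`.
#' @param policy an [augmentation_policy()].
#' @return expanded list of `pd_series`; augmented copies carry
#'   `source_id` and have `augmented = TRUE`.
#' @export
augment_training_set <- function(train, policy = augmentation_policy()) {
  if (!inherits(policy, "pd_augmentation_policy"))
    stopf("policy must be an augmentation_policy()")
  if (policy$expansion_factor == 1L) return(train)
  out <- train
  for (i in seq_along(train)) {
    s <- train[[i]]
    for (k in seq_len(policy$expansion_factor - 1L)) {
      pars <- with_seed(substream_seed(policy$seed, i, k), list(
        bright = stats::runif(1, 1 - policy$brightness_range,
                              1 + policy$brightness_range),
        flip = stats::runif(1) < 0.5,
        angle = stats::runif(1, -policy$rotation_range, policy$rotation_range)))
      imgs <- lapply(s$images, function(img) {
        for (op in policy$ops) {
          img <- switch(op,
            brightness = img_brightness(img, pars$bright),
            flip = if (pars$flip) img_flip_h(img) else img,
            rotation = img_rotate(img, pars$angle))
        }
        img
      })
      aug <- s
      aug$series_id <- sprintf("%s_aug%d", s$series_id, k)
      aug$source_id <- s$series_id
      aug$augmented <- TRUE
      aug$images <- imgs
      out[[length(out) + 1L]] <- aug
    }
  }
  out
}

#' Per-stage sample-count summary table
#'
#' One row per stage plus an `ALL` row; columns give the training count
#' before augmentation (augmented copies excluded), after augmentation,
#' validation, test, and the overall total (after-augmentation train + val
#' + test).
#'
#' @param train training samples (possibly augmented).
#' @param val,test validation and test samples.
#' @return a data.frame mirroring the standard per-stage accounting table.
#' @export
dataset_summary <- function(train, val, test) {
  lab <- function(samples) vapply(samples, function(s) s$label, integer(1))
  is_aug <- vapply(train, function(s) isTRUE(s$augmented), logical(1))
  cnt <- function(labels) as.integer(table(factor(labels, levels = 1:8)))
  before <- cnt(lab(train[!is_aug]))
  after <- cnt(lab(train))
  v <- cnt(lab(val)); te <- cnt(lab(test))
  df <- data.frame(stage = stage_names(),
                   train_before_aug = before, train_after_aug = after,
                   val = v, test = te,
                   overall = after + v + te, stringsAsFactors = FALSE)
  rbind(df, data.frame(stage = "ALL", train_before_aug = sum(before),
                       train_after_aug = sum(after), val = sum(v),
                       test = sum(te), overall = sum(after + v + te)))
}

#' Write split assignments as CSV (`series_id,split`)
#' @param split result of [split_series()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_split_assignments <- function(split, path) {
  utils::write.csv(split$assignments, path, row.names = FALSE)
  invisible(path)
}
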