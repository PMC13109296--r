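#' Configuration for the synthetic growth-stage image generator
#'
#' The generator emulates the statistical structure a series-to-stage
#' classifier assumes: each series follows a monotone latent growth state
#' `g` on `[0, 1]`, binned into 8 equal-width ordinal stages; single frames
#' are rendered from a noisy observation of `g` (standard deviation
#' `sigma`, in latent units, so adjacent stages overlap in appearance when
#' `sigma` is large relative to the stage-bin width 1/8), while the ordered
#' series as a whole pins the trajectory down — the ambiguity knob that
#' separates a temporal teacher from a single-frame student.
#'
#' @param n_series number of series to generate (default 200).
#' @param frames_per_series frames per series (default 30).
#' @param image_size square image side in pixels (default 32).
#' @param sigma appearance-noise scale in latent growth units (>= 0,
#'   default 0.05; the stage-bin width is 0.125).
#' @param growth_step_mean,growth_step_sd per-frame latent growth increment
#'   mean and standard deviation (increments are clamped at 0 so trajectories
#'   never decrease).
#' @param brightness_jitter per-frame multiplicative brightness jitter
#'   half-range (default 0.05).
#' @param geometry_jitter scale of random element placement jitter in
#'   `[0, 1]` (default 1: fully random placement).
#' @param seed global integer seed; per-series substreams are derived by
#'   counter-based splitting, so earlier series are unchanged when
#'   `n_series` grows.
#' @return an object of class `pd_synth_config`.
#' @export
synth_config <- function(n_series = 200L, frames_per_series = 30L,
                         image_size = 32L, sigma = 0.05,
                         growth_step_mean = 0.012, growth_step_sd = 0.004,
                         brightness_jitter = 0.05, geometry_jitter = 1,
                         seed = 1L) {
  chk <- function(ok, field, what) if (!ok) stopf("invalid %s: %s", field, what)
  chk(is.numeric(n_series) && n_series >= 1, "n_series", "must be a positive count")
  chk(is.numeric(frames_per_series) && frames_per_series >= 1,
      "frames_per_series", "must be a positive count")
  chk(is.numeric(image_size) && image_size >= 8 && image_size %% 2 == 0,
      "image_size", "must be an even count >= 8")
  chk(is.numeric(sigma) && sigma >= 0, "sigma", "must be >= 0")
  chk(is.numeric(growth_step_mean) && growth_step_mean >= 0,
      "growth_step_mean", "must be >= 0")
  chk(is.numeric(growth_step_sd) && growth_step_sd >= 0,
      "growth_step_sd", "must be >= 0")
  chk(is.numeric(brightness_jitter) && brightness_jitter >= 0 &&
        brightness_jitter < 1, "brightness_jitter", "must be in [0, 1)")
  chk(is.numeric(geometry_jitter) && geometry_jitter >= 0 &&
        geometry_jitter <= 1, "geometry_jitter", "must be in [0, 1]")
  chk(is.numeric(seed) && abs(seed) < 2^31, "seed", "must be a 32-bit integer")
  structure(list(n_series = as.integer(n_series),
                 frames_per_series = as.integer(frames_per_series),
                 image_size = as.integer(image_size), n_stages = 8L,
                 sigma = sigma, growth_step_mean = growth_step_mean,
                 growth_step_sd = growth_step_sd,
                 brightness_jitter = brightness_jitter,
                 geometry_jitter = geometry_jitter, seed = as.integer(seed)),
            class = "pd_synth_config")
}

#' Ordinal stage from a latent growth state
#'
#' `stage(g) = 1 + floor(clamp(g, 0, 1) * 8)`, clamped to 8, so the unit
#' interval is split into 8 equal-width stage bins.
#'
#' @param g numeric latent growth value(s).
#' @param n_stages number of stages (default 8).
#' @return integer stage(s) in `1..n_stages`.
#' @export
stage_from_growth <- function(g, n_stages = 8L) {
  pmin(1L + as.integer(floor(clamp(g, 0, 1) * n_stages)), n_stages)
}

#' Stage names in ordinal order
#' @return character vector of the 8 stage names.
#' @export
stage_names <- function() {
  c("emergence", "tillering", "jointing", "booting",
    "heading", "anthesis", "filling", "maturity")
}

#' Generate one monotone latent growth trajectory
#'
#' Draws a target final growth state uniformly over `[0.02, 0.98]` (so final
#' stages are roughly balanced across series), draws non-negative per-frame
#' increments, and anchors the cumulative path at the target; values are
#' clamped to `[0, 1]`, which preserves monotonicity.
#'
#' @param config a [synth_config()].
#' @param series_index 1-based series counter selecting the substream.
#' @return a `pd_trajectory`: list with `series_id`, `g` (non-decreasing
#'   numeric vector of length `frames_per_series`) and `stage` (per-frame
#'   stage labels, non-decreasing).
#' @export
generate_trajectory <- function(config, series_index = 1L) {
  if (!inherits(config, "pd_synth_config")) stopf("invalid config: not a pd_synth_config")
  L <- config$frames_per_series
  with_seed(substream_seed(config$seed, series_index, 1L), {
    steps <- if (L > 1L)
      pmax(0, stats::rnorm(L - 1L, config$growth_step_mean, config$growth_step_sd))
    else numeric(0)
    g_final <- stats::runif(1, 0.02, 0.98)
    g <- clamp(g_final - sum(steps) + c(0, cumsum(steps)), 0, 1)
    structure(list(series_id = sprintf("S%04d", series_index), g = g,
                   stage = stage_from_growth(g, config$n_stages)),
              class = "pd_trajectory")
  })
}

# color helpers: linear mix of two RGB triples
.mix <- function(a, b, w) a * (1 - w) + b * w

#' Render one synthetic frame from a latent growth state
#'
#' Appearance is driven by a noisy observation `g_obs = clamp(g + N(0,
#' sigma))` of the latent state: elongated green strokes ("leaves") whose
#' count and length grow with `g_obs` up to the heading boundary (`g = 0.5`),
#' golden ellipse clusters ("spikes") appearing past it, a canopy color that
#' senesces from green toward yellow, plus additive pixel noise. Mean pixel
#' statistics are monotone in `g`, so stages are learnable from single
#' frames up to the ambiguity injected by `sigma`. Uses the current RNG
#' state; seed externally for reproducibility.
#'
#' @param g latent growth state (finite; clamped to `[0, 1]`).
#' @param config a [synth_config()].
#' @return an `H x W x 3` array in `[0, 1]` with attribute `elements`
#'   (named vector: ground-truth `n_strokes`, `n_spikes`, and the rendered
#'   `g_obs`) for oracle-checkable renderer tests.
#' @export
render_frame <- function(g, config) {
  if (!is.finite(g)) stopf("g must be finite")
  s <- config$image_size
  g_obs <- clamp(g + stats::rnorm(1, 0, config$sigma), 0, 1)

  soil <- c(0.38, 0.30, 0.20)
  veg <- .mix(c(0.10, 0.48, 0.14), c(0.72, 0.66, 0.20), g_obs)
  spikecol <- c(0.82, 0.72, 0.28)

  img <- array(rep(soil, each = s * s), c(s, s, 3))
  img <- img + array(stats::rnorm(s * s, 0, 0.02), c(s, s, 3))

  n_strokes <- as.integer(round(2 + 16 * min(g_obs, 0.5) / 0.5))
  n_spikes <- if (g_obs > 0.5) as.integer(round(10 * (g_obs - 0.5) / 0.5)) else 0L

  jit <- config$geometry_jitter
  for (k in seq_len(n_strokes)) {
    cx <- s / 2 + (stats::runif(1, -0.45, 0.45) * jit) * s
    cy <- s / 2 + (stats::runif(1, -0.45, 0.45) * jit) * s
    ang <- stats::rnorm(1, pi / 2, (1 - 0.6 * g_obs) * 0.8)
    len <- s * (0.18 + 0.22 * g_obs)
    tt <- seq(-len / 2, len / 2, by = 0.5)
    px <- clamp(round(cx + tt * cos(ang)), 1, s)
    py <- clamp(round(cy + tt * sin(ang)), 1, s)
    shade <- stats::runif(1, 0.85, 1.15)
    for (ch in 1:3) img[cbind(py, px, ch)] <- veg[ch] * shade
  }
  if (n_spikes > 0L) {
    xs <- matrix(rep(seq_len(s), each = s), s, s)
    ys <- matrix(rep(seq_len(s), s), s, s)
    for (k in seq_len(n_spikes)) {
      cx <- s / 2 + (stats::runif(1, -0.4, 0.4) * jit) * s
      cy <- s / 2 + (stats::runif(1, -0.4, 0.4) * jit) * s
      a <- s * 0.065; b <- s * 0.035
      mask <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
      shade <- stats::runif(1, 0.9, 1.1)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[mask] <- spikecol[ch] * shade
        img[, , ch] <- plane
      }
    }
  }
  bright <- stats::runif(1, 1 - config$brightness_jitter,
                         1 + config$brightness_jitter)
  img <- img * bright
  img <- img + array(stats::rnorm(s * s * 3, 0, config$sigma * 0.6), c(s, s, 3))
  img <- clamp(img, 0, 1)
  attr(img, "elements") <- c(n_strokes = n_strokes, n_spikes = n_spikes,
                             g_obs = g_obs)
  img
}

#' Generate a complete labelled synthetic dataset
#'
#' Generates `n_series` growth trajectories and renders every frame. With
#' `dir = NULL` the images stay in memory (named by their manifest path
#' key); otherwise PNG files and a `manifest.csv` with header
#' `series_id,frame_index,stage,path` are written under `dir`. Identical
#' `(config, seed)` yield bit-identical manifests and pixel arrays.
#'
#' @param config a [synth_config()].
#' @param dir output directory, or `NULL` for an in-memory dataset.
#' @return (invisibly, when writing) a `pd_data` object: list with
#'   `records` (the manifest data.frame), `images` (named list of arrays),
#'   `stage_counts` (per-stage series counts by final-frame label) and
#'   `config`.
#' @export
generate_dataset <- function(config = synth_config(), dir = NULL) {
  if (!is.null(dir)) {
    dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(dir)) stopf("cannot create output directory %s", dir)
  }
  n <- config$n_series; L <- config$frames_per_series
  records <- vector("list", n)
  images <- vector("list", n * L)
  keys <- character(n * L)
  final_stage <- integer(n)
  for (i in seq_len(n)) {
    tr <- generate_trajectory(config, i)
    paths <- sprintf("images/%s_f%02d.png", tr$series_id, seq_len(L))
    for (t in seq_len(L)) {
      img <- with_seed(substream_seed(config$seed, i, 100L + t),
                       render_frame(tr$g[t], config))
      attr(img, "elements") <- NULL
      idx <- (i - 1L) * L + t
      images[[idx]] <- img
      keys[idx] <- paths[t]
      if (!is.null(dir)) write_png(img, file.path(dir, paths[t]))
    }
    final_stage[i] <- tr$stage[L]
    records[[i]] <- data.frame(series_id = tr$series_id,
                               frame_index = seq_len(L),
                               stage = tr$stage, path = paths,
                               stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, records)
  names(images) <- keys
  if (!is.null(dir))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  counts <- table(factor(final_stage, levels = 1:8))
  out <- structure(list(records = manifest, images = images,
                        stage_counts = stats::setNames(as.integer(counts),
                                                       stage_names()),
                        config = config),
                   class = "pd_data")
  if (is.null(dir)) out else invisible(out)
}

#' Single-frame nearest-centroid pilot accuracy
#'
#' A deliberately simple yardstick for the generator's ambiguity knob: mean
#' per-stage pixel centroids are fit on the frames of a training fraction of
#' series and single frames of the held-out series are classified by nearest
#' centroid. As `sigma` grows, adjacent stages overlap more and this
#' accuracy falls — the gap a temporal model can recover.
#'
#' @param config a [synth_config()].
#' @param train_fraction fraction of series used to fit centroids.
#' @return overall accuracy on held-out frames.
#' @export
pilot_frame_accuracy <- function(config, train_fraction = 0.7) {
  data <- generate_dataset(config)
  n <- config$n_series
  n_train <- max(1L, floor(n * train_fraction))
  ids <- unique(data$records$series_id)
  train_ids <- ids[seq_len(n_train)]
  is_train <- data$records$series_id %in% train_ids
  X <- t(vapply(data$images, as.vector,
                numeric(3 * config$image_size^2)))
  y <- data$records$stage
  centroids <- lapply(1:8, function(k) {
    sel <- is_train & y == k
    if (!any(sel)) return(NULL)
    colMeans(X[sel, , drop = FALSE])
  })
  have <- !vapply(centroids, is.null, logical(1))
  Cm <- do.call(rbind, centroids[have])
  lv <- (1:8)[have]
  Xe <- X[!is_train, , drop = FALSE]
  d2 <- outer(rowSums(Xe^2), rep(1, nrow(Cm))) - 2 * Xe %*% t(Cm) +
    outer(rep(1, nrow(Xe)), rowSums(Cm^2))
  pred <- lv[max.col(-d2, ties.method = "first")]
  mean(pred == y[!is_train])
}
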