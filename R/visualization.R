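# Fixed colormap and overlay settings so panels are byte-stable across runs.
.heat_stops <- matrix(c(0.267, 0.005, 0.329,   # viridis-like anchors
                        0.283, 0.141, 0.458,
                        0.254, 0.265, 0.530,
                        0.207, 0.372, 0.553,
                        0.164, 0.471, 0.558,
                        0.128, 0.567, 0.551,
                        0.135, 0.659, 0.518,
                        0.267, 0.749, 0.441,
                        0.478, 0.821, 0.318,
                        0.741, 0.873, 0.150,
                        0.993, 0.906, 0.144), ncol = 3, byrow = TRUE)

heat_color <- function(v) {
  # v in [0,1] -> H x W x 3 via piecewise-linear interpolation of the stops
  n <- nrow(.heat_stops)
  pos <- clamp(v, 0, 1) * (n - 1)
  lo <- pmin(floor(pos) + 1, n); hi <- pmin(lo + 1, n)
  w <- pos - (lo - 1)
  out <- array(0, c(dim(v), 3))
  for (ch in 1:3)
    out[, , ch] <- .heat_stops[lo, ch] * (1 - w) + .heat_stops[hi, ch] * w
  out
}

# parameter-free bilinear upsampling of a map to (H, W)
upsample_bilinear <- function(map, H, W) {
  h0 <- nrow(map); w0 <- ncol(map)
  if (h0 == H && w0 == W) return(map)
  sy <- (seq_len(H) - 0.5) * h0 / H + 0.5
  sx <- (seq_len(W) - 0.5) * w0 / W + 0.5
  y0 <- clamp(floor(sy), 1, h0); y1 <- clamp(y0 + 1, 1, h0)
  x0 <- clamp(floor(sx), 1, w0); x1 <- clamp(x0 + 1, 1, w0)
  fy <- clamp(sy - y0, 0, 1); fx <- clamp(sx - x0, 0, 1)
  A <- map[y0, x0, drop = FALSE]; B <- map[y1, x0, drop = FALSE]
  C <- map[y0, x1, drop = FALSE]; D <- map[y1, x1, drop = FALSE]
  FY <- matrix(fy, H, W); FX <- matrix(fx, H, W, byrow = TRUE)
  A * (1 - FY) * (1 - FX) + B * FY * (1 - FX) + C * (1 - FY) * FX + D * FY * FX
}

minmax_scale <- function(m) {
  rng <- range(m)
  if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
}

#' Render an attention-interpretability panel
#'
#' Writes a PNG showing the input frame followed by the five per-layer
#' attention heatmaps (upsampled bilinearly to the input resolution,
#' min-max scaled per map, fixed colormap, overlay alpha 0.65 on the
#' grayscale input), in layer order. For a teacher the maps come from the
#' final frame of the series. Output is byte-deterministic.
#'
#' @param model a trained `pd_model` (student or teacher).
#' @param input an `H x W x 3` image (student) or list of frames (teacher).
#' @param path output PNG path.
#' @param dump_csv optional path: also write the raw per-layer maps as a
#'   long CSV (`layer,row,col,value`).
#' @return `path`, invisibly; the composed panel array is attached as
#'   attribute `"panel"`.
#' @export
render_attention_panel <- function(model, input, path, dump_csv = NULL) {
  if (!inherits(model, "pd_model")) stopf("model must be a pd_model")
  if (model$type == "teacher") {
    if (is.array(input)) input <- list(input)
    fw <- teacher_forward(model, input, taps = TRUE)
    frame <- input[[length(input)]]
  } else {
    frame <- if (is.list(input)) input[[length(input)]] else input
    fw <- student_forward(model, frame, taps = TRUE)
  }
  if (!all(is.finite(fw$logits))) stopf("model produced non-finite logits")
  H <- dim(frame)[1]; W <- dim(frame)[2]
  gray <- (frame[, , 1] + frame[, , 2] + frame[, , 3]) / 3
  alpha <- 0.65
  sep <- 2L
  panels <- vector("list", 6L)
  panels[[1]] <- frame
  for (l in 1:5) {
    hm <- minmax_scale(upsample_bilinear(fw$attention[[l]]$map, H, W))
    col <- heat_color(hm)
    over <- array(0, c(H, W, 3))
    for (ch in 1:3) over[, , ch] <- (1 - alpha) * gray + alpha * col[, , ch]
    panels[[l + 1]] <- over
  }
  out <- array(1, c(H, 6L * W + 5L * sep, 3L))
  for (i in 1:6) {
    x0 <- (i - 1L) * (W + sep)
    out[, x0 + seq_len(W), ] <- panels[[i]]
  }
  write_png(out, path)
  if (!is.null(dump_csv)) {
    rows <- do.call(rbind, lapply(1:5, function(l) {
      m <- fw$attention[[l]]$map
      data.frame(layer = l, row = rep(seq_len(nrow(m)), ncol(m)),
                 col = rep(seq_len(ncol(m)), each = nrow(m)),
                 value = as.vector(m))
    }))
    utils::write.csv(rows, dump_csv, row.names = FALSE)
  }
  invisible(structure(path, panel = out))
}
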