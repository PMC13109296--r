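#' Loss configuration for distillation with attention transfer
#'
#' Holds the scalar hyperparameters of the combined objective
#' `L = alpha * L_soft + (1 - alpha) * L_hard + beta * L_attention`:
#' the softmax temperature `T` (default 3), the soft/hard mixing weight
#' `alpha` (default 0.7), the attention-transfer weight `beta` (default
#' 0.001) and the set of tap layers whose attention maps are transferred
#' (default layers 1, 3 and 4).
#'
#' The soft term is not rescaled by `T^2`; set `scale_soft_by_T2 = TRUE`
#' to opt in to the classic gradient-magnitude-preserving variant.
#'
#' @param temperature softmax temperature, > 0.
#' @param alpha weight of the soft-label cross-entropy, in `[0, 1]`.
#' @param beta weight of the attention-transfer term, >= 0.
#' @param transfer_layers subset of 1..5; must be non-empty when `beta > 0`.
#' @param scale_soft_by_T2 multiply `L_soft` by `T^2` (off by default).
#' @return an object of class `pd_loss_config`.
#' @export
loss_config <- function(temperature = 3, alpha = 0.7, beta = 0.001,
                        transfer_layers = c(1L, 3L, 4L),
                        scale_soft_by_T2 = FALSE) {
  if (temperature <= 0) stopf("temperature must be > 0 (got %g)", temperature)
  if (alpha < 0 || alpha > 1) stopf("alpha must be in [0, 1] (got %g)", alpha)
  if (beta < 0) stopf("beta must be >= 0 (got %g)", beta)
  transfer_layers <- sort(unique(as.integer(transfer_layers)))
  if (beta > 0 && length(transfer_layers) == 0L)
    stopf("transfer_layers must be non-empty when beta > 0")
  if (length(transfer_layers) && (min(transfer_layers) < 1L || max(transfer_layers) > 5L))
    stopf("transfer_layers must be a subset of 1..5")
  structure(list(temperature = temperature, alpha = alpha, beta = beta,
                 transfer_layers = transfer_layers,
                 scale_soft_by_T2 = scale_soft_by_T2),
            class = "pd_loss_config")
}

.log_eps <- 1e-12

#' Temperature-softened class probabilities
#'
#' `q_i = exp(z_i / T) / sum_j exp(z_j / T)`, computed with max-subtraction
#' for overflow safety. `T = 1` is the standard softmax; larger `T` flattens
#' the distribution toward uniform.
#'
#' @param z numeric vector of logits (finite).
#' @param temperature `T > 0`.
#' @return a probability vector summing to 1.
#' @export
softened_probabilities <- function(z, temperature = 3) {
  if (temperature <= 0) stopf("temperature must be > 0 (got %g)", temperature)
  if (!all(is.finite(z))) stopf("logits must be finite")
  s <- z / temperature
  e <- exp(s - max(s))
  e / sum(e)
}

# row-wise softened softmax for a logits matrix (internal, training hot path)
softmax_rows <- function(Z, temperature = 1) {
  S <- Z / temperature
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

as_onehot <- function(c_label, n) {
  if (length(c_label) == n && all(c_label %in% c(0, 1)) && sum(c_label) == 1)
    return(as.numeric(c_label))
  if (length(c_label) == 1L && c_label >= 1 && c_label <= n) {
    v <- numeric(n); v[c_label] <- 1
    return(v)
  }
  stopf("hard label must be a one-hot vector of length %d or a class index", n)
}

#' Knowledge-distillation loss (soft + hard cross-entropy)
#'
#' `L_soft` is the cross-entropy between the teacher's temperature-softened
#' distribution `p^T` (from logits `v`) and the student's `q^T` (from logits
#' `z`, same temperature); `L_hard` is the cross-entropy between the one-hot
#' ground truth and the student's standard softmax `q^1`. The total is
#' `alpha * L_soft + (1 - alpha) * L_hard`. Logs are clamped at 1e-12.
#'
#' @param v teacher logits (length N).
#' @param z student logits (length N).
#' @param hard ground truth: one-hot vector of length N or a class index.
#' @param cfg a [loss_config()].
#' @return a loss breakdown: list with `L_soft`, `L_hard`, `L_attention`
#'   (zero here), `L_total`.
#' @export
distillation_loss <- function(v, z, hard, cfg = loss_config()) {
  if (length(v) != length(z))
    stopf("teacher and student logits differ in length (%d vs %d)",
          length(v), length(z))
  n <- length(z)
  cvec <- as_onehot(hard, n)
  Tt <- cfg$temperature
  pT <- softened_probabilities(v, Tt)
  qT <- softened_probabilities(z, Tt)
  q1 <- softened_probabilities(z, 1)
  L_soft <- -sum(pT * log(pmax(qT, .log_eps)))
  if (cfg$scale_soft_by_T2) L_soft <- L_soft * Tt^2
  L_hard <- -sum(cvec * log(pmax(q1, .log_eps)))
  total <- cfg$alpha * L_soft + (1 - cfg$alpha) * L_hard
  list(L_soft = L_soft, L_hard = L_hard, L_attention = 0, L_total = total)
}

map_of <- function(m) if (inherits(m, "pd_attention_map")) m$map else m

#' Attention-transfer loss between paired attention maps
#'
#' For each selected layer, the L2 norm of the difference between the
#' (L2-normalized, flattened) student and teacher attention maps; the loss
#' is the sum over the selected layers.
#'
#' @param student_maps,teacher_maps lists of 5 attention maps
#'   ([attention_from_activation()] objects or plain matrices), ordered by
#'   layer.
#' @param layers integer subset of 1..5 to transfer.
#' @return scalar loss, with per-layer terms in attribute `"per_layer"`.
#' @export
attention_loss <- function(student_maps, teacher_maps,
                           layers = c(1L, 3L, 4L)) {
  layers <- sort(unique(as.integer(layers)))
  if (max(layers) > length(student_maps) || max(layers) > length(teacher_maps))
    stopf("maps are not available for all requested layers")
  per <- vapply(layers, function(i) {
    a <- map_of(student_maps[[i]]); b <- map_of(teacher_maps[[i]])
    if (!all(dim(a) == dim(b)))
      stopf("attention map shape mismatch at layer %d (%s vs %s)", i,
            paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
    sqrt(sum((a - b)^2))
  }, numeric(1))
  structure(sum(per), per_layer = stats::setNames(per, paste0("layer", layers)))
}

#' Combined distillation + attention-transfer objective
#'
#' `L = alpha * L_soft + (1 - alpha) * L_hard + beta * L_attention`, with
#' every term reported individually for component ablations.
#'
#' @inheritParams distillation_loss
#' @param student_maps,teacher_maps attention maps (may be `NULL` when
#'   `beta = 0`).
#' @return a loss breakdown list: `L_soft`, `L_hard`, `L_attention`,
#'   `L_total`.
#' @export
combined_loss <- function(v, z, hard, student_maps = NULL, teacher_maps = NULL,
                          cfg = loss_config()) {
  kd <- distillation_loss(v, z, hard, cfg)
  L_att <- if (cfg$beta > 0) {
    if (is.null(student_maps) || is.null(teacher_maps))
      stopf("attention maps required when beta > 0")
    as.numeric(attention_loss(student_maps, teacher_maps, cfg$transfer_layers))
  } else 0
  list(L_soft = kd$L_soft, L_hard = kd$L_hard, L_attention = L_att,
       L_total = cfg$alpha * kd$L_soft + (1 - cfg$alpha) * kd$L_hard +
         cfg$beta * L_att)
}

## ---- analytic gradients (training internals) -------------------------------

# d(combined KD part)/d(student logits z), one sample
kd_logit_grad <- function(v, z, hard, cfg) {
  n <- length(z)
  cvec <- as_onehot(hard, n)
  Tt <- cfg$temperature
  pT <- softened_probabilities(v, Tt)
  qT <- softened_probabilities(z, Tt)
  q1 <- softened_probabilities(z, 1)
  soft_scale <- if (cfg$scale_soft_by_T2) Tt else 1 / Tt
  cfg$alpha * soft_scale * (qT - pT) + (1 - cfg$alpha) * (q1 - cvec)
}

# gradient of || A(a) - A_T ||_2 with respect to the raw activation a
# (H x W x C), where A(a) is the normalized channel-sum-of-squares map.
attention_grad_activation <- function(activation, teacher_map) {
  d <- dim(activation)
  m <- matrix(activation^2, d[1] * d[2], d[3])
  s <- rowSums(m)                       # unnormalized map, flattened
  nrm <- sqrt(sum(s^2))
  tmap <- as.vector(map_of(teacher_map))
  if (nrm <= 0) return(array(0, d))
  A <- s / nrm
  diffn <- sqrt(sum((A - tmap)^2))
  if (diffn <= .log_eps) return(array(0, d))
  gA <- (A - tmap) / diffn
  gs <- (gA - sum(A * gA) * A) / nrm
  array(as.vector(gs) * matrix(2 * activation, d[1] * d[2], d[3]), d)
}

#' Write a per-step loss-breakdown log as CSV
#'
#' @param log data.frame with columns `step`, `L_soft`, `L_hard`,
#'   `L_attention`, `L_total`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_loss_log <- function(log, path) {
  utils::write.csv(log[, c("step", "L_soft", "L_hard", "L_attention",
                           "L_total")], path, row.names = FALSE)
  invisible(path)
}
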