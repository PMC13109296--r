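#' All non-empty subsets of the five attention tap layers
#'
#' @return a list of 31 integer vectors (every non-empty subset of 1..5),
#'   ordered by cardinality.
#' @export
all_layer_subsets <- function() {
  out <- list()
  for (m in 1:5) {
    cmb <- utils::combn(5L, m)
    for (j in seq_len(ncol(cmb))) out[[length(out) + 1L]] <- cmb[, j]
  }
  out
}

#' The reduced layer-sweep grid
#'
#' The five singletons plus the shallow+deep fusion `{1,3,4}` and the
#' background-prone pair `{2,5}` — the highlighted best/worst contrast of
#' the full sweep at a fraction of the cost.
#'
#' @return a list of 7 integer vectors.
#' @export
quick_layer_subsets <- function() {
  c(lapply(1:5, identity), list(c(1L, 3L, 4L), c(2L, 5L)))
}

#' Ablation grid specification
#'
#' @param subsets list of integer layer subsets (unique, non-empty subsets
#'   of 1..5); default the full 31-subset enumeration.
#' @param modes subset of `c("baseline", "kd", "kd_at")`.
#' @param seeds integer vector of training seeds.
#' @return an object of class `pd_ablation_grid`.
#' @export
ablation_grid <- function(subsets = all_layer_subsets(),
                          modes = c("baseline", "kd", "kd_at"),
                          seeds = c(1L, 2L, 3L)) {
  keys <- vapply(subsets, function(s) paste(sort(s), collapse = ","), character(1))
  if (any(duplicated(keys))) stopf("layer subsets must be unique")
  if (any(vapply(subsets, length, integer(1)) == 0L))
    stopf("layer subsets must be non-empty")
  bad <- setdiff(modes, c("baseline", "kd", "kd_at"))
  if (length(bad)) stopf("unknown mode: %s", paste(bad, collapse = ", "))
  structure(list(subsets = subsets, modes = modes, seeds = as.integer(seeds)),
            class = "pd_ablation_grid")
}

subset_key <- function(s) paste(sort(s), collapse = "+")

# shared scaffolding: one teacher and one student init per seed, so ablation
# arms differ only in their loss configuration
train_arms <- function(data, grid, config, model_config, hidden, arms,
                       verbose = FALSE) {
  rows <- list()
  for (seed in grid$seeds) {
    cfg_seed <- config
    cfg_seed$seed <- as.integer(seed)
    needs_teacher <- any(vapply(arms, function(a) a$mode != "baseline", logical(1)))
    teacher <- NULL
    if (needs_teacher) {
      if (verbose) message(sprintf("seed %d: training teacher", seed))
      teacher <- train_teacher(data$train, data$val, cfg_seed, model_config,
                               hidden = hidden)$model
    }
    init <- copy_params(build_student(model_config, seed = cfg_seed$seed))
    for (arm in arms) {
      cfg_arm <- cfg_seed
      if (!is.null(arm$layers))
        cfg_arm$loss$transfer_layers <- sort(as.integer(arm$layers))
      if (verbose)
        message(sprintf("seed %d: student %s [%s]", seed, arm$mode,
                        subset_key(arm$layers %||% integer(0))))
      fit <- train_student(data$train, data$val, teacher, cfg_arm,
                           mode = arm$mode, model_config = model_config,
                           init = init)
      test_rep <- evaluate_model(fit$model, data$test)
      val_rep <- evaluate_model(fit$model, data$val)
      rows[[length(rows) + 1L]] <- list(
        row = data.frame(
          mode = arm$mode,
          layers = if (arm$mode == "kd_at")
            subset_key(cfg_arm$loss$transfer_layers) else "",
          OA = test_rep$OA, MAE = test_rep$MAE, F1 = test_rep$macro_f1,
          Kappa = test_rep$kappa, seed = seed, stringsAsFactors = FALSE),
        val = val_rep)
    }
  }
  res <- do.call(rbind, lapply(rows, function(r) r$row))
  attr(res, "val_reports") <- lapply(rows, function(r) r$val)
  class(res) <- c("pd_ablation_result", "data.frame")
  res
}

#' Component ablation: baseline vs KD vs KD+AT
#'
#' Trains the requested student modes under identical data splits, teacher
#' and initial student weights for each seed, so performance differences are
#' attributable to the ablated loss component. Emits one row per
#' (mode, seed) with test-set metrics; validation reports are attached as
#' the `"val_reports"` attribute.
#'
#' @param data a list with `train`, `val`, `test` (lists of `pd_series`),
#'   e.g. from [split_series()].
#' @param grid an [ablation_grid()] (its `subsets` are ignored here; the
#'   KD+AT arm uses `config$loss$transfer_layers`).
#' @param config a [train_config()].
#' @param model_config a [backbone_config()].
#' @param hidden teacher LSTM hidden size.
#' @param verbose print progress.
#' @return a `pd_ablation_result` data.frame with columns
#'   `mode, layers, OA, MAE, F1, Kappa, seed`.
#' @export
run_component_ablation <- function(data, grid = ablation_grid(),
                                   config = train_config(),
                                   model_config = backbone_config(),
                                   hidden = NULL, verbose = FALSE) {
  arms <- lapply(grid$modes, function(m)
    list(mode = m,
         layers = if (m == "kd_at") config$loss$transfer_layers else NULL))
  train_arms(data, grid, config, model_config, hidden, arms, verbose)
}

#' Layer-subset attention-transfer sweep
#'
#' One KD+AT training per layer subset per seed (teacher and student
#' initialization shared within a seed). Results carry the panel grouping
#' used to present the sweep: subsets of size 1; 2; 3; and 4–5.
#'
#' @inheritParams run_component_ablation
#' @return a `pd_ablation_result` with columns
#'   `mode, layers, OA, MAE, F1, Kappa, seed` plus `panel`.
#' @export
run_layer_sweep <- function(data, grid = ablation_grid(),
                            config = train_config(),
                            model_config = backbone_config(),
                            hidden = NULL, verbose = FALSE) {
  arms <- lapply(grid$subsets, function(s) list(mode = "kd_at", layers = s))
  res <- train_arms(data, grid, config, model_config, hidden, arms, verbose)
  card <- vapply(strsplit(res$layers, "\\+"), length, integer(1))
  res$panel <- sweep_panel(card)
  best <- stats::aggregate(OA ~ layers, data = res, FUN = stats::median)
  attr(res, "best_subset") <- best$layers[which.max(best$OA)]
  res
}

sweep_panel <- function(cardinality) {
  c("single layer", "two layers", "three layers", "four or five layers",
    "four or five layers")[cardinality]
}

#' Render an ablation result as the standard summary table
#'
#' Aggregates over seeds (median) into the familiar check-mark layout:
#' one row per mode with OA, MAE, F1 and Kappa.
#'
#' @param result a `pd_ablation_result` from [run_component_ablation()].
#' @return a data.frame with columns
#'   `knowledge_distillation, attention_transfer, OA, MAE, F1, Kappa`.
#' @export
ablation_summary <- function(result) {
  modes <- unique(result$mode)
  rows <- lapply(modes, function(m) {
    sub <- result[result$mode == m, ]
    data.frame(knowledge_distillation = if (m %in% c("kd", "kd_at")) "yes" else "",
               attention_transfer = if (m == "kd_at") "yes" else "",
               OA = stats::median(sub$OA), MAE = stats::median(sub$MAE),
               F1 = stats::median(sub$F1), Kappa = stats::median(sub$Kappa),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
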