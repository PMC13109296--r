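#' Published per-stage series counts
#'
#' The per-stage training/validation/test series counts of the reference
#' wheat phenology study (before augmentation), shipped as a plain-text
#' fixture. Used to exercise the augmentation accounting pipeline without
#' any image data.
#'
#' @return a data.frame with columns `stage`, `train`, `val`, `test`.
#' @export
reference_stage_counts <- function() {
  utils::read.csv(system.file("extdata", "stage_counts.csv",
                              package = "phenodistill"),
                  stringsAsFactors = FALSE)
}

# build placeholder single-frame series with the given per-stage counts
# (tiny constant images; only labels matter for accounting)
counts_to_samples <- function(counts, prefix, px = 2L) {
  img <- array(0.5, c(px, px, 3))
  out <- vector("list", sum(counts))
  k <- 0L
  for (stage in seq_along(counts)) {
    for (i in seq_len(counts[stage])) {
      k <- k + 1L
      out[[k]] <- structure(list(series_id = sprintf("%s_%d_%d", prefix, stage, i),
                                 frame_index = 1L, stage = stage,
                                 label = as.integer(stage),
                                 images = list(img)),
                            class = "pd_series")
    }
  }
  out
}

#' Run the augmentation-accounting pipeline on published counts
#'
#' Instantiates placeholder series with the reference per-stage counts,
#' applies the 3x training augmentation, and returns the
#' [dataset_summary()] table — reproducing the study's printed
#' after-augmentation accounting from its before-augmentation counts.
#'
#' @param counts a data.frame as from [reference_stage_counts()].
#' @param expansion_factor training-set expansion factor (default 3).
#' @return the summary data.frame (8 stage rows plus `ALL`).
#' @export
augmentation_accounting <- function(counts = reference_stage_counts(),
                                    expansion_factor = 3L) {
  train <- counts_to_samples(counts$train, "tr")
  val <- counts_to_samples(counts$val, "va")
  test <- counts_to_samples(counts$test, "te")
  aug <- augment_training_set(
    train, augmentation_policy(expansion_factor = expansion_factor, seed = 1L))
  dataset_summary(aug, val, test)
}
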