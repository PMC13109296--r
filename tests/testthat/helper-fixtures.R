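# Shared tiny fixtures: everything is generated in code at test time.

tiny_synth <- function(n_series = 12L, frames = 4L, size = 16L, sigma = 0.05,
                       seed = 7L) {
  synth_config(n_series = n_series, frames_per_series = frames,
               image_size = size, sigma = sigma, seed = seed)
}

tiny_split <- function(n_series = 12L, frames = 4L, size = 16L, seed = 7L) {
  data <- generate_dataset(tiny_synth(n_series, frames, size, seed = seed))
  samples <- assemble_series(data, L = frames)
  split_series(samples, split_spec(seed = 1L))
}

tiny_backbone <- function(size = 16L, dropout = 0.3) {
  backbone_config(input_size = as.integer(size), dropout = dropout)
}

rand_image <- function(size = 16L, seed = 1L) {
  phenodistill:::with_seed(seed, array(stats::runif(size * size * 3),
                                       c(size, size, 3)))
}

rand_series <- function(L = 3L, size = 16L, seed = 1L) {
  phenodistill:::with_seed(seed, lapply(seq_len(L), function(i)
    array(stats::runif(size * size * 3), c(size, size, 3))))
}

# independent per-definition metric oracles (naive, used only as reference)
oracle_oa <- function(y, p) sum(y == p) / length(y)
oracle_f1 <- function(y, p, K = 8L) {
  f1 <- numeric(K); present <- logical(K)
  for (k in seq_len(K)) {
    tp <- sum(y == k & p == k); fp <- sum(y != k & p == k)
    fn <- sum(y == k & p != k)
    present[k] <- (tp + fp + fn) > 0
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[k] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  mean(f1[present])
}
oracle_kappa <- function(y, p, K = 8L) {
  n <- length(y)
  p0 <- sum(y == p) / n
  pe <- 0
  for (k in seq_len(K)) pe <- pe + sum(y == k) * sum(p == k) / n^2
  (p0 - pe) / (1 - pe)
}
oracle_mae <- function(y, p) sum(abs(y - p)) / length(y)
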