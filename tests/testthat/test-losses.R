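test_that("softened probabilities match the temperature-softmax definition", {
  # uniform logits -> uniform distribution at any temperature
  for (Tt in c(0.5, 1, 3, 10))
    expect_equal(softened_probabilities(rep(0, 8), Tt), rep(1 / 8, 8))
  # two-logit case (3, 0) at T = 3: exp(1)/(exp(1)+1)
  q <- softened_probabilities(c(3, 0), 3)
  expect_equal(q, c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)
  expect_equal(q[1], 0.7310586, tolerance = 1e-6)
  # T = 1 reproduces the standard softmax
  z <- c(0.3, -1.2, 2.5, 0, 1.1, -0.4, 0.9, -2)
  expect_equal(softened_probabilities(z, 1), exp(z) / sum(exp(z)),
               tolerance = 1e-12)
  # raising T drives the max entry monotonically toward uniform
  z <- c(5, 0)
  maxes <- vapply(c(10, 100, 1000), function(Tt)
    max(softened_probabilities(z, Tt)), numeric(1))
  expect_true(all(diff(maxes) < 0))
  # closed form at T = 1000: 1 / (1 + exp(-5/1000))
  expect_equal(maxes[3], 1 / (1 + exp(-5 / 1000)), tolerance = 1e-12)
  expect_error(softened_probabilities(z, 0), "temperature")
  expect_error(softened_probabilities(c(1, NA), 1), "finite")
})

test_that("softened probabilities sum to one across random logits and temperatures", {
  set.seed(42)
  for (Tt in c(0.5, 1, 3, 10)) {
    for (i in 1:250) {
      z <- rnorm(8, sd = runif(1, 0.1, 50))
      expect_lt(abs(sum(softened_probabilities(z, Tt)) - 1), 1e-9)
    }
  }
})

test_that("distillation loss obeys its closed-form identities", {
  cfg <- loss_config()
  # student == teacher with uniform logits: cross-entropy equals the
  # entropy of the uniform 8-class distribution, ln 8
  z <- rep(0.7, 8)
  d <- distillation_loss(z, z, 3L, cfg)
  expect_equal(d$L_soft, log(8), tolerance = 1e-12)
  # confident correct student -> vanishing hard loss
  z_conf <- c(rep(-50, 2), 50, rep(-50, 5))
  expect_lt(distillation_loss(rep(0, 8), z_conf, 3L, cfg)$L_hard, 1e-9)
  # alpha endpoints collapse the total onto one term
  v <- c(1, 0.5, -0.2, 0, 2, -1, 0.3, 0.1)
  z <- c(0.2, -0.4, 1.1, 0, -0.6, 0.9, -1.2, 0.5)
  a1 <- distillation_loss(v, z, 5L, loss_config(alpha = 1))
  a0 <- distillation_loss(v, z, 5L, loss_config(alpha = 0))
  expect_equal(a1$L_total, a1$L_soft)
  expect_equal(a0$L_total, a0$L_hard)
  expect_error(distillation_loss(v[1:4], z, 5L), "length")
  # one-hot input form agrees with the index form
  hot <- numeric(8); hot[5] <- 1
  expect_equal(distillation_loss(v, z, hot, cfg), distillation_loss(v, z, 5L, cfg))
})

test_that("attention loss is a summed per-layer L2 distance", {
  mk <- function(m) attention_from_activation(array(sqrt(m), c(dim(m), 1)))
  id <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_equal(as.numeric(attention_loss(list(mk(id)), list(mk(id)), 1L)), 0)
  # orthogonal unit maps: || (1,0) - (0,1) || = sqrt(2)
  a <- matrix(c(1, 0), 1, 2); b <- matrix(c(0, 1), 1, 2)
  expect_equal(as.numeric(attention_loss(list(mk(a)), list(mk(b)), 1L)),
               sqrt(2), tolerance = 1e-12)
  # additivity over the layer set
  set.seed(9)
  smaps <- lapply(1:5, function(i) mk(matrix(runif(16), 4, 4)))
  tmaps <- lapply(1:5, function(i) mk(matrix(runif(16), 4, 4)))
  tot <- as.numeric(attention_loss(smaps, tmaps, c(1, 3, 4)))
  singles <- vapply(c(1, 3, 4), function(l)
    as.numeric(attention_loss(smaps, tmaps, l)), numeric(1))
  expect_equal(tot, sum(singles), tolerance = 1e-12)
  bad <- list(mk(matrix(runif(9), 3, 3)))
  expect_error(attention_loss(bad, list(mk(a)), 1L), "layer 1")
})

test_that("combined loss assembles the three weighted terms", {
  v <- c(1, 0.5, -0.2, 0, 2, -1, 0.3, 0.1)
  z <- c(0.2, -0.4, 1.1, 0, -0.6, 0.9, -1.2, 0.5)
  # beta = 0 reduces to the distillation loss
  cfg0 <- loss_config(beta = 0)
  expect_equal(combined_loss(v, z, 2L, cfg = cfg0)$L_total,
               distillation_loss(v, z, 2L, cfg0)$L_total)
  # defaults: total = 0.7 Ls + 0.3 Lh + 0.001 La
  set.seed(4)
  act_s <- lapply(1:5, function(i) array(runif(32), c(4, 4, 2)))
  act_t <- lapply(1:5, function(i) array(runif(32), c(4, 4, 2)))
  smaps <- lapply(act_s, attention_from_activation)
  tmaps <- lapply(act_t, attention_from_activation)
  cl <- combined_loss(v, z, 2L, smaps, tmaps, loss_config())
  expect_equal(cl$L_total,
               0.7 * cl$L_soft + 0.3 * cl$L_hard + 0.001 * cl$L_attention,
               tolerance = 1e-12)
  # known constants: 0.5*1 + 0.5*2 + 0.1*3 = 1.8
  expect_equal(0.5 * 1 + (1 - 0.5) * 2 + 0.1 * 3, 1.8)
})

test_that("losses are non-negative, shift-invariant and Gibbs-bounded", {
  set.seed(11)
  for (i in 1:40) {
    v <- rnorm(8, sd = 2); z <- rnorm(8, sd = 2)
    y <- sample(8, 1)
    cl <- distillation_loss(v, z, y, loss_config())
    expect_gte(cl$L_soft, 0); expect_gte(cl$L_hard, 0)
    # Gibbs: cross-entropy >= entropy of the target, equality iff equal
    pT <- softened_probabilities(v, 3)
    expect_gte(cl$L_soft, -sum(pT * log(pT)) - 1e-12)
    # shift invariance of every term
    sh <- distillation_loss(v + 3.7, z - 1.3, y, loss_config())
    expect_equal(sh$L_soft, cl$L_soft, tolerance = 1e-9)
    expect_equal(sh$L_hard, cl$L_hard, tolerance = 1e-9)
  }
  # equality case of Gibbs
  v <- rnorm(8)
  eq <- distillation_loss(v, v, 1L, loss_config())
  pT <- softened_probabilities(v, 3)
  expect_equal(eq$L_soft, -sum(pT * log(pT)), tolerance = 1e-12)
})

test_that("analytic logit gradient matches finite differences", {
  set.seed(21)
  for (i in 1:10) {
    v <- rnorm(8); z <- rnorm(8); y <- sample(8, 1)
    cfg <- loss_config(temperature = sample(c(1, 3, 10), 1),
                       alpha = runif(1))
    g_an <- phenodistill:::kd_logit_grad(v, z, y, cfg)
    g_fd <- vapply(1:8, function(k) {
      h <- 1e-6
      zp <- z; zp[k] <- zp[k] + h
      zm <- z; zm[k] <- zm[k] - h
      (distillation_loss(v, zp, y, cfg)$L_total -
         distillation_loss(v, zm, y, cfg)$L_total) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g_an - g_fd) / pmax(abs(g_fd), 1e-4)), 1e-4)
  }
})

test_that("loss_config validates its domain and keeps the stated defaults", {
  cfg <- loss_config()
  expect_equal(cfg$temperature, 3)
  expect_equal(cfg$alpha, 0.7)
  expect_equal(cfg$beta, 0.001)
  expect_equal(cfg$transfer_layers, c(1L, 3L, 4L))
  expect_false(cfg$scale_soft_by_T2)
  expect_error(loss_config(temperature = -1), "temperature")
  expect_error(loss_config(alpha = 1.2), "alpha")
  expect_error(loss_config(beta = 0.1, transfer_layers = integer(0)),
               "non-empty")
  # opt-in T^2 rescaling multiplies the soft term only
  v <- rnorm(8); z <- rnorm(8)
  plain <- distillation_loss(v, z, 1L, loss_config())
  scaled <- distillation_loss(v, z, 1L, loss_config(scale_soft_by_T2 = TRUE))
  expect_equal(scaled$L_soft, plain$L_soft * 9, tolerance = 1e-9)
})
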