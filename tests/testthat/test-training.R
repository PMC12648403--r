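# shared tiny training fixtures: short-sequence signal datasets with a
# planted motif, and a small hybrid model
tiny_sim_dataset <- function(consensus = "TGACTCAG", seed = 17, n_sites = 12) {
  sim <- simulate_dataset(sim_config(
    genome_length = 150000, n_sites = n_sites, min_site_gap = 1500,
    primary_pwm = pwm_from_consensus(consensus, 0.95), seed = seed))
  build_dataset(sim$genome, sim$peaks, sim$signal, task = "signal",
                length = 250, seed = seed)
}

tiny_train_model <- function(L = 250L) {
  build_model(model_config(
    task = "signal", input_length = L, first_layer = "quantum",
    qconv = qconv_config(n_qubits = 2, k_target = 8, n_layers = 1),
    channels = c(6L, 8L, 10L), pools = c(5L, 5L, 5L),
    kernels = c(conv2 = 5L, conv3 = 5L, bottleneck = 3L, decoder = 3L),
    dec_channels = 4L))
}

test_that("hard negative mining loss matches the hand-computed toy case", {
  # labels [1,0,0,0], preds [.9,.8,.2,.1], r=1: keep the positive (BCE 0.10536)
  # and the single hardest negative (BCE(0.8;0) = 1.60944)
  got <- hard_negative_mining_loss(c(0.9, 0.8, 0.2, 0.1), c(1, 0, 0, 0), r = 1)
  expect_equal(got, (-log(0.9) - log(1 - 0.8)) / 2, tolerance = 1e-9)
  expect_equal(got, 0.85740, tolerance = 1e-4)
})

test_that("mining reduces to plain BCE when all bases are kept", {
  set.seed(1)
  p <- runif(50, 0.05, 0.95)
  y <- rbinom(50, 1, 0.5)
  plain <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
  expect_equal(hard_negative_mining_loss(p, y, r = Inf), plain, tolerance = 1e-9)
  expect_equal(hard_negative_mining_loss(p, rep(1, 50), r = 3), mean(-log(p)),
               tolerance = 1e-9)
  # perfect clamped predictions floor at the clamp bound's BCE
  expect_lte(hard_negative_mining_loss(rep(1, 10), rep(1, 10), r = 3),
             -log(1 - 1e-7) + 1e-9)
  expect_error(hard_negative_mining_loss(c(0.5), c(1, 0)), "mismatch")
})

test_that("mining gradient matches finite differences", {
  set.seed(2)
  p <- runif(30, 0.1, 0.9)
  y <- rbinom(30, 1, 0.3)
  g <- hnm_loss_grad(p, y, r = 2)$grad
  h <- 1e-7
  for (k in sample(30, 6)) {
    pp <- p; pp[k] <- pp[k] + h
    pm <- p; pm[k] <- pm[k] - h
    num <- (hnm_loss_grad(pp, y, 2)$loss - hnm_loss_grad(pm, y, 2)$loss) / (2 * h)
    expect_equal(g[k], num, tolerance = 1e-5)
  }
})

test_that("RMSE loss is exact, homogeneous, and zero on identical vectors", {
  expect_equal(rmse_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse_loss(c(0, 0), c(3, 4)), sqrt(12.5), tolerance = 1e-9)
  expect_equal(rmse_loss(c(0, 0), c(3, 4)), 3.5355, tolerance = 1e-4)
  set.seed(3)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(rmse_loss(2.5 * a, 2.5 * b), 2.5 * rmse_loss(a, b),
               tolerance = 1e-9)
})

test_that("nested down-sampling produces strictly nested subsets", {
  peaks <- data.frame(chrom = "c", start = 1:40, end = 2:41,
                      peak_position = 1:40, signal_value = 1)
  subs <- downsample_nested(peaks, c(5, 10, 20), seed = 4)
  expect_true(all(subs[["5"]]$start %in% subs[["10"]]$start))
  expect_true(all(subs[["10"]]$start %in% subs[["20"]]$start))
  expect_equal(nrow(downsample_nested(peaks, 40, seed = 1)[[1]]), 40)
  expect_error(downsample_nested(peaks, c(10, 50)), "exceeds")
  expect_equal(downsample_ladder(30000),
               c(250L, 500L, 750L, 1000L, 1500L, 3000L, 6000L, 12000L,
                 24000L, 30000L))
})

test_that("training runs, is seed-deterministic, improves on untrained loss, and moves theta", {
  ds <- tiny_sim_dataset()
  set.seed(5)
  m <- tiny_train_model()
  cfg <- train_config(max_epochs = 40, patience = 6, batch_size = 8, seed = 7)
  untrained_loss <- mean(vapply(seq_along(ds$examples), function(i) {
    rmse_loss(predict(m, ds$examples[[i]]$onehot), ds$examples[[i]]$label)
  }, numeric(1)))
  fit1 <- train(m, ds, cfg, epochs = 3)
  fit2 <- train(m, ds, cfg, epochs = 3)
  expect_identical(fit1$history, fit2$history)
  expect_equal(nrow(fit1$history), 3)
  expect_true(all(is.finite(fit1$history$val_loss)))
  trained_loss <- mean(vapply(seq_along(ds$examples), function(i) {
    rmse_loss(predict(fit1$model, ds$examples[[i]]$onehot),
              ds$examples[[i]]$label)
  }, numeric(1)))
  expect_lt(trained_loss, untrained_loss)
  expect_gt(max(abs(fit1$model$params$first$theta - m$params$first$theta)), 1e-6)
  # identical partitions under the same seed
  expect_identical(fit1$split, fit2$split)
})

test_that("early stopping halts after patience epochs without improvement", {
  ds <- tiny_sim_dataset(seed = 23, n_sites = 8)
  set.seed(6)
  m <- tiny_train_model()
  # lr = 0 freezes the model: epoch 1 sets the best, then no improvement
  cfg <- train_config(lr = 0, max_epochs = 40, patience = 2, batch_size = 8,
                      seed = 9)
  fit <- train(m, ds, cfg)
  expect_equal(nrow(fit$history), 1 + 2)
})

test_that("fine-tuning with 0 epochs is the identity; training on the target helps", {
  dsA <- tiny_sim_dataset("TGACTCAG", seed = 31)
  dsB <- tiny_sim_dataset("CACGTGAC", seed = 32)
  set.seed(7)
  m <- tiny_train_model()
  cfg <- train_config(batch_size = 8, seed = 11)
  pre <- train(m, dsA, cfg, epochs = 2)
  frozen <- fine_tune(pre, dsB, cfg, epochs = 0, source_id = "A")
  expect_identical(frozen$model$params, pre$model$params)
  expect_identical(attr(frozen, "source"), "A")
  tuned <- fine_tune(pre, dsB, cfg, epochs = 2, source_id = "A")
  loss_on_B <- function(model) {
    mean(vapply(seq_along(dsB$examples), function(i) {
      rmse_loss(predict(model, dsB$examples[[i]]$onehot), dsB$examples[[i]]$label)
    }, numeric(1)))
  }
  expect_lt(loss_on_B(tuned$model), loss_on_B(pre$model))
})

test_that("the cross/self harness returns paired scores per trial", {
  ds <- tiny_sim_dataset(seed = 41, n_sites = 8)
  set.seed(8)
  m <- tiny_train_model()
  cfg <- train_config(batch_size = 8, seed = 13)
  pre <- train(m, ds, cfg, epochs = 1)
  metric <- function(model, dataset, idx) {
    evaluate_model(model, dataset, idx)$value
  }
  out <- cross_self_harness(pre, ds, cfg, metric, n_trials = 2, epochs = 1)
  expect_equal(nrow(out), 2)
  expect_named(out, c("trial", "cross", "self"))
  expect_true(all(is.finite(out$cross)) && all(is.finite(out$self)))
})
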