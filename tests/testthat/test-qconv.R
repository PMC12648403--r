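test_that("kernel division reproduces the reconstruction identity", {
  expect_equal(unname(kernel_division(4, 16)), c(4L, 13L))
  expect_equal(unname(kernel_division(1, 16)), c(1L, 16L))
  expect_equal(unname(kernel_division(16, 16)), c(16L, 1L))
  for (q in 1:16) {
    kd <- kernel_division(q, 16)
    expect_equal(kd[["k_quantum"]] + kd[["k_classical"]] - 1L, 16L)
  }
  expect_error(kernel_division(17, 16), "exceed")
})

test_that("quantum feature map matches per-window standalone circuit evaluation", {
  set.seed(31)
  cfg <- qconv_config(n_qubits = 4, n_layers = 2)
  p <- init_pqc_params(cfg$spec)
  L <- 30
  base <- sample(1:4, L, replace = TRUE)
  onehot <- matrix(0, L, 4); onehot[cbind(1:L, base)] <- 1
  fm <- quantum_feature_map(onehot, cfg$spec, p)
  expect_equal(dim(fm), c(L - 4L + 1L, 16L))
  expect_true(all(fm >= -1 - 1e-12 & fm <= 1 + 1e-12))
  for (pos in c(1, 13, 27)) {
    for (ch in 1:4) {
      bits <- onehot[pos:(pos + 3), ch]
      want <- pqc_expectations(angle_encode(bits), cfg$spec, p)
      expect_equal(unname(fm[pos, ((ch - 1) * 4 + 1):(ch * 4)]), want,
                   tolerance = 1e-12)
    }
  }
})

test_that("a nucleotide channel absent from the sequence reads out constant +1", {
  set.seed(8)
  cfg <- qconv_config(n_qubits = 3, n_layers = 2)
  p <- init_pqc_params(cfg$spec)
  onehot <- matrix(0, 20, 4)
  onehot[, 1] <- 1  # poly-A: channels C, G, T are all-zero
  # every window of an absent channel encodes to basis index 0, so its
  # readouts are constant across positions; with identity rotations
  # (theta = 0) the state stays |0...0> and the constant is exactly +1
  fm <- quantum_feature_map(onehot, cfg$spec, p)
  for (ch in 2:4) {
    block <- unname(fm[, ((ch - 1) * 3 + 1):(ch * 3)])
    expect_equal(block, matrix(block[1, ], nrow(fm), 3, byrow = TRUE),
                 tolerance = 1e-12)
  }
  p0 <- pqc_params(rep(0, n_params(cfg$spec)), cfg$spec)
  fm0 <- quantum_feature_map(onehot, cfg$spec, p0)
  for (ch in 2:4) {
    expect_equal(unname(fm0[, ((ch - 1) * 3 + 1):(ch * 3)]),
                 matrix(1, nrow(fm0), 3), tolerance = 1e-12)
  }
})

test_that("QConv1 realizes a 16 bp effective receptive field for q in 1..4", {
  set.seed(42)
  for (q in c(1L, 4L)) {
    cfg <- qconv_config(n_qubits = q, n_filters = 8, n_layers = 2)
    expect_equal(cfg$k_classical, 17L - q)
    w <- init_qconv_weights(cfg)
    affected <- probe_receptive_field(
      function(x) qconv1_forward(x, cfg, w), L = 64, position = 32)
    expect_equal(length(affected), 16L)
    expect_equal(affected, seq(min(affected), max(affected)))  # contiguous
    expect_equal(range(affected), c(32 - 7, 32 + 8))
  }
})

test_that("QConv1 output is length-preserving, zero under zero weights, and shift-equivariant", {
  set.seed(9)
  cfg <- qconv_config(n_qubits = 2, n_filters = 6, n_layers = 2)
  w <- init_qconv_weights(cfg)
  L <- 80
  base <- sample(1:4, L, replace = TRUE)
  onehot <- matrix(0, L, 4); onehot[cbind(1:L, base)] <- 1
  y <- qconv1_forward(onehot, cfg, w)
  expect_equal(dim(y), c(L, 6L))

  w0 <- w; w0$W[] <- 0; w0$b[] <- 0
  expect_equal(qconv1_forward(onehot, cfg, w0), matrix(0, L, 6))

  s <- 5L
  shifted <- rbind(onehot[(s + 1):L, ], onehot[1:s, ])
  ys <- qconv1_forward(shifted, cfg, w)
  interior <- 20:(L - 20)
  expect_equal(ys[interior, ], y[interior + s, ], tolerance = 1e-10)
})

test_that("per-channel PQC angles (channel_sharing = FALSE) are honoured", {
  set.seed(12)
  cfg <- qconv_config(n_qubits = 2, n_filters = 4, n_layers = 1,
                      channel_sharing = FALSE)
  w <- init_qconv_weights(cfg)
  expect_equal(dim(w$theta), c(n_params(cfg$spec), 4L))
  onehot <- matrix(0, 24, 4); onehot[cbind(1:24, sample(1:4, 24, TRUE))] <- 1
  y1 <- qconv1_forward(onehot, cfg, w)
  w2 <- w; w2$theta[, 2] <- w2$theta[, 2] + 0.7
  y2 <- qconv1_forward(onehot, cfg, w2)
  expect_gt(max(abs(y1 - y2)), 1e-6)
})

test_that("QConv1 backward gradients match finite differences (theta, W, b)", {
  set.seed(77)
  for (sharing in c(TRUE, FALSE)) {
    cfg <- qconv_config(n_qubits = 2, n_filters = 3, n_layers = 2,
                        k_target = 6, channel_sharing = sharing)
    w <- init_qconv_weights(cfg)
    L <- 20
    onehot <- matrix(0, L, 4); onehot[cbind(1:L, sample(1:4, L, TRUE))] <- 1
    R <- matrix(rnorm(L * 3), L, 3)  # random projection loss: sum(y * R)
    loss <- function(w) sum(qconv1_fwd(onehot, cfg, w)$y * R)

    cache <- qconv1_fwd(onehot, cfg, w)
    tabs_g <- qconv_tables(cfg, w$theta, gradients = TRUE)
    g <- qconv1_bwd(cache, cfg, w, R, tabs_g)

    h <- 1e-6
    for (k in seq_along(w$theta)) {
      wp <- w; wp$theta[k] <- wp$theta[k] + h
      wm <- w; wm$theta[k] <- wm$theta[k] - h
      expect_equal(g$theta[k], (loss(wp) - loss(wm)) / (2 * h),
                   tolerance = 1e-4)
    }
    for (k in sample(length(w$W), 5)) {
      wp <- w; wp$W[k] <- wp$W[k] + h
      wm <- w; wm$W[k] <- wm$W[k] - h
      expect_equal(g$W[k], (loss(wp) - loss(wm)) / (2 * h), tolerance = 1e-4)
    }
    expect_equal(g$b, colSums(R), tolerance = 1e-8)
  }
})

test_that("classical baseline first layer has width-16 field and 64 filters", {
  set.seed(3)
  layer <- build_classical_conv1()
  expect_equal(layer$n_filters, 64L)
  affected <- probe_receptive_field(
    function(x) classical_conv1_forward(x, layer), L = 48, position = 24)
  expect_equal(length(affected), 16L)
  layer$W[] <- 0
  onehot <- matrix(0, 30, 4); onehot[cbind(1:30, sample(1:4, 30, TRUE))] <- 1
  expect_equal(classical_conv1_forward(onehot, layer), matrix(0, 30, 64))
})
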