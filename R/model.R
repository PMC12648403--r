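# Base-resolution predictor: QConv1 (or a classical first convolution), a
# three-stage convolutional encoder with max pooling, a bottleneck, and a
# mirrored decoder with learned upsampling and skip connections, ending in a
# per-base head (sigmoid for binary site classification, linear for signal
# regression). Forward and backward passes are explicit.

#' Configure a predictor model
#'
#' @param task `"binary"` (per-base binding probability, 500 bp default
#'   input) or `"signal"` (transformed-signal regression, 1000 bp default).
#' @param input_length Sequence length L; the product of `pools` must divide
#'   it.
#' @param first_layer `"quantum"` (QConv1) or `"classical"` (plain width-16
#'   convolution), the qubit-ablation switch.
#' @param qconv A [qconv_config()] for the quantum first layer; its
#'   `n_filters` is tied to `channels[1]`.
#' @param channels Encoder channel widths (first = filters of the first
#'   layer).
#' @param pools Three pooling factors; defaults 5,4,5 for 500 bp and 5,5,8
#'   for 1000 bp.
#' @param kernels Named widths for `conv2`, `conv3`, `bottleneck`, `decoder`.
#' @param dec_channels Channel width of the last decoder stage.
#' @param precision `"single"` or `"double"`; recorded task precision
#'   (defaults: binary single, signal double). The statevector simulator is
#'   double precision regardless.
#' @return Object of class `model_config`.
#' @export
model_config <- function(task = c("binary", "signal"), input_length = NULL,
                         first_layer = c("quantum", "classical"),
                         qconv = qconv_config(),
                         channels = c(64L, 96L, 128L), pools = NULL,
                         kernels = c(conv2 = 11L, conv3 = 7L,
                                     bottleneck = 5L, decoder = 5L),
                         dec_channels = 32L, precision = NULL) {
  task <- match.arg(task)
  first_layer <- match.arg(first_layer)
  if (is.null(input_length)) {
    input_length <- if (task == "binary") 500L else 1000L
  }
  input_length <- as.integer(input_length)
  if (is.null(pools)) {
    pools <- switch(as.character(input_length),
                    "500" = c(5L, 4L, 5L),
                    "1000" = c(5L, 5L, 8L),
                    stop("no default pooling for input_length ", input_length,
                         "; supply pools explicitly"))
  }
  pools <- as.integer(pools)
  if (length(pools) != 3L) stop("pools must have length 3")
  if (input_length %% prod(pools) != 0L) {
    stop("product of pooling factors (", prod(pools),
         ") must divide input_length (", input_length, ")")
  }
  if (is.null(precision)) precision <- if (task == "binary") "single" else "double"
  qconv$n_filters <- as.integer(channels[1])
  structure(list(task = task, input_length = input_length,
                 first_layer = first_layer, qconv = qconv,
                 channels = as.integer(channels), pools = pools,
                 kernels = kernels, dec_channels = as.integer(dec_channels),
                 precision = precision),
            class = "model_config")
}

#' Build a predictor model
#'
#' Xavier-initializes every weight, including the PQC rotation angles of the
#' quantum first layer.
#'
#' @param config A [model_config()].
#' @return Object of class `quanv_model` with elements `config`, `params`,
#'   and `n_parameters`.
#' @export
build_model <- function(config) {
  ch <- config$channels
  k <- config$kernels
  first <- if (config$first_layer == "quantum") {
    init_qconv_weights(config$qconv)
  } else {
    list(W = xavier_conv(config$qconv$k_target, 4L, ch[1]),
         b = numeric(ch[1]))
  }
  params <- list(
    first = first,
    conv2 = list(W = xavier_conv(k[["conv2"]], ch[1], ch[2]), b = numeric(ch[2])),
    conv3 = list(W = xavier_conv(k[["conv3"]], ch[2], ch[3]), b = numeric(ch[3])),
    bott = list(W = xavier_conv(k[["bottleneck"]], ch[3], ch[3]), b = numeric(ch[3])),
    dec3 = list(W = xavier_conv(k[["decoder"]], 2L * ch[3], ch[2]), b = numeric(ch[2])),
    dec2 = list(W = xavier_conv(k[["decoder"]], 2L * ch[2], ch[1]), b = numeric(ch[1])),
    dec1 = list(W = xavier_conv(k[["decoder"]], 2L * ch[1], config$dec_channels),
                b = numeric(config$dec_channels)),
    head = list(W = xavier_conv(1L, config$dec_channels, 1L), b = numeric(1))
  )
  n_par <- sum(rapply(params, length, how = "unlist"))
  structure(list(config = config, params = params, n_parameters = n_par),
            class = "quanv_model")
}

#' @export
print.quanv_model <- function(x, ...) {
  cat("quanvseq model:", x$config$task, "task,",
      x$config$input_length, "bp input,",
      x$config$first_layer, "first layer,",
      x$n_parameters, "parameters\n")
  invisible(x)
}

# full forward pass; returns prediction and (optionally) every cache needed
# for the backward sweep. `skips = FALSE` zeroes the skip connections (used
# to verify they are live).
forward_model <- function(model, x, skips = TRUE, want_cache = FALSE,
                          tabs = NULL) {
  cfg <- model$config
  p <- model$params
  k <- cfg$kernels
  if (nrow(x) != cfg$input_length) {
    stop("input length ", nrow(x), " does not match configured length ",
         cfg$input_length)
  }
  if (cfg$first_layer == "quantum") {
    c1 <- qconv1_fwd(x, cfg$qconv, p$first, tabs = tabs)
  } else {
    c1 <- conv1d_same_fwd(x, p$first$W, p$first$b, cfg$qconv$k_target)
  }
  r1 <- relu_fwd(c1$y)
  p1 <- maxpool_fwd(r1$y, cfg$pools[1])
  c2 <- conv1d_same_fwd(p1$y, p$conv2$W, p$conv2$b, k[["conv2"]])
  r2 <- relu_fwd(c2$y)
  p2 <- maxpool_fwd(r2$y, cfg$pools[2])
  c3 <- conv1d_same_fwd(p2$y, p$conv3$W, p$conv3$b, k[["conv3"]])
  r3 <- relu_fwd(c3$y)
  p3 <- maxpool_fwd(r3$y, cfg$pools[3])
  cb <- conv1d_same_fwd(p3$y, p$bott$W, p$bott$b, k[["bottleneck"]])
  rb <- relu_fwd(cb$y)

  sk <- function(s) if (skips) s else s * 0
  u3 <- upsample_fwd(rb$y, cfg$pools[3])
  cat3 <- cbind(u3$y, sk(r3$y))
  d3 <- conv1d_same_fwd(cat3, p$dec3$W, p$dec3$b, k[["decoder"]])
  a3 <- relu_fwd(d3$y)
  u2 <- upsample_fwd(a3$y, cfg$pools[2])
  cat2 <- cbind(u2$y, sk(r2$y))
  d2 <- conv1d_same_fwd(cat2, p$dec2$W, p$dec2$b, k[["decoder"]])
  a2 <- relu_fwd(d2$y)
  u1 <- upsample_fwd(a2$y, cfg$pools[1])
  cat1 <- cbind(u1$y, sk(r1$y))
  d1 <- conv1d_same_fwd(cat1, p$dec1$W, p$dec1$b, k[["decoder"]])
  a1 <- relu_fwd(d1$y)
  hz <- conv1d_same_fwd(a1$y, p$head$W, p$head$b, 1L)
  pred <- if (cfg$task == "binary") sigmoid(hz$y[, 1]) else hz$y[, 1]
  if (!want_cache) return(pred)
  list(pred = pred,
       cache = list(c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2, p2 = p2,
                    c3 = c3, r3 = r3, p3 = p3, cb = cb, rb = rb,
                    u3 = u3, d3 = d3, a3 = a3, u2 = u2, d2 = d2, a2 = a2,
                    u1 = u1, d1 = d1, a1 = a1, hz = hz, skips = skips))
}

# backward sweep; `dpred` is dLoss/dprediction (after the sigmoid for the
# binary task). `tabs_grad` carries the per-window PQC gradient tables when
# the first layer is quantum.
backward_model <- function(model, x, fw, dpred, tabs_grad = NULL) {
  cfg <- model$config
  p <- model$params
  k <- cfg$kernels
  ch <- cfg$channels
  cc <- fw$cache
  dz <- if (cfg$task == "binary") {
    y <- fw$pred
    matrix(dpred * y * (1 - y), ncol = 1)
  } else {
    matrix(dpred, ncol = 1)
  }
  g <- list()
  bh <- conv1d_same_bwd(cc$hz, p$head$W, dz)
  g$head <- list(W = bh$dW, b = bh$db)
  da1 <- relu_bwd(cc$a1, bh$dx)
  b1 <- conv1d_same_bwd(cc$d1, p$dec1$W, da1)
  g$dec1 <- list(W = b1$dW, b = b1$db)
  du1 <- b1$dx[, seq_len(ch[1]), drop = FALSE]
  ds1 <- b1$dx[, ch[1] + seq_len(ch[1]), drop = FALSE]
  if (!cc$skips) ds1 <- ds1 * 0
  da2 <- relu_bwd(cc$a2, upsample_bwd(cc$u1, du1))
  b2 <- conv1d_same_bwd(cc$d2, p$dec2$W, da2)
  g$dec2 <- list(W = b2$dW, b = b2$db)
  du2 <- b2$dx[, seq_len(ch[2]), drop = FALSE]
  ds2 <- b2$dx[, ch[2] + seq_len(ch[2]), drop = FALSE]
  if (!cc$skips) ds2 <- ds2 * 0
  da3 <- relu_bwd(cc$a3, upsample_bwd(cc$u2, du2))
  b3 <- conv1d_same_bwd(cc$d3, p$dec3$W, da3)
  g$dec3 <- list(W = b3$dW, b = b3$db)
  du3 <- b3$dx[, seq_len(ch[3]), drop = FALSE]
  ds3 <- b3$dx[, ch[3] + seq_len(ch[3]), drop = FALSE]
  if (!cc$skips) ds3 <- ds3 * 0
  drb <- relu_bwd(cc$rb, upsample_bwd(cc$u3, du3))
  bb <- conv1d_same_bwd(cc$cb, p$bott$W, drb)
  g$bott <- list(W = bb$dW, b = bb$db)
  dr3 <- relu_bwd(cc$r3, maxpool_bwd(cc$p3, bb$dx)) + relu_bwd(cc$r3, ds3)
  bc3 <- conv1d_same_bwd(cc$c3, p$conv3$W, dr3)
  g$conv3 <- list(W = bc3$dW, b = bc3$db)
  dr2 <- relu_bwd(cc$r2, maxpool_bwd(cc$p2, bc3$dx)) + relu_bwd(cc$r2, ds2)
  bc2 <- conv1d_same_bwd(cc$c2, p$conv2$W, dr2)
  g$conv2 <- list(W = bc2$dW, b = bc2$db)
  dr1 <- relu_bwd(cc$r1, maxpool_bwd(cc$p1, bc2$dx)) + relu_bwd(cc$r1, ds1)
  if (cfg$first_layer == "quantum") {
    g$first <- qconv1_bwd(cc$c1, cfg$qconv, p$first, dr1, tabs_grad)
  } else {
    bf <- conv1d_same_bwd(cc$c1, p$first$W, dr1)
    g$first <- list(W = bf$dW, b = bf$db)
  }
  g[names(model$params)]
}

#' Predict per-base output for a batch of one-hot sequences
#'
#' Deterministic given the weights and batch-order invariant.
#'
#' @param object A [build_model()] model.
#' @param x A single `L x 4` one-hot matrix, or a list of them.
#' @param ... Unused.
#' @return A numeric vector of length L (single input) or a `B x L` matrix.
#'   Binary-task values lie in `[0, 1]`.
#' @export
predict.quanv_model <- function(object, x, ...) {
  tabs <- if (object$config$first_layer == "quantum") {
    qconv_tables(object$config$qconv, object$params$first$theta)
  } else NULL
  if (is.matrix(x)) return(forward_model(object, x, tabs = tabs))
  out <- t(vapply(x, function(xi) forward_model(object, xi, tabs = tabs),
                  numeric(object$config$input_length)))
  out
}
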