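# The hybrid quanvolutional first layer (QConv1): a q-qubit quantum kernel
# slid over each one-hot channel, followed by a complementary classical
# convolution chosen by the kernel-division rule so that the combined
# receptive field equals the target motif scale (16 bp by default).

#' Kernel Division Strategy
#'
#' Splits a target receptive field between a quantum kernel of width `q`
#' (one qubit per base) and a complementary classical kernel so that
#' `k_quantum + k_classical - 1 = k_target`. With the defaults `q = 4`,
#' `k_target = 16` this yields a 13 bp classical kernel.
#'
#' @param q Quantum kernel width in bp (= number of qubits).
#' @param k_target Target effective receptive field in bp (default 16).
#' @return Named integer vector `c(k_quantum, k_classical)`.
#' @export
kernel_division <- function(q, k_target = 16L) {
  q <- as.integer(q); k_target <- as.integer(k_target)
  if (is.na(q) || q < 1L) stop("q must be >= 1")
  if (q > k_target) stop("q (", q, ") must not exceed k_target (", k_target, ")")
  c(k_quantum = q, k_classical = k_target - q + 1L)
}

#' Configure a QConv1 layer
#'
#' @param n_qubits Qubits of the quantum kernel (1..4 by default guard); the
#'   quantum kernel width in bp equals `n_qubits`.
#' @param k_target Target receptive field in bp (default 16).
#' @param n_filters Output filters of the complementary classical convolution
#'   (default 64).
#' @param n_layers,entangler Ansatz depth and entangling topology of the PQC
#'   (see [circuit_spec()]).
#' @param channel_sharing Share one set of PQC angles across the 4 nucleotide
#'   channels (default TRUE; FALSE gives each channel its own angles).
#' @return Object of class `qconv_config` carrying the kernel-division
#'   arithmetic (`k_quantum`, `k_classical`) and the PQC [circuit_spec()].
#' @export
qconv_config <- function(n_qubits = 4L, k_target = 16L, n_filters = 64L,
                         n_layers = 3L, entangler = "chain",
                         channel_sharing = TRUE) {
  n_qubits <- as.integer(n_qubits)
  if (n_qubits < 1L || n_qubits > 4L) stop("n_qubits must be in [1, 4]")
  if (n_filters < 1L) stop("n_filters must be >= 1")
  kd <- kernel_division(n_qubits, k_target)
  structure(list(
    n_qubits = n_qubits,
    k_target = as.integer(k_target),
    k_quantum = kd[["k_quantum"]],
    k_classical = kd[["k_classical"]],
    n_filters = as.integer(n_filters),
    channel_sharing = isTRUE(channel_sharing),
    spec = circuit_spec(n_qubits, n_layers = n_layers, entangler = entangler)
  ), class = "qconv_config")
}

# integer window indices (0 .. 2^q - 1) of every width-q binary window in
# every one-hot channel; rows = window start positions, cols = 4 channels
qconv_window_indices <- function(onehot, q) {
  L <- nrow(onehot)
  if (L < q) stop("sequence length ", L, " shorter than quantum kernel ", q)
  n_out <- L - q + 1L
  idx <- matrix(0L, n_out, ncol(onehot))
  for (j in seq_len(q)) {
    idx <- idx + bitwShiftL(1L, q - j) *
      matrix(as.integer(onehot[j:(L - q + j), ] != 0), n_out, ncol(onehot))
  }
  idx
}

#' Quantum feature map of a one-hot sequence
#'
#' Slides the q-qubit quantum kernel over each of the 4 nucleotide channels
#' independently: every width-q binary window is angle-encoded, run through
#' the PQC, and read out as q Pauli-Z expectations, giving `4 * q` feature
#' channels per window position (columns ordered channel-major: A-channel
#' qubits 1..q, then C, G, T). All entries lie in `[-1, 1]`.
#'
#' @param onehot `L x 4` binary matrix (rows sum to 0 or 1; all-zero rows
#'   encode N).
#' @param spec PQC [circuit_spec()].
#' @param params [pqc_params()] for `spec` (one shared set across channels).
#' @return `(L - q + 1) x (4 q)` numeric matrix of class
#'   `quantum_feature_map`.
#' @export
quantum_feature_map <- function(onehot, spec, params) {
  q <- spec$n_qubits
  if (ncol(onehot) != 4L) stop("onehot must have 4 columns")
  if (any(rowSums(onehot != 0) > 1L)) stop("one-hot rows must sum to at most 1")
  tab <- pqc_window_table(spec, params)
  idx <- qconv_window_indices(onehot, q)
  fm <- matrix(0, nrow(idx), 4L * q)
  for (c in 1:4) {
    fm[, ((c - 1L) * q + 1L):(c * q)] <- tab$E[idx[, c] + 1L, , drop = FALSE]
  }
  structure(fm, class = c("quantum_feature_map", "matrix", "array"))
}

#' Initialize QConv1 weights
#'
#' Xavier initialization for the complementary classical convolution and for
#' the PQC rotation angles (see [init_pqc_params()]).
#'
#' @param config A [qconv_config()].
#' @return List with `theta` (PQC angles), `W`
#'   (`(k_classical * 4 q) x n_filters`), `b` (`n_filters`).
#' @export
init_qconv_weights <- function(config) {
  q <- config$n_qubits
  theta <- if (config$channel_sharing) {
    init_pqc_params(config$spec)$theta
  } else {
    # one independent angle set per nucleotide channel
    vapply(1:4, function(c) init_pqc_params(config$spec)$theta,
           numeric(n_params(config$spec)))
  }
  list(theta = theta,
       W = xavier_conv(config$k_classical, 4L * q, config$n_filters),
       b = numeric(config$n_filters))
}

# per-channel window tables; a single shared table is recycled 4 times
qconv_tables <- function(config, theta, gradients = FALSE) {
  if (config$channel_sharing) {
    tab <- pqc_window_table(config$spec, pqc_params(theta, config$spec),
                            gradients = gradients)
    rep(list(tab), 4L)
  } else {
    lapply(1:4, function(c) {
      pqc_window_table(config$spec, pqc_params(theta[, c], config$spec),
                       gradients = gradients)
    })
  }
}

# forward pass with cache; padding makes output length == input length and
# centers the k_target receptive field: output p sees input [p-7, p+8] for
# k_target = 16
qconv1_fwd <- function(onehot, config, weights, tabs = NULL) {
  q <- config$n_qubits
  pd <- same_pad(config$k_target)
  xp <- pad1d(onehot, pd[1], pd[2])
  if (is.null(tabs)) tabs <- qconv_tables(config, weights$theta)
  idx <- qconv_window_indices(xp, q)
  fm <- matrix(0, nrow(idx), 4L * q)
  for (c in 1:4) {
    fm[, ((c - 1L) * q + 1L):(c * q)] <- tabs[[c]]$E[idx[, c] + 1L, , drop = FALSE]
  }
  cols <- im2col1d(fm, config$k_classical)
  y <- sweep(cols %*% weights$W, 2, weights$b, "+")
  list(y = y, cols = cols, idx = idx, fm_rows = nrow(fm))
}

# backward: returns grads for W, b and theta (via the per-window gradient
# tables contracted with the upstream gradient on the quantum feature map)
qconv1_bwd <- function(cache, config, weights, dy, tabs_grad) {
  q <- config$n_qubits
  dW <- crossprod(cache$cols, dy)
  db <- colSums(dy)
  dcols <- dy %*% t(weights$W)
  dfm <- col2im1d(dcols, cache$fm_rows, config$k_classical, 4L * q)
  P <- n_params(config$spec)
  nw <- bitwShiftL(1L, q)
  # accumulate upstream gradient per (window index, readout qubit, channel)
  contract <- function(c) {
    S <- matrix(0, nw, q)
    part <- rowsum(dfm[, ((c - 1L) * q + 1L):(c * q), drop = FALSE],
                   group = cache$idx[, c])
    S[as.integer(rownames(part)) + 1L, ] <- part
    vapply(seq_len(P), function(k) sum(S * tabs_grad[[c]]$dE[, , k]),
           numeric(1))
  }
  per_channel <- vapply(1:4, contract, numeric(P))
  dtheta <- if (config$channel_sharing) rowSums(matrix(per_channel, nrow = P))
            else matrix(per_channel, nrow = P)
  list(theta = dtheta, W = dW, b = db)
}

#' Run a QConv1 layer forward
#'
#' Applies the quantum feature map to the (symmetrically zero-padded) input
#' and the complementary classical convolution on top, producing one
#' activation per input position and filter. Every interior output position
#' depends on exactly `k_target` contiguous input bases.
#'
#' @param onehot `L x 4` one-hot matrix.
#' @param config A [qconv_config()].
#' @param weights Weights from [init_qconv_weights()] (fields `theta`, `W`,
#'   `b`).
#' @return `L x n_filters` activation matrix.
#' @export
qconv1_forward <- function(onehot, config, weights) {
  if (nrow(weights$W) != config$k_classical * 4L * config$n_qubits ||
      ncol(weights$W) != config$n_filters) {
    stop("classical weight shape does not match config")
  }
  qconv1_fwd(onehot, config, weights)$y
}

#' Build a purely classical first convolution layer
#'
#' The non-quantum baseline: a width-`k` convolution over the 4 one-hot
#' channels with `n_filters` outputs and 'same' zero padding, Xavier
#' initialized.
#'
#' @param k Kernel width in bp (default 16, the baseline first-layer kernel).
#' @param n_filters Number of output filters (default 64).
#' @return List of class `classical_conv1` with `W`, `b`, `k`, `n_filters`.
#' @export
build_classical_conv1 <- function(k = 16L, n_filters = 64L) {
  structure(list(W = xavier_conv(k, 4L, n_filters), b = numeric(n_filters),
                 k = as.integer(k), n_filters = as.integer(n_filters)),
            class = "classical_conv1")
}

#' Forward pass of the classical baseline first layer
#' @param onehot `L x 4` one-hot matrix.
#' @param layer A [build_classical_conv1()] layer.
#' @return `L x n_filters` activation matrix.
#' @export
classical_conv1_forward <- function(onehot, layer) {
  conv1d_same_fwd(onehot, layer$W, layer$b, layer$k)$y
}

#' Measure the effective receptive field by input perturbation
#'
#' Flips each base of a random one-hot input in turn and records which
#' positions change the layer output at a fixed interior position; returns
#' the indices of affected input positions. The span length of the
#' contiguous affected block is the effective receptive field in bp.
#'
#' @param forward Function mapping an `L x 4` one-hot matrix to an
#'   `L x F` output matrix.
#' @param L Probe sequence length.
#' @param position Interior output position to watch (default `L %/% 2`).
#' @param seed Seed for the random probe sequence.
#' @return Integer vector of input positions whose perturbation changes the
#'   watched output.
#' @export
probe_receptive_field <- function(forward, L = 64L, position = L %/% 2L,
                                  seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  base_seq <- sample(1:4, L, replace = TRUE)
  onehot <- matrix(0, L, 4)
  onehot[cbind(seq_len(L), base_seq)] <- 1
  ref <- forward(onehot)[position, ]
  affected <- integer(0)
  for (p in seq_len(L)) {
    alt <- onehot
    new_base <- if (base_seq[p] == 1L) 2L else 1L
    alt[p, ] <- 0; alt[p, new_base] <- 1
    out <- forward(alt)[position, ]
    if (max(abs(out - ref)) > 1e-12) affected <- c(affected, p)
  }
  affected
}
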