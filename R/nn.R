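# Minimal 1D convolutional network primitives with explicit backward passes.
# Sequences are L x C matrices (positions x channels). Convolution weights are
# stored as (k * C_in) x C_out matrices whose rows are ordered offset-major
# (offset 1 channels, offset 2 channels, ...), so conv is one GEMM on the
# im2col matrix. All internal math is double precision.

# cached linear gather indices: cols[i, (j-1)*C + c] = x[i + j - 1, c];
# the same index vector drives both im2col (gather) and col2im (scatter-add)
.im2col_cache <- new.env(parent = emptyenv())

im2col_index <- function(L, k, C) {
  key <- paste(L, k, C, sep = "_")
  iv <- .im2col_cache[[key]]
  if (is.null(iv)) {
    n_out <- L - k + 1L
    # column order of cols: offset-major blocks, channels fastest inside
    i <- rep.int(seq_len(n_out), k * C)
    j <- rep(seq_len(k), each = n_out * C)
    c <- rep.int(rep(seq_len(C), each = n_out), k)
    iv <- (i + j - 1L) + (c - 1L) * L
    .im2col_cache[[key]] <- iv
  }
  iv
}

im2col1d <- function(x, k) {
  L <- nrow(x)
  if (L < k) stop("input length ", L, " shorter than kernel ", k)
  n_out <- L - k + 1L
  iv <- im2col_index(L, k, ncol(x))
  matrix(x[iv], n_out, k * ncol(x))
}

col2im1d <- function(dcols, L, k, C) {
  dx <- matrix(0, L, C)
  n_out <- L - k + 1L
  for (j in seq_len(k)) {
    rows <- j:(n_out + j - 1L)
    dx[rows, ] <- dx[rows, ] + dcols[, ((j - 1L) * C + 1L):(j * C)]
  }
  dx
}

pad1d <- function(x, left, right) {
  rbind(matrix(0, left, ncol(x)), x, matrix(0, right, ncol(x)))
}

# 'same' zero padding convention for width k: floor((k-1)/2) left, rest right
same_pad <- function(k) {
  left <- (k - 1L) %/% 2L
  c(left, k - 1L - left)
}

conv1d_same_fwd <- function(x, W, b, k) {
  pd <- same_pad(k)
  xp <- pad1d(x, pd[1], pd[2])
  cols <- im2col1d(xp, k)
  y <- cols %*% W
  y <- sweep(y, 2, b, "+")
  list(y = y, cols = cols, Lp = nrow(xp), k = k, C = ncol(x), pad = pd)
}

conv1d_same_bwd <- function(cache, W, dy) {
  dW <- crossprod(cache$cols, dy)
  db <- colSums(dy)
  dcols <- dy %*% t(W)
  dxp <- col2im1d(dcols, cache$Lp, cache$k, cache$C)
  dx <- dxp[(cache$pad[1] + 1L):(cache$Lp - cache$pad[2]), , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}

relu_bwd <- function(cache, dy) dy * cache$mask

sigmoid <- function(x) 1 / (1 + exp(-x))

maxpool_fwd <- function(x, f) {
  L <- nrow(x)
  if (L %% f != 0L) stop("pooling factor ", f, " does not divide length ", L)
  n_out <- L %/% f
  y <- matrix(0, n_out, ncol(x))
  arg <- matrix(0L, n_out, ncol(x))
  base <- (seq_len(n_out) - 1L) * f
  for (c in seq_len(ncol(x))) {
    m <- matrix(x[, c], nrow = f)              # f x n_out blocks
    a <- max.col(t(m), ties.method = "first")
    arg[, c] <- a
    y[, c] <- m[base + a]
  }
  list(y = y, arg = arg, f = f, L = L)
}

maxpool_bwd <- function(cache, dy) {
  dx <- matrix(0, cache$L, ncol(dy))
  base <- (seq_len(nrow(dy)) - 1L) * cache$f
  for (c in seq_len(ncol(dy))) {
    dx[base + cache$arg[, c], c] <- dy[, c]
  }
  dx
}

upsample_fwd <- function(x, f) {
  # nearest-neighbour row repetition; the following trained conv makes the
  # upsampling learned
  y <- x[rep(seq_len(nrow(x)), each = f), , drop = FALSE]
  list(y = y, f = f, L = nrow(x))
}

upsample_bwd <- function(cache, dy) {
  grp <- rep(seq_len(cache$L), each = cache$f)
  rowsum(dy, grp)
}

xavier_conv <- function(k, c_in, c_out) {
  lim <- sqrt(6 / (k * c_in + k * c_out))
  matrix(stats::runif(k * c_in * c_out, -lim, lim), k * c_in, c_out)
}

# AdamW: decoupled weight decay; state carries first/second moments and step
adamw_init <- function(params) {
  rapply(params, function(p) list(m = p * 0, v = p * 0), how = "list")
}

adamw_update <- function(params, grads, state, lr, weight_decay = 1e-2,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8, step = 1L) {
  walk <- function(p, g, s) {
    if (is.list(p) && !is.null(names(p)) && !("m" %in% names(s))) {
      out_p <- p; out_s <- s
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], s[[nm]])
        out_p[[nm]] <- r$p; out_s[[nm]] <- r$s
      }
      return(list(p = out_p, s = out_s))
    }
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- s$m / (1 - beta1^step)
    vhat <- s$v / (1 - beta2^step)
    p <- p - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * p)
    list(p = p, s = s)
  }
  out_p <- params; out_s <- state
  for (nm in names(params)) {
    r <- walk(params[[nm]], grads[[nm]], state[[nm]])
    out_p[[nm]] <- r$p; out_s[[nm]] <- r$s
  }
  list(params = out_p, state = out_s)
}

# elementwise sum of two same-shaped nested parameter lists
acc_grads <- function(a, b) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- acc_grads(a[[nm]], b[[nm]])
    return(a)
  }
  a + b
}

scale_grads <- function(a, s) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- scale_grads(a[[nm]], s)
    return(a)
  }
  a * s
}

zero_like <- function(a) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- zero_like(a[[nm]])
    return(a)
  }
  a * 0
}
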