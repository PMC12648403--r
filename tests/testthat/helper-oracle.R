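# Brute-force dense-matrix oracles, independent of the gate-wise simulator.

# full 2^q x 2^q matrix of a 2x2 gate on qubit i (qubit 1 = MSB)
dense_1q <- function(q, i, U) {
  left <- diag(2^(i - 1))
  right <- diag(2^(q - i))
  kronecker(kronecker(left, U), right)
}

# full CNOT(control -> target) as an explicit basis permutation
dense_cnot <- function(q, control, target) {
  n <- 2^q
  M <- matrix(0, n, n)
  for (from in 0:(n - 1)) {
    cb <- bitwAnd(from %/% 2^(q - control), 1)
    to <- if (cb == 1) bitwXor(from, 2^(q - target)) else from
    M[to + 1, from + 1] <- 1
  }
  M
}

# assemble the explicit unitary of a whole circuit, gate by gate
dense_circuit_unitary <- function(spec, theta) {
  q <- spec$n_qubits
  M <- diag(2^q)
  k <- 0
  ry <- function(th) matrix(c(cos(th / 2), sin(th / 2),
                              -sin(th / 2), cos(th / 2)), 2, 2)
  for (l in seq_len(spec$n_layers)) {
    for (i in seq_len(q)) {
      k <- k + 1
      M <- dense_1q(q, i, ry(theta[k])) %*% M
    }
    if (q > 1) {
      for (i in seq_len(q - 1)) M <- dense_cnot(q, i, i + 1) %*% M
      if (spec$entangler == "ring") M <- dense_cnot(q, q, 1) %*% M
    }
  }
  M
}

random_state <- function(q) {
  amp <- complex(real = rnorm(2^q), imaginary = rnorm(2^q))
  quantum_state(amp / sqrt(sum(Mod(amp)^2)))
}
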