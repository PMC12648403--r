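# Exact statevector simulation of small parameterized quantum circuits (PQCs):
# angle encoding, layered hardware-efficient ansatz, Pauli-Z readout, and
# exact gradients (adjoint reverse sweep, parameter-shift, finite differences).
# Convention everywhere: qubit 1 is the MOST significant bit of the basis index.

#' Construct a quantum state
#'
#' Wraps a complex amplitude vector of length `2^q` as a normalized
#' statevector. Qubit 1 is the most significant bit of the (0-based) basis
#' index, so for 4 qubits the basis state `|1000>` sits at index 8.
#'
#' @param amplitudes Complex (or numeric) vector of length `2^q`, `q` in 1..8.
#' @return An object of class `quantum_state` with fields `amplitudes` and
#'   `n_qubits`.
#' @export
quantum_state <- function(amplitudes) {
  amplitudes <- as.complex(amplitudes)
  n <- length(amplitudes)
  q <- as.integer(round(log2(n)))
  if (n < 2L || bitwAnd(n, n - 1L) != 0L) {
    stop("amplitude vector length must be a power of 2, got ", n)
  }
  if (q < 1L || q > 8L) stop("qubit count must be in [1, 8], got ", q)
  nrm <- sqrt(sum(Mod(amplitudes)^2))
  if (!is.finite(nrm) || abs(nrm - 1) > 1e-10) {
    stop("statevector norm must be 1 within 1e-10, got ", format(nrm))
  }
  structure(list(amplitudes = amplitudes, n_qubits = q),
            class = "quantum_state")
}

#' Describe a PQC ansatz
#'
#' Hardware-efficient layout: each layer applies one trainable RY rotation per
#' qubit followed by an entangling stage of CNOTs (chain: control i -> target
#' i+1; ring additionally closes q -> 1). For a single qubit the entangler is
#' a no-op. Parameter count is `n_qubits * n_layers`, ordered qubit-fastest
#' within each layer.
#'
#' @param n_qubits Number of qubits (1..8).
#' @param n_layers Number of rotation+entangler layers (default 3).
#' @param entangler `"chain"` (default) or `"ring"`.
#' @return An object of class `circuit_spec`.
#' @export
circuit_spec <- function(n_qubits, n_layers = 3L, entangler = c("chain", "ring")) {
  entangler <- match.arg(entangler)
  n_qubits <- as.integer(n_qubits)
  n_layers <- as.integer(n_layers)
  if (is.na(n_qubits) || n_qubits < 1L || n_qubits > 8L) {
    stop("n_qubits must be in [1, 8]")
  }
  if (is.na(n_layers) || n_layers < 1L) stop("n_layers must be >= 1")
  structure(list(n_qubits = n_qubits, n_layers = n_layers,
                 entangler = entangler),
            class = "circuit_spec")
}

#' Number of trainable parameters of a circuit spec
#' @param spec A [circuit_spec()].
#' @return Integer, `n_qubits * n_layers`.
#' @export
n_params <- function(spec) spec$n_qubits * spec$n_layers

#' Wrap rotation angles as PQC parameters
#'
#' @param theta Numeric vector of rotation angles (radians); length must equal
#'   [n_params()] of `spec`.
#' @param spec The [circuit_spec()] the angles belong to.
#' @return Object of class `pqc_params`.
#' @export
pqc_params <- function(theta, spec) {
  theta <- as.numeric(theta)
  if (any(!is.finite(theta))) stop("theta must be finite")
  if (length(theta) != n_params(spec)) {
    stop("theta length ", length(theta), " does not match spec parameter count ",
         n_params(spec))
  }
  structure(list(theta = theta), class = "pqc_params")
}

#' Xavier-style initialization of PQC angles
#'
#' Uniform Xavier (Glorot) draw with fan-in = fan-out = `n_qubits`, rescaled
#' by pi so angles start within the radians range explored by the rotations.
#'
#' @param spec A [circuit_spec()].
#' @return A `pqc_params` object.
#' @export
init_pqc_params <- function(spec) {
  lim <- sqrt(6 / (spec$n_qubits + spec$n_qubits)) * pi
  pqc_params(stats::runif(n_params(spec), -lim, lim), spec)
}

# single-qubit RY matrix
ry_gate <- function(theta) {
  c2 <- cos(theta / 2); s2 <- sin(theta / 2)
  matrix(c(c2, s2, -s2, c2), 2, 2)  # column-major: [[c,-s],[s,c]]
}

# derivative of RY wrt its angle
ry_gate_deriv <- function(theta) {
  c2 <- cos(theta / 2); s2 <- sin(theta / 2)
  0.5 * matrix(c(-s2, c2, -c2, -s2), 2, 2)
}

# apply a 2x2 gate to qubit i (1 = MSB) of amplitude vector `amp`
apply_1q <- function(amp, q, i, U) {
  s <- bitwShiftL(1L, q - i)           # stride between |0> and |1> partners
  idx0 <- which(bitwAnd((seq_along(amp) - 1L) %/% s, 1L) == 0L)
  idx1 <- idx0 + s
  a0 <- amp[idx0]; a1 <- amp[idx1]
  amp[idx0] <- U[1, 1] * a0 + U[1, 2] * a1
  amp[idx1] <- U[2, 1] * a0 + U[2, 2] * a1
  amp
}

# apply CNOT(control -> target) to amplitude vector
apply_cnot <- function(amp, q, control, target) {
  idx <- seq_along(amp) - 1L
  sc <- bitwShiftL(1L, q - control)
  st <- bitwShiftL(1L, q - target)
  sel <- which(bitwAnd(idx %/% sc, 1L) == 1L & bitwAnd(idx %/% st, 1L) == 0L)
  tmp <- amp[sel]
  amp[sel] <- amp[sel + st]
  amp[sel + st] <- tmp
  amp
}

# flat gate list of a circuit: rotations carry their parameter index
circuit_gates <- function(spec) {
  q <- spec$n_qubits
  gates <- list()
  k <- 0L
  for (l in seq_len(spec$n_layers)) {
    for (i in seq_len(q)) {
      k <- k + 1L
      gates[[length(gates) + 1L]] <- list(type = "ry", qubit = i, param = k)
    }
    if (q > 1L) {
      for (i in seq_len(q - 1L)) {
        gates[[length(gates) + 1L]] <- list(type = "cnot", control = i,
                                            target = i + 1L)
      }
      if (spec$entangler == "ring") {
        gates[[length(gates) + 1L]] <- list(type = "cnot", control = q,
                                            target = 1L)
      }
    }
  }
  gates
}

#' Angle-encode a classical window into a quantum state
#'
#' Each value x in `[0, 1]` becomes a qubit `RY(pi * x)|0>`; the full state is
#' the tensor product over qubits. Binary input therefore yields a
#' computational basis state: all-zeros maps to basis index 0 and all-ones to
#' index `2^q - 1`.
#'
#' @param bits Numeric vector in `[0, 1]` (typically binary), one entry per
#'   qubit; qubit 1 = first entry = most significant bit.
#' @param n_qubits Expected qubit count; defaults to `length(bits)`.
#' @return A [quantum_state()].
#' @export
angle_encode <- function(bits, n_qubits = length(bits)) {
  bits <- as.numeric(bits)
  if (length(bits) != n_qubits) {
    stop("expected ", n_qubits, " values, got ", length(bits))
  }
  if (any(!is.finite(bits))) stop("encoding input must be finite")
  # kronecker keeps earlier qubits more significant, so bits[1] becomes the MSB
  amp <- complex(real = 1)
  for (x in bits) {
    qb <- complex(real = c(cos(pi * x / 2), sin(pi * x / 2)))
    amp <- kronecker(amp, qb)
  }
  quantum_state(amp)
}

#' Apply a parameterized quantum circuit to a state
#'
#' Runs the layered ansatz of `spec` with angles `params` over the
#' statevector; exactly unitary, so the norm is preserved.
#'
#' @param state A [quantum_state()].
#' @param spec A [circuit_spec()] with matching qubit count.
#' @param params A [pqc_params()] (or bare numeric vector of angles).
#' @return The transformed [quantum_state()].
#' @export
apply_pqc <- function(state, spec, params) {
  if (!inherits(params, "pqc_params")) params <- pqc_params(params, spec)
  if (state$n_qubits != spec$n_qubits) {
    stop("state has ", state$n_qubits, " qubits but spec expects ",
         spec$n_qubits)
  }
  amp <- state$amplitudes
  q <- spec$n_qubits
  for (g in circuit_gates(spec)) {
    if (g$type == "ry") {
      amp <- apply_1q(amp, q, g$qubit, ry_gate(params$theta[g$param]))
    } else {
      amp <- apply_cnot(amp, q, g$control, g$target)
    }
  }
  quantum_state(amp)
}

#' Pauli-Z expectation of one qubit
#'
#' `<psi| sigma_z^(i) |psi>`: the probability-weighted sum of +1 where bit i
#' of the basis index is 0 and -1 where it is 1. Always in `[-1, 1]`.
#'
#' @param state A [quantum_state()].
#' @param qubit 1-based qubit index (1 = most significant bit).
#' @return Numeric scalar in `[-1, 1]`.
#' @export
expect_z <- function(state, qubit) {
  q <- state$n_qubits
  if (qubit < 1L || qubit > q) stop("qubit index out of range [1, ", q, "]")
  idx <- seq_along(state$amplitudes) - 1L
  z <- 1 - 2 * bitwAnd(idx %/% bitwShiftL(1L, q - qubit), 1L)
  sum(Mod(state$amplitudes)^2 * z)
}

#' All-qubit Pauli-Z expectations after the PQC
#'
#' Convenience readout: applies the circuit and measures `sigma_z` on every
#' qubit.
#'
#' @inheritParams apply_pqc
#' @return Numeric vector of length `n_qubits`, each entry in `[-1, 1]`.
#' @export
pqc_expectations <- function(state, spec, params) {
  out <- apply_pqc(state, spec, params)
  vapply(seq_len(spec$n_qubits), function(i) expect_z(out, i), numeric(1))
}

#' Gradient of a Pauli-Z expectation with respect to the circuit angles
#'
#' Computes `d<Z_qubit>/d theta_k` for every parameter. The default
#' `"adjoint"` method is an exact reverse-mode sweep through the statevector
#' simulator (used during training); `"parameter_shift"` evaluates
#' `(f(theta + pi/2) - f(theta - pi/2)) / 2` per parameter and
#' `"finite_diff"` uses central differences -- both serve as independent
#' verification routes and agree with the adjoint sweep to high precision.
#'
#' @inheritParams apply_pqc
#' @param qubit Which qubit's Z expectation to differentiate.
#' @param method One of `"adjoint"`, `"parameter_shift"`, `"finite_diff"`.
#' @param h Step size for finite differences.
#' @return Numeric vector of length [n_params()].
#' @export
pqc_gradient <- function(state, spec, params, qubit,
                         method = c("adjoint", "parameter_shift", "finite_diff"),
                         h = 1e-5) {
  method <- match.arg(method)
  if (!inherits(params, "pqc_params")) params <- pqc_params(params, spec)
  if (method == "parameter_shift" || method == "finite_diff") {
    shift <- if (method == "parameter_shift") pi / 2 else h
    denom <- if (method == "parameter_shift") 2 else 2 * h
    f <- function(th) {
      out <- apply_pqc(state, spec, pqc_params(th, spec))
      expect_z(out, qubit)
    }
    g <- numeric(n_params(spec))
    for (k in seq_along(g)) {
      up <- params$theta; up[k] <- up[k] + shift
      dn <- params$theta; dn[k] <- dn[k] - shift
      g[k] <- (f(up) - f(dn)) / denom
    }
    return(g)
  }
  # adjoint sweep: phi walks back through the circuit, lambda = Z phi_out is
  # pulled back through the same inverse gates; each rotation contributes
  # 2 Re <lambda | dG | phi_before>.
  q <- spec$n_qubits
  out <- apply_pqc(state, spec, params)
  idx <- seq_along(out$amplitudes) - 1L
  z <- 1 - 2 * bitwAnd(idx %/% bitwShiftL(1L, q - qubit), 1L)
  phi <- out$amplitudes
  lambda <- z * phi
  gates <- circuit_gates(spec)
  grad <- numeric(n_params(spec))
  for (g in rev(gates)) {
    if (g$type == "cnot") {
      phi <- apply_cnot(phi, q, g$control, g$target)
      lambda <- apply_cnot(lambda, q, g$control, g$target)
    } else {
      Uinv <- ry_gate(-params$theta[g$param])
      phi <- apply_1q(phi, q, g$qubit, Uinv)
      dphi <- apply_1q(phi, q, g$qubit, ry_gate_deriv(params$theta[g$param]))
      grad[g$param] <- 2 * Re(sum(Conj(lambda) * dphi))
      lambda <- apply_1q(lambda, q, g$qubit, Uinv)
    }
  }
  grad
}

# Precomputed readout/gradient tables over all 2^q binary windows.
# Inside QConv1 every window is binary, so the quantum stage is fully
# described by: E [2^q x q] expectations and (optionally) dE [2^q x q x P]
# gradients. Recomputed whenever theta changes; cost is negligible.
pqc_window_table <- function(spec, params, gradients = FALSE) {
  if (!inherits(params, "pqc_params")) params <- pqc_params(params, spec)
  q <- spec$n_qubits
  nw <- bitwShiftL(1L, q)
  E <- matrix(0, nw, q)
  dE <- if (gradients) array(0, c(nw, q, n_params(spec))) else NULL
  for (w in seq_len(nw)) {
    bits <- as.integer(bitwAnd((w - 1L) %/% bitwShiftL(1L, q - seq_len(q)), 1L))
    st <- angle_encode(bits, q)
    out <- apply_pqc(st, spec, params)
    for (i in seq_len(q)) {
      E[w, i] <- expect_z(out, i)
      if (gradients) dE[w, i, ] <- pqc_gradient(st, spec, params, i)
    }
  }
  list(E = E, dE = dE)
}
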