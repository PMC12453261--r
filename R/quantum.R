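#' Create an N-qubit statevector
#'
#' Builds a normalized complex amplitude vector of length `2^n_qubits`.
#' Qubit 0 is the least-significant bit of the basis-state index, so for
#' two qubits the amplitude order is `|00>, |01>, |10>, |11>` with the
#' *right-most* written bit belonging to qubit 1 under this convention
#' (index `i` has qubit `k` set when `bitwAnd(i, 2^k) > 0`).
#'
#' @param n_qubits Number of qubits (integer >= 1).
#' @param amplitudes Optional complex vector of length `2^n_qubits`; defaults
#'   to the ground state `|0...0>`. Normalized on construction.
#' @return An object of class `qstate` with elements `amp` (complex vector)
#'   and `n` (qubit count).
#' @export
#' @examples
#' qstate(2)
qstate <- function(n_qubits, amplitudes = NULL) {
  stopifnot(is.numeric(n_qubits), length(n_qubits) == 1, n_qubits >= 1)
  n_qubits <- as.integer(n_qubits)
  dim_full <- 2L^n_qubits
  if (is.null(amplitudes)) {
    amplitudes <- complex(dim_full)
    amplitudes[1] <- 1 + 0i
  }
  if (length(amplitudes) != dim_full) {
    stop("amplitude vector has length ", length(amplitudes),
         " but an ", n_qubits, "-qubit register needs ", dim_full,
         call. = FALSE)
  }
  amplitudes <- as.complex(amplitudes)
  nrm <- sqrt(sum(Mod(amplitudes)^2))
  if (nrm < 1e-12) stop("cannot normalize a zero amplitude vector", call. = FALSE)
  structure(list(amp = amplitudes / nrm, n = n_qubits), class = "qstate")
}

#' @export
print.qstate <- function(x, ...) {
  cat("<qstate> ", x$n, " qubit(s), ", length(x$amp), " amplitudes\n", sep = "")
  basis <- vapply(seq_along(x$amp) - 1L, function(i) {
    paste(rev(as.integer(intToBits(i))[seq_len(x$n)]), collapse = "")
  }, character(1))
  df <- data.frame(basis = paste0("|", basis, ">"),
                   amplitude = format(x$amp, digits = 4),
                   probability = round(Mod(x$amp)^2, 6))
  print(df, row.names = FALSE)
  invisible(x)
}

.check_qubit <- function(state, qubit) {
  if (!is.numeric(qubit) || length(qubit) != 1 || qubit < 0 || qubit >= state$n) {
    stop("qubit index ", qubit, " out of range for ", state$n, " qubits",
         call. = FALSE)
  }
  as.integer(qubit)
}

# Positions (1-based) of basis states with bit `qubit` clear; paired states
# with the bit set sit at offset +2^qubit. Cached: gates are applied inside
# per-sample training loops.
.qidx_cache <- new.env(parent = emptyenv())

.lower_idx <- function(n, qubit) {
  key <- paste0(n, ":", qubit)
  hit <- .qidx_cache[[key]]
  if (!is.null(hit)) return(hit)
  idx <- 0:(2L^n - 1L)
  out <- which(bitwAnd(idx, bitwShiftL(1L, qubit)) == 0L)
  .qidx_cache[[key]] <- out
  out
}

# Pauli-Z parity eigenvalues (-1)^popcount(i) per basis state, cached per n.
.parity_vec <- function(n) {
  key <- paste0("parity:", n)
  hit <- .qidx_cache[[key]]
  if (!is.null(hit)) return(hit)
  idx <- 0:(2L^n - 1L)
  out <- (-1)^vapply(idx, function(i) sum(as.integer(intToBits(i))), 0L)
  .qidx_cache[[key]] <- out
  out
}

#' Elementary gates on a statevector
#'
#' Exact single- and two-qubit gate applications. All gates preserve the
#' norm; `apply_h_all()` applies a Hadamard to every qubit, `apply_phase()`
#' the diagonal phase gate `P(phi) = diag(1, exp(i*phi))`, `apply_ry()` the
#' real rotation `Ry(theta) = [[cos(theta/2), -sin(theta/2)],
#' [sin(theta/2), cos(theta/2)]]`, `apply_cz()` the symmetric controlled-Z,
#' and `apply_cp()` a controlled phase (phase `exp(i*phi)` on the `|11>`
#' component of the addressed pair).
#'
#' @param state A [qstate()].
#' @param qubit,i,j Zero-based qubit indices.
#' @param phi,theta Angles in radians.
#' @return The transformed `qstate`.
#' @name gates
NULL

#' @rdname gates
#' @export
apply_h <- function(state, qubit) {
  qubit <- .check_qubit(state, qubit)
  lo <- .lower_idx(state$n, qubit)
  hi <- lo + 2L^qubit
  a0 <- state$amp[lo]; a1 <- state$amp[hi]
  s <- 1 / sqrt(2)
  state$amp[lo] <- s * (a0 + a1)
  state$amp[hi] <- s * (a0 - a1)
  state
}

#' @rdname gates
#' @export
apply_h_all <- function(state) {
  for (q in seq_len(state$n) - 1L) state <- apply_h(state, q)
  state
}

#' @rdname gates
#' @export
apply_phase <- function(state, qubit, phi) {
  qubit <- .check_qubit(state, qubit)
  hi <- .lower_idx(state$n, qubit) + 2L^qubit
  state$amp[hi] <- state$amp[hi] * exp(1i * phi)
  state
}

#' @rdname gates
#' @export
apply_ry <- function(state, qubit, theta) {
  qubit <- .check_qubit(state, qubit)
  lo <- .lower_idx(state$n, qubit)
  hi <- lo + 2L^qubit
  a0 <- state$amp[lo]; a1 <- state$amp[hi]
  c2 <- cos(theta / 2); s2 <- sin(theta / 2)
  state$amp[lo] <- c2 * a0 - s2 * a1
  state$amp[hi] <- s2 * a0 + c2 * a1
  state
}

.pair_mask_idx <- function(n, i, j) {
  key <- paste0("pair:", n, ":", min(i, j), ":", max(i, j))
  hit <- .qidx_cache[[key]]
  if (!is.null(hit)) return(hit)
  idx <- 0:(2L^n - 1L)
  both <- bitwShiftL(1L, i) + bitwShiftL(1L, j)
  out <- which(bitwAnd(idx, both) == both)
  .qidx_cache[[key]] <- out
  out
}

#' @rdname gates
#' @export
apply_cz <- function(state, i, j) {
  i <- .check_qubit(state, i); j <- .check_qubit(state, j)
  if (i == j) stop("controlled-Z needs two distinct qubits", call. = FALSE)
  k <- .pair_mask_idx(state$n, i, j)
  state$amp[k] <- -state$amp[k]
  state
}

#' @rdname gates
#' @export
apply_cp <- function(state, i, j, phi) {
  i <- .check_qubit(state, i); j <- .check_qubit(state, j)
  if (i == j) stop("controlled phase needs two distinct qubits", call. = FALSE)
  k <- .pair_mask_idx(state$n, i, j)
  state$amp[k] <- state$amp[k] * exp(1i * phi)
  state
}

#' Specify the data-encoding circuit
#'
#' The encoder follows the ZZ feature map: Hadamards on all qubits, a
#' per-qubit phase `P(2 * x[i])`, then an entangling block whose form is the
#' one genuinely open choice. Dialect `"zz-interaction"` applies, for every
#' pair `i < j`, a controlled phase of `2 * (pi - x[i]) * (pi - x[j])` on the
#' `|11>` component (the pairwise ZZ-interaction reading of the circuit
#' diagram); dialect `"eq3-cz"` applies a bare controlled-Z to every pair
#' (the literal closed-form expression). `feature_scaling` maps raw features
#' to angles before encoding: `"identity"` uses them as-is, `"pi-tanh"`
#' squashes via `pi * tanh(x)` so unbounded upstream activations cannot
#' alias across the `2*pi` phase period.
#'
#' @param n_qubits Register width N.
#' @param dialect `"zz-interaction"` (default) or `"eq3-cz"`.
#' @param feature_scaling `"identity"` (default) or `"pi-tanh"`.
#' @return An `encoding_spec` object.
#' @export
encoding_spec <- function(n_qubits,
                          dialect = c("zz-interaction", "eq3-cz"),
                          feature_scaling = c("identity", "pi-tanh")) {
  dialect <- match.arg(dialect)
  feature_scaling <- match.arg(feature_scaling)
  stopifnot(n_qubits >= 1)
  structure(list(n_qubits = as.integer(n_qubits), dialect = dialect,
                 feature_scaling = feature_scaling),
            class = "encoding_spec")
}

.scale_features <- function(x, spec) {
  switch(spec$feature_scaling,
         "identity" = x,
         "pi-tanh" = pi * tanh(x))
}

#' Encode a classical feature vector into an entangled state
#'
#' @param x Real feature vector of length `spec$n_qubits`.
#' @param spec An [encoding_spec()].
#' @return A [qstate()] carrying the encoded, entangled register.
#' @export
#' @examples
#' encode(c(pi / 2, pi / 3), encoding_spec(2, dialect = "eq3-cz"))
encode <- function(x, spec) {
  stopifnot(inherits(spec, "encoding_spec"))
  if (length(x) != spec$n_qubits) {
    stop("feature vector length ", length(x), " does not match ",
         spec$n_qubits, " qubits", call. = FALSE)
  }
  x <- .scale_features(as.numeric(x), spec)
  n <- spec$n_qubits
  state <- apply_h_all(qstate(n))
  for (q in seq_len(n) - 1L) state <- apply_phase(state, q, 2 * x[q + 1L])
  if (n > 1L) {
    for (i in 0:(n - 2L)) for (j in (i + 1L):(n - 1L)) {
      state <- switch(spec$dialect,
        "eq3-cz" = apply_cz(state, i, j),
        "zz-interaction" =
          apply_cp(state, i, j, 2 * (pi - x[i + 1L]) * (pi - x[j + 1L])))
    }
  }
  state
}

#' Apply the trainable Ry ansatz
#'
#' One repetition applies `Ry(theta[i])` to qubit `i` for `i = 0..N-1`;
#' `length(theta)` must equal `N * repetitions`.
#'
#' @param state A [qstate()].
#' @param theta Real parameter vector (radians).
#' @param repetitions Number of ansatz layers (default 1).
#' @return The rotated `qstate`.
#' @export
apply_ansatz <- function(state, theta, repetitions = 1L) {
  n <- state$n
  if (length(theta) != n * repetitions) {
    stop("theta has length ", length(theta), " but ", n, " qubits x ",
         repetitions, " repetition(s) require ", n * repetitions,
         call. = FALSE)
  }
  k <- 0L
  for (r in seq_len(repetitions)) {
    for (q in seq_len(n) - 1L) {
      k <- k + 1L
      state <- apply_ry(state, q, theta[k])
    }
  }
  state
}

#' Measure a statevector in the computational basis
#'
#' Computes basis-state probabilities `p_i = |<i|psi>|^2`, attaches the
#' Pauli-Z eigenvalue of each basis state, and reduces them to a scalar
#' expectation `<M> = sum_i l_i p_i` and the unit-interval output
#' `o1 = (1 - <M>) / 2`. The default observable is the all-qubit Z parity,
#' `l_i = (-1)^popcount(i)`; `observable = "z0"` instead measures Z on qubit
#' 0 only (`l_i = +1` when bit 0 is clear, `-1` when set). Exact by default;
#' passing `shots` replaces the exact probabilities with seeded empirical
#' frequencies.
#'
#' @param state A [qstate()].
#' @param observable `"z-parity"` (default) or `"z0"`.
#' @param shots Optional number of measurement shots; `NULL` for exact mode.
#' @param seed RNG seed for shot sampling (required when `shots` is given).
#' @return A `cq_measurement` list: `probabilities`, `eigenvalues`,
#'   `expectation`, `o1`, plus `shots`.
#' @export
measure_state <- function(state, observable = c("z-parity", "z0"),
                          shots = NULL, seed = NULL) {
  observable <- match.arg(observable)
  probs <- Mod(state$amp)^2
  probs <- probs / sum(probs)
  idx <- 0:(length(probs) - 1L)
  eig <- switch(observable,
    "z-parity" = .parity_vec(round(log2(length(probs)))),
    "z0" = ifelse(bitwAnd(idx, 1L) == 0L, 1, -1))
  if (!is.null(shots)) {
    stopifnot(shots >= 1)
    if (is.null(seed)) stop("shot sampling requires an explicit seed", call. = FALSE)
    draws <- local({
      old <- .Random.seed_exists()
      on.exit(old(), add = TRUE)
      set.seed(seed)
      sample.int(length(probs), size = shots, replace = TRUE, prob = probs)
    })
    probs <- tabulate(draws, nbins = length(probs)) / shots
  }
  expectation <- sum(eig * probs)
  structure(list(probabilities = probs, eigenvalues = eig,
                 expectation = expectation, o1 = (1 - expectation) / 2,
                 shots = shots),
            class = "cq_measurement")
}

# Save/restore .Random.seed so seeded shot sampling does not perturb the
# caller's RNG stream. Returns a restorer closure.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", old, envir = globalenv())
  } else {
    function() {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }
  }
}

#' @export
print.cq_measurement <- function(x, ...) {
  cat("<cq_measurement>", if (is.null(x$shots)) "exact" else paste(x$shots, "shots"), "\n")
  cat("  expectation <M> =", format(x$expectation, digits = 6),
      "  o1 =", format(x$o1, digits = 6), "\n")
  invisible(x)
}

#' Full forward pass through the parameterized quantum circuit
#'
#' Encodes `x`, applies the Ry ansatz with parameters `theta`, measures, and
#' returns the scalar circuit output `o1 = (1 - <M>) / 2` in `[0, 1]`.
#' Deterministic in exact mode.
#'
#' @inheritParams measure_state
#' @param x Feature vector (length N).
#' @param theta Ansatz parameters (length `N * repetitions`).
#' @param spec An [encoding_spec()].
#' @param repetitions Ansatz repetitions.
#' @return Numeric scalar `o1`.
#' @export
pqc_forward <- function(x, theta, spec, repetitions = 1L,
                        observable = "z-parity", shots = NULL, seed = NULL) {
  state <- apply_ansatz(encode(x, spec), theta, repetitions)
  measure_state(state, observable = observable, shots = shots, seed = seed)$o1
}

#' Parameter-shift gradient of the circuit output
#'
#' Exact gradient of `o1` with respect to each ansatz angle using the
#' parameter-shift rule for generators with eigenvalues +/-1/2:
#' `d o1 / d theta_i = (o1(theta_i + pi/2) - o1(theta_i - pi/2)) / 2`.
#'
#' @inheritParams pqc_forward
#' @return Numeric vector of length `length(theta)`.
#' @export
parameter_shift_grad <- function(x, theta, spec, repetitions = 1L,
                                 observable = "z-parity") {
  vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + pi / 2
    tm <- theta; tm[i] <- tm[i] - pi / 2
    (pqc_forward(x, tp, spec, repetitions, observable) -
       pqc_forward(x, tm, spec, repetitions, observable)) / 2
  }, numeric(1))
}

#' Numeric gradient of the circuit output with respect to its inputs
#'
#' Central finite differences on the raw features (through any configured
#' feature scaling), enabling the chain rule back into upstream classical
#' layers.
#'
#' @inheritParams pqc_forward
#' @param h Finite-difference step (default `1e-4`).
#' @return Numeric vector of length `length(x)`.
#' @export
input_grad <- function(x, theta, spec, repetitions = 1L,
                       observable = "z-parity", h = 1e-4) {
  vapply(seq_along(x), function(k) {
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    (pqc_forward(xp, theta, spec, repetitions, observable) -
       pqc_forward(xm, theta, spec, repetitions, observable)) / (2 * h)
  }, numeric(1))
}
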