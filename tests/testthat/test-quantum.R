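test_that("elementary gates act correctly and preserve the norm", {
  s <- apply_h_all(qstate(1))
  expect_equal(s$amp, complex(real = c(1, 1) / sqrt(2)), tolerance = 1e-12)

  expect_equal(apply_ry(qstate(1), 0, 0)$amp, qstate(1)$amp)
  s1 <- apply_ry(qstate(1), 0, pi)
  expect_equal(Mod(s1$amp), c(0, 1), tolerance = 1e-12)

  s11 <- qstate(2, c(0, 0, 0, 1))
  flipped <- apply_cz(s11, 0, 1)
  expect_equal(flipped$amp[4], complex(real = -1), tolerance = 1e-12)
  expect_equal(flipped$amp[1:3], complex(3), tolerance = 1e-12)
  # CZ is symmetric in its qubits
  set.seed(5)
  amp <- complex(real = rnorm(4), imaginary = rnorm(4))
  sr <- qstate(2, amp)
  expect_equal(apply_cz(sr, 0, 1)$amp, apply_cz(sr, 1, 0)$amp)

  # norm preserved across a random gate sequence
  set.seed(7)
  st <- qstate(3, complex(real = rnorm(8), imaginary = rnorm(8)))
  for (rep in 1:20) {
    op <- sample(4, 1)
    q <- sample(0:2, 1)
    st <- switch(op,
                 apply_h(st, q),
                 apply_phase(st, q, runif(1, -pi, pi)),
                 apply_ry(st, q, runif(1, -pi, pi)),
                 apply_cz(st, q, (q + 1) %% 3))
    expect_equal(sum(Mod(st$amp)^2), 1, tolerance = 1e-10)
  }

  expect_error(apply_h(qstate(2), 2), "out of range")
  expect_error(apply_cz(qstate(2), 1, 1), "distinct")
})

test_that("encoding matches its defining circuit", {
  # zero features under the literal-CZ dialect: uniform probabilities
  s <- encode(c(0, 0), encoding_spec(2, dialect = "eq3-cz"))
  expect_equal(Mod(s$amp)^2, rep(0.25, 4), tolerance = 1e-12)

  # single qubit: phases never change magnitudes after one Hadamard
  for (d in c("eq3-cz", "zz-interaction")) {
    s1 <- encode(1.3, encoding_spec(1, dialect = d))
    expect_equal(Mod(s1$amp)^2, c(0.5, 0.5), tolerance = 1e-12)
  }

  # dense 4x4 matrix-product oracle
  s2 <- encode(c(pi / 2, pi / 3), encoding_spec(2, dialect = "eq3-cz"))
  oracle <- dense_circuit_state(c(pi / 2, pi / 3), c(0, 0), 2, "eq3-cz")
  expect_equal(s2$amp, oracle, tolerance = 1e-12)

  expect_error(encode(c(1, 2, 3), encoding_spec(2)), "does not match")
})

test_that("full circuit equals the dense unitary-product oracle (N <= 4)", {
  set.seed(101)
  worst <- 0
  for (trial in 1:100) {
    n <- sample(2:4, 1)
    dialect <- sample(c("eq3-cz", "zz-interaction"), 1)
    x <- runif(n, -pi, pi)
    theta <- runif(n, -pi, pi)
    got <- apply_ansatz(encode(x, encoding_spec(n, dialect = dialect)), theta)
    want <- dense_circuit_state(x, theta, n, dialect)
    worst <- max(worst, max(Mod(got$amp - want)))
  }
  expect_lt(worst, 1e-10)
})

test_that("ansatz applies Ry rotations per qubit", {
  s <- apply_ansatz(apply_h_all(qstate(2)), c(0, 0))
  expect_equal(s$amp, apply_h_all(qstate(2))$amp)

  s1 <- apply_ansatz(qstate(1), pi)
  expect_equal(Mod(s1$amp), c(0, 1), tolerance = 1e-12)

  expect_error(apply_ansatz(qstate(2), c(0.1)), "require")
  # two repetitions compose
  s2 <- apply_ansatz(qstate(1), c(0.4, 0.6), repetitions = 2)
  expect_equal(s2$amp, apply_ry(apply_ry(qstate(1), 0, 0.4), 0, 0.6)$amp)
})

test_that("measurement gives Born probabilities, parity expectation, o1", {
  m0 <- measure_state(qstate(3))
  expect_equal(m0$expectation, 1)
  expect_equal(m0$o1, 0)

  mh <- measure_state(apply_h(qstate(1), 0))
  expect_equal(mh$probabilities, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(mh$expectation, 0, tolerance = 1e-12)
  expect_equal(mh$o1, 0.5, tolerance = 1e-12)

  # <Z> = cos(theta) for the 1-qubit Ry circuit
  for (th in c(0.3, 1.2, 2.9)) {
    m <- measure_state(apply_ry(qstate(1), 0, th))
    expect_equal(m$expectation, cos(th), tolerance = 1e-12)
  }

  # parity eigenvalues: popcount sign
  m2 <- measure_state(qstate(2, c(0, 0, 0, 1)))
  expect_equal(m2$expectation, 1)  # |11> has even parity
  m1 <- measure_state(qstate(2, c(0, 1, 0, 0)))
  expect_equal(m1$expectation, -1)

  # first-qubit observable
  mz0 <- measure_state(qstate(2, c(0, 1, 0, 0)), observable = "z0")
  expect_equal(mz0$expectation, -1)
})

test_that("probabilities stay on the simplex everywhere", {
  set.seed(11)
  for (trial in 1:25) {
    n <- sample(1:4, 1)
    x <- runif(n, -2, 2)
    theta <- runif(n, -pi, pi)
    st <- apply_ansatz(encode(x, encoding_spec(n)), theta)
    p <- measure_state(st)$probabilities
    expect_true(all(p >= -1e-15))
    expect_equal(sum(p), 1, tolerance = 1e-10)
  }
})

test_that("shot sampling converges to exact probabilities", {
  st <- apply_ansatz(encode(c(0.7, -0.4), encoding_spec(2)), c(0.5, 1.1))
  exact <- measure_state(st)$probabilities
  emp <- measure_state(st, shots = 1e5, seed = 42)$probabilities
  # 3 sigma binomial envelope per outcome
  tol <- 3 * sqrt(exact * (1 - exact) / 1e5)
  expect_true(all(abs(emp - exact) <= pmax(tol, 1e-4)))
  # seeded: reproducible, and exact mode unaffected
  emp2 <- measure_state(st, shots = 1e5, seed = 42)$probabilities
  expect_identical(emp, emp2)
  expect_error(measure_state(st, shots = 100), "seed")
})

test_that("pqc_forward is deterministic and matches the oracle", {
  spec <- encoding_spec(2, dialect = "eq3-cz")
  o <- pqc_forward(c(0, 0), c(0, 0), spec)
  expect_equal(o, 0.5, tolerance = 1e-12)   # uniform state has zero parity

  set.seed(21)
  for (trial in 1:10) {
    n <- sample(2:3, 1)
    x <- runif(n, -1, 1); th <- runif(n, -pi, pi)
    sp <- encoding_spec(n)
    expect_equal(pqc_forward(x, th, sp), dense_circuit_o1(x, th, n),
                 tolerance = 1e-10)
    expect_identical(pqc_forward(x, th, sp), pqc_forward(x, th, sp))
  }
})

test_that("parameter-shift gradients match finite differences", {
  set.seed(31)
  worst <- 0
  for (trial in 1:50) {
    n <- sample(2:3, 1)
    dialect <- sample(c("eq3-cz", "zz-interaction"), 1)
    sp <- encoding_spec(n, dialect = dialect)
    x <- runif(n, -1.5, 1.5)
    th <- runif(n, -pi, pi)
    ps <- parameter_shift_grad(x, th, sp)
    h <- 1e-5
    fd <- vapply(seq_len(n), function(i) {
      tp <- th; tp[i] <- tp[i] + h
      tm <- th; tm[i] <- tm[i] - h
      (pqc_forward(x, tp, sp) - pqc_forward(x, tm, sp)) / (2 * h)
    }, numeric(1))
    worst <- max(worst, max(abs(ps - fd)))
  }
  expect_lt(worst, 1e-6)

  # 2*pi periodicity
  sp <- encoding_spec(2)
  x <- c(0.3, -0.8); th <- c(1.1, 0.4)
  expect_equal(parameter_shift_grad(x, th, sp),
               parameter_shift_grad(x, th + 2 * pi, sp), tolerance = 1e-12)
})

test_that("input gradients are correct and vanish where o1 is flat", {
  sp <- encoding_spec(2)
  x <- c(0.4, -0.9); th <- c(0.7, 1.3)
  g <- input_grad(x, th, sp)
  expect_length(g, 2)
  # Richardson-extrapolated oracle (two step sizes)
  rich <- vapply(1:2, function(k) {
    d <- function(h) {
      xp <- x; xp[k] <- xp[k] + h
      xm <- x; xm[k] <- xm[k] - h
      (pqc_forward(xp, th, sp) - pqc_forward(xm, th, sp)) / (2 * h)
    }
    (4 * d(5e-4) - d(1e-3)) / 3
  }, numeric(1))
  expect_equal(g, rich, tolerance = 1e-5)

  # with an identity ansatz the encoder only shifts phases, so o1 is
  # constant in x and every input gradient vanishes
  g0 <- input_grad(c(0.2, 0.5), c(0, 0), sp)
  expect_equal(g0, c(0, 0), tolerance = 1e-8)
})
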