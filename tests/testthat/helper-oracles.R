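# Independent oracles used to cross-check the implementation. Everything
# here builds quantities from first principles (dense matrix products,
# brute-force enumeration, closed forms) and never calls the code paths it
# checks.

# ---- dense unitary-product circuit oracle -----------------------------------

# Single-qubit operator on qubit k (0 = least-significant bit) embedded in an
# n-qubit register: kron(I_left, U, I_right) with the left factor owning the
# most-significant bits.
embed_1q <- function(u, k, n) {
  left <- diag(2^(n - 1 - k))
  right <- diag(2^k)
  kron3 <- kronecker(kronecker(left, u), right)
  kron3
}

H1 <- matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2)
P1 <- function(phi) diag(c(1, exp(1i * phi)))
RY1 <- function(theta) matrix(c(cos(theta / 2), sin(theta / 2),
                                -sin(theta / 2), cos(theta / 2)), 2, 2)

# Diagonal two-qubit phase on the |11> component of qubits (i, j).
embed_cphase <- function(phi, i, j, n) {
  idx <- 0:(2^n - 1)
  both <- bitwAnd(idx, bitwShiftL(1, i)) > 0 & bitwAnd(idx, bitwShiftL(1, j)) > 0
  diag(ifelse(both, exp(1i * phi), 1 + 0i))
}

# Full dense statevector for the encode -> ansatz circuit.
dense_circuit_state <- function(x, theta, n, dialect = "zz-interaction",
                                repetitions = 1) {
  psi <- complex(2^n); psi[1] <- 1
  u <- diag(2^n)
  for (k in 0:(n - 1)) u <- embed_1q(H1, k, n) %*% u
  for (k in 0:(n - 1)) u <- embed_1q(P1(2 * x[k + 1]), k, n) %*% u
  if (n > 1) {
    for (i in 0:(n - 2)) for (j in (i + 1):(n - 1)) {
      u <- if (dialect == "eq3-cz") {
        embed_cphase(pi, i, j, n) %*% u
      } else {
        embed_cphase(2 * (pi - x[i + 1]) * (pi - x[j + 1]), i, j, n) %*% u
      }
    }
  }
  th <- matrix(theta, nrow = n)
  for (r in seq_len(repetitions)) {
    for (k in 0:(n - 1)) u <- embed_1q(RY1(th[k + 1, r]), k, n) %*% u
  }
  drop(u %*% psi)
}

dense_circuit_o1 <- function(x, theta, n, dialect = "zz-interaction",
                             repetitions = 1) {
  psi <- dense_circuit_state(x, theta, n, dialect, repetitions)
  probs <- Mod(psi)^2
  parity <- (-1)^vapply(0:(2^n - 1),
                        function(i) sum(as.integer(intToBits(i))), 0L)
  (1 - sum(parity * probs)) / 2
}

# ---- brute-force slice schedule ---------------------------------------------

# Literal enumeration of the extraction pseudocode: interval, valid count,
# then the index loop with the trailing guard.
brute_force_plan <- function(m, n, k1, k2) {
  i <- floor(m / n)
  n_slices <- ceiling(m / i) - (k1 + k2)
  s_out <- integer()
  for (j in 0:(n_slices - 1)) {
    s <- k1 + j * i
    if (s < m - k2) s_out <- c(s_out, s)
  }
  list(interval = i, n_slices = n_slices, indices = s_out)
}

# ---- misc oracles -----------------------------------------------------------

# Nearest-centroid classifier accuracy: centroids from the training split,
# accuracy on the test split.
centroid_accuracy <- function(dataset) {
  train <- dataset[dataset$split == "train", ]
  test <- dataset[dataset$split == "test", ]
  mu <- lapply(0:1, function(lb) {
    imgs <- train$image[train$label == lb]
    Reduce(`+`, imgs) / length(imgs)
  })
  pred <- vapply(test$image, function(im) {
    d0 <- sum((im - mu[[1]])^2); d1 <- sum((im - mu[[2]])^2)
    if (d0 <= d1) 0L else 1L
  }, integer(1))
  mean(pred == test$label)
}

# Two-sample permutation test on the difference of class mean-image norms.
permutation_pvalue <- function(dataset, n_perm = 200, seed = 99) {
  set.seed(seed)
  feats <- vapply(dataset$image, mean, numeric(1))
  labs <- dataset$label
  obs <- abs(mean(feats[labs == 0]) - mean(feats[labs == 1]))
  null <- replicate(n_perm, {
    p <- sample(labs)
    abs(mean(feats[p == 0]) - mean(feats[p == 1]))
  })
  mean(null >= obs)
}

# Textbook one-way fixed-effects ANOVA F.
closed_form_f <- function(groups) {
  k <- length(groups)
  n <- sum(lengths(groups))
  grand <- mean(unlist(groups))
  ssb <- sum(lengths(groups) * (vapply(groups, mean, numeric(1)) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Small helper: a fresh tiny image dataset for model tests.
tiny_dataset <- function(n_per_class = 20, side = 32, delta = 8, seed = 11,
                         noise_sd = 0.05) {
  make_class_pair(class_pair_recipe(n_per_class = n_per_class, side = side,
                                    delta = delta, noise_sd = noise_sd,
                                    seed = seed))
}
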