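#' Training configuration
#'
#' Defaults follow the reference classification setup: batch size 32,
#' learning rate 0.001, Adam, cross-entropy loss.
#'
#' @param batch_size Minibatch size (default 32).
#' @param learning_rate Step size eta (default 0.001).
#' @param optimizer One of `"adam"` (default), `"sgd"`, `"rmsprop"`,
#'   `"adagrad"`, `"lbfgs"`. Only Adam reliably drives the hybrid model to
#'   convergence; the alternatives are provided for ablation.
#' @param epochs Training epochs.
#' @param seed RNG seed for shuffling and dropout.
#' @param runs Number of repeated runs for [run_repeated()].
#' @return A `train_config` object.
#' @export
train_config <- function(batch_size = 32L, learning_rate = 0.001,
                         optimizer = c("adam", "sgd", "rmsprop", "adagrad",
                                       "lbfgs"),
                         epochs = 10L, seed = 1L, runs = 5L) {
  optimizer <- match.arg(optimizer)
  stopifnot(batch_size >= 1, learning_rate >= 0, epochs >= 1, runs >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 runs = as.integer(runs)),
            class = "train_config")
}

#' Two-class cross-entropy loss
#'
#' Mean negative log-probability of the true class,
#' `L = -(1/N) sum_j sum_c y_jc log p_jc`, with the log argument clamped at
#' `1e-12`.
#'
#' @param gamma Numeric matrix (N x 2) of class probabilities, rows on the
#'   simplex; a single probability pair may be given as a vector.
#' @param labels Integer vector of true classes (0/1), or an N x 2 one-hot
#'   matrix.
#' @return Scalar loss.
#' @export
#' @examples
#' cross_entropy(c(0.5, 0.5), 0)  # log(2)
cross_entropy <- function(gamma, labels) {
  if (is.vector(gamma)) gamma <- matrix(gamma, nrow = 1)
  if (nrow(gamma) == 0) stop("empty batch", call. = FALSE)
  if (is.matrix(labels)) labels <- max.col(labels) - 1L
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(gamma), all(labels %in% c(0L, 1L)))
  p_true <- ifelse(labels == 0L, gamma[, 1], gamma[, 2])
  mean(-log(pmax(p_true, 1e-12)))
}

# ---- optimizers -------------------------------------------------------------

# Each first-order optimizer is a closure over its state, mapping a flat
# gradient to a flat parameter update (to be *added* to the parameters).
.make_optimizer <- function(name, lr, n) {
  switch(name,
    sgd = function(g) -lr * g,
    adagrad = local({
      acc <- numeric(n)
      function(g) {
        acc <<- acc + g^2
        -lr * g / (sqrt(acc) + 1e-10)
      }
    }),
    rmsprop = local({
      acc <- numeric(n); alpha <- 0.99
      function(g) {
        acc <<- alpha * acc + (1 - alpha) * g^2
        -lr * g / (sqrt(acc) + 1e-8)
      }
    }),
    adam = local({
      m <- numeric(n); v <- numeric(n); t <- 0L
      b1 <- 0.9; b2 <- 0.999
      function(g) {
        t <<- t + 1L
        m <<- b1 * m + (1 - b1) * g
        v <<- b2 * v + (1 - b2) * g^2
        mhat <- m / (1 - b1^t)
        vhat <- v / (1 - b2^t)
        -lr * mhat / (sqrt(vhat) + 1e-8)
      }
    }),
    stop("unknown optimizer: ", name, call. = FALSE))
}

# Mean loss, flat mean gradient, and running correct-prediction count over a
# set of samples.
.batch_loss_grad <- function(model, images, labels, training = TRUE) {
  n <- length(images)
  gsum <- NULL
  loss <- 0
  correct <- 0L
  for (k in seq_len(n)) {
    fw <- .forward_sample(model, images[[k]], training = training)
    loss <- loss + cross_entropy(c(fw$o1, 1 - fw$o1), labels[k])
    pred <- if (fw$o1 >= 0.5) 0L else 1L
    correct <- correct + (pred == labels[k])
    g <- .backward_sample(model, fw$cache, labels[k])
    gf <- .flatten_params(g[names(model$params)])
    gsum <- if (is.null(gsum)) gf else gsum + gf
  }
  list(loss = loss / n, grad = gsum / n, correct = correct)
}

.accuracy <- function(model, images, labels) {
  pred <- predict_model(model, images)$predicted
  mean(pred == labels)
}

#' Train a model
#'
#' Minibatch gradient descent on the cross-entropy loss. Quantum ansatz
#' angles receive exact parameter-shift gradients chained through the output
#' head; classical weights receive ordinary backpropagation gradients. With
#' the exact-expectation simulator the whole run is a pure function of
#' `cfg$seed`.
#'
#' `optimizer = "lbfgs"` instead runs full-batch `stats::optim` L-BFGS-B for
#' a few quasi-Newton iterations per epoch (the approximation memory resets
#' at epoch boundaries).
#'
#' @param model A [build_model()] result.
#' @param data Tibble with list-column `image` and column `label` (0/1). If
#'   a `split` column is present, rows with `split == "train"` are used for
#'   updates and `split == "test"` rows for per-epoch validation accuracy.
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch progress?
#' @return A `cq_fit`: list with the trained `model`, the `history` tibble
#'   (`epoch`, `loss`, `train_accuracy`, `val_accuracy`), and `cfg`.
#' @export
cq_train <- function(model, data, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "cq_model"), inherits(cfg, "train_config"))
  if (!all(c("image", "label") %in% names(data))) {
    stop("data must have 'image' and 'label' columns", call. = FALSE)
  }
  train_rows <- if ("split" %in% names(data)) data$split == "train" else
    rep(TRUE, nrow(data))
  images <- data$image[train_rows]
  labels <- as.integer(data$label[train_rows])
  if (length(unique(labels)) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }
  val_images <- if ("split" %in% names(data)) data$image[!train_rows] else list()
  val_labels <- if ("split" %in% names(data)) as.integer(data$label[!train_rows]) else integer()

  restore <- .Random.seed_exists()
  on.exit(restore(), add = TRUE)
  set.seed(cfg$seed)

  n <- length(images)
  flat <- .flatten_params(model$params)
  hist <- vector("list", cfg$epochs)

  if (cfg$optimizer == "lbfgs") {
    for (ep in seq_len(cfg$epochs)) {
      fn <- function(par) {
        model$params <- .unflatten_params(par, model$params)
        .batch_loss_grad(model, images, labels, training = FALSE)$loss
      }
      gr <- function(par) {
        model$params <- .unflatten_params(par, model$params)
        .batch_loss_grad(model, images, labels, training = FALSE)$grad
      }
      opt <- stats::optim(flat, fn, gr, method = "L-BFGS-B",
                          control = list(maxit = 3))
      flat <- opt$par
      model$params <- .unflatten_params(flat, model$params)
      hist[[ep]] <- .epoch_row(ep, opt$value,
                               .accuracy(model, images, labels),
                               model, val_images, val_labels)
      if (verbose) .report_epoch(hist[[ep]])
    }
  } else {
    step <- .make_optimizer(cfg$optimizer, cfg$learning_rate, length(flat))
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      ep_correct <- 0L
      starts <- seq(1L, n, by = cfg$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
        bg <- .batch_loss_grad(model, images[idx], labels[idx])
        ep_loss <- ep_loss + bg$loss * length(idx)
        ep_correct <- ep_correct + bg$correct
        if (cfg$learning_rate > 0) {
          flat <- flat + step(bg$grad)
          model$params <- .unflatten_params(flat, model$params)
        }
      }
      # running training accuracy, accumulated batch by batch as the
      # parameters move (the convention deep-learning frameworks log)
      hist[[ep]] <- .epoch_row(ep, ep_loss / n, ep_correct / n, model,
                               val_images, val_labels)
      if (verbose) .report_epoch(hist[[ep]])
    }
  }
  structure(list(model = model, history = dplyr::bind_rows(hist), cfg = cfg),
            class = "cq_fit")
}

.epoch_row <- function(ep, loss, train_acc, model, val_images, val_labels) {
  tibble::tibble(
    epoch = ep, loss = loss, train_accuracy = train_acc,
    val_accuracy = if (length(val_images)) .accuracy(model, val_images, val_labels)
    else NA_real_)
}

.report_epoch <- function(row) {
  cat(sprintf("epoch %d  loss %.4f  train acc %.3f%s\n", row$epoch, row$loss,
              row$train_accuracy,
              if (is.na(row$val_accuracy)) "" else
                sprintf("  val acc %.3f", row$val_accuracy)))
}

#' @export
print.cq_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat("<cq_fit>", x$model$cfg$variant, "model,", nrow(x$history), "epoch(s),",
      x$cfg$optimizer, "\n")
  cat(sprintf("  final loss %.4f, train accuracy %.3f\n",
              last$loss, last$train_accuracy))
  invisible(x)
}

#' Evaluate a model on labeled data
#'
#' Decision rule: `argmax(gamma)`. The positive class defaults to label 1
#' (the minority clinical class in the motivating dementia task).
#' Undefined ratios (zero denominators) are reported as 0 and flagged.
#'
#' @param object A `cq_model` or `cq_fit`.
#' @param data Tibble with `image` and `label` columns; if a `split` column
#'   exists, only `split == "test"` rows are scored.
#' @param positive_class Label treated as positive (default 1).
#' @return A one-row tibble of class `cq_metrics`: `precision`, `recall`,
#'   `f1`, `specificity`, `accuracy`, `n`, `undefined_flags`, with the 2x2
#'   confusion table in `attr(, "confusion")` (rows = truth, cols =
#'   prediction).
#' @export
evaluate_model <- function(object, data, positive_class = 1L) {
  model <- if (inherits(object, "cq_fit")) object$model else object
  stopifnot(inherits(model, "cq_model"))
  if ("split" %in% names(data)) data <- data[data$split == "test", ]
  if (nrow(data) == 0) stop("evaluation data is empty", call. = FALSE)
  pred <- predict_model(model, data$image)$predicted
  truth <- as.integer(data$label)
  pos <- as.integer(positive_class)
  confusion_metrics(tp = sum(truth == pos & pred == pos),
                    fp = sum(truth != pos & pred == pos),
                    fn = sum(truth == pos & pred != pos),
                    tn = sum(truth != pos & pred != pos),
                    positive_class = pos)
}

#' Classification metrics from confusion-table counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, `f1` their harmonic
#' mean, `specificity = TN/(TN+FP)`, `accuracy = (TP+TN)/total`.
#'
#' @param tp,fp,fn,tn Confusion counts.
#' @param positive_class Label recorded as positive (metadata only).
#' @return See [evaluate_model()].
#' @export
#' @examples
#' confusion_metrics(tp = 9, fp = 1, fn = 1, tn = 89)
confusion_metrics <- function(tp, fp, fn, tn, positive_class = 1L) {
  pos <- as.integer(positive_class)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  specificity <- safe_div(tn, tn + fp)
  flags <- c(precision = is.na(precision), recall = is.na(recall),
             f1 = is.na(f1), specificity = is.na(specificity))
  zero_na <- function(x) if (is.na(x)) 0 else x
  conf <- matrix(c(tn, fp, fn, tp), 2, 2, byrow = TRUE,
                 dimnames = list(truth = c("neg", "pos"),
                                 prediction = c("neg", "pos")))
  total <- tp + fp + fn + tn
  out <- tibble::tibble(
    precision = zero_na(precision), recall = zero_na(recall),
    f1 = zero_na(f1), specificity = zero_na(specificity),
    accuracy = (tp + tn) / total, n = total,
    undefined_flags = paste(names(flags)[flags], collapse = ","))
  structure(out, class = c("cq_metrics", class(out)), confusion = conf,
            positive_class = pos)
}

#' Repeated training runs with a convergence ANOVA
#'
#' Trains `runs` independent models (seeds `cfg$seed, cfg$seed + 1, ...` for
#' both initialization and shuffling) and quantifies between-run variability
#' with a one-way ANOVA whose groups are each run's last `k` per-epoch
#' training accuracies. Unstable convergence (the near-identical-class
#' regime) shows up as a large F and small p; identical deterministic runs
#' have zero between-group variance, reported as `F = 0`, `p = 1`.
#'
#' @param model_factory Function `(seed) -> cq_model`.
#' @param data Training data (see [cq_train()]).
#' @param cfg A [train_config()]; `cfg$runs >= 2`.
#' @param k Number of trailing epochs per run entering the ANOVA (default 3,
#'   capped at the epoch count).
#' @return A `cq_convergence`: list with `curves` (tibble: `run`, `epoch`,
#'   `loss`, `train_accuracy`, `val_accuracy`), `anova_f`, `anova_p`, `k`,
#'   and `final_accuracy` per run.
#' @export
run_repeated <- function(model_factory, data, cfg = train_config(), k = 3L) {
  if (cfg$runs < 2) stop("runs must be >= 2", call. = FALSE)
  curves <- vector("list", cfg$runs)
  for (r in seq_len(cfg$runs)) {
    seed_r <- cfg$seed + r - 1L
    run_cfg <- cfg
    run_cfg$seed <- seed_r
    fit <- cq_train(model_factory(seed_r), data, run_cfg)
    curves[[r]] <- dplyr::mutate(fit$history, run = r, .before = 1)
  }
  curves <- dplyr::bind_rows(curves)
  k <- min(as.integer(k), max(curves$epoch))
  tail_acc <- curves[curves$epoch > max(curves$epoch) - k, ]
  groups <- split(tail_acc$train_accuracy, tail_acc$run)
  av <- .oneway_f(groups)
  final_acc <- vapply(split(curves, curves$run), function(d) {
    d$train_accuracy[which.max(d$epoch)]
  }, numeric(1))
  structure(list(curves = curves, anova_f = av$f, anova_p = av$p, k = k,
                 final_accuracy = final_acc),
            class = "cq_convergence")
}

# Classic one-way fixed-effects F with explicit degenerate handling:
# zero between-group variance -> F = 0, p = 1; positive between- with zero
# within-group variance -> F = Inf, p = 0. Regular cases defer to
# stats::oneway.test(var.equal = TRUE).
.oneway_f <- function(groups) {
  means <- vapply(groups, mean, numeric(1))
  if (max(means) - min(means) < 1e-12) return(list(f = 0, p = 1))
  wvar <- vapply(groups, stats::var, numeric(1))
  if (all(wvar < 1e-24)) return(list(f = Inf, p = 0))
  vals <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::oneway.test(vals ~ fac, var.equal = TRUE)
  list(f = unname(ht$statistic), p = unname(ht$p.value))
}

#' @export
print.cq_convergence <- function(x, ...) {
  cat("<cq_convergence>", length(x$final_accuracy), "runs,",
      max(x$curves$epoch), "epochs\n")
  cat(sprintf("  final accuracies: %s\n",
              paste(sprintf("%.3f", x$final_accuracy), collapse = " ")))
  cat(sprintf("  one-way ANOVA (last %d epochs): F = %.4g, p = %.4g\n",
              x$k, x$anova_f, x$anova_p))
  invisible(x)
}
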