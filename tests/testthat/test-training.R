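test_that("cross-entropy matches its closed forms and a hand-summed oracle", {
  expect_lt(cross_entropy(c(1, 0), 0L), 1e-10)
  expect_equal(cross_entropy(c(0.5, 0.5), 0L), log(2), tolerance = 1e-12)
  expect_equal(cross_entropy(c(0.5, 0.5), 1L), log(2), tolerance = 1e-12)

  set.seed(8)
  o1 <- runif(16)
  gamma <- cbind(o1, 1 - o1)
  labels <- sample(0:1, 16, replace = TRUE)
  oracle <- -mean(ifelse(labels == 0, log(o1), log(1 - o1)))
  expect_equal(cross_entropy(gamma, labels), oracle, tolerance = 1e-12)

  # one-hot labels accepted
  onehot <- cbind(labels == 0, labels == 1) * 1
  expect_equal(cross_entropy(gamma, onehot), oracle, tolerance = 1e-12)

  # clamp keeps a certain-but-wrong prediction finite
  expect_true(is.finite(cross_entropy(c(1, 0), 1L)))
  expect_error(cross_entropy(matrix(numeric(0), 0, 2), integer(0)), "empty")
})

test_that("plain gradient descent reproduces the update recursion", {
  # L(t) = (t - 3)^2 / 2 so grad = t - 3 and t_k = 3 + (t_0 - 3)(1 - eta)^k
  eta <- 0.1
  step <- cqcnn:::.make_optimizer("sgd", eta, 1L)
  t <- 10
  for (k in 1:25) t <- t + step(t - 3)
  expect_equal(t, 3 + (10 - 3) * (1 - eta)^25, tolerance = 1e-12)
})

test_that("a zero learning rate leaves every parameter unchanged", {
  ds <- tiny_dataset(n_per_class = 20, side = 24, delta = 6, seed = 2)
  m <- build_model(model_config(image_side = 24, omega = 2, seed = 2))
  before <- cqcnn:::.flatten_params(m$params)
  fit <- cq_train(m, ds, train_config(learning_rate = 0, epochs = 1, seed = 2))
  expect_identical(cqcnn:::.flatten_params(fit$model$params), before)
})

test_that("training is bit-reproducible and rejects single-class data", {
  ds <- tiny_dataset(n_per_class = 20, side = 24, delta = 6, seed = 4)
  cfg <- train_config(epochs = 2, seed = 7, batch_size = 8)
  fit1 <- cq_train(build_model(model_config(image_side = 24, seed = 7)), ds, cfg)
  fit2 <- cq_train(build_model(model_config(image_side = 24, seed = 7)), ds, cfg)
  expect_identical(cqcnn:::.flatten_params(fit1$model$params),
                   cqcnn:::.flatten_params(fit2$model$params))
  expect_identical(fit1$history, fit2$history)
  expect_identical(nrow(fit1$history), 2L)
  expect_true(all(is.finite(fit1$history$loss)))

  ds1 <- ds[ds$label == 0, ]
  expect_error(cq_train(build_model(model_config(image_side = 24)), ds1,
                        cfg), "both classes")
})

test_that("one parameter-shift step decreases the loss on a frozen batch", {
  set.seed(15)
  ds <- tiny_dataset(n_per_class = 20, side = 24, delta = 8, seed = 15)
  imgs <- ds$image[ds$split == "train"][1:4]
  labels <- as.integer(ds$label[ds$split == "train"][1:4])
  m <- build_model(model_config(image_side = 24, omega = 2, dropout_rate = 0,
                                seed = 15))
  bg <- cqcnn:::.batch_loss_grad(m, imgs, labels, training = FALSE)
  # small-step line search along the negative gradient
  decreased <- FALSE
  for (eta in c(1e-2, 1e-3, 1e-4)) {
    m2 <- m
    m2$params <- cqcnn:::.unflatten_params(
      cqcnn:::.flatten_params(m$params) - eta * bg$grad, m$params)
    loss2 <- cqcnn:::.batch_loss_grad(m2, imgs, labels, training = FALSE)$loss
    if (loss2 < bg$loss) { decreased <- TRUE; break }
  }
  expect_true(decreased)
})

test_that("evaluation metrics agree with confusion-table arithmetic", {
  perfect <- confusion_metrics(tp = 10, fp = 0, fn = 0, tn = 10)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)

  m <- confusion_metrics(tp = 9, fp = 1, fn = 1, tn = 89)
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 0.9)
  expect_equal(m$f1, 0.9)
  expect_equal(m$specificity, 89 / 90, tolerance = 1e-12)
  expect_equal(m$accuracy, 0.98)
  conf <- attr(m, "confusion")
  # metrics recomputed from the exported table equal the reported scalars
  expect_equal(conf["pos", "pos"] / sum(conf[, "pos"]), m$precision)
  expect_equal(conf["neg", "neg"] / sum(conf["neg", ]), m$specificity)
  expect_equal(sum(diag(conf)) / sum(conf), m$accuracy)

  # all-negative predictor on balanced data: specificity 1, precision
  # undefined -> 0 with a flag
  deg <- confusion_metrics(tp = 0, fp = 0, fn = 10, tn = 10)
  expect_equal(deg$specificity, 1)
  expect_equal(deg$precision, 0)
  expect_match(deg$undefined_flags, "precision")

  # end to end: a model scored on its own predictions reproduces accuracy
  ds <- tiny_dataset(n_per_class = 20, side = 24, seed = 3)
  model <- build_model(model_config(image_side = 24, seed = 3))
  rep_ <- evaluate_model(model, ds)
  test_rows <- ds[ds$split == "test", ]
  pred <- predict_model(model, test_rows$image)$predicted
  expect_equal(rep_$accuracy, mean(pred == test_rows$label))
  expect_identical(rep_$n, nrow(test_rows))
})

test_that("the one-way ANOVA matches the textbook F and its conventions", {
  groups <- list(c(6, 8, 4, 5, 3, 4), c(8, 12, 9, 11, 6, 8), c(13, 9, 11, 8, 7, 12))
  got <- cqcnn:::.oneway_f(groups)
  expect_equal(got$f, closed_form_f(groups), tolerance = 1e-10)
  vals <- unlist(groups)
  fac <- factor(rep(1:3, each = 6))
  ref <- stats::oneway.test(vals ~ fac, var.equal = TRUE)
  expect_equal(got$p, unname(ref$p.value), tolerance = 1e-12)

  # identical groups: variance 0 -> F = 0, p = 1 by convention
  same <- cqcnn:::.oneway_f(list(c(1, 1), c(1, 1), c(1, 1)))
  expect_equal(same$f, 0)
  expect_equal(same$p, 1)
  # distinct means, zero within-group variance -> F = Inf, p = 0
  sep <- cqcnn:::.oneway_f(list(c(1, 1), c(2, 2)))
  expect_equal(sep$f, Inf)
  expect_equal(sep$p, 0)

  expect_error(run_repeated(function(s) NULL, NULL, train_config(runs = 1)),
               ">= 2")
})

test_that("repeated runs expose the similarity-driven convergence contrast", {
  # scaled-down regime: 32-px phantoms, small batches and a slightly larger
  # step size so each short run performs enough optimizer updates to leave
  # the chance plateau when the classes are separable
  cfg <- train_config(epochs = 20, seed = 21, runs = 5, batch_size = 4,
                      learning_rate = 0.003)
  factory <- function(s) build_model(model_config(image_side = 32, omega = 2,
                                                  seed = s))
  sep <- run_repeated(factory,
                      tiny_dataset(n_per_class = 40, side = 32, delta = 14,
                                   seed = 21, noise_sd = 0.02),
                      cfg)
  near <- run_repeated(factory,
                       tiny_dataset(n_per_class = 40, side = 32, delta = 0,
                                    seed = 21, noise_sd = 0.02),
                       cfg)
  expect_identical(max(sep$curves$run), 5L)
  expect_identical(length(sep$final_accuracy), 5L)
  expect_true(all(c("run", "epoch", "train_accuracy") %in% names(sep$curves)))
  expect_gte(near$anova_p, 0)
  expect_lte(near$anova_p, 1)
  # separable classes are learned; near-identical classes hover near chance
  expect_gt(mean(sep$final_accuracy), 0.8)
  expect_lt(mean(near$final_accuracy), 0.65)
  expect_s3_class(ggplot2::autoplot(sep), "ggplot")
  gl <- generics::glance(sep)
  expect_identical(names(gl)[4:5], c("anova_f", "anova_p"))
})

test_that("early epochs stagnate near chance on near-identical classes", {
  hit <- vapply(1:3, function(s) {
    ds <- make_class_pair(class_pair_recipe(n_per_class = 20, side = 24,
                                            delta = 0, seed = s))
    m <- build_model(model_config(image_side = 24, omega = 2, seed = s))
    fit <- cq_train(m, ds, train_config(epochs = 2, seed = s))
    all(abs(fit$history$train_accuracy[1:2] - 0.5) <= 0.03 + 1e-9)
  }, logical(1))
  expect_gte(mean(hit), 2 / 3)
})

test_that("tidy, glance, and autoplot methods expose fits and diagnostics", {
  ds <- tiny_dataset(n_per_class = 20, side = 24, delta = 8, seed = 5)
  fit <- cq_train(build_model(model_config(image_side = 24, seed = 5)), ds,
                  train_config(epochs = 2, seed = 5, batch_size = 8))
  td <- generics::tidy(fit)
  expect_identical(names(td),
                   c("epoch", "loss", "train_accuracy", "val_accuracy"))
  gl <- generics::glance(fit)
  expect_identical(gl$epochs, 2L)
  expect_identical(gl$variant, "quantum")
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")

  metrics <- evaluate_model(fit, ds)
  long <- generics::tidy(metrics)
  expect_identical(sort(long$metric),
                   sort(c("precision", "recall", "f1", "specificity",
                          "accuracy")))
  summ <- summarize_metrics(list(metrics, metrics))
  expect_true(all(summ$sd == 0))
})
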