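#' Configure a hybrid classical-quantum model
#'
#' The architecture is a small convolutional front-end (two 5x5 valid
#' convolutions with ReLU and 2x2 max pooling), channel dropout, a dense
#' bottleneck down to `omega` features, and then either a parameterized
#' quantum circuit (variant `"quantum"`) or a matched-parameter classical
#' block (variant `"classical-control"`), followed by a 1->1 linear head, a
#' logistic squash, and the two-class output `gamma = (o1, 1 - o1)`.
#'
#' @param image_side Input edge length in pixels; 128 reproduces the
#'   reference layer shapes (124, 62, 58, 29, flatten 3364). Other sides are
#'   supported when both intermediate extents stay even and positive.
#' @param omega Qubit count (width of the bottleneck), typically 2 or 3.
#' @param variant `"quantum"` or `"classical-control"`.
#' @param dropout_rate Channel-dropout probability (default 0.25).
#' @param dialect Encoding dialect, see [encoding_spec()].
#' @param feature_scaling Feature-to-angle map before encoding (default
#'   `"pi-tanh"`, keeping phases in `(-pi, pi)`).
#' @param repetitions Ansatz repetitions (default 1).
#' @param observable PQC measurement observable, see [measure_state()].
#' @param seed Seed for weight initialization.
#' @return A `model_config` object.
#' @export
model_config <- function(image_side = 128L, omega = 2L,
                         variant = c("quantum", "classical-control"),
                         dropout_rate = 0.25,
                         dialect = "zz-interaction",
                         feature_scaling = "pi-tanh",
                         repetitions = 1L,
                         observable = "z-parity",
                         seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(omega >= 1, dropout_rate >= 0, dropout_rate < 1, repetitions >= 1)
  shapes <- .derive_shapes(image_side)
  structure(list(image_side = as.integer(image_side), omega = as.integer(omega),
                 variant = variant, dropout_rate = dropout_rate,
                 encoding = encoding_spec(omega, dialect = dialect,
                                          feature_scaling = feature_scaling),
                 repetitions = as.integer(repetitions),
                 observable = observable, seed = as.integer(seed),
                 shapes = shapes),
            class = "model_config")
}

# Shape chain for the two conv/pool stages; errors name the offending stage
# and the derived flatten length when the side is unsupported.
.derive_shapes <- function(side) {
  side <- as.integer(side)
  s1 <- side - 4L
  if (s1 < 2L || s1 %% 2L != 0L) {
    stop("image_side ", side, " unsupported: first conv output ", s1,
         " cannot be 2x2-pooled", call. = FALSE)
  }
  p1 <- s1 %/% 2L
  s2 <- p1 - 4L
  if (s2 < 2L || s2 %% 2L != 0L) {
    stop("image_side ", side, " unsupported: second conv output ", s2,
         " cannot be 2x2-pooled (flatten would need ",
         max(s2, 0L) * max(s2, 0L) * 4L, " units)", call. = FALSE)
  }
  p2 <- s2 %/% 2L
  list(conv1 = c(s1, s1, 2L), pool1 = c(p1, p1, 2L),
       conv2 = c(s2, s2, 4L), pool2 = c(p2, p2, 4L),
       flatten = 4L * p2 * p2)
}

# Kaiming-uniform bound as deep-learning frameworks parameterize it for
# conv/linear layers (gain for a = sqrt(5) leaky slope): 1 / sqrt(fan_in).
.kaiming_uniform <- function(dims, fan_in) {
  lim <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

#' Build (initialize) a model from a configuration
#'
#' Conv and dense weights use Kaiming-style uniform initialization; ansatz
#' angles start uniform on `(0, pi)` (one Ry half-period). All randomness is
#' driven by `cfg$seed`, so identical configurations give identical models.
#'
#' @param cfg A [model_config()].
#' @return A `cq_model`: list with `cfg` and the named parameter list
#'   `params`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  restore <- .Random.seed_exists()
  on.exit(restore(), add = TRUE)
  set.seed(cfg$seed)
  fl <- cfg$shapes$flatten
  w <- cfg$omega
  params <- list(
    conv1_w = .kaiming_uniform(c(5, 5, 1, 2), 25),
    conv1_b = numeric(2),
    conv2_w = .kaiming_uniform(c(5, 5, 2, 4), 50),
    conv2_b = numeric(4),
    dense1_w = .kaiming_uniform(c(4, fl), fl),
    dense1_b = numeric(4),
    dense2_w = .kaiming_uniform(c(w, 4), 4),
    dense2_b = numeric(w),
    out_w = .kaiming_uniform(c(1, 1), 1),
    out_b = numeric(1)
  )
  # calibrate the head: a mid-range circuit output q = 0.5 maps to
  # probability 0.5, so early training is spent on discrimination rather
  # than on re-centering the output bias
  params$out_b <- -0.5 * params$out_w[1, 1]
  if (cfg$variant == "quantum") {
    params$theta <- stats::runif(w * cfg$repetitions, 0, pi)
  } else {
    # matched-parameter classical block: omega scalars, no bias, so the
    # trainable count equals the quantum branch's ansatz exactly
    params$mid_w <- .kaiming_uniform(c(w * cfg$repetitions), w)
  }
  structure(list(cfg = cfg, params = params), class = "cq_model")
}

#' @export
print.cq_model <- function(x, ...) {
  pc <- count_parameters(x$cfg)
  cat("<cq_model> variant:", x$cfg$variant, " omega:", x$cfg$omega,
      " side:", x$cfg$image_side, "\n")
  cat("  trainable parameters:", attr(pc, "grand_total"),
      sprintf(" (%.2f MB at 32-bit)", model_size_mb(x$cfg)), "\n")
  invisible(x)
}

#' Per-layer trainable-parameter accounting
#'
#' Closed-form counts: a convolution holds `(kh*kw*in + 1)*out` parameters,
#' a dense layer `(in + 1)*out`. At `image_side = 128` the fixed classical
#' layers (Conv1, Conv2, Dense1, Output) hold 52 + 204 + 13,460 + 2 =
#' 13,718 parameters; the bottleneck contributes `(4*omega) + omega` and
#' the quantum (or matched classical) block `omega * repetitions`, for a
#' grand total of `13,718 + 5*omega + omega*repetitions`.
#'
#' @param cfg A [model_config()] or `cq_model`.
#' @return A tibble (class `cq_param_count`) with columns `layer`, `type`,
#'   `output_shape`, `parameters`, and attributes `fixed_total`,
#'   `omega_term`, `pqc_term`, `grand_total`.
#' @export
#' @examples
#' count_parameters(model_config(omega = 3))
count_parameters <- function(cfg) {
  if (inherits(cfg, "cq_model")) cfg <- cfg$cfg
  stopifnot(inherits(cfg, "model_config"))
  sh <- cfg$shapes
  w <- cfg$omega
  fmt <- function(d) paste(rev(d), collapse = "x")  # channels-first display
  conv1 <- (5L * 5L * 1L + 1L) * 2L
  conv2 <- (5L * 5L * 2L + 1L) * 4L
  dense1 <- (sh$flatten + 1L) * 4L
  dense2 <- (4L + 1L) * w
  pqc <- w * cfg$repetitions
  outp <- (1L + 1L) * 1L
  mid_name <- if (cfg$variant == "quantum") "PQC" else "ClassicalMid"
  tb <- tibble::tibble(
    layer = c("Input", "Conv1", "MaxPool1", "Conv2", "MaxPool2", "Dropout",
              "Flatten", "Dense1", "Dense2", mid_name, "Output"),
    type = c("-", "Conv2D", "MaxPooling2D", "Conv2D", "MaxPooling2D",
             "Dropout2D", "Flatten", "Fully Connected", "Fully Connected",
             if (cfg$variant == "quantum") "QuantumCircuit" else "Fully Connected",
             "Fully Connected"),
    output_shape = c(paste0("1x", cfg$image_side, "x", cfg$image_side),
                     fmt(sh$conv1), fmt(sh$pool1), fmt(sh$conv2),
                     fmt(sh$pool2), fmt(sh$pool2),
                     as.character(sh$flatten), "1x4", paste0("1x", w),
                     "1x1", "1x1"),
    parameters = c(0L, conv1, 0L, conv2, 0L, 0L, 0L, dense1, dense2, pqc, outp)
  )
  fixed <- conv1 + conv2 + dense1 + outp
  structure(tb, class = c("cq_param_count", class(tb)),
            fixed_total = fixed, omega_term = dense2, pqc_term = pqc,
            grand_total = fixed + dense2 + pqc)
}

#' @export
print.cq_param_count <- function(x, ...) {
  NextMethod()
  cat("fixed total:", attr(x, "fixed_total"),
      " + bottleneck:", attr(x, "omega_term"),
      " + circuit:", attr(x, "pqc_term"),
      " = ", attr(x, "grand_total"), "\n")
  invisible(x)
}

#' Serialized model size at 32-bit precision
#'
#' @param x A `model_config`, `cq_model`, or integer parameter count.
#' @return Size in MB (megabytes, 2^20 bytes) of the trainable parameters
#'   stored as 32-bit floats.
#' @export
model_size_mb <- function(x) {
  n <- if (is.numeric(x)) x else attr(count_parameters(x), "grand_total")
  n * 4 / 2^20
}

# ---- forward / backward ----------------------------------------------------

# Full forward pass for one image (side x side matrix). Returns o1 plus the
# cache needed for backprop. Dropout is active only when training = TRUE and
# draws from the current RNG stream.
.forward_sample <- function(model, img, training = FALSE) {
  cfg <- model$cfg; p <- model$params
  if (!is.matrix(img) || !all(dim(img) == cfg$image_side)) {
    stop("expected a ", cfg$image_side, "x", cfg$image_side,
         " single-channel image, got ",
         paste(dim(img), collapse = "x"), call. = FALSE)
  }
  x0 <- array(img, c(dim(img), 1L))
  z1 <- .conv_forward(x0, p$conv1_w, p$conv1_b)
  a1 <- .relu_forward(z1)
  pl1 <- .pool_forward(a1)
  z2 <- .conv_forward(pl1$out, p$conv2_w, p$conv2_b)
  a2 <- .relu_forward(z2)
  pl2 <- .pool_forward(a2)
  if (training && cfg$dropout_rate > 0) {
    dr <- .dropout2d_forward(pl2$out, cfg$dropout_rate)
  } else {
    dr <- list(out = pl2$out, scale = rep(1, dim(pl2$out)[3]))
  }
  flat <- as.vector(dr$out)
  zd1 <- .dense_forward(flat, p$dense1_w, p$dense1_b)
  ad1 <- .relu_forward(zd1)
  zd2 <- .dense_forward(ad1, p$dense2_w, p$dense2_b)
  if (cfg$variant == "quantum") {
    q <- pqc_forward(zd2, p$theta, cfg$encoding, cfg$repetitions,
                     cfg$observable)
  } else {
    # first omega scalars weight the bottleneck; any further repetition
    # scalars enter additively (matched-count stand-ins for extra ansatz
    # layers)
    w <- cfg$omega
    act <- sum(p$mid_w[seq_len(w)] * zd2) +
      if (length(p$mid_w) > w) sum(p$mid_w[-seq_len(w)]) else 0
    q <- .sigmoid(act)
  }
  u <- p$out_w[1, 1] * q + p$out_b
  o1 <- .sigmoid(u)
  list(o1 = o1, cache = list(x0 = x0, z1 = z1, pl1 = pl1, z2 = z2,
                             a2_dim = dim(a2), pl2 = pl2, dr = dr,
                             flat = flat, zd1 = zd1, ad1 = ad1, zd2 = zd2,
                             q = q, u = u, o1 = o1))
}

# Per-sample gradient of the cross-entropy loss w.r.t. every parameter.
# label in {0, 1}; gamma = (o1, 1 - o1) so class 0 has probability o1.
.backward_sample <- function(model, cache, label) {
  cfg <- model$cfg; p <- model$params
  o1 <- cache$o1
  p_true <- if (label == 0L) o1 else 1 - o1
  dL_do1 <- if (label == 0L) -1 / max(p_true, 1e-12) else 1 / max(p_true, 1e-12)
  du <- dL_do1 * o1 * (1 - o1)
  g <- list(out_w = matrix(du * cache$q, 1, 1), out_b = du)
  dq <- du * p$out_w[1, 1]
  if (cfg$variant == "quantum") {
    g$theta <- dq * parameter_shift_grad(cache$zd2, p$theta, cfg$encoding,
                                         cfg$repetitions, cfg$observable)
    dzd2 <- dq * input_grad(cache$zd2, p$theta, cfg$encoding,
                            cfg$repetitions, cfg$observable)
  } else {
    sq <- cache$q * (1 - cache$q)
    w <- cfg$omega
    g$mid_w <- dq * sq * c(cache$zd2, rep(1, length(p$mid_w) - w))
    dzd2 <- dq * sq * p$mid_w[seq_len(w)]
  }
  d2 <- .dense_backward(cache$ad1, p$dense2_w, dzd2)
  g$dense2_w <- d2$dw; g$dense2_b <- d2$db
  dad1 <- .relu_backward(cache$zd1, d2$dx)
  d1 <- .dense_backward(cache$flat, p$dense1_w, dad1)
  g$dense1_w <- d1$dw; g$dense1_b <- d1$db
  dflat <- array(d1$dx, dim(cache$dr$out))
  dflat <- .dropout2d_backward(cache$dr$scale, dflat)
  dpool2 <- .pool_backward(cache$pl2$amax, dflat, cache$a2_dim)
  dz2 <- .relu_backward(cache$z2, dpool2)
  c2 <- .conv_backward(cache$pl1$out, p$conv2_w, dz2)
  g$conv2_w <- c2$dw; g$conv2_b <- c2$db
  dpool1 <- .pool_backward(cache$pl1$amax, c2$dx, dim(cache$z1))
  dz1 <- .relu_backward(cache$z1, dpool1)
  c1 <- .conv_backward(cache$x0, p$conv1_w, dz1, need_dx = FALSE)
  g$conv1_w <- c1$dw; g$conv1_b <- c1$db
  g
}

#' Forward pass over a batch of images
#'
#' @param model A [build_model()] result.
#' @param images A list of `side x side` matrices, or a single matrix.
#' @param training Apply channel dropout (draws from the current RNG
#'   stream)? Default `FALSE` (deterministic evaluation).
#' @return A tibble with one row per input: `o1`, `gamma0`, `gamma1`
#'   (`gamma = (o1, 1 - o1)`), and the argmax `predicted` label (0/1,
#'   class 0 wins ties).
#' @export
predict_model <- function(model, images, training = FALSE) {
  stopifnot(inherits(model, "cq_model"))
  if (is.matrix(images)) images <- list(images)
  o1 <- vapply(images, function(im) .forward_sample(model, im, training)$o1,
               numeric(1))
  tibble::tibble(o1 = o1, gamma0 = o1, gamma1 = 1 - o1,
                 predicted = ifelse(o1 >= 0.5, 0L, 1L))
}

#' @export
predict.cq_model <- function(object, images, ...) {
  predict_model(object, images)
}

# ---- flat parameter <-> list utilities (optimizers, checkpoints) ----------

.flatten_params <- function(params) {
  unlist(lapply(params, as.numeric), use.names = FALSE)
}

.unflatten_params <- function(flat, template) {
  out <- template
  pos <- 0L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    v <- flat[pos + seq_len(n)]
    out[[nm]] <- if (is.array(template[[nm]])) array(v, dim(template[[nm]])) else v
    pos <- pos + n
  }
  stopifnot(pos == length(flat))
  out
}

#' Save / load a model checkpoint
#'
#' Single-file JSON container: a config header plus the flat parameter
#' record (base64-encoded IEEE-754 doubles, so the round trip is bit-exact).
#'
#' @param model A `cq_model`.
#' @param path Destination file.
#' @return `path` invisibly for `cq_save_model()`; the restored `cq_model`
#'   for `cq_load_model()`.
#' @export
cq_save_model <- function(model, path) {
  stopifnot(inherits(model, "cq_model"))
  cfg <- model$cfg
  payload <- list(
    format = "cqcnn-checkpoint",
    version = 1L,
    config = list(image_side = cfg$image_side, omega = cfg$omega,
                  variant = cfg$variant, dropout_rate = cfg$dropout_rate,
                  dialect = cfg$encoding$dialect,
                  feature_scaling = cfg$encoding$feature_scaling,
                  repetitions = cfg$repetitions, observable = cfg$observable,
                  seed = cfg$seed),
    param_names = names(model$params),
    param_doubles = jsonlite::base64_enc(
      writeBin(.flatten_params(model$params), raw(), size = 8L,
               endian = "little"))
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname cq_save_model
#' @export
cq_load_model <- function(path) {
  payload <- tryCatch(jsonlite::fromJSON(path),
                      error = function(e) stop("not a readable checkpoint: ",
                                               conditionMessage(e),
                                               call. = FALSE))
  if (!identical(payload$format, "cqcnn-checkpoint")) {
    stop("'", path, "' is not a cqcnn checkpoint (missing format header)",
         call. = FALSE)
  }
  if (!identical(as.integer(payload$version), 1L)) {
    stop("unsupported checkpoint version: ", payload$version, call. = FALSE)
  }
  cf <- payload$config
  cfg <- model_config(image_side = cf$image_side, omega = cf$omega,
                      variant = cf$variant, dropout_rate = cf$dropout_rate,
                      dialect = cf$dialect,
                      feature_scaling = cf$feature_scaling,
                      repetitions = cf$repetitions, observable = cf$observable,
                      seed = cf$seed)
  model <- build_model(cfg)
  if (!identical(payload$param_names, names(model$params))) {
    stop("checkpoint parameter record does not match the configured ",
         "architecture", call. = FALSE)
  }
  raw_bytes <- jsonlite::base64_dec(payload$param_doubles)
  flat <- readBin(raw_bytes, what = "numeric", size = 8L,
                  n = length(raw_bytes) / 8L, endian = "little")
  if (length(flat) != length(.flatten_params(model$params))) {
    stop("checkpoint parameter record has wrong length (corrupted file?)",
         call. = FALSE)
  }
  model$params <- .unflatten_params(flat, model$params)
  model
}
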