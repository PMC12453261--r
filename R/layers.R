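# CNN layer primitives. Feature maps are H x W x C arrays; kernels are
# kh x kw x Cin x Cout; dense weights are out x in matrices. The
# convolution and pooling hot loops live in src/conv.cpp; these wrappers
# keep the layer contracts in one place.

.conv_forward <- function(x, w, b) .cpp_conv_forward(x, w, b)

.conv_backward <- function(x, w, dout, need_dx = TRUE) {
  .cpp_conv_backward(x, w, dout, need_dx)
}

.pool_forward <- function(x) {
  d <- dim(x)
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L) {
    stop("pooling input extents must be even, got ",
         d[1], "x", d[2], call. = FALSE)
  }
  .cpp_pool_forward(x)
}

.pool_backward <- function(amax, dout, in_dim) {
  .cpp_pool_backward(amax, dout, as.integer(in_dim))
}

.relu_forward <- function(x) pmax(x, 0)
.relu_backward <- function(x, dout) dout * (x > 0)

.dense_forward <- function(x, w, b) drop(w %*% x) + b
.dense_backward <- function(x, w, dout) {
  list(dx = drop(crossprod(w, dout)), dw = outer(dout, x), db = dout)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Channel-wise (2D) dropout: zeroes whole feature maps with prob `rate`,
# rescaling survivors by 1/(1-rate). Returns the mask for backprop.
.dropout2d_forward <- function(x, rate) {
  ch <- dim(x)[3]
  keep <- stats::runif(ch) >= rate
  scale <- ifelse(keep, 1 / (1 - rate), 0)
  for (c0 in seq_len(ch)) x[, , c0] <- x[, , c0] * scale[c0]
  list(out = x, scale = scale)
}

.dropout2d_backward <- function(scale, dout) {
  for (c0 in seq_along(scale)) dout[, , c0] <- dout[, , c0] * scale[c0]
  dout
}
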