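# Minimal hand-written layers for the desk-scale detector. Feature maps are
# R arrays (H, W, C); "position matrices" are (H*W, C) reshapes in R's
# column-major order, so position p = i + (j - 1) * H.

relu <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) return(cpp_relu(x))
  x[x < 0] <- 0
  x
}

relu_bw <- function(pre, dout) {
  if (is.array(pre) && length(dim(pre)) == 3) return(cpp_relu_bw(pre, dout))
  dout * (pre > 0)
}

# forward keeps the im2col matrix (`m`) so backward need not rebuild it
conv_fw <- function(x, p, stride, pad = 1L) {
  k <- attr(p$w, "ksize")
  cpp_conv2d_forward(x, p$w, p$b, k, k, stride, pad)
}

conv_bw <- function(fwd, xdim, p, dout, stride, pad = 1L, skip_dx = FALSE) {
  k <- attr(p$w, "ksize")
  cpp_conv2d_backward(fwd$m, p$w, dout, xdim, k, k, stride, pad, skip_dx)
}

conv_param <- function(k, cin, cout) {
  fan_in <- k * k * cin
  w <- matrix(stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout)
  attr(w, "ksize") <- as.integer(k)
  list(w = w, b = rep(0, cout))
}

fc_param <- function(din, dout, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / din)
  list(w = matrix(stats::rnorm(din * dout, sd = sd), din, dout), b = rep(0, dout))
}

fc_fw <- function(x, p) {
  sweep(x %*% p$w, 2, p$b, "+")
}

# returns list(dx, dw, db)
fc_bw <- function(x, p, dout) {
  list(dx = dout %*% t(p$w), dw = t(x) %*% dout, db = colSums(dout))
}

softmax_rows <- function(logits) {
  mx <- apply(logits, 1, max)
  e <- exp(logits - mx)
  e / rowSums(e)
}

# d/dpred of elementwise smooth L1 applied to (pred - target)
smooth_l1_grad <- function(d) {
  ifelse(abs(d) < 1, d, sign(d))
}

# Global L2 norm over every numeric leaf; rescale if above clip.
clip_gradients <- function(grads, clip) {
  nrm <- sqrt(cpp_sq_norm(grads))
  if (is.finite(nrm) && nrm > clip) {
    grads <- rapply(grads, function(v) v * (clip / nrm), how = "replace")
  }
  grads
}

sgd_update <- function(params, grads, velocity, lr, momentum) {
  for (nm in names(params)) {
    for (leaf in names(params[[nm]])) {
      v <- momentum * velocity[[nm]][[leaf]] - lr * grads[[nm]][[leaf]]
      velocity[[nm]][[leaf]] <- v
      a <- attributes(params[[nm]][[leaf]])
      params[[nm]][[leaf]] <- params[[nm]][[leaf]] + v
      attributes(params[[nm]][[leaf]]) <- a
    }
  }
  list(params = params, velocity = velocity)
}

zero_like <- function(params) {
  rapply(params, function(v) v * 0, how = "replace")
}
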