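# Minimal dense-network plumbing: parameter initialization and Adam.
# Parameters are flat named lists of matrices/vectors; gradients mirror the
# structure. Everything is driven by R's RNG so runs are seed-reproducible.

init_weight <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / (fan_in + fan_out))),
         nrow = fan_in, ncol = fan_out)
}

init_bias <- function(fan_out) numeric(fan_out)

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (inherits(g, "sliced_grad")) {
      # column-subsampled gradient: touch only the sampled columns
      cols <- g$cols; G <- g$G
      m <- beta1 * state$m[[nm]][, cols, drop = FALSE] + (1 - beta1) * G
      v <- beta2 * state$v[[nm]][, cols, drop = FALSE] + (1 - beta2) * G * G
      state$m[[nm]][, cols] <- m
      state$v[[nm]][, cols] <- v
      params[[nm]][, cols] <- params[[nm]][, cols, drop = FALSE] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    } else {
      state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
      state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
      params[[nm]] <- params[[nm]] -
        lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

head_grad <- function(G, cols = NULL) {
  if (is.null(cols)) G else structure(list(G = G, cols = cols),
                                      class = "sliced_grad")
}

scale_grad <- function(x, scale) {
  if (inherits(x, "sliced_grad")) { x$G <- x$G * scale; x } else x * scale
}

# Accumulate grads b into a (same structure), treating missing as zero.
grads_add <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}

# y = relu(x W + b) forward returning activation.
dense_relu <- function(x, W, b) relu(sweep(x %*% W, 2, b, "+"))

dense_linear <- function(x, W, b) sweep(x %*% W, 2, b, "+")

# Backward through y = relu(xW + b): given dy and the activation y.
dense_relu_backward <- function(x, W, y, dy) {
  dpre <- dy * (y > 0)
  list(dx = dpre %*% t(W), dW = crossprod(x, dpre), db = colSums(dpre))
}

dense_linear_backward <- function(x, W, dy) {
  list(dx = dy %*% t(W), dW = crossprod(x, dy), db = colSums(dy))
}
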