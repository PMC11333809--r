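# Shared neural-network utilities: parameter initialization and the Adam
# optimizer, operating on flat named lists of numeric arrays.

sigmoid <- function(x) 1 / (1 + exp(-x))

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

glorot_init <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# gradient of the combined 0.5*DiceLoss + 0.5*BCE loss with respect to the
# pre-sigmoid logits, given prediction p = sigmoid(z) and hard target g
combined_loss_grad_logits <- function(p, g, smooth = 1e-5) {
  n <- length(p)
  A <- 2 * sum(p * g) + smooth
  B <- sum(p) + sum(g) + smooth
  ddice_dp <- (2 * g * B - A) / B^2
  # d/dz [0.5*BCE] = 0.5*(p-g)/n ; d/dz [0.5*(1-dice)] = -0.5*ddice_dp*p(1-p)
  0.5 * (p - g) / n - 0.5 * ddice_dp * p * (1 - p)
}
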