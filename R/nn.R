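# Compact dense-network trainer on BLAS matrix ops: arbitrary layer widths,
# relu/sigmoid/linear activations, MSE or softmax cross-entropy loss, Adam
# updates, seeded initialization and shuffling. Deterministic for a fixed
# seed on a fixed BLAS.

mlp_init <- function(widths, activations, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_layer <- length(widths) - 1
  stopifnot(length(activations) == n_layer)
  layers <- vector("list", n_layer)
  for (i in seq_len(n_layer)) {
    fan_in <- widths[i]; fan_out <- widths[i + 1]
    sd <- if (activations[i] == "relu") sqrt(2 / fan_in) else
      sqrt(2 / (fan_in + fan_out))
    layers[[i]] <- list(
      w = matrix(stats::rnorm(fan_in * fan_out, 0, sd), fan_in, fan_out),
      b = numeric(fan_out),
      act = activations[i])
  }
  list(layers = layers, widths = widths)
}

mlp_act <- function(z, act) {
  switch(act,
         relu = pmax(z, 0),
         # logits clamped to +/-30, matching the compiled core (avoids
         # subnormal outputs from saturated units)
         sigmoid = 1 / (1 + exp(-pmin(pmax(z, -30), 30))),
         linear = z)
}

mlp_forward <- function(net, x, keep = FALSE) {
  as_list <- if (keep) vector("list", length(net$layers) + 1) else NULL
  h <- x
  if (keep) as_list[[1]] <- h
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    z <- h %*% ly$w
    z <- sweep(z, 2, ly$b, "+")
    h <- mlp_act(z, ly$act)
    if (keep) as_list[[i + 1]] <- h
  }
  if (keep) list(out = h, acts = as_list) else h
}

# Gradient of loss w.r.t. parameters. For loss = "mse" the output layer may
# be sigmoid or linear; for "softmax_ce" the final activation must be linear
# (logits) and y must be a one-hot matrix.
mlp_backward <- function(net, acts, y, loss) {
  n_layer <- length(net$layers)
  out <- acts[[n_layer + 1]]
  n <- nrow(out)
  if (loss == "mse") {
    delta <- 2 * (out - y) / length(y)
    act <- net$layers[[n_layer]]$act
    if (act == "sigmoid") delta <- delta * out * (1 - out)
    else if (act == "relu") delta <- delta * (out > 0)
  } else { # softmax cross-entropy on logits
    m <- apply(out, 1, max)
    e <- exp(out - m)
    probs <- e / rowSums(e)
    delta <- (probs - y) / n
  }
  grads <- vector("list", n_layer)
  for (i in n_layer:1) {
    h_prev <- acts[[i]]
    grads[[i]] <- list(w = crossprod(h_prev, delta), b = colSums(delta))
    if (i > 1) {
      delta <- delta %*% t(net$layers[[i]]$w)
      act <- net$layers[[i - 1]]$act
      h <- acts[[i]]
      if (act == "relu") delta <- delta * (h > 0)
      else if (act == "sigmoid") delta <- delta * h * (1 - h)
    }
  }
  grads
}

mlp_loss <- function(out, y, loss) {
  if (loss == "mse") return(mean((out - y)^2))
  m <- apply(out, 1, max)
  e <- exp(out - m)
  lse <- log(rowSums(e)) + m
  mean(rowSums(y * out) * -1 + lse)
}

adam_init <- function(net) {
  lapply(net$layers, function(ly) list(
    mw = matrix(0, nrow(ly$w), ncol(ly$w)), vw = matrix(0, nrow(ly$w), ncol(ly$w)),
    mb = numeric(length(ly$b)), vb = numeric(length(ly$b))))
}

adam_step <- function(net, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]; s <- state[[i]]
    s$mw <- beta1 * s$mw + (1 - beta1) * g$w
    s$vw <- beta2 * s$vw + (1 - beta2) * g$w^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    net$layers[[i]]$w <- net$layers[[i]]$w -
      lr * (s$mw / bc1) / (sqrt(s$vw / bc2) + eps)
    net$layers[[i]]$b <- net$layers[[i]]$b -
      lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[i]] <- s
  }
  list(net = net, state = state)
}

# Mini-batch Adam training loop. `x`, `y` are row-per-sample matrices. The
# heavy loop runs in the compiled core (src/fcnet.cpp) with in-place
# parameter updates; initialization and shuffling orders are drawn from R's
# RNG here, so a run is a pure function of `seed`. The learning rate steps
# down by `lr_decay` at one third and two thirds of the epochs.
mlp_fit <- function(x, y, widths, activations, loss = "mse", epochs = 20,
                    batch_size = 128, lr = 1e-3, lr_decay = 0.3, seed = 1,
                    verbose = FALSE) {
  net <- mlp_init(widths, activations, seed)
  n <- nrow(x)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed + 1)
  perms <- vapply(seq_len(epochs), function(i) sample.int(n) - 1L,
                  integer(n))
  lr_per_epoch <- lr * lr_decay^(floor(3 * (seq_len(epochs) - 1) / epochs))
  act_code <- match(activations, c("linear", "relu", "sigmoid")) - 1L
  fit <- fc_fit_core(x, y,
                     lapply(net$layers, `[[`, "w"),
                     lapply(net$layers, `[[`, "b"),
                     act_code, if (loss == "mse") 0L else 1L,
                     as.integer(epochs), as.integer(batch_size),
                     lr_per_epoch, perms, 0.9, 0.999, 1e-8,
                     as.integer(isTRUE(verbose)))
  for (i in seq_along(net$layers)) {
    net$layers[[i]]$w <- fit$w[[i]]
    net$layers[[i]]$b <- as.numeric(fit$b[[i]])
  }
  net$history <- as.numeric(fit$history)
  net
}
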