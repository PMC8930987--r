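# Small convolutional encoder-decoder ("U-Net"-style) on the 64x64 waveform
# reshape: three 2x2 poolings, a bottleneck, nearest-neighbour upsampling
# with skip concatenations, and a sigmoid 1x1 output head. Convolutions are
# 3x3 same-padding via im2col matrix products. Production training runs in
# the compiled core (src/convnet.cpp); the pure-R forward/backward pass
# below is the reference implementation the compiled core is tested
# against. This layout is this package's own; deeper per-level stacks are a
# straightforward extension.

# x: array (B, H, W, C). Returns matrix (B*H*W, 9*C).
im2col3 <- function(x) {
  d <- dim(x)
  b <- d[1]; h <- d[2]; w <- d[3]; cc <- d[4]
  xp <- array(0, c(b, h + 2, w + 2, cc))
  xp[, 2:(h + 1), 2:(w + 1), ] <- x
  cols <- matrix(0, b * h * w, 9 * cc)
  k <- 1
  for (dy in 0:2) for (dx in 0:2) {
    patch <- xp[, (1 + dy):(h + dy), (1 + dx):(w + dx), , drop = FALSE]
    cols[, k:(k + cc - 1)] <- matrix(patch, b * h * w, cc)
    k <- k + cc
  }
  cols
}

col2im3 <- function(dcol, b, h, w, cc) {
  dxp <- array(0, c(b, h + 2, w + 2, cc))
  k <- 1
  for (dy in 0:2) for (dx in 0:2) {
    patch <- array(dcol[, k:(k + cc - 1)], c(b, h, w, cc))
    dxp[, (1 + dy):(h + dy), (1 + dx):(w + dx), ] <-
      dxp[, (1 + dy):(h + dy), (1 + dx):(w + dx), , drop = FALSE] + patch
    k <- k + cc
  }
  dxp[, 2:(h + 1), 2:(w + 1), , drop = FALSE]
}

conv3_fwd <- function(x, layer) {
  d <- dim(x)
  col <- im2col3(x)
  y <- col %*% layer$w
  y <- sweep(y, 2, layer$b, "+")
  list(out = array(y, c(d[1], d[2], d[3], ncol(layer$w))), col = col)
}

conv3_bwd <- function(dy, cache_col, layer, xdim) {
  dym <- matrix(dy, nrow = nrow(cache_col))
  dw <- crossprod(cache_col, dym)
  db <- colSums(dym)
  dcol <- dym %*% t(layer$w)
  dx <- col2im3(dcol, xdim[1], xdim[2], xdim[3], xdim[4])
  list(dx = dx, w = dw, b = db)
}

pool2_fwd <- function(x) {
  d <- dim(x)
  h2 <- d[2] / 2; w2 <- d[3] / 2
  x5 <- array(x, c(d[1], 2, h2, 2, w2, d[4]))
  cand <- array(0, c(d[1], h2, w2, d[4], 4))
  cand[, , , , 1] <- x5[, 1, , 1, , ]
  cand[, , , , 2] <- x5[, 2, , 1, , ]
  cand[, , , , 3] <- x5[, 1, , 2, , ]
  cand[, , , , 4] <- x5[, 2, , 2, , ]
  out <- pmax(cand[, , , , 1], cand[, , , , 2], cand[, , , , 3],
              cand[, , , , 4])
  out <- array(out, c(d[1], h2, w2, d[4]))
  # argmax mask for backward (first max wins)
  first <- array(0, dim(cand))
  taken <- array(FALSE, c(d[1], h2, w2, d[4]))
  for (k in 1:4) {
    sel <- (cand[, , , , k] == out) & !taken
    first[, , , , k] <- sel
    taken <- taken | sel
  }
  list(out = out, mask = first, xdim = d)
}

pool2_bwd <- function(dy, cache) {
  d <- cache$xdim
  h2 <- d[2] / 2; w2 <- d[3] / 2
  dstack <- array(rep(dy, 4), c(d[1], h2, w2, d[4], 4)) * cache$mask
  dx5 <- array(0, c(d[1], 2, h2, 2, w2, d[4]))
  dx5[, 1, , 1, , ] <- dstack[, , , , 1]
  dx5[, 2, , 1, , ] <- dstack[, , , , 2]
  dx5[, 1, , 2, , ] <- dstack[, , , , 3]
  dx5[, 2, , 2, , ] <- dstack[, , , , 4]
  array(dx5, d)
}

up2_fwd <- function(x) {
  d <- dim(x)
  idx_h <- rep(seq_len(d[2]), each = 2)
  idx_w <- rep(seq_len(d[3]), each = 2)
  x[, idx_h, idx_w, , drop = FALSE]
}

up2_bwd <- function(dy) {
  d <- dim(dy)
  h2 <- d[2] / 2; w2 <- d[3] / 2
  dy5 <- array(dy, c(d[1], 2, h2, 2, w2, d[4]))
  dy5[, 1, , 1, , , drop = FALSE] + dy5[, 2, , 1, , , drop = FALSE] +
    dy5[, 1, , 2, , , drop = FALSE] + dy5[, 2, , 2, , , drop = FALSE] ->
    s
  array(s, c(d[1], h2, w2, d[4]))
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

unet_layer_specs <- function(base = 8) {
  c1 <- base; c2 <- 2 * base; c3 <- 4 * base; cb <- 8 * base
  list(
    e1 = c(9 * 1, c1), e2 = c(9 * c1, c2), e3 = c(9 * c2, c3),
    bn = c(9 * c3, cb),
    d3 = c(9 * (cb + c3), c3), d2 = c(9 * (c3 + c2), c2),
    d1 = c(9 * (c2 + c1), c1),
    out = c(c1, 1))
}

unet_init <- function(seed, base = 8) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  specs <- unet_layer_specs(base)
  layers <- lapply(specs, function(s) {
    sd <- sqrt(2 / s[1])
    list(w = matrix(stats::rnorm(s[1] * s[2], 0, sd), s[1], s[2]),
         b = numeric(s[2]))
  })
  list(layers = layers, base = base)
}

relu_ <- function(x) {
  x[x < 0] <- 0
  x
}

unet_forward <- function(net, x, keep = FALSE) {
  ly <- net$layers
  cv <- function(x, l) conv3_fwd(x, ly[[l]])
  f1 <- cv(x, "e1");  a1 <- relu_(f1$out)
  p1 <- pool2_fwd(a1)
  f2 <- cv(p1$out, "e2"); a2 <- relu_(f2$out)
  p2 <- pool2_fwd(a2)
  f3 <- cv(p2$out, "e3"); a3 <- relu_(f3$out)
  p3 <- pool2_fwd(a3)
  fb <- cv(p3$out, "bn"); ab <- relu_(fb$out)
  u3 <- concat_c(up2_fwd(ab), a3)
  g3 <- cv(u3, "d3"); b3 <- relu_(g3$out)
  u2 <- concat_c(up2_fwd(b3), a2)
  g2 <- cv(u2, "d2"); b2 <- relu_(g2$out)
  u1 <- concat_c(up2_fwd(b2), a1)
  g1 <- cv(u1, "d1"); b1 <- relu_(g1$out)
  # 1x1 sigmoid head
  d <- dim(b1)
  zm <- matrix(b1, d[1] * d[2] * d[3], d[4]) %*% ly$out$w
  zm <- sweep(zm, 2, ly$out$b, "+")
  zm <- pmin(pmax(zm, -30), 30) # keep saturated outputs non-subnormal
  out <- array(1 / (1 + exp(-zm)), c(d[1], d[2], d[3], 1))
  if (!keep) return(out)
  list(out = out, x = x, f1 = f1, a1 = a1, p1 = p1, f2 = f2, a2 = a2,
       p2 = p2, f3 = f3, a3 = a3, p3 = p3, fb = fb, ab = ab,
       u3 = u3, g3 = g3, b3 = b3, u2 = u2, g2 = g2, b2 = b2,
       u1 = u1, g1 = g1, b1 = b1)
}

split_c <- function(d, c_first) {
  list(first = d[, , , seq_len(c_first), drop = FALSE],
       second = d[, , , -seq_len(c_first), drop = FALSE])
}

unet_backward <- function(net, cache, y, loss_scale = NULL) {
  ly <- net$layers
  out <- cache$out
  n_el <- length(out)
  dz <- 2 * (out - y) / n_el * out * (1 - out) # MSE through sigmoid
  d <- dim(cache$b1)
  dzm <- matrix(dz, d[1] * d[2] * d[3], 1)
  b1m <- matrix(cache$b1, d[1] * d[2] * d[3], d[4])
  grads <- list()
  grads$out <- list(w = crossprod(b1m, dzm), b = colSums(dzm))
  db1 <- array(dzm %*% t(ly$out$w), d) * (cache$b1 > 0)
  g1 <- conv3_bwd(db1, cache$g1$col, ly$d1, dim(cache$u1))
  grads$d1 <- list(w = g1$w, b = g1$b)
  sp <- split_c(g1$dx, dim(cache$b2)[4] * 1) # upsampled b2 channels first
  db2 <- up2_bwd(sp$first) + 0
  da1_skip <- sp$second
  db2 <- db2 * (cache$b2 > 0) * 1
  # note: relu mask applies to b2 itself
  g2 <- conv3_bwd(db2, cache$g2$col, ly$d2, dim(cache$u2))
  grads$d2 <- list(w = g2$w, b = g2$b)
  sp <- split_c(g2$dx, dim(cache$b3)[4])
  db3 <- up2_bwd(sp$first) * (cache$b3 > 0)
  da2_skip <- sp$second
  g3 <- conv3_bwd(db3, cache$g3$col, ly$d3, dim(cache$u3))
  grads$d3 <- list(w = g3$w, b = g3$b)
  sp <- split_c(g3$dx, dim(cache$ab)[4])
  dab <- up2_bwd(sp$first) * (cache$ab > 0)
  da3_skip <- sp$second
  gb <- conv3_bwd(dab, cache$fb$col, ly$bn, dim(cache$p3$out))
  grads$bn <- list(w = gb$w, b = gb$b)
  da3 <- pool2_bwd(gb$dx, cache$p3) + da3_skip
  da3 <- da3 * (cache$a3 > 0)
  ge3 <- conv3_bwd(da3, cache$f3$col, ly$e3, dim(cache$p2$out))
  grads$e3 <- list(w = ge3$w, b = ge3$b)
  da2 <- pool2_bwd(ge3$dx, cache$p2) + da2_skip
  da2 <- da2 * (cache$a2 > 0)
  ge2 <- conv3_bwd(da2, cache$f2$col, ly$e2, dim(cache$p1$out))
  grads$e2 <- list(w = ge2$w, b = ge2$b)
  da1 <- pool2_bwd(ge2$dx, cache$p1) + da1_skip
  da1 <- da1 * (cache$a1 > 0)
  ge1 <- conv3_bwd(da1, cache$f1$col, ly$e1, dim(cache$x))
  grads$e1 <- list(w = ge1$w, b = ge1$b)
  grads[names(ly)]
}

unet_fit <- function(x, y, epochs = 10, batch_size = 32, lr = 1e-3,
                     lr_decay = 0.3, seed = 1, base = 8, verbose = FALSE) {
  side <- as.integer(round(sqrt(ncol(x))))
  net <- unet_init(seed, base)
  n <- nrow(x)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed + 1)
  perms <- vapply(seq_len(epochs), function(i) sample.int(n) - 1L,
                  integer(n))
  lr_per_epoch <- lr * lr_decay^(floor(3 * (seq_len(epochs) - 1) / epochs))
  fit <- unet_fit_core(x, y,
                       lapply(net$layers, `[[`, "w"),
                       lapply(net$layers, `[[`, "b"),
                       as.integer(base), side, as.integer(epochs),
                       as.integer(batch_size), lr_per_epoch, perms,
                       0.9, 0.999, 1e-8, as.integer(isTRUE(verbose)))
  for (i in seq_along(net$layers)) {
    net$layers[[i]]$w <- fit$w[[i]]
    net$layers[[i]]$b <- as.numeric(fit$b[[i]])
  }
  net$history <- as.numeric(fit$history)
  net
}
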