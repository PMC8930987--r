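# Network engines: the compiled cores are cross-checked against the pure-R
# reference implementations, and the R backward pass against numerical
# differentiation.

test_that("compiled and reference dense forward passes agree", {
  set.seed(2)
  net <- fibertwin:::mlp_init(c(20, 12, 6), c("relu", "sigmoid"), 3)
  x <- matrix(rnorm(40 * 20), 40)
  ref <- fibertwin:::mlp_forward(net, x)
  got <- fibertwin:::fc_predict_core(x, lapply(net$layers, `[[`, "w"),
                                     lapply(net$layers, `[[`, "b"),
                                     c(1L, 2L))
  expect_lt(max(abs(ref - got)), 1e-5)
})

test_that("the reference dense backward pass matches numerical gradients", {
  set.seed(4)
  net <- fibertwin:::mlp_init(c(6, 5, 4), c("relu", "sigmoid"), 7)
  x <- matrix(rnorm(3 * 6), 3)
  y <- matrix(runif(3 * 4), 3)
  fw <- fibertwin:::mlp_forward(net, x, keep = TRUE)
  grads <- fibertwin:::mlp_backward(net, fw$acts, y, "mse")
  loss_at <- function(n2) {
    fibertwin:::mlp_loss(fibertwin:::mlp_forward(n2, x), y, "mse")
  }
  eps <- 1e-6
  for (l in 1:2) {
    for (idx in list(c(1, 1), c(3, 2))) {
      np <- net; np$layers[[l]]$w[idx[1], idx[2]] <-
        np$layers[[l]]$w[idx[1], idx[2]] + eps
      nm <- net; nm$layers[[l]]$w[idx[1], idx[2]] <-
        nm$layers[[l]]$w[idx[1], idx[2]] - eps
      num <- (loss_at(np) - loss_at(nm)) / (2 * eps)
      expect_equal(grads[[l]]$w[idx[1], idx[2]], num, tolerance = 1e-5)
    }
  }
})

test_that("the compiled conv core reproduces the reference U-Net gradients", {
  set.seed(42)
  b <- 3; side <- 16; base <- 2
  x <- matrix(runif(b * side^2), b)
  y <- matrix(runif(b * side^2), b)
  net <- fibertwin:::unet_init(7, base)
  a <- array(x, c(b, side, side, 1))
  cache <- fibertwin:::unet_forward(net, a, keep = TRUE)
  out_r <- matrix(cache$out, b)
  ya <- array(y, c(b, side, side, 1))
  grads_r <- fibertwin:::unet_backward(net, cache, ya)
  loss_r <- mean((cache$out - ya)^2)
  g <- fibertwin:::unet_grad_core(x, y, lapply(net$layers, `[[`, "w"),
                                  lapply(net$layers, `[[`, "b"), base, side)
  expect_lt(max(abs(out_r - g$out)), 1e-5)
  expect_equal(g$loss, loss_r, tolerance = 1e-6)
  for (i in seq_along(net$layers)) {
    gr <- grads_r[[names(net$layers)[i]]]
    rel <- max(abs(gr$w - g$gw[[i]])) / (max(abs(gr$w)) + 1e-12)
    expect_lt(rel, 1e-4)
    relb <- max(abs(gr$b - g$gb[[i]])) / (max(abs(gr$b)) + 1e-12)
    expect_lt(relb, 1e-4)
  }
})
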