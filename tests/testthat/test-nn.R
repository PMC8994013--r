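## The analytic gradients of the hand-written network engine are pinned
## against central finite differences on small graphs.

num_grad <- function(f, v, eps = 1e-6) {
  g <- numeric(length(v))
  for (i in seq_along(v)) {
    vp <- v; vp[i] <- v[i] + eps
    vm <- v; vm[i] <- v[i] - eps
    g[i] <- (f(vp) - f(vm)) / (2 * eps)
  }
  g
}

test_that("convolution gradients match finite differences", {
  set.seed(7)
  x <- array(runif(6 * 8 * 2 * 2), c(6, 8, 2, 2))
  w1 <- array(rnorm(3 * 3 * 2 * 4, sd = 0.3), c(3, 3, 2, 4))
  b1 <- rnorm(4, sd = 0.1)
  w2 <- array(rnorm(4, sd = 0.3), c(1, 1, 4, 1))
  b2 <- rnorm(1, sd = 0.1)
  y <- (array(runif(3 * 4 * 2), c(3, 4, 1, 2)) > 0.5) * 1
  build <- function(xv, w1v, b1v, w2v, b2v, tape = NULL) {
    xn <- echoseg:::new_node(tape, xv)
    ns <- list(x = xn,
               w1 = echoseg:::new_node(tape, w1v),
               b1 = echoseg:::new_node(tape, b1v),
               w2 = echoseg:::new_node(tape, w2v),
               b2 = echoseg:::new_node(tape, b2v))
    h <- echoseg:::op_conv2d(tape, xn, ns$w1, ns$b1, stride = 2L, pad = 1L)
    h <- echoseg:::op_relu(tape, h)
    h <- echoseg:::op_conv2d(tape, h, ns$w2, ns$b2, stride = 1L, pad = 0L)
    p <- echoseg:::op_sigmoid(tape, h)
    ns$loss <- echoseg:::op_bce(tape, p, y)
    ns
  }
  tape <- echoseg:::tape_new()
  ns <- build(x, w1, b1, w2, b2, tape)
  echoseg:::backward(tape, ns$loss)
  f_of <- function(which) function(v) {
    args <- list(x, w1, b1, w2, b2)
    args[[which]] <- if (which == 1L) array(v, dim(x))
      else if (which %in% c(2L, 4L)) array(v, dim(args[[which]])) else v
    do.call(build, args)$loss$val
  }
  expect_equal(as.vector(ns$w1$grad), num_grad(f_of(2L), as.vector(w1)),
               tolerance = 1e-6)
  expect_equal(ns$b1$grad, num_grad(f_of(3L), b1), tolerance = 1e-6)
  expect_equal(as.vector(ns$w2$grad), num_grad(f_of(4L), as.vector(w2)),
               tolerance = 1e-6)
  expect_equal(as.vector(ns$x$grad), num_grad(f_of(1L), as.vector(x)),
               tolerance = 1e-6)
})

test_that("upsampling, concat, broadcast and RoIAlign backpropagate", {
  set.seed(12)
  x <- array(runif(4 * 4 * 2 * 1), c(4, 4, 2, 1))
  r <- array(runif(4 * 4 * 1 * 1), c(4, 4, 1, 1))
  box <- matrix(c(2, 1, 14, 13), 1L)  # image coords, scale 1/4
  y <- (array(runif(3 * 3 * 3), c(3, 3, 3, 1)) > 0.5) * 1
  build <- function(xv, rv, tape = NULL) {
    xn <- echoseg:::new_node(tape, xv)
    rn <- echoseg:::new_node(tape, rv)
    h <- echoseg:::op_concat_c(tape, xn, echoseg:::op_broadcast_n(tape, rn, 1L))
    h <- echoseg:::op_upsample2(tape, h)
    h <- echoseg:::op_crop_hw(tape, h, 7L, 7L)
    cr <- echoseg:::op_roi_align(tape, h, box, 3L, 1 / 2)
    p <- echoseg:::op_sigmoid(tape, cr)
    list(x = xn, r = rn, loss = echoseg:::op_bce(tape, p, y))
  }
  tape <- echoseg:::tape_new()
  ns <- build(x, r, tape)
  echoseg:::backward(tape, ns$loss)
  gx <- num_grad(function(v) build(array(v, dim(x)), r)$loss$val,
                 as.vector(x))
  gr <- num_grad(function(v) build(x, array(v, dim(r)))$loss$val,
                 as.vector(r))
  expect_equal(as.vector(ns$x$grad), gx, tolerance = 1e-6)
  expect_equal(as.vector(ns$r$grad), gr, tolerance = 1e-6)
})

test_that("focal and smooth-L1 loss ops backpropagate", {
  set.seed(20)
  z <- rnorm(30)
  labels <- sample(c(1, 0, NA), 30, replace = TRUE, prob = c(.2, .6, .2))
  tgt <- rnorm(12)
  build <- function(zv, tape = NULL) {
    zn <- echoseg:::new_node(tape, zv)
    p <- echoseg:::op_sigmoid(tape, zn)
    lf <- echoseg:::op_focal(tape, p, labels, focal_params())
    pred <- echoseg:::op_gather(tape, zn, 3:14)
    ls <- echoseg:::op_smooth_l1(tape, pred, tgt, 3)
    list(z = zn, loss = echoseg:::op_weighted_sum(tape, list(lf, ls),
                                                  c(1, 1)))
  }
  tape <- echoseg:::tape_new()
  ns <- build(z, tape)
  echoseg:::backward(tape, ns$loss)
  gz <- num_grad(function(v) build(v)$loss$val, z)
  expect_equal(as.vector(ns$z$grad), gz, tolerance = 1e-6)
})

test_that("focal op agrees with the reference focal_loss forward", {
  set.seed(3)
  p <- runif(100, 0.02, 0.98)
  labels <- sample(c(1, 0, NA), 100, replace = TRUE, prob = c(.1, .8, .1))
  node <- echoseg:::op_focal(NULL, echoseg:::new_node(NULL, p), labels,
                             focal_params())
  expect_equal(node$val, focal_loss(labels, p), tolerance = 1e-12)
})

test_that("RoIAlign reproduces closed-form bilinear interpolation", {
  ## feature map is a linear ramp f(r, c) = 2 r + 3 c (0-based centres),
  ## so bilinear interpolation is exact everywhere in the interior
  H <- 8L; W <- 10L
  f <- outer(0:(H - 1), 0:(W - 1), function(r, c) 2 * r + 3 * c)
  x <- array(f, c(H, W, 1L, 1L))
  box <- matrix(c(2, 1, 8, 7), 1L)  # within the interior, scale 1
  out <- echoseg:::op_roi_align(NULL, echoseg:::new_node(NULL, x), box, 4L, 1)
  bw <- (8 - 2) / 4; bh <- (7 - 1) / 4
  for (i in 1:4) for (j in 1:4) {
    yy <- 1 + (i - 0.5) * bh - 0.5   # continuous 0-based pixel coordinate
    xx <- 2 + (j - 0.5) * bw - 0.5
    expect_equal(out$val[i, j, 1L, 1L], 2 * yy + 3 * xx, tolerance = 1e-12)
  }
  ## constant map -> constant crop; identity crop over the full map
  xc <- array(5, c(4, 4, 2L, 1L))
  cc <- echoseg:::op_roi_align(NULL, echoseg:::new_node(NULL, xc),
                               matrix(c(0, 0, 4, 4), 1L), 4L, 1)
  expect_true(all(cc$val == 5))
  expect_error(echoseg:::op_roi_align(NULL, echoseg:::new_node(NULL, xc),
                                      matrix(c(2, 2, 2, 3), 1L), 4L, 1),
               "degenerate")
})

test_that("SGD leaves parameters unchanged at zero learning rate", {
  p <- list(a = matrix(c(1, 2, 3, 4), 2), b = list(c = rnorm(3)))
  g <- list(a = matrix(1, 2, 2), b = list(c = rep(1, 3)))
  expect_identical(echoseg:::sgd_step(p, g, 0), lapply(p, identity))
  p2 <- echoseg:::sgd_step(p, g, 0.5)
  expect_equal(p2$a, p$a - 0.5)
})
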