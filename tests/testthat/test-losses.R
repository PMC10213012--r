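test_that("ncc handles self, sign flips, scalings and degenerate input", {
  set.seed(1)
  a <- matrix(rnorm(64), 8, 8)
  expect_equal(ncc(a, a), 1, tolerance = 1e-7)
  expect_equal(ncc(a, -a), -1, tolerance = 1e-7)
  a2 <- matrix(c(1, 3, 2, 4), 2, 2)  # [[1,2],[3,4]] in row-major reading
  expect_equal(ncc(a2, 2 * a2), 1, tolerance = 1e-9)
  expect_equal(ncc(matrix(5, 4, 4), a[1:4, 1:4]), 0)   # zero variance -> 0
  expect_error(ncc(a, a[1:4, 1:4]), "shape")
})

test_that("gradient correlation is affine-invariant and component-matched", {
  set.seed(2)
  a <- matrix(rnorm(100), 10, 10)
  b <- matrix(rnorm(100), 10, 10)
  expect_equal(gradient_correlation(a, a), 1, tolerance = 1e-7)
  expect_lt(abs(gradient_correlation(a, 3 * a + 7) - 1), 1e-6)
  expect_lt(abs(gradient_correlation(a, 3 * b + 7) -
                  gradient_correlation(a, b)), 1e-6)
  expect_equal(gradient_correlation(a, -a), -1, tolerance = 1e-7)
  # a horizontal ramp with one perturbed interior pixel, against the
  # brute-force Sobel + NCC oracle
  ramp <- matrix(rep(1:5, each = 5), 5, 5)
  pert <- ramp; pert[3, 3] <- pert[3, 3] + 2
  expect_equal(gradient_correlation(ramp, pert), brute_gc(ramp, pert),
               tolerance = 1e-12)
  # central-difference operator variant stays bounded and exact on self
  expect_equal(gradient_correlation(a, a, operator = "central"), 1,
               tolerance = 1e-7)
})

test_that("gc/ncc match the brute-force implementations on random pairs", {
  set.seed(42)
  for (i in 1:100) {
    a <- matrix(rnorm(256, sd = runif(1, 0.5, 50)), 16, 16)
    b <- matrix(rnorm(256, sd = runif(1, 0.5, 50)), 16, 16)
    expect_lt(abs(ncc(a, b) - brute_ncc(a, b)), 1e-10)
    expect_lt(abs(gradient_correlation(a, b) - brute_gc(a, b)), 1e-10)
    g <- gradient_correlation(a, b)
    expect_true(g >= -1 - 1e-12 && g <= 1 + 1e-12)
  }
})

test_that("adversarial loss matches its closed forms", {
  half <- array(0.5, c(4, 4, 1))
  l <- adversarial_loss(half, half)
  expect_equal(l$discriminator, 2 * log(0.5), tolerance = 1e-12)
  # perfect discriminator approaches the supremum 0
  l2 <- adversarial_loss(array(1, c(4, 4, 1)), array(0, c(4, 4, 1)))
  expect_gt(l2$discriminator, -1e-5)
  # invariance to patch order (mean reduction)
  set.seed(3)
  r <- array(runif(16, 0.1, 0.9), c(4, 4, 1))
  f <- array(runif(16, 0.1, 0.9), c(4, 4, 1))
  perm <- sample(16)
  l3 <- adversarial_loss(r, f)
  l4 <- adversarial_loss(array(r[perm], c(4, 4, 1)),
                         array(f[perm], c(4, 4, 1)))
  expect_equal(l3$discriminator, l4$discriminator)
  expect_equal(l3$generator, l4$generator)
})

test_that("cycle loss is a symmetric mean absolute error", {
  set.seed(4)
  x <- array(rnorm(64), c(8, 8, 1))
  y <- array(rnorm(192), c(8, 8, 3))
  expect_equal(cycle_loss(x, x, y, y), 0)
  expect_equal(cycle_loss(x, x + 2, y, y), 2)
  perm <- c(3, 1, 2)
  expect_equal(cycle_loss(x, x + 1, y, y + 0.5),
               cycle_loss(x, x + 1, y[, , perm], y[, , perm] + 0.5))
  expect_error(cycle_loss(x, array(0, c(4, 4, 1)), y, y), "shape")
})

test_that("reconstruction GC loss has the stated zeros, offsets and negation", {
  set.seed(5)
  x <- matrix(rnorm(64), 8, 8)
  y <- array(rnorm(192), c(8, 8, 3))
  sy <- apply(y, c(1, 2), sum)
  # channels that sum to x exactly, and a perfect reverse mapping
  ch <- array(0, c(8, 8, 3))
  ch[, , 1] <- x / 2; ch[, , 2] <- x / 4; ch[, , 3] <- x / 4
  expect_lt(reconstruction_gc_loss(x, ch, y, sy), 1e-6)
  # constant offset in the channel-sum leaves the x-direction term at zero
  ch_off <- ch; ch_off[, , 1] <- ch_off[, , 1] + 11
  expect_lt(reconstruction_gc_loss(x, ch_off, y, sy), 1e-6)
  # negated reconstruction: GC = -1 on the x side, perfect y side -> 1
  expect_equal(reconstruction_gc_loss(x, -ch, y, sy), 1, tolerance = 1e-6)
  # bounds
  r <- reconstruction_gc_loss(x, array(rnorm(192), c(8, 8, 3)), y,
                              matrix(rnorm(64), 8, 8))
  expect_true(r >= 0 && r <= 2)
})

test_that("reconstruction l2 loss depends on the channels only through their sum", {
  set.seed(6)
  x <- matrix(rnorm(64), 8, 8)
  ch <- array(rnorm(192), c(8, 8, 3))
  expect_equal(reconstruction_l2_loss(apply(ch, c(1, 2), sum), ch), 0,
               tolerance = 1e-12)
  ch3 <- array(0, c(8, 8, 3)); ch3[, , 2] <- x + 3
  ch3[, , 1] <- 5; ch3[, , 3] <- -5
  expect_equal(reconstruction_l2_loss(x, ch3), 9, tolerance = 1e-12)
  expect_equal(reconstruction_l2_loss(x, ch),
               reconstruction_l2_loss(x, ch[, , c(2, 3, 1)]))
})

test_that("total loss applies weights and the ablation term matrix", {
  terms <- list(gan = -1.2, cyc = 0.4, recon_gc = 0.3, recon_l2 = 0.09)
  w <- loss_weights()       # 10 / 1.0 / 0.5
  expect_equal(w$lambda_cyc, 10)
  expect_equal(w$lambda_gc, 1.0)
  expect_equal(w$lambda_recon_l2, 0.5)

  t1 <- total_loss(terms, w, "conventional1")
  expect_equal(t1$total, -1.2 + 10 * 0.4)
  expect_equal(t1$breakdown$recon_gc_weighted, 0)
  expect_equal(t1$breakdown$recon_l2_weighted, 0)

  t2 <- total_loss(terms, w, "conventional2")
  expect_equal(t2$total, -1.2 + 10 * 0.4 + 0.5 * 0.09)

  t4 <- total_loss(terms, w, "proposed2")
  expect_equal(t4$total, -1.2 + 10 * 0.4 + 1.0 * 0.3)
  t4b <- total_loss(terms, loss_weights(lambda_gc = 2), "proposed2")
  expect_equal(t4b$breakdown$recon_gc_weighted,
               2 * t4$breakdown$recon_gc_weighted)

  t0 <- total_loss(terms, loss_weights(0, 0, 0), "proposed2")
  expect_equal(t0$total, terms$gan)

  expect_error(total_loss(terms, w, "nope"), "unknown variant")
  m <- variant_terms()
  expect_equal(m$local_enhancer, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(m$recon_l2, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(m$recon_gc, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("loss gradients agree with finite differences", {
  set.seed(7)
  a <- matrix(rnorm(36), 6, 6)
  b <- matrix(rnorm(36), 6, 6)
  eps <- 1e-6

  nb <- xraydecomp:::ncc_with_grad(a, b)
  gc <- xraydecomp:::gc_with_grad_b(a, b)
  for (i in c(1, 14, 36)) {
    bp <- b; bp[i] <- bp[i] + eps
    bm <- b; bm[i] <- bm[i] - eps
    fd_ncc <- (ncc(a, bp) - ncc(a, bm)) / (2 * eps)
    expect_lt(abs(fd_ncc - nb$gb[i]) / max(abs(fd_ncc), 1e-8), 1e-4)
    fd_gc <- (gradient_correlation(a, bp) - gradient_correlation(a, bm)) /
      (2 * eps)
    expect_lt(abs(fd_gc - gc$gb[i]) / max(abs(fd_gc), 1e-8), 1e-4)
  }
})
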