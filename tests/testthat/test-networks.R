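test_that("receptive-field recurrence reproduces the patch sizes", {
  expect_equal(receptive_field(4, 1, 0), 4)
  expect_equal(receptive_field(4, 4, 2), 142)
  expect_equal(receptive_field(4, 3, 2), 70)
  # one stride-2 then two stride-1 layers: 1 -> 4 -> 10 -> 16
  expect_equal(receptive_field(4, 1, 2), 16)
})

test_that("gradient-support measurement agrees with the recurrence", {
  set.seed(1)
  d4 <- build_discriminator(discriminator_spec(1, stride2_layers = 4,
                                               base_width = 4))
  expect_equal(measure_receptive_field(d4, 192), 142)
  d3 <- build_discriminator(discriminator_spec(1, stride2_layers = 3,
                                               base_width = 4))
  expect_equal(measure_receptive_field(d3, 96), 70)
  d2 <- build_discriminator(discriminator_spec(1, stride2_layers = 2,
                                               base_width = 4, norm = "none"))
  expect_equal(measure_receptive_field(d2, 64), receptive_field(4, 2, 2))
})

test_that("discriminator score maps are sigmoid-bounded and local", {
  set.seed(2)
  d <- build_discriminator(discriminator_spec(1, stride2_layers = 2,
                                              base_width = 4, norm = "none"))
  x <- array(rnorm(64 * 64), c(64, 64, 1))
  s <- discriminator_forward(d, x)$scores
  expect_true(all(s > 0 & s < 1))
  # constant input -> constant score map for units whose receptive field
  # avoids the zero-padded borders (translation equivariance)
  sc <- discriminator_forward(d, array(1, c(128, 128, 1)))$scores
  margin <- ceiling(d$spec$receptive_field / 4) + 1   # stride 4 at the map
  inner <- sc[margin:(dim(sc)[1] - margin), margin:(dim(sc)[2] - margin), 1]
  expect_lt(diff(range(inner)), 1e-10)
  # perturbing one pixel only changes score units whose receptive field
  # covers it
  rf <- d$spec$receptive_field
  x2 <- x
  x2[32, 32, 1] <- x2[32, 32, 1] + 10
  s2 <- discriminator_forward(d, x2)$scores
  changed <- which(abs(s2 - s) > 1e-12, arr.ind = TRUE)
  # map output units to input-pixel centers: stride 4 after two s2 layers,
  # plus the stride-1 stages' offset; every changed unit must be within
  # rf/2 of the perturbed pixel along both axes
  stride <- 4
  centers_v <- (changed[, 1] - 1) * stride + rf / 2
  centers_u <- (changed[, 2] - 1) * stride + rf / 2
  expect_true(all(abs(centers_v - 32) <= rf / 2 + 2 * stride))
  expect_true(all(abs(centers_u - 32) <= rf / 2 + 2 * stride))
  expect_gt(nrow(changed), 0)
})

test_that("generator shape contracts hold across the architecture matrix", {
  set.seed(3)
  for (down in c(2, 3)) {
    g <- build_generator(generator_spec(1, 23, residual_blocks = 2,
                                        downsample_layers = down,
                                        base_width = 4))
    out <- generator_forward(g, array(rnorm(64 * 64), c(64, 64, 1)))
    expect_equal(dim(out$y), c(64, 64, 23))
    expect_true(all(out$y >= -1 & out$y <= 1))
    g2 <- build_generator(generator_spec(23, 1, residual_blocks = 2,
                                         downsample_layers = down,
                                         base_width = 4))
    out2 <- generator_forward(g2, array(rnorm(64 * 64 * 23), c(64, 64, 23)))
    expect_equal(dim(out2$y), c(64, 64, 1))
  }
})

test_that("parameter counts are pure functions of the spec and grow with depth", {
  set.seed(4)
  s3 <- generator_spec(1, 4, residual_blocks = 2, downsample_layers = 3,
                       base_width = 4)
  expect_equal(parameter_count(build_generator(s3)),
               parameter_count(build_generator(s3)))
  s4 <- generator_spec(1, 4, residual_blocks = 2, downsample_layers = 4,
                       base_width = 4)
  expect_gt(parameter_count(build_generator(s4)),
            parameter_count(build_generator(s3)))
})

test_that("hierarchical generator composes and reduces to g1 at init", {
  set.seed(5)
  spec <- generator_spec(1, 3, residual_blocks = 2, downsample_layers = 2,
                         base_width = 4, hierarchical = TRUE,
                         scales = c(32, 64))
  hg <- build_hierarchical_generator(spec)
  x <- array(rnorm(64 * 64), c(64, 64, 1))
  fw <- hier_forward(hg, x)
  expect_equal(dim(fw$y), c(64, 64, 3))
  # zero-initialized local branch: composed output == upsampled g1 output
  up <- xraydecomp:::upsample2_nearest(fw$y_low)
  expect_lt(max(abs(fw$y - up)), 1e-6)
  # g1 remains usable standalone at the low scale
  g1out <- generator_forward(hg$g1, array(rnorm(32 * 32), c(32, 32, 1)))
  expect_equal(dim(g1out$y), c(32, 32, 3))
  expect_error(generator_spec(1, 3, hierarchical = TRUE, scales = c(32, 96)),
               "high = 2")
})

test_that("inference is deterministic for fixed weights", {
  set.seed(6)
  g <- build_generator(generator_spec(1, 2, residual_blocks = 1,
                                      downsample_layers = 2, base_width = 4))
  x <- array(rnorm(32 * 32), c(32, 32, 1))
  expect_identical(generator_forward(g, x)$y, generator_forward(g, x)$y)
})

test_that("network gradients agree with finite differences", {
  set.seed(7)
  g <- build_generator(generator_spec(1, 2, residual_blocks = 1,
                                      downsample_layers = 2, base_width = 3))
  x <- array(rnorm(16 * 16), c(16, 16, 1))
  fw <- generator_forward(g, x, want_cache = TRUE)
  bk <- xraydecomp:::generator_backward(g, fw, 2 * fw$y)
  loss <- function(gg, xx) sum(generator_forward(gg, xx)$y^2)
  eps <- 1e-6
  for (i in c(5, 100)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    fd <- (loss(g, xp) - loss(g, xm)) / (2 * eps)
    expect_lt(abs(fd - bk$gx[i]) / max(abs(fd), 1e-6), 1e-4)
  }
  gp <- g; gp$backbone[[1]]$params$w[7] <- gp$backbone[[1]]$params$w[7] + eps
  gm <- g; gm$backbone[[1]]$params$w[7] <- gm$backbone[[1]]$params$w[7] - eps
  fd <- (loss(gp, x) - loss(gm, x)) / (2 * eps)
  expect_lt(abs(fd - bk$grads$backbone[[1]]$w[7]) / max(abs(fd), 1e-6), 1e-4)
})
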