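test_that("learning-rate schedule is constant then linearly decaying", {
  cfg <- training_config("conventional1", epochs = 200)
  expect_equal(lr_at_epoch(1, cfg), 2e-4)
  expect_equal(lr_at_epoch(50, cfg), 2e-4)
  expect_equal(lr_at_epoch(100, cfg), 2e-4)
  expect_equal(lr_at_epoch(150, cfg), 1e-4)
  expect_equal(lr_at_epoch(200, cfg), 0)
  expect_error(lr_at_epoch(0, cfg), "range")
  expect_error(lr_at_epoch(201, cfg), "range")
})

test_that("training config validates variants and schedule shape", {
  expect_error(training_config("nope"), "unknown variant")
  expect_error(training_config("proposed1", epochs = 3), "epochs")
})

trained_tiny <- function(variant, epochs = 2, seed = 5) {
  fixture(paste0("train_", variant, "_", epochs, "_", seed), function() {
    train(tiny_manifest(),
          training_config(variant, epochs = epochs, image_size = 64,
                          base_width = 6, residual_blocks = 1, seed = seed))
  })
}

test_that("loss breakdown contains exactly the variant's terms", {
  h1 <- loss_history(trained_tiny("conventional1"))
  # total excludes both reconstruction penalties
  expect_equal(h1$total, h1$gan + 10 * h1$cyc, tolerance = 1e-12)
  expect_equal(unique(h1$stage), "single")

  h4 <- loss_history(trained_tiny("proposed2"))
  expect_equal(h4$total, h4$gan + 10 * h4$cyc + 1.0 * h4$recon_gc,
               tolerance = 1e-12)
  expect_setequal(unique(h4$stage), c("global", "local"))

  h2 <- loss_history(trained_tiny("conventional2"))
  expect_equal(h2$total, h2$gan + 10 * h2$cyc + 0.5 * h2$recon_l2,
               tolerance = 1e-12)

  # all losses stay finite throughout
  for (h in list(h1, h2, h4)) {
    expect_true(all(is.finite(as.matrix(h[, c("gan", "d_drr", "d_xp", "cyc",
                                              "recon_gc", "recon_l2",
                                              "total")]))))
  }
})

test_that("training is deterministic for a fixed seed", {
  man <- tiny_manifest()
  cfg <- training_config("conventional1", epochs = 2, image_size = 64,
                         base_width = 6, residual_blocks = 1, seed = 5)
  st1 <- trained_tiny("conventional1")
  st2 <- train(man, cfg)
  expect_identical(loss_history(st1)$total, loss_history(st2)$total)
})

test_that("checkpoint/resume reproduces an uninterrupted run", {
  man <- tiny_manifest()
  cfg <- training_config("proposed2", epochs = 2, image_size = 64,
                         base_width = 6, residual_blocks = 1, seed = 5)
  full <- trained_tiny("proposed2")
  half <- train(man, cfg, stop_after_epoch = 2)
  ck <- tempfile(fileext = ".rds")
  saveRDS(half, ck)                      # serialize/deserialize round-trip
  resumed <- train(man, cfg, state = readRDS(ck))
  expect_equal(loss_history(resumed)$total, loss_history(full)$total,
               tolerance = 1e-10)
  # parameters agree too
  expect_equal(resumed$models$gd$g2_head$params$w,
               full$models$gd$g2_head$params$w, tolerance = 1e-5)
})

test_that("decompose honors the contracts", {
  man <- tiny_manifest()
  st <- trained_tiny("proposed2")
  test_id <- which(man$cases$split == "test")[1]
  dec <- decompose(man$data[[test_id]]$radiograph, st)
  expect_s3_class(dec, "xdecomp_decomposed")
  expect_equal(dim(dec$channels), c(64, 64, 4))     # K+1 channels
  expect_false(dec$raw)
  expect_true(all(dec$channels >= 0 & dec$channels <= 255))
  # denormalizable via the shared normalization
  raw <- denormalize_image(dec)
  expect_true(raw$raw)
  # bit-identical on repeated calls
  dec2 <- decompose(man$data[[test_id]]$radiograph, st)
  expect_identical(dec$channels, dec2$channels)
  # wrong input scale is refused
  expect_error(decompose(matrix(0, 32, 32), st), "size")
})

test_that("training requires a train split", {
  man <- tiny_manifest()
  man$cases$split[] <- "test"
  expect_error(train(man, training_config("conventional1", epochs = 2,
                                          image_size = 64, base_width = 6,
                                          residual_blocks = 1)),
               "empty train split")
})
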