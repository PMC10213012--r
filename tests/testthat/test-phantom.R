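test_that("phantom spec validates its invariants", {
  expect_error(phantom_spec(asymmetry_factor = 0), "asymmetry_factor")
  expect_error(phantom_spec(asymmetry_factor = 1.2), "asymmetry_factor")
  expect_error(phantom_spec(bone_hu_range = c(10, 20)), "bone_hu_range")
  expect_error(phantom_spec(grid_shape = c(63, 64, 64)), "grid_shape")
  expect_error(phantom_spec(n_muscles = 0), "n_muscles")
})

test_that("phantom generation is deterministic and exactly mirror-symmetric", {
  spec <- phantom_spec(grid_shape = c(48, 48, 48), n_bones = 3,
                       n_muscles = 4, asymmetry_factor = 1, seed = 7)
  ph1 <- generate_phantom(spec)
  ph2 <- generate_phantom(spec)
  expect_identical(ph1$hu, ph2$hu)
  expect_identical(ph1$label, ph2$label)

  # factor 1: every muscle's two sides have identical voxel counts
  m <- ph1$side_volumes[grepl("muscle", ph1$side_volumes$name), ]
  wide <- tidyr::pivot_wider(m[, c("name", "side", "voxels")],
                             names_from = "side", values_from = "voxels")
  expect_equal(wide$left, wide$right)
})

test_that("default structure count matches the emulated cohort layout", {
  # 3 bones + 19 muscles + background = 23 labels
  ph <- generate_phantom(phantom_spec(seed = 3))
  expect_equal(ph$n_channels, 23L)
  expect_equal(nrow(ph$labels), 23L)
  expect_setequal(unique(ph$labels$group),
                  c("bone", "hip muscle", "thigh muscle", "background"))
})

test_that("masks partition the body support and volumes are bookkept exactly", {
  ph <- tiny_phantom()
  # union of all masks == body support (HU above the air threshold)
  expect_identical(ph$label > 0, ph$hu > -200)
  # per-structure voxel counts equal the recorded side volumes
  for (lid in ph$labels$label_id) {
    sv <- ph$side_volumes[ph$side_volumes$label_id == lid, ]
    expect_equal(sum(sv$voxels), sum(ph$label == lid))
    expect_equal(sv$volume_mm3, sv$voxels * prod(ph$spacing))
  }
})

test_that("asymmetry factor is recovered by voxel counting", {
  spec <- phantom_spec(grid_shape = c(64, 64, 64), n_bones = 1,
                       n_muscles = 3, asymmetry_factor = 0.8, seed = 5,
                       muscle_size_frac = c(0.30, 0.42))
  ph <- generate_phantom(spec)
  m <- ph$side_volumes[grepl("muscle", ph$side_volumes$name), ]
  wide <- tidyr::pivot_wider(m[, c("name", "side", "voxels")],
                             names_from = "side", values_from = "voxels")
  ratio <- wide$left / wide$right  # affected side is left by default
  expect_true(all(abs(ratio - 0.8) < 0.02))
  expect_true(all(ratio <= 1))
})

test_that("pose perturbation is bounded, seeded and uniform", {
  ph <- tiny_phantom()
  expect_true(xraydecomp:::is_identity_transform(
    perturb_pose(ph, c(0, 0, 0), c(0, 0, 0), seed = 4)))
  t1 <- perturb_pose(ph, c(5, 5, 5), c(10, 10, 10), seed = 9)
  t2 <- perturb_pose(ph, c(5, 5, 5), c(10, 10, 10), seed = 9)
  expect_identical(t1$rotation, t2$rotation)
  expect_identical(t1$translation, t2$translation)

  # uniform draws on [-5, 5]: mean within 3 standard errors of 0
  n <- 1e4
  draws <- vapply(seq_len(n), function(s)
    perturb_pose(ph, c(5, 5, 5), c(10, 10, 10), seed = s)$angles_deg[1],
    numeric(1))
  se <- 5 / sqrt(3) / sqrt(n)
  expect_lt(abs(mean(draws)), 3 * se)
  expect_true(all(abs(draws) <= 5))
})

test_that("dataset splits are case-wise disjoint and normalization is shared", {
  man <- tiny_manifest()
  tab <- table(man$cases$split)
  expect_setequal(names(tab), c("train", "val", "test"))
  expect_equal(sum(tab), 6)
  expect_true(all(tab >= 1))
  expect_equal(length(unique(man$cases$case_id)), 6)

  # 4 cases at 50/25/25 split into exactly 2/1/1
  specs4 <- lapply(1:4, function(s)
    phantom_spec(grid_shape = c(32, 32, 32), n_bones = 1, n_muscles = 1,
                 seed = s))
  man4 <- build_dataset(specs4, seed = 2)
  expect_equal(as.integer(table(man4$cases$split)[c("train", "val", "test")]),
               c(2L, 1L, 1L))

  # one normalization object, max taken from the training split only
  train_ids <- which(man$cases$split == "train")
  train_max <- max(vapply(train_ids,
                          function(i) max(man$data[[i]]$composite$pixels),
                          numeric(1)))
  expect_equal(man$normalization$raw_max, train_max)
  expect_equal(man$normalization$raw_min, 0)
})

test_that("with zero perturbation and no noise the radiograph equals the DRR channel-sum", {
  specs <- lapply(1:2, function(s)
    phantom_spec(grid_shape = c(32, 32, 32), spacing = c(4, 4, 4),
                 n_bones = 1, n_muscles = 2, seed = s))
  man <- build_dataset(specs, noise = NULL,
                       pose_bounds = list(rotation = c(0, 0, 0),
                                          translation = c(0, 0, 0)),
                       splits = c(train = 0.5, test = 0.5), seed = 1)
  for (i in 1:2) {
    cs <- apply(man$data[[i]]$drr$channels, c(1, 2), sum)
    expect_equal(man$data[[i]]$radiograph$pixels, cs, tolerance = 1e-12)
  }
})

test_that("degenerate dataset requests fail loudly", {
  specs <- lapply(1:2, function(s)
    phantom_spec(grid_shape = c(32, 32, 32), n_bones = 1, n_muscles = 1,
                 seed = s))
  expect_error(build_dataset(specs[1]), "length")
  expect_error(build_dataset(specs, splits = c(train = 0.6, test = 0.3)),
               "sum to 1")
})
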