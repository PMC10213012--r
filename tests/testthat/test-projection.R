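test_that("HU to attenuation follows the monoenergetic linear relation", {
  expect_equal(hu_to_attenuation(0, mu_water = 0.02), 0.02)
  expect_equal(hu_to_attenuation(-1000, mu_water = 0.02), 0)
  expect_equal(hu_to_attenuation(-2000, mu_water = 0.02), 0) # clamped
  # a 10 HU drop at muscle-range HU lowers the AC by about 1%
  drop <- 1 - hu_to_attenuation(40) / hu_to_attenuation(50)
  expect_equal(drop, 10 / 1050)
  expect_lt(abs(drop * 100 - 1), 0.1)
  expect_error(hu_to_attenuation(NA_real_), "non-finite")
})

test_that("parallel projection of a homogeneous cube gives mu times path length", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(32, 32, 32),
                                      spacing = c(1, 1, 1), n_bones = 1,
                                      n_muscles = 1, seed = 1))
  ph$hu[] <- -1000; ph$label[] <- 0L
  ph$hu[12:21, 12:21, 12:21] <- 0      # water: mu = mu_water
  ph$label[12:21, 12:21, 12:21] <- 1L
  geo <- geometry_for_phantom(ph)
  r <- render(ph, geo, mu_water = 0.02, integrator = "exact")
  # 10 mm of water at 0.02/mm -> 0.2 for every interior pixel
  expect_equal(r$radiograph$pixels[16, 16], 0.2, tolerance = 1e-12)
  expect_equal(max(r$radiograph$pixels), 0.2, tolerance = 1e-12)
  expect_equal(r$radiograph$pixels[1, 1], 0)
})

test_that("channel-sum equals the composite under the exact integrator", {
  for (s in 1:3) {
    ph <- generate_phantom(phantom_spec(grid_shape = c(32, 32, 32),
                                        spacing = c(4, 4, 4), n_bones = 2,
                                        n_muscles = 3, seed = s))
    pose <- perturb_pose(ph, c(10, 10, 10), c(8, 8, 8), seed = s)
    geo <- projection_geometry("pinhole", sdd = 1000,
                               detector_shape = c(48, 48), pixel_pitch = 4,
                               pose = compose_transform(
                                 rigid_transform(translation = c(0, 0, 500)),
                                 pose))
    r <- render(ph, geo, integrator = "exact")
    cs <- apply(r$drr$channels, c(1, 2), sum)
    expect_lt(max(abs(cs - r$radiograph$pixels)) / max(r$radiograph$pixels),
              1e-6)
  }
})

test_that("sampled integrator converges to the exact-intersection oracle", {
  ph <- two_box_phantom()
  pose <- rigid_transform(euler_xyz_matrix(c(8, -12, 5)), c(0, 0, 500),
                          c(8, -12, 5))
  geo <- projection_geometry("pinhole", sdd = 1000,
                             detector_shape = c(48, 48), pixel_pitch = 3,
                             pose = pose)
  re <- render(ph, geo, integrator = "exact")
  err_at <- function(step) {
    rs <- render(ph, geo, integrator = "sampled", step = step)
    max(abs(rs$radiograph$pixels - re$radiograph$pixels)) /
      max(re$radiograph$pixels)
  }
  e_fine <- err_at(0.2)   # 0.1 voxel
  e_default <- err_at(1)  # 0.5 voxel (default)
  expect_lt(e_fine, 1e-2)
  expect_lt(e_fine, e_default)

  # channel-sum conservation holds for the sampled integrator by construction
  rs <- render(ph, geo, integrator = "sampled")
  cs <- apply(rs$drr$channels, c(1, 2), sum)
  expect_lt(max(abs(cs - rs$radiograph$pixels)), 1e-12)
})

test_that("pixel sums of uniform structures recover attenuation-weighted volumes", {
  ph <- tiny_phantom()
  geo <- geometry_for_phantom(ph)
  r <- render(ph, geo, integrator = "exact")
  area <- geo$pixel_pitch^2
  fg <- ph$labels[ph$labels$group != "background", ]
  for (i in seq_len(nrow(fg))) {
    lid <- fg$label_id[i]
    alpha <- hu_to_attenuation(fg$hu[i])
    v <- sum(ph$side_volumes$volume_mm3[ph$side_volumes$label_id == lid])
    expect_equal(sum(r$drr$channels[, , lid]) * area, alpha * v,
                 tolerance = 1e-10)
  }
})

test_that("raising a voxel's HU never decreases the composite", {
  ph <- two_box_phantom()
  geo <- projection_geometry("parallel", sdd = 200,
                             detector_shape = c(32, 32), pixel_pitch = 2,
                             pose = rigid_transform(translation = c(0, 0, 100)))
  base <- render(ph, geo, integrator = "exact")$radiograph$pixels
  ph2 <- ph
  ph2$hu[10, 10, 10] <- ph2$hu[10, 10, 10] + 500
  bumped <- render(ph2, geo, integrator = "exact")$radiograph$pixels
  expect_true(all(bumped - base >= -1e-12))
  expect_gt(sum(bumped - base), 0)
})

test_that("quantum noise has the right limit, mean and determinism", {
  p <- matrix(seq(0, 5, length.out = 64), 8, 8)
  img <- radiograph(p, raw = TRUE)
  # vanishing-noise limit
  hi <- add_poisson_noise(img, i0 = 1e9, seed = 1)
  expect_lt(max(abs(hi$pixels - p)), 1e-2)
  # delta-method mean at p = 1, i0 = 1e4 over 1e4 pixel draws
  p1 <- matrix(1, 100, 100)
  noisy <- add_poisson_noise(radiograph(p1, raw = TRUE), i0 = 1e4, seed = 2)
  se <- sqrt(exp(1) / 1e4) / sqrt(length(p1))
  expect_lt(abs(mean(noisy$pixels) - 1), 3 * se)
  # empirical variance matches exp(p)/i0 within 20%
  expect_lt(abs(var(as.numeric(noisy$pixels)) / (exp(1) / 1e4) - 1), 0.2)
  # determinism
  n1 <- add_poisson_noise(img, i0 = 1e4, seed = 7)
  n2 <- add_poisson_noise(img, i0 = 1e4, seed = 7)
  expect_identical(n1$pixels, n2$pixels)
})

test_that("fixed-range normalization maps endpoints and inverts exactly", {
  nm <- normalization(raw_min = 0, raw_max = 4)
  expect_equal(normalize_image(0, nm), 0)
  expect_equal(normalize_image(4, nm), 255)
  expect_equal(normalize_image(2, nm), 127.5)
  x <- matrix(runif(64, 0, 4), 8, 8)
  expect_lt(max(abs(denormalize_image(normalize_image(x, nm), nm) - x)),
            1e-12)
  # clipping outside the range
  expect_equal(normalize_image(9, nm), 255)
  expect_error(normalization(2, 2), "exceed")
})

test_that("bi-cubic resize reproduces trivial and polynomial cases", {
  x <- matrix(rnorm(256), 16, 16)
  expect_equal(resize_image(x, 16), x)
  expect_equal(resize_image(matrix(3, 16, 16), 8), matrix(3, 8, 8),
               tolerance = 1e-12)
  # downsampling a linear ramp by 2 keeps it a linear ramp
  ramp <- matrix(rep(seq_len(32), each = 32), 32, 32)
  small <- resize_image(ramp, 16)
  expect_lt(max(abs(small - matrix(rep(seq(1.5, 31.5, 2), each = 16),
                                   16, 16))), 1e-6)
  expect_error(resize_image(x, 4), "target")
})
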