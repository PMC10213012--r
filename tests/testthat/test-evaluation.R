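test_that("psnr matches its closed forms and logarithm identities", {
  truth <- matrix(runif(64, 0, 255), 8, 8)
  p <- psnr(truth, truth)
  expect_equal(as.numeric(p), 99)
  expect_true(attr(p, "capped"))
  expect_equal(psnr(truth + 1, truth), 20 * log10(255), tolerance = 1e-12)
  # halving the MSE raises PSNR by 10*log10(2)
  e <- matrix(rnorm(64), 8, 8)
  gain <- psnr(truth + e / sqrt(2), truth) - psnr(truth + e, truth)
  expect_equal(gain, 10 * log10(2), tolerance = 1e-9)
  expect_error(psnr(truth, truth[1:4, 1:4]), "shape")
})

test_that("dice matches its definition including conventions", {
  a <- matrix(FALSE, 4, 4); b <- a
  d0 <- dice(a, b)
  expect_equal(as.numeric(d0), 1)          # both empty
  expect_true(attr(d0, "both_empty"))
  a[1:2, 1] <- TRUE
  expect_equal(dice(a, a), 1)
  b[3:4, 4] <- TRUE
  expect_equal(dice(a, b), 0)              # disjoint
  b2 <- matrix(FALSE, 4, 4); b2[2:3, 1] <- TRUE
  expect_equal(dice(a, b2), 0.5)           # |a|=|b|=2, overlap 1
})

test_that("psnr and dice agree with loop-based reimplementations", {
  set.seed(8)
  for (i in 1:20) {
    pred <- matrix(runif(256, 0, 255), 16, 16)
    truth <- matrix(runif(256, 0, 255), 16, 16)
    expect_lt(abs(psnr(pred, truth) - brute_psnr(pred, truth, 255)), 1e-10)
    ma <- matrix(runif(256) > 0.5, 16, 16)
    mb <- matrix(runif(256) > 0.5, 16, 16)
    expect_lt(abs(dice(ma, mb) - brute_dice(ma, mb)), 1e-10)
  }
})

test_that("threshold selection maximizes mean Dice with smallest-tie rule", {
  truth <- matrix(0, 8, 8); truth[3:6, 3:6] <- 1
  # float {0, 255} prediction: every threshold in (0, 255) attains Dice 1
  pred <- truth * 255
  sel <- select_threshold(list(pred), list(truth), sweep = c(50, 100, 200))
  expect_equal(sel$threshold, 50)          # smallest tie wins
  expect_equal(sel$mean_dice, 1)

  # two-level prediction: structure 100, background 10
  pred2 <- matrix(10, 8, 8); pred2[3:6, 3:6] <- 100
  sweep <- c(5, 11, 50, 99)
  sel2 <- select_threshold(list(pred2), list(truth), sweep)
  expect_equal(sel2$threshold, 11)
  expect_equal(sel2$mean_dice, 1)
  # below the background level everything is foreground -> Dice < 1
  expect_lt(sel2$sweep$mean_dice[sel2$sweep$threshold == 5], 1)
  # returned mean equals the max of the recomputed sweep
  expect_equal(sel2$mean_dice, max(sel2$sweep$mean_dice))
  expect_error(select_threshold(list(), list(), 1), "length")
})

test_that("volume ratio is exact for symmetric and scaled structures", {
  # symmetric phantom: ratio 1 within numerical noise
  ph <- generate_phantom(phantom_spec(grid_shape = c(64, 64, 64),
                                      n_bones = 1, n_muscles = 2,
                                      asymmetry_factor = 1, seed = 3,
                                      muscle_size_frac = c(0.28, 0.38)))
  geo <- geometry_for_phantom(ph)
  r <- render(ph, geo, integrator = "exact")
  lid <- ph$labels$label_id[ph$labels$name == "muscle_01"]
  supp <- project_side_supports(ph, geo, lid)
  vr <- volume_ratio(r$drr$channels[, , lid], supp$left, supp$right,
                     ground_truth_ratio = 1, label = "muscle_01")
  expect_equal(vr$r, 1, tolerance = 1e-6)

  # scaled phantom: ratio equals the asymmetry factor up to voxelization
  ph8 <- generate_phantom(phantom_spec(grid_shape = c(64, 64, 64),
                                       n_bones = 1, n_muscles = 2,
                                       asymmetry_factor = 0.8, seed = 4,
                                       muscle_size_frac = c(0.28, 0.38)))
  r8 <- render(ph8, geo, integrator = "exact")
  for (nm in c("muscle_01", "muscle_02")) {
    lid <- ph8$labels$label_id[ph8$labels$name == nm]
    supp <- project_side_supports(ph8, geo, lid)
    vr8 <- volume_ratio(r8$drr$channels[, , lid], supp$left, supp$right)
    expect_lt(abs(vr8$r - 0.8), 0.01)
  }

  expect_error(volume_ratio(matrix(1, 4, 4), matrix(TRUE, 4, 4),
                            matrix(TRUE, 4, 4)), "disjoint")
  expect_error(volume_ratio(matrix(0, 4, 4),
                            matrix(c(TRUE, rep(FALSE, 15)), 4, 4),
                            matrix(c(FALSE, TRUE, rep(FALSE, 14)), 4, 4)),
               "zero")
})

test_that("icc matches ANOVA mean squares and behaves under noise", {
  # perfect agreement
  x <- c(0.7, 0.8, 0.9, 1.0, 0.75)
  expect_equal(icc(x, x), 1, tolerance = 1e-12)

  # 4-pair hand table cross-checked against aov()-derived mean squares
  est <- c(9, 6, 8, 7)
  ref <- c(9.5, 6.5, 9, 7)
  d <- data.frame(y = c(est, ref),
                  case = factor(rep(1:4, 2)),
                  rater = factor(rep(1:2, each = 4)))
  ms <- summary(stats::aov(y ~ case + rater, data = d))[[1]]$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  expected <- (msr - mse) / (msr + mse + 2 * (msc - mse) / 4)
  expect_equal(icc(est, ref), expected, tolerance = 1e-12)

  # estimates dominated by independent noise give low agreement
  set.seed(9)
  truth <- runif(200, 0.7, 1.0)
  noisy <- truth + rnorm(200, sd = 1.5)
  expect_lt(icc(noisy, truth), 0.3)

  expect_error(icc(1:2, 1:2), "at least 3")
  expect_error(icc(rep(1, 5), rep(1, 5)), "variance")
})

test_that("evaluate_decomposition scores perfect decompositions perfectly", {
  man <- tiny_manifest()
  test_ids <- which(man$cases$split == "test")
  # feed the normalized ground truth back as the "prediction"
  decs <- lapply(test_ids, function(ci)
    normalize_image(man$data[[ci]]$drr, man$normalization))
  rep <- evaluate_decomposition(man, decs, cases = test_ids)
  expect_true(all(rep$structures$dice == 1))
  expect_true(all(rep$structures$psnr_normalized == 99))
  expect_equal(rep$ratios$r, rep$ratios$ground_truth_ratio, tolerance = 1e-9)

  # group means are recomputable from per-structure records
  g <- rep$structures |>
    dplyr::group_by(case_id, group) |>
    dplyr::summarise(dice = mean(dice), .groups = "drop")
  expect_equal(dplyr::arrange(g, case_id, group)$dice,
               dplyr::arrange(rep$groups, case_id, group)$dice)

  # tidy/glance interface
  expect_s3_class(tidy(rep), "tbl_df")
  gl <- glance(rep)
  expect_equal(gl$mean_dice, 1)

  # report serialization round-trips
  dir <- tempfile()
  paths <- write_report(rep, dir)
  expect_true(all(file.exists(unlist(paths))))
  back <- utils::read.csv(paths$structures)
  expect_equal(nrow(back), nrow(rep$structures))
  expect_equal(back$dice, rep$structures$dice)
})
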