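#' Build the toy ablation benchmark dataset
#'
#' A small, fixed study design used to compare the ablation variants in a
#' CPU-tractable setting: 64-voxel phantoms with one midline bone and two
#' bilateral muscles (K+1 = 4 channels), 64x64 axis-aligned parallel
#' projections, moderate pose perturbation and quantum noise on the
#' radiograph stand-ins, and a fixed muscle asymmetry of 0.85.
#'
#' @param n_cases cases in total (split 1/2 train, 1/4 val, 1/4 test).
#' @param seed integer seed for phantoms, poses and noise.
#' @return an `xdecomp_manifest`.
#' @export
toy_benchmark_manifest <- function(n_cases = 24, seed = 1) {
  specs <- lapply(seq_len(n_cases), function(i)
    phantom_spec(grid_shape = c(64, 64, 64), spacing = c(3, 3, 3),
                 n_bones = 1, n_muscles = 2, asymmetry_factor = 0.85,
                 seed = derive_seed(seed, 500 + i)))
  build_dataset(specs, noise = list(i0 = 1e4),
                pose_bounds = list(rotation = c(3, 3, 3),
                                   translation = c(6, 6, 6)),
                splits = c(train = 0.5, val = 0.25, test = 0.25),
                seed = derive_seed(seed, 1))
}

#' Train one variant on the toy benchmark and score held-out Dice
#'
#' Trains with a shortened schedule (same shape as the full one: constant
#' learning rate for the first half, linear decay for the second),
#' decomposes the held-out test radiographs and returns the mean Dice over
#' the foreground structures.
#'
#' @param manifest a [toy_benchmark_manifest()].
#' @param variant ablation variant name.
#' @param seed training seed.
#' @param epochs epochs per stage.
#' @param base_width,residual_blocks toy network sizes.
#' @return list with `mean_dice`, the `report` and the train `state`.
#' @export
toy_benchmark_run <- function(manifest, variant, seed = 1, epochs = 20,
                              base_width = 8, residual_blocks = 2) {
  cfg <- training_config(variant, epochs = epochs, image_size = 64,
                         base_width = base_width,
                         residual_blocks = residual_blocks, seed = seed)
  state <- train(manifest, cfg)
  test_ids <- manifest_split(manifest, "test")
  decs <- lapply(test_ids, function(ci)
    decompose(manifest$data[[ci]]$radiograph, state))
  report <- evaluate_decomposition(manifest, decs, cases = test_ids)
  list(mean_dice = mean(report$structures$dice), report = report,
       state = state)
}

#' Run the full toy ablation comparison
#'
#' @param manifest a [toy_benchmark_manifest()].
#' @param variants variants to compare.
#' @param seeds training seeds.
#' @param ... passed to [toy_benchmark_run()].
#' @return tibble with one row per variant x seed and its held-out mean
#'   Dice.
#' @export
toy_benchmark_ablation <- function(manifest,
                                   variants = c("conventional1",
                                                "proposed1", "proposed2"),
                                   seeds = 1:3, ...) {
  rows <- list()
  for (s in seeds) {
    for (v in variants) {
      r <- toy_benchmark_run(manifest, v, seed = s, ...)
      rows[[length(rows) + 1]] <- tibble::tibble(
        variant = v, seed = s, mean_dice = r$mean_dice)
    }
  }
  dplyr::bind_rows(rows)
}
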