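#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)`. A zero MSE is reported as the capped sentinel
#' 99 dB with attribute `capped = TRUE`.
#'
#' @param pred,truth numeric matrices of equal shape.
#' @param peak peak intensity of the scale (255 on the normalized scale).
#' @return PSNR in dB.
#' @export
psnr <- function(pred, truth, peak = 255) {
  pred <- as_image_matrix(pred); truth <- as_image_matrix(truth)
  if (!all(dim(pred) == dim(truth))) stop("shape mismatch in psnr")
  stopifnot(peak > 0)
  mse <- mean((pred - truth)^2)
  if (mse == 0) return(structure(99, capped = TRUE))
  10 * log10(peak^2 / mse)
}

#' Dice overlap coefficient of two binary masks
#'
#' `2|a & b| / (|a| + |b|)`; two empty masks score 1 by convention (flagged
#' with attribute `both_empty`).
#'
#' @param a,b logical (or 0/1) matrices/arrays of equal shape.
#' @return Dice in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch in dice")
  a <- a > 0; b <- b > 0
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(structure(1, both_empty = TRUE))
  2 * sum(a & b) / (na + nb)
}

#' Select a binarization threshold by best average Dice
#'
#' Evaluates the mean Dice over cases at every candidate threshold and
#' returns the maximizer (smallest threshold on ties), the selection rule
#' used to suppress threshold bias when comparing methods.
#'
#' @param preds list of predicted images (matrices, common intensity scale).
#' @param truths list of ground-truth binary masks.
#' @param sweep numeric vector of candidate thresholds.
#' @return list with `threshold`, `mean_dice`, and the full `sweep` tibble.
#' @export
select_threshold <- function(preds, truths, sweep) {
  stopifnot(length(preds) == length(truths), length(preds) > 0,
            length(sweep) > 0)
  mean_dice <- vapply(sweep, function(th) {
    mean(mapply(function(p, t) dice(p > th, t > 0), preds, truths))
  }, numeric(1))
  best <- which.max(mean_dice)   # which.max takes the first (smallest) tie
  list(threshold = sweep[best], mean_dice = mean_dice[best],
       sweep = tibble::tibble(threshold = sweep, mean_dice = mean_dice))
}

# default sweep: evenly spaced over 1..25% of the per-structure ground truth
# maximum
default_sweep <- function(truth_max, n = 41) {
  seq(0.01 * truth_max, 0.25 * truth_max, length.out = n)
}

#' Affected/unaffected volume ratio from one decomposed channel
#'
#' Under a parallel projection the pixel sum of a uniform structure's DRR is
#' proportional to its attenuation-weighted volume, so the ratio of channel
#' sums over the affected and unaffected side regions estimates the
#' AC-weighted volume ratio of the two sides.
#'
#' @param channel decomposed structure image in raw (denormalized)
#'   line-integral units.
#' @param omega_affected,omega_unaffected disjoint logical masks on the
#'   detector delineating the two side regions.
#' @param ground_truth_ratio optional reference ratio `alpha_A V_A /
#'   (alpha_U V_U)` from the phantom masks.
#' @param label structure name carried into the result.
#' @return a one-row tibble: `label`, `r`, `sum_affected`, `sum_unaffected`,
#'   `ground_truth_ratio`.
#' @export
volume_ratio <- function(channel, omega_affected, omega_unaffected,
                         ground_truth_ratio = NA_real_, label = NA_character_) {
  channel <- as_image_matrix(channel)
  if (any(omega_affected & omega_unaffected))
    stop("affected/unaffected regions must be disjoint")
  sa <- sum(channel[omega_affected])
  su <- sum(channel[omega_unaffected])
  if (su == 0) stop("unaffected-side sum is zero")
  tibble::tibble(label = label, r = sa / su, sum_affected = sa,
                 sum_unaffected = su, ground_truth_ratio = ground_truth_ratio)
}

#' Intraclass correlation coefficient (two-way, absolute agreement, single
#' measure)
#'
#' Computed from the two-way ANOVA mean squares of an n-cases x k-raters
#' table (here k = 2: estimate and reference):
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param estimates,truths numeric vectors (>= 3 pairs).
#' @return ICC in \[-1, 1\].
#' @export
icc <- function(estimates, truths) {
  stopifnot(length(estimates) == length(truths))
  n <- length(estimates)
  if (n < 3) stop("icc needs at least 3 pairs")
  x <- cbind(estimates, truths)
  k <- 2
  grand <- mean(x)
  if (all(x == grand)) stop("zero total variance")
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((x - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

group_of <- function(labels) {
  labels$group
}

#' Score decompositions against ground-truth DRRs
#'
#' Computes per-structure PSNR (on both the normalized and raw scales) and
#' Dice with best-average-threshold selection (per structure, across cases),
#' per-case means over the structure groups (bones, hip muscles, thigh
#' muscles; the background channel is not evaluated), affected/unaffected
#' volume ratios of asymmetric muscles with their ground-truth references,
#' and the ICC between estimated and reference ratios across cases.
#'
#' @param manifest an `xdecomp_manifest`.
#' @param decompositions named/indexed list of [decomposed_set()] predictions
#'   (normalized scale) for a subset of cases; names or `cases` give the case
#'   ids.
#' @param cases integer case ids matching `decompositions`.
#' @param sweep_n number of candidate thresholds for Dice binarization.
#' @return an `xdecomp_report` with tibbles `structures` (per case x
#'   structure), `thresholds`, `groups`, `ratios` and `icc`.
#' @export
evaluate_decomposition <- function(manifest, decompositions,
                                   cases = seq_along(decompositions),
                                   sweep_n = 41) {
  stopifnot(length(decompositions) == length(cases))
  labels <- manifest$labels
  norm <- manifest$normalization
  fg <- labels[labels$group != "background", ]

  # per-structure truth/pred pairs on the normalized scale
  per <- list()
  thr_rows <- list()
  for (si in seq_len(nrow(fg))) {
    lid <- fg$label_id[si]
    preds <- lapply(seq_along(cases), function(j)
      decompositions[[j]]$channels[, , lid])
    truths_n <- lapply(cases, function(ci)
      norm_fwd(manifest$data[[ci]]$drr$channels[, , lid], norm))
    tmax <- max(vapply(truths_n, max, numeric(1)))
    sel <- select_threshold(preds, lapply(truths_n, function(t) t > 0),
                            default_sweep(max(tmax, 1e-6), sweep_n))
    thr_rows[[si]] <- tibble::tibble(
      label_id = lid, name = fg$name[si], group = fg$group[si],
      threshold = sel$threshold, mean_dice = sel$mean_dice)
    for (j in seq_along(cases)) {
      ci <- cases[j]
      pred_raw <- norm_inv(preds[[j]], norm)
      truth_raw <- manifest$data[[ci]]$drr$channels[, , lid]
      per[[length(per) + 1]] <- tibble::tibble(
        case_id = ci, label_id = lid, name = fg$name[si],
        group = fg$group[si],
        psnr_normalized = as.numeric(psnr(preds[[j]], truths_n[[j]], 255)),
        psnr_raw = as.numeric(psnr(pred_raw, truth_raw,
                                   peak = norm$raw_max - norm$raw_min)),
        dice = dice(preds[[j]] > sel$threshold, truths_n[[j]] > 0))
    }
  }
  structures <- dplyr::bind_rows(per)
  thresholds <- dplyr::bind_rows(thr_rows)

  groups <- structures |>
    dplyr::group_by(.data$case_id, .data$group) |>
    dplyr::summarise(psnr = mean(.data$psnr_normalized),
                     dice = mean(.data$dice), .groups = "drop")

  # volume ratios for asymmetric muscles, against phantom ground truth
  ratio_rows <- list()
  asym <- labels[labels$asymmetric, ]
  for (j in seq_along(cases)) {
    ci <- cases[j]
    ph <- manifest$data[[ci]]$phantom
    for (si in seq_len(nrow(asym))) {
      lid <- asym$label_id[si]
      supp <- project_side_supports(ph, manifest$geometry, lid)
      aff <- ph$affected_side
      om_a <- if (aff == "left") supp$left else supp$right
      om_u <- if (aff == "left") supp$right else supp$left
      sv <- manifest$data[[ci]]$phantom$side_volumes
      va <- sv$volume_mm3[sv$label_id == lid & sv$side == aff]
      vu <- sv$volume_mm3[sv$label_id == lid & sv$side != aff]
      ch_raw <- norm_inv(decompositions[[j]]$channels[, , lid], norm)
      rr <- volume_ratio(ch_raw, om_a, om_u,
                         ground_truth_ratio = va / vu, label = asym$name[si])
      rr$case_id <- ci
      ratio_rows[[length(ratio_rows) + 1]] <- rr
    }
  }
  ratios <- if (length(ratio_rows)) dplyr::bind_rows(ratio_rows) else
    tibble::tibble(label = character(), r = numeric(),
                   sum_affected = numeric(), sum_unaffected = numeric(),
                   ground_truth_ratio = numeric(), case_id = integer())

  icc_parts <- lapply(split(ratios, ratios$label), function(d) {
    if (nrow(d) < 3) return(NULL)
    tibble::tibble(label = d$label[1],
                   icc = icc(d$r, d$ground_truth_ratio), n = nrow(d))
  })
  icc_tbl <- if (length(icc_parts)) dplyr::bind_rows(icc_parts) else
    tibble::tibble(label = character(), icc = numeric(), n = integer())

  structure(list(structures = structures, thresholds = thresholds,
                 groups = groups, ratios = ratios, icc = icc_tbl,
                 cases = cases),
            class = "xdecomp_report")
}

#' @export
print.xdecomp_report <- function(x, ...) {
  cat("<xdecomp_report> ", length(x$cases), " cases\n", sep = "")
  g <- x$groups |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(psnr = mean(.data$psnr), dice = mean(.data$dice),
                     .groups = "drop")
  print(g)
  if (nrow(x$icc)) {
    cat("volume-ratio ICC:\n")
    print(x$icc)
  }
  invisible(x)
}
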