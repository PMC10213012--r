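#' Tidy an evaluation report
#'
#' @param x an `xdecomp_report`.
#' @param ... unused.
#' @return the per-case, per-structure metric tibble.
#' @exportS3Method generics::tidy
tidy.xdecomp_report <- function(x, ...) {
  x$structures
}

#' One-row summary of an evaluation report
#'
#' @param x an `xdecomp_report`.
#' @param ... unused.
#' @return tibble with overall mean PSNR/Dice, per-group Dice means, mean
#'   volume-ratio error and mean ICC.
#' @exportS3Method generics::glance
glance.xdecomp_report <- function(x, ...) {
  g <- x$groups |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(dice = mean(.data$dice), .groups = "drop")
  wide <- setNames(as.list(g$dice), paste0("dice_", gsub(" ", "_", g$group)))
  ratio_rmse <- if (nrow(x$ratios))
    sqrt(mean((x$ratios$r - x$ratios$ground_truth_ratio)^2)) else NA_real_
  tibble::tibble(n_cases = length(x$cases),
                 mean_psnr = mean(x$structures$psnr_normalized),
                 mean_dice = mean(x$structures$dice),
                 !!!wide,
                 ratio_rmse = ratio_rmse,
                 mean_icc = if (nrow(x$icc)) mean(x$icc$icc) else NA_real_)
}

#' Tidy a training state (loss history)
#' @param x an `xdecomp_train_state`.
#' @param ... unused.
#' @return the per-step loss tibble.
#' @exportS3Method generics::tidy
tidy.xdecomp_train_state <- function(x, ...) {
  loss_history(x)
}

#' One-row summary of a training run
#' @param x an `xdecomp_train_state`.
#' @param ... unused.
#' @return tibble with the variant, epochs trained and final-epoch loss
#'   means.
#' @exportS3Method generics::glance
glance.xdecomp_train_state <- function(x, ...) {
  h <- loss_history(x)
  last <- h[h$pos == max(h$pos), ]
  tibble::tibble(variant = x$config$variant, epochs = x$pos,
                 gan = mean(last$gan), cyc = mean(last$cyc),
                 recon_gc = mean(last$recon_gc),
                 recon_l2 = mean(last$recon_l2), total = mean(last$total))
}

#' Plot estimated versus reference volume ratios
#'
#' Scatter of the affected/unaffected volume ratio estimated from decomposed
#' channels against the phantom ground truth, one point per case and muscle.
#'
#' @param object an `xdecomp_report`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.xdecomp_report <- function(object, ...) {
  ggplot2::ggplot(object$ratios,
                  ggplot2::aes(x = .data$r, y = .data$ground_truth_ratio,
                               colour = .data$label)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "estimated ratio (from decomposed DRR)",
                  y = "reference ratio (from 3D masks)",
                  colour = "muscle",
                  title = "Affected/unaffected volume ratio") +
    ggplot2::theme_minimal()
}

#' Plot training loss curves
#' @param object an `xdecomp_train_state`.
#' @param ... unused.
#' @return a ggplot of per-epoch mean loss terms.
#' @exportS3Method ggplot2::autoplot
autoplot.xdecomp_train_state <- function(object, ...) {
  h <- loss_history(object) |>
    dplyr::group_by(.data$pos, .data$stage) |>
    dplyr::summarise(dplyr::across(c("gan", "d_drr", "d_xp", "cyc",
                                     "recon_gc", "recon_l2"), mean),
                     .groups = "drop") |>
    tidyr::pivot_longer(c("gan", "d_drr", "d_xp", "cyc", "recon_gc",
                          "recon_l2"),
                        names_to = "term", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$pos, y = .data$value,
                                  colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "epoch (stages concatenated)", y = "loss term") +
    ggplot2::theme_minimal()
}

#' Display a decomposed channel set as an image mosaic
#'
#' @param x an [decomposed_set()] (or a raw channel array).
#' @param labels optional character channel names.
#' @return a ggplot with one facet per channel.
#' @export
plot_decomposition <- function(x, labels = NULL) {
  ch <- if (inherits(x, "xdecomp_decomposed")) x$channels else x
  if (is.null(labels) && inherits(x, "xdecomp_decomposed"))
    labels <- x$labels$name
  if (is.null(labels)) labels <- paste0("channel ", seq_len(dim(ch)[3]))
  d <- dim(ch)
  df <- tidyr::expand_grid(channel = seq_len(d[3]), v = seq_len(d[1]),
                           u = seq_len(d[2]))
  df$value <- as.numeric(aperm(ch, c(2, 1, 3)))
  df$channel <- factor(labels[df$channel], levels = labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::facet_wrap(~channel) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "intensity")
}
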