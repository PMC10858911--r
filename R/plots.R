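#' Plot a population characterization
#'
#' Bar histograms of the flash count, inter-flash gap and flash duration
#' distributions, one facet per statistic.
#'
#' @param object A `firefly_characterization`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.firefly_characterization <- function(object, ...) {
  h <- object$histograms
  ggplot2::ggplot(h, ggplot2::aes(
    x = (.data$bin_left + .data$bin_right) / 2,
    y = .data$mass,
    width = .data$bin_right - .data$bin_left
  )) +
    ggplot2::geom_col(fill = "#e6b422", colour = "grey30", linewidth = 0.2) +
    ggplot2::facet_wrap(~statistic, scales = "free") +
    ggplot2::labs(
      x = NULL, y = "probability mass",
      title = object$population,
      subtitle = sprintf("%d sequences", object$n_sequences)
    ) +
    ggplot2::theme_minimal()
}

#' Plot sympatry identification rates
#'
#' Identification rate of the minority species as a function of its
#' proportion in the mixture, one line per ordered species pair.
#'
#' @param object A `fireflash_sympatry` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fireflash_sympatry <- function(object, ...) {
  d <- object[object$role == "minority", , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$proportion, y = .data$identification_rate,
    colour = .data$species,
    group = interaction(.data$species, .data$majority)
  )) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "minority species proportion",
                  y = "identification rate", colour = "minority species") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Heatmap of a confusion matrix
#'
#' @param m A matrix from [confusion_matrix()].
#' @return A ggplot object.
#' @export
plot_confusion <- function(m) {
  d <- tibble::as_tibble(as.table(m), .name_repair = "minimal")
  names(d) <- c("truth", "predicted", "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$predicted, .data$truth,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$value)),
                       colour = "white", size = 3) +
    ggplot2::scale_y_discrete(limits = rev(rownames(m))) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(fill = "ratio") +
    ggplot2::theme_minimal()
}

#' One-vs-rest ROC curves
#'
#' @param roc A tibble from [roc_curves()].
#' @return A ggplot object.
#' @export
plot_roc <- function(roc) {
  d <- tidyr::unnest(roc[, c("species", "curve")], "curve")
  lab <- setNames(sprintf("%s (AUC %.2f)", roc$species, roc$auc), roc$species)
  ggplot2::ggplot(d, ggplot2::aes(.data$fpr, .data$tpr,
                                  colour = .data$species)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::scale_colour_discrete(labels = lab) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' Raster plot of flash sequences
#'
#' Each sequence is drawn as a row, with flashes as filled cells -- the
#' standard way to eyeball species-characteristic patterns.
#'
#' @param ds A sequence table.
#' @param fps Frames per second. Default 30.
#' @return A ggplot object.
#' @export
plot_flash_raster <- function(ds, fps = 30) {
  ds <- as_sequence_table(ds)
  vs <- bits_to_vecs(ds$bits)
  d <- purrr::imap_dfr(vs, function(v, i) {
    on <- which(v == 1L)
    tibble::tibble(
      seq = i, t = (on - 1) / fps,
      species = if ("species" %in% names(ds)) ds$species[i] else NA_character_
    )
  })
  ggplot2::ggplot(d, ggplot2::aes(.data$t, .data$seq)) +
    ggplot2::geom_tile(width = 1 / fps, height = 0.8, fill = "#e6b422") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$species), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = "time (s)", y = "sequence") +
    ggplot2::theme_minimal()
}
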