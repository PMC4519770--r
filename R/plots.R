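#' Plot a variant PCA
#'
#' Scatter of the first two principal components of the variant frequency
#' spectra, colored by group when available.
#'
#' @param object a `variant_pca` from [pca_variants()].
#' @param ... ignored.
#' @return a ggplot.
#' @method autoplot variant_pca
#' @export
autoplot.variant_pca <- function(object, ...) {
  vf <- object$variance_fraction
  p <- ggplot2::ggplot(object$scores, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * vf[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * vf[2])
    ) +
    ggplot2::theme_minimal()
  if ("group" %in% names(object$scores)) {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$group), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}

#' Plot variant frequency spectra
#'
#' Per-variant frequencies across samples, optionally grouped.
#'
#' @param variant_table output of [tabulate_variants()].
#' @param metadata optional tibble with `sample_id` and `group`.
#' @param top_n show only the `top_n` most abundant variants (default 10).
#' @return a ggplot.
#' @export
plot_variant_frequencies <- function(variant_table, metadata = NULL, top_n = 10) {
  keep <- variant_table |>
    group_by(.data$variant) |>
    summarise(m = mean(.data$frequency), .groups = "drop") |>
    arrange(desc(.data$m)) |>
    head(top_n) |>
    pull("variant")
  dat <- filter(variant_table, .data$variant %in% keep) |>
    mutate(variant = factor(.data$variant, levels = keep))
  if (!is.null(metadata)) {
    meta <- as_tibble(metadata)
    if ("sample_id" %in% names(meta)) meta <- rename(meta, sample = "sample_id")
    dat <- left_join(dat, meta[, c("sample", "group")], by = "sample")
    ggplot2::ggplot(dat, ggplot2::aes(.data$variant, .data$frequency,
                                      color = .data$group)) +
      ggplot2::geom_jitter(width = 0.15, height = 0) +
      ggplot2::theme_minimal() +
      ggplot2::labs(x = "editing variant", y = "frequency")
  } else {
    ggplot2::ggplot(dat, ggplot2::aes(.data$variant, .data$frequency)) +
      ggplot2::geom_jitter(width = 0.15, height = 0) +
      ggplot2::theme_minimal() +
      ggplot2::labs(x = "editing variant", y = "frequency")
  }
}

#' Plot per-site editing efficiencies
#'
#' @param site_eff output of [site_efficiencies()].
#' @param metadata optional tibble with `sample_id` and `group`.
#' @return a ggplot.
#' @export
plot_site_efficiencies <- function(site_eff, metadata = NULL) {
  dat <- site_eff
  if (!is.null(metadata)) {
    meta <- as_tibble(metadata)
    if ("sample_id" %in% names(meta)) meta <- rename(meta, sample = "sample_id")
    dat <- left_join(dat, meta[, c("sample", "group")], by = "sample")
    ggplot2::ggplot(dat, ggplot2::aes(.data$site, .data$efficiency,
                                      color = .data$group)) +
      ggplot2::geom_jitter(width = 0.1, height = 0) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(dat, ggplot2::aes(.data$site, .data$efficiency)) +
      ggplot2::geom_jitter(width = 0.1, height = 0) +
      ggplot2::theme_minimal()
  }
}

#' Volcano plot of a differential-expression result
#'
#' @param object a `de_result` from [differential_expression()].
#' @param ... ignored.
#' @return a ggplot.
#' @method autoplot de_result
#' @export
autoplot.de_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$log2_fc,
                                       -log10(.data$p_adjusted),
                                       color = .data$de)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p",
                  color = "DE") +
    ggplot2::theme_minimal()
}

#' Scale-free fit plot of a co-expression network
#'
#' R^2 of the scale-free degree-distribution fit across candidate powers,
#' with the chosen beta marked.
#'
#' @param object a `coexpression_network`.
#' @param ... ignored.
#' @return a ggplot.
#' @method autoplot coexpression_network
#' @export
autoplot.coexpression_network <- function(object, ...) {
  ggplot2::ggplot(object$fit, ggplot2::aes(.data$beta, .data$r2)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$beta, linetype = 2) +
    ggplot2::labs(x = "soft-threshold power", y = "scale-free fit R²") +
    ggplot2::theme_minimal()
}

#' Category tallies of a network classification
#'
#' @param object a `bna_result` from [classify_all()].
#' @param ... ignored.
#' @return a ggplot.
#' @method autoplot bna_result
#' @export
autoplot.bna_result <- function(object, ...) {
  tall <- count(as_tibble(object), category = .data$category)
  ggplot2::ggplot(tall, ggplot2::aes(.data$category, .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal()
}
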