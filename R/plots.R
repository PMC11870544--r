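#' Plot cluster mean temporal profiles
#'
#' One line per cell-type segment of each cluster's mean concatenated
#' profile.
#'
#' @param object a `stim_modules`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.stim_modules <- function(object, ...) {
  nb <- object$n_bins
  cts <- object$cell_types
  long <- purrr::imap(seq_along(cts), function(i, ...) {
    cols <- ((i - 1) * nb + 1):(i * nb)
    tibble(cluster = rep(seq_len(object$k), times = nb),
           cell_type = cts[i],
           bin = rep(seq_len(nb), each = object$k),
           value = as.vector(object$centers[, cols]))
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin, y = .data$value,
                                     colour = .data$cell_type)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "pseudotime bin", y = "mean z-scored expression",
                  colour = "cell type") +
    ggplot2::theme_minimal()
}

#' Plot binned pseudotime profiles for selected features
#'
#' @param profiles a `stim_profiles`.
#' @param features feature ids to draw (default: first 6).
#' @return a ggplot.
#' @export
plot_bin_profiles <- function(profiles,
                              features = head(rownames(profiles$values), 6)) {
  tab <- profile_tbl(profiles)
  tab <- tab[tab$feature_id %in% features, ]
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$bin, y = .data$value,
                                    colour = .data$feature_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pseudotime bin",
                  y = if (profiles$scale == "z") "z-scored signal"
                      else "normalized signal",
                  colour = NULL,
                  title = profiles$cell_type) +
    ggplot2::theme_minimal()
}

#' Scatter of ASoC allelic ratios against caQTL effect sizes
#'
#' Mirrors the standard concordance display: pooled log allelic ratio on x,
#' caQTL beta on y, with the zero-intercept fitted slope.
#'
#' @param asoc_results,caqtl_results as in [caqtl_concordance()].
#' @return a ggplot.
#' @export
plot_asoc_concordance <- function(asoc_results, caqtl_results) {
  joined <- dplyr::inner_join(asoc_results, caqtl_results,
                              by = c("snp_id", "cell_type", "time"),
                              suffix = c("_asoc", "_caqtl"))
  joined <- joined[joined$ref_count > 0 & joined$alt_count > 0, ]
  joined$log_ratio <- log(joined$alt_count / joined$ref_count)
  slope <- sum(joined$log_ratio * joined$beta) / sum(joined$log_ratio^2)
  ggplot2::ggplot(joined, ggplot2::aes(x = .data$log_ratio, y = .data$beta)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = slope, intercept = 0, colour = "red") +
    ggplot2::labs(x = "ASoC log(alt/ref)", y = "caQTL effect size") +
    ggplot2::theme_minimal()
}

#' Stacked per-context PIPs for top genes
#'
#' @param gene_pips [aggregate_gene_pip()] output.
#' @param top number of genes shown, by gene PIP (default 20).
#' @return a ggplot.
#' @export
plot_gene_pips <- function(gene_pips, top = 20) {
  tab <- dplyr::arrange(gene_pips, dplyr::desc(.data$gene_pip))
  tab <- head(tab, top)
  long <- tidyr::pivot_longer(
    tab[, c("feature_id", "pip_0h", "pip_1h", "pip_6h")],
    cols = dplyr::starts_with("pip_"), names_to = "time",
    names_prefix = "pip_", values_to = "pip")
  long$feature_id <- factor(long$feature_id, levels = rev(tab$feature_id))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pip, y = .data$feature_id,
                                     fill = .data$time)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "PIP (summed over contexts)", y = NULL,
                  fill = "time") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential result table
#'
#' @param diff_results a [response_de()] / [da_peaks()] /
#'   [case_control_de()] tibble.
#' @param q_threshold significance colouring cutoff.
#' @return a ggplot.
#' @export
plot_volcano <- function(diff_results, q_threshold = 0.05) {
  diff_results$significant <- diff_results$q < q_threshold
  ggplot2::ggplot(diff_results,
                  ggplot2::aes(x = .data$lfc, y = -log10(pmax(.data$p, 1e-300)),
                               colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_minimal()
}
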