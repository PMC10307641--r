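#' @importFrom ggplot2 ggplot aes geom_col geom_line geom_point geom_tile
#'   geom_boxplot geom_errorbar facet_wrap labs theme_minimal autoplot
#'   scale_fill_gradient2 element_text theme
NULL

#' Plot a stop-codon metagene profile
#'
#' 5'-end counts by position relative to the stop codon, one panel per
#' footprint length; the upstream peak structure is what the A-site
#' calibration reads off.
#'
#' @param profile A [stop_metagene()] profile.
#' @return A ggplot object.
#' @export
plot_stop_metagene <- function(profile) {
  ggplot(profile, aes(x = .data$position, y = .data$count)) +
    geom_col(width = 0.8) +
    facet_wrap(~length, scales = "free_y") +
    labs(x = "position of 5' end relative to stop codon (nt)",
         y = "footprint 5' ends",
         title = "Stop-codon metagene by footprint length") +
    theme_minimal()
}

#' @rdname plot_stop_metagene
#' @param object,... Autoplot interface.
#' @export
autoplot.metagene_profile <- function(object, ...) plot_stop_metagene(object)

#' Plot adjusted reading-frame counts
#' @param object A [frame_statistic()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.frame_stat <- function(object, ...) {
  d <- tibble(frame = factor(0:2), count = unname(object$triplet))
  ggplot(d, aes(x = .data$frame, y = .data$count)) +
    geom_col() +
    labs(x = "adjusted reading frame", y = "footprints",
         subtitle = sprintf("chi-squared = %.3g, p = %.3g",
                            object$statistic, object$p_value)) +
    theme_minimal()
}

#' Plot read fractions across transcript regions
#' @param region_df A [region_distribution()] result.
#' @return A ggplot object.
#' @export
plot_region_distribution <- function(region_df) {
  ggplot(region_df, aes(x = .data$region, y = .data$fraction)) +
    geom_col() +
    labs(x = NULL, y = "fraction of reads") +
    theme_minimal()
}

#' Plot the corrected paternal percentage trajectory across stages
#' @param summary A [stage_paternal_summary()] table.
#' @param stage_order Optional stage ordering for the x axis.
#' @return A ggplot object.
#' @export
plot_stage_paternal <- function(summary, stage_order = NULL) {
  if (!is.null(stage_order)) {
    summary <- mutate(summary, stage = factor(.data$stage, levels = stage_order))
  }
  ggplot(summary, aes(x = .data$stage, y = .data$mean_corrected_pct,
                      colour = .data$modality, group = .data$modality)) +
    geom_line() + geom_point() +
    geom_errorbar(aes(ymin = .data$mean_corrected_pct - .data$sem,
                      ymax = .data$mean_corrected_pct + .data$sem),
                  width = 0.15) +
    labs(x = NULL, y = "corrected paternal reads (%)", colour = NULL) +
    theme_minimal()
}

#' Boxplots of translation efficiency by poly(A) tail-length bin
#' @param object A [polya_te_association()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.polya_assoc <- function(object, ...) {
  ggplot(object$data, aes(x = factor(.data$bin), y = .data$te)) +
    geom_boxplot(outlier.shape = NA) +
    labs(x = "poly(A) tail length bin (short to long)",
         y = "translation efficiency",
         subtitle = sprintf("Spearman rho = %.3f (p = %.3g)",
                            object$rho, object$p_value)) +
    theme_minimal()
}

#' Heatmap of the cross-stage correlation grid
#' @param object A [cross_stage_grid()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_grid <- function(object, ...) {
  ggplot(object, aes(x = .data$protein_stage, y = .data$source_stage,
                     fill = .data$corrected)) +
    geom_tile() +
    facet_wrap(~modality) +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(x = "protein stage", y = "source stage",
         fill = "corrected rho") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
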