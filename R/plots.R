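# ggplot2 visualizations for the main result types.

gray_raster_df <- function(m, name = "value") {
  tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.numeric(m)
  )
}

#' Plot a grayscale matrix
#'
#' @param image Numeric matrix.
#' @param title Optional plot title.
#' @return A ggplot object (raster, gray palette, image orientation).
#' @export
plot_gray <- function(image, title = NULL) {
  df <- gray_raster_df(image)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn oriented_pc Faceted raster plot of the oriented PC maps.
#' @param object A `pc_stack`.
#' @param ... Unused.
#' @method autoplot pc_stack
#' @export
autoplot.pc_stack <- function(object, ...) {
  dfs <- lapply(seq_along(object$pc), function(o) {
    df <- gray_raster_df(object$pc[[o]])
    df$orientation <- sprintf("o = %d", o)
    df
  })
  df <- dplyr::bind_rows(dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~orientation) +
    ggplot2::labs(x = NULL, y = NULL, fill = "PC") +
    ggplot2::theme_minimal()
}

#' @describeIn loo_cv ROC curve of the pooled held-out scores.
#' @param object A `pcbp_eval`.
#' @method autoplot pcbp_eval
#' @export
autoplot.pcbp_eval <- function(object, ...) {
  rc <- roc_curve(object$scores$score, object$scores$label)
  ggplot2::ggplot(rc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC (AUC = %.3f)", object$report$auc)) +
    ggplot2::theme_minimal()
}

#' @describeIn bootstrap_eval Boxplot of the bootstrap AUC replicates.
#' @param object A `pcbp_boot`.
#' @method autoplot pcbp_boot
#' @export
autoplot.pcbp_boot <- function(object, ...) {
  ggplot2::ggplot(object$replicates, ggplot2::aes(x = "", y = .data$auc)) +
    ggplot2::geom_boxplot(width = 0.3, outlier.size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 16) +
    ggplot2::labs(x = NULL, y = "AUC",
                  title = sprintf("Bootstrap AUC (B = %d)", object$B)) +
    ggplot2::theme_minimal()
}

#' @describeIn cross_contrast_experiment Bar chart of AUC per database.
#' @param object A `cross_contrast_eval`.
#' @method autoplot cross_contrast_eval
#' @export
autoplot.cross_contrast_eval <- function(object, ...) {
  df <- object$summary
  df$database <- factor(df$database, levels = df$database)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$database, y = .data$auc)) +
    ggplot2::geom_col(width = 0.6, fill = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0.5, 1)) +
    ggplot2::labs(x = NULL, y = "AUC",
                  title = "Cross-contrast train/test AUC") +
    ggplot2::theme_minimal()
}
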