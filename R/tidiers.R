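# broom-style tidiers for the evaluation objects.

eval_metric_row <- function(report) {
  tibble::tibble(auc = report$auc, acc = report$acc, sens = report$sens,
                 spec = report$spec, ppv = report$ppv, npv = report$npv,
                 mcc = report$mcc)
}

#' @describeIn confusion_metrics Long tibble of the seven metrics.
#' @param x An `eval_report`.
#' @param ... Unused.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  tidyr::pivot_longer(eval_metric_row(x), dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @describeIn confusion_metrics One-row tibble of the seven metrics.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) eval_metric_row(x)

#' @describeIn loo_cv Per-case held-out scores and predictions.
#' @param x A `pcbp_eval`.
#' @param ... Unused.
#' @method tidy pcbp_eval
#' @export
tidy.pcbp_eval <- function(x, ...) x$scores

#' @describeIn loo_cv One-row summary: the seven metrics plus `n`, `C`,
#'   `gamma` and the evaluation mode.
#' @method glance pcbp_eval
#' @export
glance.pcbp_eval <- function(x, ...) {
  dplyr::bind_cols(eval_metric_row(x$report),
                   tibble::tibble(n = x$n, C = x$config$C,
                                  gamma = x$config$gamma, mode = x$mode))
}

#' @describeIn bootstrap_eval Per-replicate metric tibble.
#' @param x A `pcbp_boot`.
#' @param ... Unused.
#' @method tidy pcbp_boot
#' @export
tidy.pcbp_boot <- function(x, ...) x$replicates

#' @describeIn bootstrap_eval One-row summary: mean and sd of every metric
#'   (columns `<metric>_mean`, `<metric>_sd`) plus `B` and `redraws`.
#' @method glance pcbp_boot
#' @export
glance.pcbp_boot <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "sd"),
                             names_glue = "{metric}_{.value}")
  dplyr::bind_cols(wide, tibble::tibble(B = x$B, redraws = x$redraws))
}

#' @describeIn cross_contrast_experiment Per-database metric tibble.
#' @param x A `cross_contrast_eval`.
#' @param ... Unused.
#' @method tidy cross_contrast_eval
#' @export
tidy.cross_contrast_eval <- function(x, ...) x$summary

#' @describeIn cross_contrast_experiment One-row summary: AUC per database
#'   and the largest absolute AUC shift from `Origin`.
#' @method glance cross_contrast_eval
#' @export
glance.cross_contrast_eval <- function(x, ...) {
  aucs <- setNames(x$summary$auc, paste0("auc_", tolower(x$summary$database)))
  delta <- max(abs(x$summary$auc - x$summary$auc[x$summary$database == "Origin"]))
  dplyr::bind_cols(tibble::as_tibble(as.list(aucs)),
                   tibble::tibble(max_delta_auc = delta))
}
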