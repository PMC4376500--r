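# RBF-SVM evaluation protocols: [-1,1] feature scaling, grid search with
# k-fold CV, leave-one-out CV, and bootstrap out-of-bag evaluation.
# Scaling is refitted on every training split so no test information leaks
# into the scaler.

#' Scale features to \[-1, 1\]
#'
#' Fits a per-feature affine map on the training table sending the observed
#' minimum to -1 and maximum to +1, and applies it to both tables. Test
#' values outside the training range extend beyond \[-1, 1\] (no clipping);
#' constant training columns map to 0 everywhere.
#'
#' @param train Feature tibble (`id`/`label` columns preserved) or matrix.
#' @param test Optional second table with the same feature columns.
#' @return List with `train`, `test` (or `NULL`) and `scaler` (list of
#'   per-feature `min`/`max`).
#' @export
scale_features <- function(train, test = NULL) {
  xtr <- if (is.data.frame(train)) feature_matrix(train) else as.matrix(train)
  if (nrow(xtr) == 0) stop("training table is empty")
  mins <- apply(xtr, 2, min)
  maxs <- apply(xtr, 2, max)
  apply_scale <- function(x) {
    out <- x
    for (j in seq_len(ncol(x))) {
      rng <- maxs[j] - mins[j]
      out[, j] <- if (rng > 0) 2 * (x[, j] - mins[j]) / rng - 1 else 0
    }
    out
  }
  put_back <- function(orig, scaled) {
    if (is.data.frame(orig)) {
      cols <- setdiff(names(orig), c("id", "label"))
      orig[, cols] <- tibble::as_tibble(scaled)
      orig
    } else scaled
  }
  res_test <- NULL
  if (!is.null(test)) {
    xte <- if (is.data.frame(test)) feature_matrix(test) else as.matrix(test)
    if (ncol(xte) != ncol(xtr)) stop("train and test feature columns differ")
    res_test <- put_back(test, apply_scale(xte))
  }
  list(train = put_back(train, apply_scale(xtr)), test = res_test,
       scaler = list(min = mins, max = maxs))
}

#' SVM configuration
#'
#' @param C Regularization parameter (> 0).
#' @param gamma RBF kernel width (> 0).
#' @param k Folds for cross-validated selection (default 10).
#' @param seed Seed controlling fold assignment.
#' @return Object of class `svm_config`.
#' @export
svm_config <- function(C, gamma, k = 10L, seed = 1L) {
  if (C <= 0 || gamma <= 0) stop("C and gamma must be > 0")
  if (k < 2) stop("k must be >= 2")
  structure(list(C = C, gamma = gamma, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "svm_config")
}

#' @export
print.svm_config <- function(x, ...) {
  cat("RBF-SVM config: C = ", format(x$C), ", gamma = ", format(x$gamma),
      " (k = ", x$k, ", seed = ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Candidate grid for SVM parameter search
#'
#' Log2-spaced grid after the standard practical recipe:
#' `C = 2^(-5), 2^(-3), ..., 2^15` and `gamma = 2^(-15), ..., 2^3` at
#' `step` powers of two (use `step = 1` for the finer half-decade grid).
#'
#' @param step Exponent step (default 2).
#' @return List with numeric vectors `C` and `gamma`.
#' @export
svm_grid <- function(step = 2) {
  list(C = 2^seq(-5, 15, by = step), gamma = 2^seq(-15, 3, by = step))
}

# fit an RBF SVM on a scaled feature matrix; labels benign/malignant
fit_rbf_svm <- function(x, labels, C, gamma) {
  e1071::svm(x = x, y = as_label_factor(labels), type = "C-classification",
             kernel = "radial", cost = C, gamma = gamma, scale = FALSE)
}

# decision values oriented so larger = more malignant
decision_scores <- function(model, x) {
  dv <- attr(stats::predict(model, x, decision.values = TRUE),
             "decision.values")
  s <- as.numeric(dv[, 1])
  nm <- colnames(dv)[1]
  if (identical(nm, "benign/malignant")) s <- -s
  s
}

#' Grid search for SVM parameters
#'
#' Selects `(C, gamma)` maximizing mean `k`-fold cross-validated accuracy
#' on the (internally scaled) training features. Fold assignment is
#' stratified by class and fixed by `seed`; ties are broken toward smaller
#' `C`, then smaller `gamma`.
#'
#' On small perfectly separable data wide regions of the accuracy surface
#' tie at 100% and the tie rule then returns the most-regularized corner,
#' whose near-zero-margin model can be fragile under leave-one-out;
#' inspect `attr(, "cv_accuracy")` or fix [svm_config()] explicitly there.
#'
#' @param features Feature tibble with a `label` column (or matrix plus
#'   `labels`).
#' @param grid A [svm_grid()].
#' @param k Number of folds (default 10); each class must have at least `k`
#'   members.
#' @param seed Seed for the fold assignment.
#' @param labels Class labels when `features` is a bare matrix.
#' @return A [svm_config()] carrying the winning parameters; attribute
#'   `cv_accuracy` holds the full grid of fold-averaged accuracies.
#' @export
grid_search_svm <- function(features, grid = svm_grid(), k = 10L, seed = 1L,
                            labels = NULL) {
  if (is.data.frame(features)) {
    labels <- features$label
    x <- feature_matrix(features)
  } else {
    x <- as.matrix(features)
  }
  lab <- as_label_factor(labels)
  if (length(unique(lab)) < 2) stop("both classes must be present")
  if (min(table(lab)) < k) stop("need at least k = ", k, " samples per class")

  n <- nrow(x)
  folds <- integer(n)
  withr::with_seed(seed, {
    for (cl in levels(lab)) {
      idx <- sample(which(lab == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })

  acc <- matrix(NA_real_, length(grid$C), length(grid$gamma),
                dimnames = list(format(grid$C), format(grid$gamma)))
  for (ci in seq_along(grid$C)) {
    for (gi in seq_along(grid$gamma)) {
      correct <- 0L
      for (f in seq_len(k)) {
        tr <- folds != f
        sc <- scale_features(x[tr, , drop = FALSE], x[!tr, , drop = FALSE])
        model <- fit_rbf_svm(sc$train, lab[tr], grid$C[ci], grid$gamma[gi])
        pred <- stats::predict(model, sc$test)
        correct <- correct + sum(pred == lab[!tr])
      }
      acc[ci, gi] <- correct / n
    }
  }
  best <- which(acc == max(acc), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  cfg <- svm_config(C = grid$C[best[1]], gamma = grid$gamma[best[2]],
                    k = k, seed = seed)
  attr(cfg, "cv_accuracy") <- acc
  cfg
}

#' Leave-one-out cross-validation
#'
#' `n` rounds each holding out one case: the scaler and SVM are refitted on
#' the remaining `n - 1` cases and the held-out case is scored by its SVM
#' decision value. The report pools all held-out scores (AUC from the
#' scores, confusion counts from the sign of the decision value).
#'
#' With `test_features` supplied (the cross-contrast scheme), training still
#' uses rows of `features` but round `i` scores row `i` of `test_features`
#' instead — features of a gray-scale-transformed copy of the same case.
#'
#' @param features Feature tibble with `label` (and optionally `id`).
#' @param config A fixed [svm_config()].
#' @param test_features Optional parallel feature table scored in place of
#'   the held-out originals.
#' @return Object of class `pcbp_eval`: `scores` tibble
#'   (`id`, `label`, `score`, `pred`), `report` ([confusion_metrics()] plus
#'   AUC), `config`, `mode = "loo"`.
#' @export
loo_cv <- function(features, config, test_features = NULL) {
  stopifnot(is.data.frame(features), "label" %in% names(features),
            inherits(config, "svm_config"))
  x <- feature_matrix(features)
  lab <- as_label_factor(features$label)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 cases")
  if (length(unique(lab)) < 2) stop("both classes must be present")
  xt <- x
  if (!is.null(test_features)) {
    stopifnot(nrow(test_features) == n)
    xt <- feature_matrix(test_features)
    if (ncol(xt) != ncol(x)) stop("train and test feature columns differ")
  }
  scores <- numeric(n)
  for (i in seq_len(n)) {
    sc <- scale_features(x[-i, , drop = FALSE], xt[i, , drop = FALSE])
    model <- fit_rbf_svm(sc$train, lab[-i], config$C, config$gamma)
    scores[i] <- decision_scores(model, sc$test)
  }
  ids <- if ("id" %in% names(features)) features$id else as.character(seq_len(n))
  structure(
    list(scores = tibble::tibble(id = ids, label = as.character(lab),
                                 score = scores,
                                 pred = ifelse(scores > 0, "malignant", "benign")),
         report = report_from_scores(scores, lab),
         config = config, mode = "loo", n = n),
    class = "pcbp_eval"
  )
}

#' @export
print.pcbp_eval <- function(x, ...) {
  cat("SVM evaluation (", x$mode, ", n = ", x$n, ")\n", sep = "")
  print(x$report)
  invisible(x)
}

#' Bootstrap out-of-bag evaluation
#'
#' `B` replicates: the training set resamples the database with replacement
#' to its original size; cases never drawn (on average about 36.8%) form
#' the out-of-bag test set. Replicates whose training or test set lacks a
#' class are redrawn (and counted). Each replicate refits the scaler and
#' SVM and yields the full metric set; the summary reports mean and
#' standard deviation per metric.
#'
#' @inheritParams loo_cv
#' @param B Number of bootstrap replicates (default 500).
#' @param seed Master seed for the resampling.
#' @return Object of class `pcbp_boot`: `replicates` (B-row tibble of
#'   metrics plus OOB size), `summary` (mean/sd per metric), `redraws`,
#'   `config`.
#' @export
bootstrap_eval <- function(features, config, B = 500L, seed = 1L) {
  stopifnot(is.data.frame(features), inherits(config, "svm_config"))
  if (B <= 0) stop("B must be positive")
  x <- feature_matrix(features)
  lab <- as_label_factor(features$label)
  n <- nrow(x)
  if (n < 10) stop("need at least 10 cases")

  metric_names <- c("auc", "acc", "sens", "spec", "ppv", "npv", "mcc")
  rows <- vector("list", B)
  redraws <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        tr <- sample.int(n, n, replace = TRUE)
        oob <- setdiff(seq_len(n), tr)
        if (length(oob) >= 2 &&
            length(unique(lab[tr])) == 2 &&
            length(unique(lab[oob])) == 2) break
        redraws <- redraws + 1L
      }
      sc <- scale_features(x[tr, , drop = FALSE], x[oob, , drop = FALSE])
      model <- fit_rbf_svm(sc$train, lab[tr], config$C, config$gamma)
      s <- decision_scores(model, sc$test)
      rep_b <- report_from_scores(s, lab[oob])
      rows[[b]] <- tibble::tibble(
        replicate = b, n_oob = length(oob),
        !!!setNames(lapply(metric_names, function(m) rep_b[[m]]), metric_names)
      )
    }
  })
  replicates <- dplyr::bind_rows(rows)
  summary <- tidyr::pivot_longer(replicates, dplyr::all_of(metric_names),
                                 names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = sd(.data$value, na.rm = TRUE), .groups = "drop") |>
    dplyr::arrange(match(.data$metric, metric_names))
  structure(list(replicates = replicates, summary = summary,
                 redraws = redraws, config = config, B = as.integer(B),
                 seed = as.integer(seed)),
            class = "pcbp_boot")
}

#' @export
print.pcbp_boot <- function(x, ...) {
  cat("bootstrap evaluation: B = ", x$B, " replicates (", x$redraws,
      " redrawn)\n", sep = "")
  print(x$summary)
  invisible(x)
}
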