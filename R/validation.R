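label_levels <- function(merge_minor) {
  if (merge_minor) c("neglect", "non_neglect") else c("neglect", "non_neglect", "minor_atypicality")
}

#' Cross-tabulate a binary reference test against the three-class labels
#'
#' Rows are predictor classes, columns truth classes, both in the order
#' neglect, non-neglect, minor atypicality. The binary predictor never emits
#' `minor_atypicality`, so its row exists with zero counts in the full model.
#' With `merge_minor = TRUE` the minor class is pooled into non-neglect in
#' both dimensions, giving the 2x2 reduced model.
#'
#' @param predictor Binary labels (`"neglect"`/`"non_neglect"`, or logical or
#'   0/1 meaning neglect).
#' @param truth Three-class labels (`"neglect"`, `"non_neglect"`,
#'   `"minor_atypicality"`).
#' @param merge_minor Pool minor atypicality into non-neglect?
#' @return An integer matrix with predictor rows and truth columns.
#' @export
crosstab <- function(predictor, truth, merge_minor = FALSE) {
  if (length(predictor) != length(truth) || length(truth) == 0) {
    stop("crosstab(): predictor and truth must be nonempty and equal length.", call. = FALSE)
  }
  if (is.logical(predictor) || all(predictor %in% c(0, 1))) {
    predictor <- ifelse(as.logical(predictor), "neglect", "non_neglect")
  }
  if (!all(predictor %in% c("neglect", "non_neglect"))) {
    stop("crosstab(): unknown predictor labels.", call. = FALSE)
  }
  if (!all(truth %in% label_levels(FALSE))) {
    stop("crosstab(): unknown truth labels.", call. = FALSE)
  }
  if (merge_minor) {
    truth <- ifelse(truth == "minor_atypicality", "non_neglect", truth)
  }
  lv <- label_levels(merge_minor)
  m <- table(
    factor(predictor, levels = lv),
    factor(truth, levels = lv)
  )
  m <- matrix(as.integer(m), nrow = length(lv), dimnames = dimnames(m))
  names(dimnames(m)) <- c("predictor", "truth")
  m
}

ovr_cells <- function(matrix, positive_class) {
  i <- match(positive_class, rownames(matrix))
  j <- match(positive_class, colnames(matrix))
  if (is.na(i) || is.na(j)) {
    stop("class_metrics(): class '", positive_class, "' not in matrix.", call. = FALSE)
  }
  tp <- matrix[i, j]
  fp <- sum(matrix[i, -j])
  fn <- sum(matrix[-i, j])
  tn <- sum(matrix[-i, -j])
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' One-vs-rest diagnostic metrics for a confusion matrix class
#'
#' Sensitivity, specificity, balanced accuracy, positive and negative
#' predictive values (computed through the prevalence formulas), F1 (beta =
#' 1), prevalence, detection rate and detection prevalence, all as
#' proportions. Zero-denominator metrics are reported as `NA` (undefined),
#' never silently as 0.
#'
#' @param matrix Confusion matrix from [crosstab()].
#' @param positive_class Class treated as positive.
#' @return A one-row tibble of the nine statistics plus the TP/FP/FN/TN cells.
#' @export
class_metrics <- function(matrix, positive_class) {
  cells <- ovr_cells(matrix, positive_class)
  tp <- cells["tp"]
  fp <- cells["fp"]
  fn <- cells["fn"]
  tn <- cells["tn"]
  n <- sum(cells)
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, fp + tn)
  prev <- safe_div(tp + fn, n)
  ppv <- if (is.na(sens) || is.na(spec)) {
    NA_real_
  } else {
    safe_div(sens * prev, sens * prev + (1 - spec) * (1 - prev))
  }
  npv <- if (is.na(sens) || is.na(spec)) {
    NA_real_
  } else {
    safe_div(spec * (1 - prev), (1 - sens) * prev + spec * (1 - prev))
  }
  precision <- safe_div(tp, tp + fp)
  f1 <- if (is.na(precision) || is.na(sens) || (precision + sens) == 0) {
    NA_real_
  } else {
    2 * precision * sens / (precision + sens)
  }
  tibble::tibble(
    class = positive_class,
    tp = unname(tp), fp = unname(fp), fn = unname(fn), tn = unname(tn),
    sensitivity = unname(sens),
    specificity = unname(spec),
    balanced_accuracy = unname((sens + spec) / 2),
    ppv = unname(ppv),
    npv = unname(npv),
    f1 = unname(f1),
    prevalence = unname(prev),
    detection_rate = unname(safe_div(tp, n)),
    detection_prevalence = unname(safe_div(tp + fp, n))
  )
}

#' Overall accuracy with an exact binomial confidence interval
#'
#' Accuracy is the proportion of predictor-truth agreements (diagonal / n);
#' the 95% interval is the exact Clopper-Pearson interval.
#'
#' @param matrix Confusion matrix from [crosstab()].
#' @return One-row tibble: `correct`, `n`, `accuracy`, `ci_low`, `ci_high`
#'   (proportions).
#' @export
overall_accuracy <- function(matrix) {
  n <- sum(matrix)
  if (n < 1) stop("overall_accuracy(): empty matrix.", call. = FALSE)
  correct <- sum(diag(matrix))
  ci <- stats::binom.test(correct, n)$conf.int
  tibble::tibble(
    correct = correct, n = n, accuracy = correct / n,
    ci_low = ci[1], ci_high = ci[2]
  )
}

#' No-information (null) accuracy
#'
#' The accuracy achieved by always guessing the most prevalent truth class.
#'
#' @param truth Truth labels, or a confusion matrix (columns = truth).
#' @return Proportion in (0, 1].
#' @export
null_accuracy <- function(truth) {
  if (is.matrix(truth)) {
    counts <- colSums(truth)
  } else {
    if (!length(truth)) stop("null_accuracy(): empty labels.", call. = FALSE)
    counts <- table(truth)
  }
  max(counts) / sum(counts)
}

#' Exact one-sided test of accuracy against the null accuracy
#'
#' The standard no-information-rate test: the exact binomial upper tail
#' probability `P(X >= correct)` for `X ~ Binomial(n, null_p)`.
#'
#' @param correct Number of correct predictions.
#' @param n Total predictions.
#' @param null_p Null accuracy (proportion in (0, 1)).
#' @return One-sided p-value.
#' @export
accuracy_vs_null_test <- function(correct, n, null_p) {
  stopifnot(correct >= 0, correct <= n, null_p > 0, null_p < 1)
  stats::binom.test(correct, n, p = null_p, alternative = "greater")$p.value
}

#' Cohen's kappa of a confusion matrix
#'
#' `kappa = (Po - Pc) / (1 - Pc)` with `Po` the observed agreement proportion
#' and `Pc` the chance agreement from the row and column marginals.
#'
#' @param matrix Confusion matrix from [crosstab()] (rows and columns over the
#'   same classes).
#' @return Kappa in \[-1, 1\], or `NA` when chance agreement is 1.
#' @export
cohen_kappa <- function(matrix) {
  n <- sum(matrix)
  po <- sum(diag(matrix)) / n
  pc <- sum(rowSums(matrix) * colSums(matrix)) / n^2
  if (pc == 1) {
    return(NA_real_)
  }
  (po - pc) / (1 - pc)
}

#' Full diagnostic-validation analysis of a binary reference test
#'
#' Builds both confusion models (full: three truth classes; reduced: minor
#' atypicality pooled into non-neglect), with overall accuracy and its exact
#' 95% CI, null accuracy, the exact one-sided null-accuracy test, Cohen's
#' kappa, and one-vs-rest metrics for every class.
#'
#' @inheritParams crosstab
#' @return An object of class `neglect_confusion` (list with `model1`,
#'   `model2`, each holding `matrix`, `accuracy`, `null_accuracy`, `p_vs_null`
#'   and `kappa`, plus `class_metrics`).
#' @export
confusion_analysis <- function(predictor, truth) {
  one_model <- function(merge_minor) {
    m <- crosstab(predictor, truth, merge_minor = merge_minor)
    acc <- overall_accuracy(m)
    null_p <- null_accuracy(m)
    list(
      matrix = m,
      accuracy = acc,
      null_accuracy = null_p,
      p_vs_null = accuracy_vs_null_test(acc$correct, acc$n, null_p),
      kappa = cohen_kappa(m)
    )
  }
  m1 <- one_model(FALSE)
  metrics <- dplyr::bind_rows(
    lapply(rownames(m1$matrix), function(cl) class_metrics(m1$matrix, cl))
  )
  structure(
    list(model1 = m1, model2 = one_model(TRUE), class_metrics = metrics),
    class = "neglect_confusion"
  )
}

#' @export
print.neglect_confusion <- function(x, ...) {
  cat("<neglect_confusion>\n\nModel 1 (three truth classes):\n")
  print(x$model1$matrix)
  cat(sprintf(
    "accuracy %.1f%% (95%% CI %.1f-%.1f), null %.1f%%, P(null) = %.2f, kappa = %.2f\n",
    100 * x$model1$accuracy$accuracy, 100 * x$model1$accuracy$ci_low,
    100 * x$model1$accuracy$ci_high, 100 * x$model1$null_accuracy,
    x$model1$p_vs_null, x$model1$kappa
  ))
  cat(sprintf(
    "\nModel 2 (minor pooled): accuracy %.1f%% (95%% CI %.1f-%.1f), null %.1f%%, P(null) = %.2f, kappa = %.2f\n",
    100 * x$model2$accuracy$accuracy, 100 * x$model2$accuracy$ci_low,
    100 * x$model2$accuracy$ci_high, 100 * x$model2$null_accuracy,
    x$model2$p_vs_null, x$model2$kappa
  ))
  invisible(x)
}

#' Per-class metrics of a confusion analysis as a tibble
#'
#' @param x A `neglect_confusion`.
#' @param ... Unused.
#' @method tidy neglect_confusion
#' @export
tidy.neglect_confusion <- function(x, ...) {
  x$class_metrics
}

#' One-row summary of a confusion analysis
#'
#' @param x A `neglect_confusion`.
#' @param ... Unused.
#' @method glance neglect_confusion
#' @export
glance.neglect_confusion <- function(x, ...) {
  tibble::tibble(
    model1_accuracy = x$model1$accuracy$accuracy,
    model1_ci_low = x$model1$accuracy$ci_low,
    model1_ci_high = x$model1$accuracy$ci_high,
    model1_null_accuracy = x$model1$null_accuracy,
    model1_p_vs_null = x$model1$p_vs_null,
    model1_kappa = x$model1$kappa,
    model2_accuracy = x$model2$accuracy$accuracy,
    model2_ci_low = x$model2$accuracy$ci_low,
    model2_ci_high = x$model2$accuracy$ci_high,
    model2_null_accuracy = x$model2$null_accuracy,
    model2_p_vs_null = x$model2$p_vs_null,
    model2_kappa = x$model2$kappa,
    n = x$model1$accuracy$n
  )
}

#' Univariable Poisson risk model for atypicality counts
#'
#' Fits `atypicality ~ predictor` with a log-link Poisson GLM by maximum
#' likelihood and reports incidence rate ratios (exponentiated coefficients)
#' with Wald 95% confidence intervals. For categorical predictors the
#' reference level is the least frequent category (optionally the two least
#' frequent combined); continuous predictors are used as-is.
#'
#' @param data Data frame containing the outcome and predictor columns.
#' @param outcome Name of the count outcome column (atypicality, 0-8).
#' @param predictor Name of the predictor column.
#' @param combine_two_least For factors, pool the two least frequent levels
#'   into a combined reference category.
#' @return A `neglect_risk` tibble: `predictor`, `level`, `reference`, `irr`,
#'   `ci_low`, `ci_high`, `p_value`, `n`.
#' @export
poisson_risk <- function(data, outcome = "atypicality", predictor,
                         combine_two_least = FALSE) {
  d <- data[!is.na(data[[predictor]]) & !is.na(data[[outcome]]), , drop = FALSE]
  y <- d[[outcome]]
  x <- d[[predictor]]
  if (any(y < 0)) stop("poisson_risk(): counts must be >= 0.", call. = FALSE)
  if (length(unique(x)) < 2) {
    stop("poisson_risk(): predictor '", predictor, "' has < 2 distinct values.",
      call. = FALSE
    )
  }
  ref <- NA_character_
  if (!is.numeric(x)) {
    x <- as.character(x)
    counts <- sort(table(x))
    if (combine_two_least && length(counts) > 2) {
      low2 <- names(counts)[1:2]
      ref <- paste(sort(low2), collapse = "+")
      x[x %in% low2] <- ref
    } else {
      ref <- names(counts)[1]
    }
    x <- stats::relevel(factor(x), ref = ref)
  }
  fit <- stats::glm(y ~ x, family = stats::poisson())
  if (!fit$converged) {
    stop("poisson_risk(): Poisson fit did not converge for '", predictor, "'.",
      call. = FALSE
    )
  }
  co <- summary(fit)$coefficients
  keep <- rownames(co) != "(Intercept)"
  est <- co[keep, "Estimate"]
  se <- co[keep, "Std. Error"]
  if (any(!is.finite(se)) || any(se > 50)) {
    stop("poisson_risk(): separation or unstable fit for '", predictor, "'.",
      call. = FALSE
    )
  }
  lev <- sub("^x", "", rownames(co)[keep])
  out <- tibble::tibble(
    predictor = predictor,
    level = ifelse(lev == "", predictor, lev),
    reference = ref,
    irr = exp(est),
    ci_low = exp(est - stats::qnorm(0.975) * se),
    ci_high = exp(est + stats::qnorm(0.975) * se),
    p_value = co[keep, "Pr(>|z|)"],
    n = nrow(d)
  )
  structure(out, class = c("neglect_risk", class(out)))
}

#' Univariable risk models over a set of covariates
#'
#' Runs [poisson_risk()] for each named covariate against patient atypicality
#' and stacks the results into one risk-factor table.
#'
#' @param classification A `neglect_classification` (patients are selected
#'   from it).
#' @param covariates Per-player covariates data frame (must share
#'   `player_id`).
#' @param predictors Covariate columns to model; defaults to every covariate
#'   column except identifiers.
#' @return A `neglect_risk` tibble with one row per non-reference level.
#' @export
risk_factor_table <- function(classification, covariates,
                              predictors = NULL) {
  pat <- tibble::as_tibble(as.data.frame(classification)) %>%
    dplyr::filter(.data$group == "patient") %>%
    dplyr::select("player_id", "atypicality") %>%
    dplyr::inner_join(tibble::as_tibble(covariates), by = "player_id")
  if (is.null(predictors)) {
    predictors <- setdiff(names(pat), c("player_id", "atypicality", "preset"))
  }
  res <- purrr::map(predictors, function(p) {
    tryCatch(poisson_risk(pat, "atypicality", p),
      error = function(e) NULL
    )
  })
  out <- dplyr::bind_rows(res)
  structure(out, class = c("neglect_risk", class(out)))
}

#' Risk-model results as a plain tibble
#'
#' @param x A `neglect_risk` table.
#' @param ... Unused.
#' @method tidy neglect_risk
#' @export
tidy.neglect_risk <- function(x, ...) tibble::as_tibble(as.data.frame(x))
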