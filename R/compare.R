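#' Cross-validated comparison of selector/classifier pairs
#'
#' The evaluation harness: for every requested (selector, classifier) pair
#' it runs stratified cross-validation, refitting the descriptor selector on
#' each training fold only (no selection leakage into the test fold),
#' training the classifier on the reduced fold, evaluating the full metric
#' panel on the held-out fold, and averaging the panel across folds.
#' Reproducible for a fixed seed.
#'
#' @param data A normalized descriptor tibble.
#' @param selectors Character vector of selector registry names
#'   (`"none"` = no reduction).
#' @param classifiers Character vector of classifier registry names.
#' @param cv_folds Number of stratified folds.
#' @param k Descriptors kept by each reducing selector.
#' @param seed Integer RNG seed.
#' @param selector_args,classifier_args Named lists (by component name) of
#'   extra arguments.
#' @param positive,pairing Passed to [evaluate_classifier()].
#' @return A `qw_comparison` tibble: one row per (selector, classifier) pair
#'   with the averaged metric panel; attributes `cv_folds` and `seed`.
#' @export
compare_algorithms <- function(data,
                               selectors = c("none", "gwo"),
                               classifiers = c("nb", "lr", "dt", "rf", "svm"),
                               cv_folds = 3, k = 200, seed = 1,
                               selector_args = list(),
                               classifier_args = list(),
                               positive = "long",
                               pairing = c("binary", "macro")) {
  pairing <- match.arg(pairing)
  data <- as_descriptor_table(data)
  if (length(selectors) < 1 || length(classifiers) < 1) {
    abort("At least one selector and one classifier are required.")
  }
  for (s in selectors) registry_check("selector", s)
  for (cl in classifiers) registry_check("classifier", cl)

  fold_assign <- qw_folds(data$label, cv_folds, seed)
  rows <- list()
  for (f in seq_len(cv_folds)) {
    train <- data[fold_assign != f, , drop = FALSE]
    test <- data[fold_assign == f, , drop = FALSE]
    for (s in selectors) {
      idx <- fit_selector(s, train, k = k, seed = qw_subseed(seed, f),
                          args = selector_args[[s]] %||% list())
      train_red <- apply_selection(train, idx)
      test_red <- apply_selection(test, idx)
      for (cl in classifiers) {
        fit <- train_classifier(cl, train_red,
                                seed = qw_subseed(seed, 100L * f + match(cl, classifiers)),
                                args = classifier_args[[cl]] %||% list())
        panel <- evaluate_classifier(fit, test_red, positive = positive,
                                     pairing = pairing)
        rows[[length(rows) + 1]] <- dplyr::bind_cols(
          tibble(selector = s, classifier = cl, fold = f), panel
        )
      }
    }
  }
  per_fold <- dplyr::bind_rows(rows)
  out <- per_fold |>
    dplyr::group_by(.data$selector, .data$classifier) |>
    dplyr::summarise(dplyr::across(
      c("accuracy", "classification_error", "auc", "precision",
        "sensitivity", "specificity"),
      ~ mean(.x, na.rm = TRUE)
    ), .groups = "drop") |>
    dplyr::arrange(match(.data$selector, selectors),
                   match(.data$classifier, classifiers))
  attr(out, "cv_folds") <- cv_folds
  attr(out, "seed") <- seed
  attr(out, "per_fold") <- per_fold
  class(out) <- c("qw_comparison", class(out))
  out
}

#' Format a comparison table in the conventional panel layout
#'
#' One column per (selector, classifier) pair, metric rows in the standard
#' order (accuracy, classification error, AUC, precision, sensitivity,
#' specificity).
#'
#' @param comparison A `qw_comparison` tibble.
#' @return A tibble with a `performance` column and one column per pair.
#' @export
format_comparison <- function(comparison) {
  metrics <- c("accuracy", "classification_error", "auc", "precision",
               "sensitivity", "specificity")
  long <- comparison |>
    tidyr::pivot_longer(dplyr::all_of(metrics),
                        names_to = "performance", values_to = "value") |>
    dplyr::mutate(pair = paste(.data$selector, .data$classifier, sep = "-")) |>
    dplyr::select("performance", "pair", "value")
  tidyr::pivot_wider(long, names_from = "pair", values_from = "value") |>
    dplyr::arrange(match(.data$performance, metrics))
}

#' @describeIn compare_algorithms `autoplot()` draws grouped accuracy bars
#'   per classifier, split by selector.
#' @param object A `qw_comparison` tibble.
#' @param ... Unused.
#' @export
autoplot.qw_comparison <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$classifier, .data$accuracy,
                                       fill = .data$selector)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Classifier", y = "Accuracy (%)",
                  title = "Cross-validated accuracy by selector") +
    ggplot2::ylim(0, 100)
}
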