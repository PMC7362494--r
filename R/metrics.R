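#' Bayes posterior probability
#'
#' The posterior of class `c` given feature value `x`:
#' `P(c|x) = P(x|c) P(c) / P(x)` — the rule behind the naive Bayes baseline.
#'
#' @param p_x_given_c Likelihood `P(x|c)` in \[0, 1\].
#' @param p_c Prior `P(c)` in \[0, 1\].
#' @param p_x Evidence `P(x)`, strictly positive, with
#'   `p_x_given_c * p_c <= p_x`.
#' @return The posterior `P(c|x)` in \[0, 1\].
#' @export
bayes_posterior <- function(p_x_given_c, p_c, p_x) {
  vals <- c(p_x_given_c = p_x_given_c, p_c = p_c, p_x = p_x)
  if (any(vals < 0 | vals > 1)) abort("All probabilities must lie in [0, 1].")
  if (p_x == 0) abort("`p_x` must be strictly positive.")
  if (p_x_given_c * p_c > p_x + 1e-12) {
    abort("`p_x_given_c * p_c` must not exceed `p_x`.")
  }
  p_x_given_c * p_c / p_x
}

#' Confusion-matrix metric panel
#'
#' Binary classification metrics in percent: accuracy, classification error
#' (their sum is exactly 100), precision, sensitivity and specificity.
#' Ratios with a zero denominator are reported as 0, flagged in the
#' `degenerate` column, and raise a warning.
#'
#' @param y_true,y_pred Equal-length label vectors; `y_true` must contain
#'   both a positive and a negative case.
#' @param positive The positive class label.
#' @return A one-row tibble (`accuracy`, `classification_error`, `precision`,
#'   `sensitivity`, `specificity`, `degenerate`).
#' @export
confusion_metrics <- function(y_true, y_pred, positive) {
  if (length(y_true) != length(y_pred)) {
    abort("`y_true` and `y_pred` must have the same length.")
  }
  truth_pos <- as.character(y_true) == positive
  pred_pos <- as.character(y_pred) == positive
  if (all(truth_pos) || !any(truth_pos)) {
    abort("`y_true` must contain both positive and negative cases.")
  }
  tp <- sum(truth_pos & pred_pos)
  fp <- sum(!truth_pos & pred_pos)
  fn <- sum(truth_pos & !pred_pos)
  tn <- sum(!truth_pos & !pred_pos)
  safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe_ratio(tp, tp + fp)
  sensitivity <- safe_ratio(tp, tp + fn)
  specificity <- safe_ratio(tn, tn + fp)
  degenerate <- anyNA(c(precision, sensitivity, specificity))
  if (degenerate) {
    warn("Undefined ratio (zero denominator) reported as 0.")
  }
  accuracy <- 100 * (tp + tn) / length(y_true)
  tibble(
    accuracy = accuracy,
    classification_error = 100 - accuracy,
    precision = 100 * (precision %|NA|% 0),
    sensitivity = 100 * (sensitivity %|NA|% 0),
    specificity = 100 * (specificity %|NA|% 0),
    degenerate = degenerate
  )
}

`%|NA|%` <- function(x, y) if (is.na(x)) y else x

#' ROC curve and area under it
#'
#' Thresholds the scores from high to low, accumulating the true- and
#' false-positive rates, and integrates by the trapezoid rule.  Tied scores
#' are grouped into a single threshold step, which makes the trapezoid area
#' equal the rank (Mann-Whitney) statistic: concordant pairs count 1, ties
#' 1/2.
#'
#' @param y_true Label vector containing both classes.
#' @param scores Numeric scores, higher = more positive.
#' @param positive The positive class label.
#' @return An object of class `qw_roc`: list with `auc` and `points`
#'   (tibble of `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(y_true, scores, positive) {
  stopifnot(length(y_true) == length(scores))
  pos <- as.character(y_true) == positive
  P <- sum(pos)
  N <- sum(!pos)
  if (P == 0 || N == 0) {
    abort("`y_true` must contain both positive and negative cases.")
  }
  ord <- order(-scores)
  s <- scores[ord]
  p <- pos[ord]
  # group tied scores into single steps
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p)
  fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / P)
  fpr <- c(0, fp[last] / N)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(
    list(
      auc = auc,
      points = tibble(
        threshold = c(Inf, s[last]),
        fpr = fpr, tpr = tpr
      )
    ),
    class = "qw_roc"
  )
}

#' @export
print.qw_roc <- function(x, ...) {
  cat(sprintf("<qw_roc> AUC = %.4f (%d thresholds)\n", x$auc, nrow(x$points)))
  invisible(x)
}

#' @describeIn roc_auc `tidy()` returns the curve points.
#' @param x A `qw_roc` object.
#' @param ... Unused.
#' @export
tidy.qw_roc <- function(x, ...) x$points

#' @describeIn roc_auc `glance()` returns a one-row summary with the AUC.
#' @export
glance.qw_roc <- function(x, ...) tibble(auc = x$auc)

#' @describeIn roc_auc `autoplot()` draws the ROC curve.
#' @param object A `qw_roc` object.
#' @export
autoplot.qw_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)
    )
}

#' Lift table
#'
#' Sorts by descending score, splits into `n_bins` near-equal bins (earlier
#' bins take the remainder), and reports per-bin lift — the positive rate in
#' the bin over the overall positive rate — and the cumulative coverage of
#' positives in percent.
#'
#' @param y_true Label vector with at least one positive.
#' @param scores Numeric scores, higher = more positive.
#' @param positive The positive class label.
#' @param n_bins Number of bins, `1 <= n_bins <= length(y_true)`.
#' @return An object of class `qw_lift`: a tibble (`bin`, `n`, `positives`,
#'   `lift`, `cum_coverage`).
#' @export
lift_table <- function(y_true, scores, positive, n_bins = 10) {
  stopifnot(length(y_true) == length(scores))
  n <- length(y_true)
  if (n_bins < 1 || n_bins > n) abort("`n_bins` must satisfy 1 <= n_bins <= n.")
  pos <- as.character(y_true) == positive
  total_pos <- sum(pos)
  if (total_pos == 0) abort("`y_true` contains no positive cases.")
  ord <- order(-scores)
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin_id <- rep(seq_len(n_bins), times = sizes)
  pos_per_bin <- as.integer(rowsum(as.numeric(pos[ord]), bin_id)[, 1])
  base_rate <- total_pos / n
  out <- tibble(bin = seq_len(n_bins)) |>
    dplyr::mutate(
      n = sizes,
      positives = pos_per_bin,
      lift = (.data$positives / .data$n) / base_rate,
      cum_coverage = 100 * cumsum(.data$positives) / total_pos
    )
  class(out) <- c("qw_lift", class(out))
  out
}

#' @describeIn lift_table `autoplot()` draws bin lift bars with the
#'   cumulative-coverage curve.
#' @param object A `qw_lift` tibble.
#' @param ... Unused.
#' @export
autoplot.qw_lift <- function(object, ...) {
  scale <- max(object$lift)
  ggplot2::ggplot(object, ggplot2::aes(.data$bin, .data$lift)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cum_coverage / 100 * scale),
                       colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_continuous(
      sec.axis = ggplot2::sec_axis(~ . / scale * 100,
                                   name = "Cumulative coverage (%)")
    ) +
    ggplot2::labs(x = "Score bin (best first)", y = "Lift",
                  title = "Lift chart")
}

#' Evaluate a fitted classifier on a test table
#'
#' Produces the standard metric panel: accuracy and classification error are
#' computed on the full (possibly 3-class) test set; precision, sensitivity,
#' specificity and AUC come from a binary reduction — by default the
#' `short` vs `long` pairing with `long` positive (rows of other classes are
#' dropped for these), or macro one-vs-rest averaging with
#' `pairing = "macro"`.  AUC uses the model's scores when available, falling
#' back to vote fractions.
#'
#' @param fit A fitted model with a `predict(fit, newdata)` method returning
#'   labels and (optionally) `predict(fit, newdata, type = "score")`
#'   returning a per-class score matrix.
#' @param test A descriptor tibble.
#' @param positive Positive class for the binary pairing (default `"long"`).
#' @param pairing `"binary"` (short vs long) or `"macro"` (one-vs-rest).
#' @return A one-row `MetricsReport` tibble: `accuracy`,
#'   `classification_error`, `auc`, `precision`, `sensitivity`,
#'   `specificity`, `degenerate`.
#' @export
evaluate_classifier <- function(fit, test, positive = "long",
                                pairing = c("binary", "macro")) {
  pairing <- match.arg(pairing)
  test <- as_descriptor_table(test)
  truth <- as.character(test$label)
  pred <- as.character(predict(fit, test))
  accuracy <- 100 * mean(pred == truth)

  scores <- tryCatch(predict(fit, test, type = "score"), error = function(e) NULL)
  present <- intersect(QW_CLASSES, unique(truth))

  one_vs <- function(pos_label, keep) {
    cm <- confusion_metrics(truth[keep], pred[keep], pos_label)
    auc <- NA_real_
    if (!is.null(scores) && pos_label %in% colnames(scores)) {
      sc <- scores[keep, pos_label]
      if (length(unique(truth[keep] == pos_label)) == 2) {
        auc <- roc_auc(truth[keep], sc, pos_label)$auc
      }
    }
    dplyr::mutate(cm, auc = auc)
  }

  panel <- if (pairing == "binary") {
    pair <- intersect(c("short", "long"), present)
    if (length(pair) < 2) {
      # fall back to the two classes actually present
      pair <- head(present, 2)
    }
    keep <- truth %in% pair
    pos_label <- if (positive %in% pair) positive else pair[length(pair)]
    one_vs(pos_label, keep)
  } else {
    rows <- purrr::map_dfr(present, function(cl) one_vs(cl, rep(TRUE, length(truth))))
    dplyr::summarise(rows, dplyr::across(
      c("precision", "sensitivity", "specificity", "auc"),
      ~ mean(.x, na.rm = TRUE)
    ), degenerate = any(.data$degenerate))
  }

  tibble(
    accuracy = accuracy,
    classification_error = 100 - accuracy,
    auc = panel$auc,
    precision = panel$precision,
    sensitivity = panel$sensitivity,
    specificity = panel$specificity,
    degenerate = panel$degenerate
  )
}
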