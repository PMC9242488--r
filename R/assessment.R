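#' Confusion counts of model-predicted responses
#'
#' Classifies every non-missing cell by comparing the predicted response
#' probability (see [predict.lsirm()]) against a threshold: predicted
#' positive iff probability >= threshold.  Missing cells are excluded, so
#' TP + TN + FP + FN equals the number of observed cells.
#'
#' @param fit an [lsirm()] fit.
#' @param data a [response_matrix()]; defaults to the fitting data
#'   (in-sample assessment).
#' @param threshold classification threshold in (0, 1).
#' @param method probability rule passed to [predict.lsirm()] (`"plugin"`
#'   or `"average"`).
#' @return A list of class `"confusion_counts"` with integer `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
confusion <- function(fit, data = fit$data, threshold = 0.5,
                      method = "plugin") {
  stopifnot(inherits(fit, "lsirm"), threshold > 0, threshold < 1)
  if (!inherits(data, "response_matrix")) data <- response_matrix(data)
  y <- data$values
  if (!identical(dim(y), dim(fit$data$values)))
    stop("data shape does not match the fitted model", call. = FALSE)
  p <- predict(fit, method = method)
  pred <- p >= threshold
  obs <- !is.na(y)
  structure(list(TP = sum(pred & y == 1 & obs, na.rm = TRUE),
                 TN = sum(!pred & y == 0 & obs, na.rm = TRUE),
                 FP = sum(pred & y == 0 & obs, na.rm = TRUE),
                 FN = sum(!pred & y == 1 & obs, na.rm = TRUE)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts: TP %d, TN %d, FP %d, FN %d (total %d)\n",
              x$TP, x$TN, x$FP, x$FN, x$TP + x$TN + x$FP + x$FN))
  invisible(x)
}

#' Classification goodness-of-fit metrics
#'
#' The three standard binary-classification summaries of a fitted model's
#' in-sample predictions:
#' specificity = TN / (TN + FP), sensitivity = TP / (TP + FN),
#' overall accuracy = (TP + TN) / (TP + TN + FP + FN).
#' A zero denominator yields `NA` with a warning, never a silent zero.
#'
#' @param counts a [confusion()] result, or a list/vector with elements
#'   `TP`, `TN`, `FP`, `FN`.
#' @return Named numeric vector `c(specificity, sensitivity,
#'   overall_accuracy)`.
#' @export
gof_metrics <- function(counts) {
  cts <- as.list(counts)[c("TP", "TN", "FP", "FN")]
  if (any(vapply(cts, is.null, NA)))
    stop("counts must provide TP, TN, FP and FN", call. = FALSE)
  cts <- lapply(cts, as.numeric)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator")
      return(NA_real_)
    }
    num / den
  }
  c(specificity = ratio(cts$TN, cts$TN + cts$FP, "specificity"),
    sensitivity = ratio(cts$TP, cts$TP + cts$FN, "sensitivity"),
    overall_accuracy = ratio(cts$TP + cts$TN,
                             cts$TP + cts$TN + cts$FP + cts$FN,
                             "overall accuracy"))
}
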