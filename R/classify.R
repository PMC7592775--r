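# Three-category clinical classification of CVP and agreement statistics.

.CVP_LEVELS <- c("low", "normal", "high")

#' Classify CVP into low / normal / high
#'
#' The normal range is 2--8 mmHg, i.e. 2.72--10.88 cmH2O; boundary values are
#' classified as normal (the range is treated as closed). Vectorized.
#'
#' @param value mean CVP in cmH2O (finite).
#' @param bounds_cmh2o lower/upper bounds of the normal range in cmH2O.
#' @return factor with levels `low`, `normal`, `high`.
#' @examples
#' classify_cvp(c(1, 6, 12))
#' @export
classify_cvp <- function(value, bounds_cmh2o = c(2.72, 10.88)) {
  value <- as.numeric(value)
  if (any(!is.finite(value))) .stop_validation("non-finite CVP value")
  stopifnot(length(bounds_cmh2o) == 2L, bounds_cmh2o[1L] < bounds_cmh2o[2L])
  lab <- ifelse(value < bounds_cmh2o[1L], "low",
                ifelse(value > bounds_cmh2o[2L], "high", "normal"))
  factor(lab, levels = .CVP_LEVELS)
}

#' Classification agreement report
#'
#' 3x3 confusion matrix (true class x predicted class), per-class sensitivity
#' (diagonal over row total), overall accuracy (trace over total), and
#' unweighted Cohen's kappa `(p_o - p_e) / (1 - p_e)` with the chance
#' agreement `p_e` from marginal products.
#'
#' @param true_labels,predicted_labels equal-length vectors over
#'   `low`/`normal`/`high` (factors or character).
#' @param zero_division how to report sensitivity for a class with no true
#'   members: `"na"` (default) or `"zero"` (the convention that reports 0\%
#'   for an empty class).
#' @return an object of class `confusion_report`: `matrix`,
#'   `per_class_sensitivity`, `overall_accuracy`, `kappa`, `n`.
#' @export
confusion_report <- function(true_labels, predicted_labels,
                             zero_division = c("na", "zero")) {
  zero_division <- match.arg(zero_division)
  tl <- factor(as.character(true_labels), levels = .CVP_LEVELS)
  pl <- factor(as.character(predicted_labels), levels = .CVP_LEVELS)
  if (length(tl) == 0L) .stop_validation("empty label input")
  if (length(tl) != length(pl)) .stop_validation("label lengths differ")
  if (anyNA(tl) || anyNA(pl))
    .stop_validation("labels must be among: ", paste(.CVP_LEVELS, collapse = ", "))
  m <- table(true = tl, predicted = pl)
  n <- sum(m)
  acc <- sum(diag(m)) / n
  row_tot <- rowSums(m)
  sens <- ifelse(row_tot > 0, diag(m) / row_tot,
                 if (zero_division == "na") NA_real_ else 0)
  names(sens) <- .CVP_LEVELS
  p_o <- acc
  p_e <- sum(rowSums(m) * colSums(m)) / n^2
  kappa <- if (abs(1 - p_e) < .Machine$double.eps) 1 else (p_o - p_e) / (1 - p_e)
  structure(list(matrix = unclass(m), per_class_sensitivity = sens,
                 overall_accuracy = acc, kappa = kappa, n = n),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat("<confusion_report> true class (rows) x predicted class (cols)\n")
  print(x$matrix)
  sens <- ifelse(is.na(x$per_class_sensitivity), "n/a",
                 sprintf("%.1f%%", 100 * x$per_class_sensitivity))
  cat(sprintf("sensitivity: low %s, normal %s, high %s\n",
              sens["low"], sens["normal"], sens["high"]))
  cat(sprintf("accuracy: %.1f%%  kappa: %.3f  (n = %d)\n",
              100 * x$overall_accuracy, x$kappa, x$n))
  invisible(x)
}

#' Key-value form of a confusion report
#'
#' Machine-readable flat representation: matrix cells as
#' `count_<true>_<pred>`, per-class sensitivities, accuracy and kappa.
#'
#' @param report a `confusion_report`.
#' @return named numeric vector.
#' @export
confusion_keyvalue <- function(report) {
  stopifnot(inherits(report, "confusion_report"))
  m <- report$matrix
  cells <- as.vector(m)
  names(cells) <- as.vector(outer(rownames(m), colnames(m),
                                  function(a, b) paste0("count_", a, "_", b)))
  sens <- report$per_class_sensitivity
  names(sens) <- paste0("sensitivity_", names(sens))
  c(cells, sens, accuracy = report$overall_accuracy, kappa = report$kappa,
    n = as.numeric(report$n))
}
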