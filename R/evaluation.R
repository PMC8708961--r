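#' Confusion matrix for binary metastasis detection
#'
#' Bundles the four outcome counts of a binary classifier: true positives
#' (metastasis present, called present), false positives, false negatives and
#' true negatives.
#'
#' @param tp,fp,fn,tn Nonnegative integer counts.
#' @return An object of class `confusion_matrix`.
#' @examples
#' confusion_matrix(tp = 273, fp = 38, fn = 183, tn = 5121)
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("confusion-matrix counts must be nonnegative integers", call. = FALSE)
  }
  out <- as.list(as.integer(round(counts)))
  names(out) <- names(counts)
  structure(out, class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (n =", x$tp + x$fp + x$fn + x$tn, ")\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("pos", "neg"), call = c("pos", "neg")))
  print(m)
  invisible(x)
}

#' Threshold continuous scores into a confusion matrix
#'
#' A score at or above the threshold is called positive; ties at the threshold
#' count as positive calls.
#'
#' @param labels Binary vector (0/1), truth per sample.
#' @param scores Numeric vector of classifier scores, same length.
#' @param threshold Decision threshold (default 0.5).
#' @return A [confusion_matrix()].
#' @export
confusion_from_scores <- function(labels, scores, threshold = 0.5) {
  check_binary_labels(labels)
  if (length(labels) != length(scores)) {
    stop("labels and scores must have equal length", call. = FALSE)
  }
  if (length(labels) == 0L) stop("empty input", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  pred <- scores >= threshold
  confusion_matrix(
    tp = sum(labels == 1 & pred),
    fp = sum(labels == 0 & pred),
    fn = sum(labels == 1 & !pred),
    tn = sum(labels == 0 & !pred)
  )
}

#' Confusion-matrix performance metrics
#'
#' Computes accuracy, sensitivity (= recall), specificity, precision, negative
#' predictive value, F1 score and prevalence from a confusion matrix. Any
#' metric whose denominator is zero is reported as `NA` and listed in the
#' `undefined` attribute rather than raising an error: at ~8% prevalence,
#' small evaluation folds can legitimately lack one class.
#'
#' @param cm A [confusion_matrix()].
#' @return A `metrics_report`: named list of metrics in `[0, 1]` (full double
#'   precision; use [round_half_up()] for 3-decimal table display), with
#'   attribute `undefined` naming any metric with a zero denominator.
#' @examples
#' m <- compute_metrics(confusion_matrix(273, 38, 183, 5121))
#' round_half_up(m$accuracy, 3)  # 0.961
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  total <- tp + fp + fn + tn
  if (total == 0L) stop("all-zero confusion matrix: no samples to evaluate", call. = FALSE)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe_div(tp, tp + fn)
  prec <- safe_div(tp, tp + fp)
  f1 <- if (is.na(sens) || is.na(prec) || (sens + prec) == 0) NA_real_ else {
    2 * sens * prec / (sens + prec)
  }
  out <- list(
    accuracy    = (tp + tn) / total,
    sensitivity = sens,
    specificity = safe_div(tn, fp + tn),
    precision   = prec,
    recall      = sens,
    npv         = safe_div(tn, tn + fn),
    f1          = f1,
    prevalence  = (tp + fn) / total
  )
  structure(out,
            class = "metrics_report",
            confusion = cm,
            undefined = names(out)[vapply(out, is.na, logical(1))])
}

#' @export
print.metrics_report <- function(x, ...) {
  v <- unlist(x)
  cat("Classification metrics\n")
  print(round_half_up(v, 3))
  und <- attr(x, "undefined")
  if (length(und)) cat("undefined (zero denominator):", paste(und, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname compute_metrics
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @export
tidy.metrics_report <- function(x, ...) {
  tibble::tibble(
    metric = names(unclass(x)),
    value = unlist(x, use.names = FALSE),
    undefined = names(unclass(x)) %in% attr(x, "undefined")
  )
}

#' Round half away from zero
#'
#' Fixed-precision rounding in which exact halves move away from zero
#' (0.5965 -> 0.597 at 3 digits), the convention used for the printed
#' comparison tables. Base `round()` rounds half to even instead.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector (`NA` passes through).
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' ROC curve and area under it
#'
#' Computes the receiver operating characteristic curve over all score
#' thresholds and its area by the trapezoidal rule (via \pkg{pROC}), which
#' equals the concordance probability with tied scores counted one half.
#'
#' @param labels Binary truth vector containing both classes.
#' @param scores Numeric scores, higher meaning more likely positive.
#' @return An object of class `roc_result`: list with `auc` (scalar) and
#'   `curve` (tibble of `fpr`, `tpr` ordered along the curve).
#' @examples
#' roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))$auc  # 0.75
#' @export
roc_auc <- function(labels, scores) {
  check_binary_labels(labels)
  if (length(labels) != length(scores)) stop("length mismatch", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  }
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  curve <- tibble::tibble(fpr = 1 - r$specificities, tpr = r$sensitivities)
  curve <- curve[order(curve$fpr, curve$tpr), ]
  structure(list(auc = as.numeric(pROC::auc(r)), curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC curve with %d points, AUC = %.4f\n", nrow(x$curve), x$auc))
  invisible(x)
}

#' Side-by-side comparison table of classifier runs
#'
#' Formats one or more evaluated runs into the standard comparison layout:
#' metric rows (Accuracy, Sensitivity, Specificity, Prevalence, Precision,
#' NPV, F1 Score) rounded half-away-from-zero to 3 decimals, followed by the
#' raw TP/FP/FN/TN counts, one column per run.
#'
#' @param runs A data frame (or tibble) with columns `backbone`, `method` and
#'   either a list-column `cm` of [confusion_matrix()] objects or integer
#'   columns `tp`, `fp`, `fn`, `tn`.
#' @param csv,json Optional paths; when given, the table is also written out.
#' @return A tibble with a `metric` column and one column per run.
#' @export
comparison_table <- function(runs, csv = NULL, json = NULL) {
  runs <- as.data.frame(runs)
  if (nrow(runs) < 1L) stop("at least one run is required", call. = FALSE)
  cms <- if ("cm" %in% names(runs)) runs$cm else {
    lapply(seq_len(nrow(runs)), function(i) {
      confusion_matrix(runs$tp[i], runs$fp[i], runs$fn[i], runs$tn[i])
    })
  }
  metric_rows <- c(accuracy = "Accuracy", sensitivity = "Sensitivity",
                   specificity = "Specificity", prevalence = "Prevalence",
                   precision = "Precision", npv = "NPV", f1 = "F1 Score")
  cols <- lapply(seq_along(cms), function(i) {
    m <- compute_metrics(cms[[i]])
    c(round_half_up(unlist(m[names(metric_rows)]), 3),
      tp = cms[[i]]$tp, fp = cms[[i]]$fp, fn = cms[[i]]$fn, tn = cms[[i]]$tn)
  })
  out <- tibble::tibble(metric = c(unname(metric_rows), "TP", "FP", "FN", "TN"))
  for (i in seq_along(cols)) {
    out[[paste(runs$backbone[i], runs$method[i], sep = "_")]] <- unname(cols[[i]])
  }
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  if (!is.null(json)) jsonlite::write_json(out, json, dataframe = "columns", digits = NA)
  out
}

#' Published benchmark confusion matrices
#'
#' Test-set confusion matrices (n = 5615 whole-body bone scans, prevalence
#' 8.1%) for six classifier configurations — CNN, DenseNet121 and ResNet50V2
#' backbones, each trained plainly supervised and with a supervised
#' contrastive phase — from a published hospital-scale benchmark. Useful as a
#' fixed input for verifying the metric computations and the comparison-table
#' formatter.
#'
#' @return A tibble with columns `backbone`, `method`, `tp`, `fp`, `fn`, `tn`.
#' @export
reference_confusions <- function() {
  path <- system.file("extdata", "reference_confusions.csv", package = "scintimet",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

check_binary_labels <- function(labels) {
  if (!all(labels %in% c(0, 1))) {
    stop("labels must be binary (0 = no metastasis, 1 = metastasis)", call. = FALSE)
  }
  invisible(labels)
}
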