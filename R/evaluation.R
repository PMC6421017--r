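# Pixel-wise segmentation evaluation: confusion counts, the five standard
# overlap metrics, and the paired "reduced rate" report quantifying how
# much tumor and healthy area the thermal route recovers over the
# intensity-based baseline.

#' Pixel-wise confusion counts
#'
#' @param pred Predicted logical mask.
#' @param truth Ground-truth logical mask of the same shape.
#' @return Object of class `confusion_counts`: list with integers `tp`
#'   (tumor pixels segmented as tumor), `fp` (healthy segmented as tumor),
#'   `tn` (healthy as healthy), `fn` (tumor as healthy).
#' @export
#' @examples
#' confusion(matrix(c(TRUE, FALSE), 2, 2), matrix(TRUE, 2, 2))
confusion <- function(pred, truth) {
  stopifnot(is.matrix(pred) || is.logical(pred),
            is.matrix(truth) || is.logical(truth))
  if (!all(dim(pred) == dim(truth)))
    stop("input error: pred and truth have different shapes")
  pred <- pred != 0; truth <- truth != 0
  confusion_counts(tp = sum(pred & truth), fp = sum(pred & !truth),
                   tn = sum(!pred & !truth), fn = sum(!pred & truth))
}

#' @rdname confusion
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts: TP=%d FP=%d TN=%d FN=%d (total %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' The five segmentation evaluation metrics
#'
#' Computes
#' \deqn{\mathrm{Sensitivity} = TP/(TP+FN),\quad
#'       \mathrm{Specificity} = TN/(TN+FP),\quad
#'       \mathrm{Accuracy} = (TP+TN)/(TP+FP+TN+FN),}
#' \deqn{\mathrm{Dice} = 2TP/(2TP+FP+FN),\quad
#'       \mathrm{Jaccard} = TP/(TP+FP+FN).}
#' A metric with zero denominator is reported as `NA` (undefined), never
#' coerced to 0 or 1.
#'
#' @param x A `confusion_counts` object (or a list with `tp`, `fp`, `tn`,
#'   `fn`).
#' @return Object of class `metric_set`: named numeric vector with
#'   `sensitivity`, `specificity`, `accuracy`, `dice`, `jaccard`.
#' @export
#' @examples
#' compute_metrics(confusion_counts(556, 5, 14795, 37))
compute_metrics <- function(x) {
  tp <- x$tp; fp <- x$fp; tn <- x$tn; fn <- x$fn
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  structure(c(sensitivity = ratio(tp, tp + fn),
              specificity = ratio(tn, tn + fp),
              accuracy    = ratio(tp + tn, tp + fp + tn + fn),
              dice        = ratio(2 * tp, 2 * tp + fp + fn),
              jaccard     = ratio(tp, tp + fp + fn)),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  v <- unclass(x)
  cat(paste(sprintf("%s = %s", names(v),
                    ifelse(is.na(v), "undefined", sprintf("%.4f", v))),
            collapse = ", "), "\n")
  invisible(x)
}

#' Reduced false-positive and false-negative rates
#'
#' Quantifies, for one subject, the image area that the thermal route
#' classifies correctly while the intensity baseline does not: the drop in
#' false positives as a percentage of the healthy area, and the drop in
#' false negatives as a percentage of the tumor area.  Increases are
#' clamped at zero.
#'
#' @param baseline `confusion_counts` of the baseline (level-set)
#'   segmentation.
#' @param thermal `confusion_counts` of the thermal segmentation against
#'   the same ground truth.
#' @return Named numeric vector `c(reduced_fp_pct, reduced_fn_pct)`.
#' @export
#' @examples
#' reduced_rates(confusion_counts(592, 285, 14515, 1),
#'               confusion_counts(556, 5, 14795, 37))
reduced_rates <- function(baseline, thermal) {
  healthy_b <- baseline$tn + baseline$fp
  tumor_b <- baseline$tp + baseline$fn
  if (healthy_b != thermal$tn + thermal$fp ||
      tumor_b != thermal$tp + thermal$fn)
    stop("input error: baseline and thermal counts disagree on ground truth")
  c(reduced_fp_pct = max(0, baseline$fp - thermal$fp) / healthy_b * 100,
    reduced_fn_pct = max(0, baseline$fn - thermal$fn) / tumor_b * 100)
}

#' Cohort means of per-patient reduced-rate pairs
#'
#' @param rows A matrix or data frame of per-patient pairs (two columns),
#'   or a list of length-2 vectors.
#' @return Numeric vector of the two column means.
#' @export
cohort_summary <- function(rows) {
  if (is.list(rows) && !is.data.frame(rows)) rows <- do.call(rbind, rows)
  rows <- as.matrix(rows)
  if (nrow(rows) == 0) stop("input error: empty cohort")
  stopifnot(ncol(rows) == 2)
  colMeans(rows)
}

#' Published per-patient confusion counts and metrics
#'
#' The per-patient confusion counts (TP, FP, TN, FN) and the five printed
#' metrics from the validation study this package's method reproduces at
#' phantom scale: four simulated phantom patients segmented by
#' level set on T1c and Flair and by the thermal route (`table = "phantom"`),
#' the same four patients under three tumor perfusion rates
#' (`"perfusion"`), and six high-grade and six low-grade tumor patients
#' (`"hgg"`, `"lgg"`).  Useful as fixed inputs for metric-identity checks.
#'
#' @param table One of `"phantom"`, `"perfusion"`, `"hgg"`, `"lgg"`, or
#'   `"all"`.
#' @return Data frame with columns `table`, `patient`, `method`, `tp`,
#'   `fp`, `tn`, `fn`, `sensitivity`, `specificity`, `accuracy`, `dice`,
#'   `jaccard`.
#' @export
#' @examples
#' head(reference_segmentations("phantom"))
reference_segmentations <- function(table = c("all", "phantom", "perfusion",
                                              "hgg", "lgg")) {
  table <- match.arg(table)
  path <- system.file("extdata", "reference_segmentations.csv",
                      package = "thermoseg", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (table != "all") df <- df[df$table == table, ]
  df
}

#' Published per-patient reduced-rate report
#'
#' The printed per-patient percentages of tumor area (`tumor_pct`) and
#' healthy area (`healthy_pct`) differentiated by the thermal route only,
#' for the sixteen validation patients.  Their means are the study's
#' headline averages (about 0.8% of tumor area and about 2.48% of healthy
#' area).
#'
#' @return Data frame with columns `dataset`, `patient`, `tumor_pct`,
#'   `healthy_pct`.
#' @export
reference_reduced_rates <- function() {
  path <- system.file("extdata", "reference_reduced_rates.csv",
                      package = "thermoseg", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
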