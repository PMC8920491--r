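#' Pixelwise confusion matrix
#'
#' Counts pixels by (ground-truth class, predicted class) at the analysis
#' resolution. Only pixels carrying both a ground-truth label and a
#' prediction are evaluated: sentinel codes (background 0, unclassified
#' 254, rejected 255) and unannotated ground truth (0) are excluded.
#'
#' @param gt Integer ground-truth raster (0 = unannotated; classes 1..K).
#' @param pred A `class_map` or integer raster of predictions.
#' @param n_classes Number of classes K (default: inferred from legend or
#'   the maximum class code present).
#' @return K x K integer matrix (rows = ground truth, columns =
#'   prediction) of class `confusion_matrix`, with attributes `total`
#'   (evaluated pixels) and `excluded` (pixel counts by reason).
#' @export
confusion <- function(gt, pred, n_classes = NULL) {
  codes <- if (inherits(pred, "class_map")) pred$codes else pred
  stopifnot_aligned(gt, codes, "ground truth and prediction")
  if (is.null(n_classes)) {
    n_classes <- if (inherits(pred, "class_map") && !is.null(pred$legend))
      length(pred$legend)
    else max(gt, codes[codes < 200L], 1L)
  }
  sent <- sentinel_codes()
  valid <- gt >= 1L & gt <= n_classes &
           codes >= 1L & codes <= n_classes
  g <- gt[valid]; p <- codes[valid]
  cm <- matrix(0L, n_classes, n_classes)
  if (length(g)) {
    tab <- table(factor(g, levels = seq_len(n_classes)),
                 factor(p, levels = seq_len(n_classes)))
    cm <- matrix(as.integer(tab), n_classes, n_classes)
  }
  excluded <- c(total_pixels = length(gt),
                unannotated = sum(gt < 1L | gt > n_classes),
                rejected = sum(codes == sent[["REJECTED"]]),
                unclassified = sum(codes == sent[["UNCLASSIFIED"]]),
                background_pred = sum(codes == sent[["BACKGROUND"]]))
  structure(cm, total = sum(cm), excluded = excluded,
            class = c("confusion_matrix", "matrix", "array"))
}

#' Classification metrics from a confusion matrix
#'
#' Overall accuracy is trace/total. Per-class recall, precision and F1
#' treat each class one-vs-rest (all negative classes combined). Zero
#' denominators yield `NA` entries.
#'
#' @param cm A `confusion_matrix`.
#' @return A `metrics_report`: list with `accuracy`, `per_class`
#'   (data.frame: class, recall, precision, f1), `total`.
#' @export
metrics <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix: no jointly labelled pixels")
  tp <- diag(cm)
  rowc <- rowSums(cm); colc <- colSums(cm)
  recall <- ifelse(rowc > 0, tp / rowc, NA_real_)
  precision <- ifelse(colc > 0, tp / colc, NA_real_)
  f1 <- ifelse(!is.na(recall) & !is.na(precision) & (recall + precision) > 0,
               2 * recall * precision / (recall + precision), NA_real_)
  structure(list(accuracy = sum(tp) / total,
                 per_class = data.frame(class = seq_len(nrow(cm)),
                                        recall = recall,
                                        precision = precision, f1 = f1),
                 total = total),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("overall accuracy %.4f on %d pixels\n", x$accuracy, x$total))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Effect of rejection on pixel counts
#'
#' Compares predictions before and after rejection (the two maps must
#' differ only by pixels turned into the REJECTED sentinel) and reports
#' the rejected fraction, the change in correct- and false-pixel counts,
#' and accuracy before/after over the respectively evaluated pixels.
#'
#' @param gt Ground-truth raster.
#' @param pred_before,pred_after Class maps without / with rejection.
#' @return List: `rejected_fraction`, `true_before`, `true_after`,
#'   `false_before`, `false_after`, `delta_true`, `delta_false`,
#'   `accuracy_before`, `accuracy_after`.
#' @export
rejection_report <- function(gt, pred_before, pred_after) {
  cb <- if (inherits(pred_before, "class_map")) pred_before$codes else pred_before
  ca <- if (inherits(pred_after, "class_map")) pred_after$codes else pred_after
  stopifnot_aligned(cb, ca, "prediction maps")
  sent <- sentinel_codes()
  changed <- cb != ca
  if (any(ca[changed] != sent[["REJECTED"]]))
    stop("maps differ by more than rejection: predictions are not nested")
  K <- max(1L, max(gt))
  cmb <- confusion(gt, cb, n_classes = K)
  cma <- confusion(gt, ca, n_classes = K)
  tb <- sum(diag(cmb)); ta <- sum(diag(cma))
  fb <- sum(cmb) - tb;  fa <- sum(cma) - ta
  list(rejected_fraction = sum(ca == sent[["REJECTED"]]) / length(ca),
       true_before = tb, true_after = ta,
       false_before = fb, false_after = fa,
       delta_true = ta - tb, delta_false = fa - fb,
       accuracy_before = if (sum(cmb) > 0) tb / sum(cmb) else NA_real_,
       accuracy_after = if (sum(cma) > 0) ta / sum(cma) else NA_real_)
}
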