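#' Confusion matrix and accuracy of an unmixed label image
#'
#' Compares a predicted label image with the ground truth. The confusion
#' matrix counts all pixels (background row/column included);
#' `pixel_accuracy` is the trace fraction restricted to truth-foreground
#' pixels, since the method's claim concerns labeled compartments, with
#' background confusion reported separately in row/column 0. Object-level
#' metrics use each object's modal predicted label; modal ties count as
#' incorrect. A class is "recovered" when it has at least one object and
#' every one of its objects is majority-correct.
#'
#' @param predicted Integer label matrix (0 = background) or an
#'   `unmix_result`.
#' @param truth A [sample_layout()] ground truth, or a bare label matrix (in
#'   which case objects are reconstructed as connected components per
#'   class).
#' @return Object of class `"evaluation_report"`: list with `confusion`,
#'   `pixel_accuracy`, `object_majority_accuracy`, `recovered_class_count`,
#'   `per_class_recall`, `n_classes`, `notes`.
#' @export
confusion_and_accuracy <- function(predicted, truth) {
  if (inherits(predicted, "unmix_result")) predicted <- predicted$labels
  if (!is.matrix(predicted)) stop("predicted must be a label matrix")
  if (inherits(truth, "ground_truth")) {
    tl <- truth$labels
    objects <- truth$objects
  } else if (is.matrix(truth)) {
    tl <- truth
    objects <- NULL
  } else stop("truth must be a ground_truth or a label matrix")
  if (!identical(dim(predicted), dim(tl)))
    stop("geometry mismatch between predicted and truth label images")
  m <- max(tl, predicted, 1L)
  lv <- 0:m
  confusion <- table(truth = factor(tl, levels = lv),
                     predicted = factor(predicted, levels = lv))
  confusion <- unclass(confusion)
  fg <- tl > 0L
  fg_total <- sum(fg)
  pixel_accuracy <- if (fg_total > 0)
    sum(predicted[fg] == tl[fg]) / fg_total else NA_real_
  per_class_recall <- vapply(seq_len(m), function(j) {
    cnt <- sum(tl == j)
    if (cnt == 0) NA_real_ else sum(tl == j & predicted == j) / cnt
  }, 0)
  if (is.null(objects)) objects <- objects_from_labels(tl)
  obj_ok <- obj_class <- integer(0)
  if (nrow(objects)) {
    obj_ok <- vapply(seq_len(nrow(objects)), function(k) {
      px <- object_pixel_index(objects[k, ], tl)
      votes <- tabulate(predicted[px] + 1L, nbins = m + 1L)
      winners <- which(votes == max(votes)) - 1L
      length(winners) == 1L && winners == objects$class[k]
    }, TRUE)
    obj_class <- objects$class
  }
  object_majority_accuracy <- if (length(obj_ok)) mean(obj_ok) else NA_real_
  recovered <- vapply(seq_len(m), function(j) {
    idx <- obj_class == j
    any(idx) && all(obj_ok[idx])
  }, TRUE)
  structure(list(confusion = confusion,
                 pixel_accuracy = pixel_accuracy,
                 object_majority_accuracy = object_majority_accuracy,
                 recovered_class_count = sum(recovered),
                 per_class_recall = per_class_recall,
                 n_classes = m,
                 notes = sprintf("%d objects evaluated; %d truth-foreground pixels",
                                 length(obj_ok), fg_total)),
            class = "evaluation_report")
}

# pixel linear indices of one object: its disk when geometry columns are
# present, otherwise its stored pixel set
object_pixel_index <- function(obj, labels) {
  if ("pixels" %in% names(obj)) return(obj$pixels[[1L]])
  px <- disk_pixels(obj$cx, obj$cy, obj$radius, nrow(labels), ncol(labels))
  px <- px[labels[px] == obj$class, , drop = FALSE]
  (px[, 2L] - 1L) * nrow(labels) + px[, 1L]
}

# reconstruct per-class connected components when no object table exists
objects_from_labels <- function(tl) {
  ids <- integer(); cls <- integer(); pix <- list()
  for (cl in sort(unique(tl[tl > 0L]))) {
    cc <- EBImage::bwlabel(tl == cl)
    for (k in seq_len(max(cc))) {
      ids <- c(ids, length(ids) + 1L)
      cls <- c(cls, cl)
      pix[[length(pix) + 1L]] <- which(cc == k)
    }
  }
  df <- data.frame(id = ids, class = cls)
  df$pixels <- pix
  df
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat("  pixel accuracy (foreground):", round(x$pixel_accuracy, 4), "\n")
  cat("  object majority accuracy:   ", round(x$object_majority_accuracy, 4), "\n")
  cat("  recovered classes:          ", x$recovered_class_count, "of",
      x$n_classes, "\n")
  cat("  per-class recall:           ",
      paste(round(x$per_class_recall, 3), collapse = " "), "\n")
  cat(" ", x$notes, "\n")
  invisible(x)
}

#' Fingerprint recovery error
#'
#' Elementwise error between an estimated and a reference fingerprint:
#' the maximum absolute difference (L-infinity) and the total absolute
#' difference (L1).
#'
#' @param estimated,reference [fingerprint()] objects (or bare weight
#'   vectors) of equal length.
#' @return List with `linf` and `l1`.
#' @export
fingerprint_recovery_error <- function(estimated, reference) {
  e <- as_weight_vector(estimated)
  r <- as_weight_vector(reference)
  if (length(e) != length(r))
    stop("dimension mismatch: fingerprints have lengths ",
         length(e), " and ", length(r))
  d <- abs(e - r)
  list(linf = max(d), l1 = sum(d))
}
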