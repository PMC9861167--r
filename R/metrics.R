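#' Generalised IoU loss between two bounding boxes
#'
#' Reference implementation of the GIoU bounding-box regression loss:
#' `1 - (IoU - |C \ (A U B)| / |C|)`, where `C` is the smallest
#' axis-aligned rectangle enclosing both boxes. The loss is 0 for
#' identical boxes and lies in `[0, 2)` for all valid box pairs; it equals
#' `1 - IoU` whenever the enclosing box adds no area.
#'
#' @param a,b Boxes as numeric vectors `c(x_min, y_min, x_max, y_max)`
#'   (pixel coordinates, `x_min < x_max`, `y_min < y_max`).
#' @return The scalar loss.
#' @export
#' @examples
#' giou_loss(c(0, 0, 2, 2), c(0, 0, 2, 2)) # 0
#' giou_loss(c(0, 0, 2, 2), c(1, 1, 3, 3)) # 68/63
giou_loss <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == 4, length(b) == 4)
  if (!(a[1] < a[3] && a[2] < a[4] && b[1] < b[3] && b[2] < b[4])) {
    stop("degenerate bounding box")
  }
  area <- function(v) (v[3] - v[1]) * (v[4] - v[2])
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  uni <- area(a) + area(b) - inter
  enclosing <- c(min(a[1], b[1]), min(a[2], b[2]),
                 max(a[3], b[3]), max(a[4], b[4]))
  c_area <- area(enclosing)
  1 - (inter / uni - (c_area - uni) / c_area)
}

#' Binary cross-entropy loss over the five object classes
#'
#' Reference implementation of the classification loss summed over the
#' five detection classes (four postures plus piglet):
#' `-sum(y * log(p) + (1 - y) * log(1 - p))` with natural logarithms.
#' Predictions are post-sigmoid probabilities, clipped to
#' `[eps, 1 - eps]` before the logarithm.
#'
#' @param y_true Length-5 vector of 0/1 class indicators.
#' @param y_pred Length-5 vector of predicted probabilities.
#' @param eps Clipping bound (default `1e-7`).
#' @return The scalar loss (natural-log units).
#' @export
#' @examples
#' bce_loss(c(1, 0, 0, 0, 0), rep(0.5, 5)) # 5 * log(2)
bce_loss <- function(y_true, y_pred, eps = 1e-7) {
  stopifnot(length(y_true) == 5, length(y_pred) == 5,
            all(y_true %in% c(0, 1)), all(y_pred >= 0 & y_pred <= 1))
  p <- pmin(pmax(y_pred, eps), 1 - eps)
  -sum(y_true * log(p) + (1 - y_true) * log(1 - p))
}

#' Confusion counts
#'
#' @param tp,fp,fn Non-negative integer counts of true positives, false
#'   positives, and false negatives.
#' @return An object of class `"confusion_counts"`.
#' @export
confusion_counts <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn)),
            class = "confusion_counts")
}

#' Precision and recall
#'
#' `precision = TP / (TP + FP)` and `recall = TP / (TP + FN)`. When the
#' denominator is zero the value is undefined: `NA` is returned, flagged
#' with an attribute `"reason"`.
#'
#' @param counts A [confusion_counts()].
#' @return A numeric scalar in `[0, 1]`, or flagged `NA`.
#' @export
#' @examples
#' precision(confusion_counts(93, 7, 0)) # 0.93
precision <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  denom <- counts$tp + counts$fp
  if (denom == 0) {
    return(structure(NA_real_, reason = "no positive predictions"))
  }
  counts$tp / denom
}

#' @rdname precision
#' @export
recall <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  denom <- counts$tp + counts$fn
  if (denom == 0) {
    return(structure(NA_real_, reason = "no positive samples"))
  }
  counts$tp / denom
}

#' Piglet-counting accuracy (CA and DA)
#'
#' Current Number Accuracy and Detected Number Accuracy of piglet counting
#' over a farrowing, computed from a per-frame count table:
#' `CA = sum(cur_num) / sum(true_num)` and
#' `DA = sum(detected_num) / sum(true_num)`, sums over frames. On any
#' table produced by [piglet_count_report()], `DA >= CA` because
#' `detected_num` is the running maximum of `cur_num`.
#'
#' @param table Data frame with columns `cur_num`, `detected_num`,
#'   `true_num` (see [piglet_count_report()]).
#' @return A list with elements `ca` and `da`.
#' @export
ca_da <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("cur_num", "detected_num", "true_num") %in% names(table)))
  denom <- sum(table$true_num)
  if (denom <= 0) stop("sum of true_num is zero; CA/DA undefined")
  list(ca = sum(table$cur_num) / denom,
       da = sum(table$detected_num) / denom)
}

#' Summarise per-sow metrics over a cohort
#'
#' Unweighted per-sow means and ranges of the supplied metric columns —
#' the aggregation under which a cohort's overall CA/DA are the plain
#' averages of the per-pen values.
#'
#' @param per_sow Data frame, one row per sow, metric columns numeric.
#' @return Tibble with one row per metric: `metric`, `mean`, `min`, `max`,
#'   `n`.
#' @export
summarize_cohort <- function(per_sow) {
  stopifnot(is.data.frame(per_sow), nrow(per_sow) > 0)
  num <- vapply(per_sow, is.numeric, logical(1))
  cols <- names(per_sow)[num]
  stopifnot(length(cols) > 0)
  tibble::tibble(
    metric = cols,
    mean = vapply(cols, function(c) mean(per_sow[[c]], na.rm = TRUE), 0,
                  USE.NAMES = FALSE),
    min = vapply(cols, function(c) min(per_sow[[c]], na.rm = TRUE), 0,
                 USE.NAMES = FALSE),
    max = vapply(cols, function(c) max(per_sow[[c]], na.rm = TRUE), 0,
                 USE.NAMES = FALSE),
    n = vapply(cols, function(c) sum(!is.na(per_sow[[c]])), 0L,
               USE.NAMES = FALSE)
  )
}

#' Published per-pen piglet-counting accuracy (22-sow cohort)
#'
#' The per-pen Current/Detected Number Accuracy values from the 22-sow
#' field evaluation of this supervision method, shipped as a worked
#' example for [summarize_cohort()] (their unweighted means reproduce the
#' cohort's overall 63.2% / 92.9%).
#'
#' @return Tibble with columns `sow_id`, `ca_pct`, `da_pct` (percent).
#' @export
sow_pen_accuracy <- function() {
  path <- system.file("extdata", "pen_piglet_accuracy.csv",
                      package = "farrowwatch", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, colClasses = c("character",
                                                         "numeric",
                                                         "numeric")))
}
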