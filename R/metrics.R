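# Segmentation quality metrics from confusion counts, with the closed-form
# identities linking F1, IoU, precision/recall and accuracy/error rate.

#' Confusion counts from a decision/truth map pair
#'
#' Tallies pixel-wise confusion counts with defect as the positive class
#' and healthy as the negative class. By default only fruit pixels are
#' evaluated (truth label 1 or 2 and a nonzero prediction); `"full_frame"`
#' also counts background pixels, treating background as healthy.
#'
#' @param pred a [DecisionMap] or H x W matrix in \{0,1,2\}.
#' @param truth H x W ground-truth label matrix in \{0,1,2\}.
#' @param region `"fruit_only"` (default) or `"full_frame"`.
#' @return A [ConfusionCounts].
#' @export
confusionFromMaps <- function(pred, truth, region = c("fruit_only", "full_frame")) {
  region <- match.arg(region)
  p <- if (is(pred, "DecisionMap")) pred@map else pred
  if (!identical(dim(p), dim(truth))) stop("prediction and truth shapes differ")
  if (region == "fruit_only") {
    sel <- truth > 0L & p > 0L
  } else {
    sel <- rep(TRUE, length(truth))
  }
  pd <- p[sel] == 2L; td <- truth[sel] == 2L
  ConfusionCounts(tp = sum(pd & td), fp = sum(pd & !td),
                  fn = sum(!pd & td), tn = sum(!pd & !td))
}

#' The seven segmentation metrics from confusion counts
#'
#' Accuracy, error rate (in percent), IoU, precision, recall, specificity
#' and F1, all with defect as the positive class. Ratios with a zero
#' denominator are reported as `NA` (undefined), never as 0.
#'
#' @param counts a [ConfusionCounts].
#' @return A [MetricSet].
#' @examples
#' metricValues(metricsFromConfusion(ConfusionCounts(50, 10, 25, 915)))
#' @export
metricsFromConfusion <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  tp <- counts@tp; fp <- counts@fp; fn <- counts@fn; tn <- counts@tn
  total <- tp + fp + fn + tn
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  v <- c(accuracy = (tp + tn) / total,
         error_rate = (fp + fn) / total * 100,
         precision = precision,
         recall = recall,
         specificity = ratio(tn, tn + fp),
         f1 = ratio(2 * tp, 2 * tp + fp + fn),
         iou = ratio(tp, tp + fp + fn))
  new("MetricSet", values = v)
}

#' Metric identities on precision/recall and accuracy
#'
#' Closed-form identities used to cross-check reported metric tables:
#' F1 is the harmonic mean `2PR/(P+R)`, IoU follows from precision and
#' recall as `PR/(P+R-PR)`, and the error rate in percent is
#' `(1 - accuracy) * 100`.
#'
#' @param precision,recall values in `[0, 1]`, not both zero.
#' @param accuracy value in `[0, 1]`.
#' @return scalar metric value.
#' @examples
#' f1FromPR(0.9522, 0.8525)   # 0.8996 at 4 decimals
#' iouFromPR(0.4801, 0.7275)  # 0.4069 at 4 decimals
#' errorRateFromAccuracy(0.8544)  # 14.56 percent
#' @name metricIdentities
NULL

#' @rdname metricIdentities
#' @export
f1FromPR <- function(precision, recall) {
  if (any(precision < 0 | precision > 1 | recall < 0 | recall > 1))
    stop("precision and recall must lie in [0, 1]")
  out <- 2 * precision * recall / (precision + recall)
  out[precision + recall == 0] <- NA_real_
  out
}

#' @rdname metricIdentities
#' @export
iouFromPR <- function(precision, recall) {
  if (any(precision < 0 | precision > 1 | recall < 0 | recall > 1))
    stop("precision and recall must lie in [0, 1]")
  pr <- precision * recall
  out <- pr / (precision + recall - pr)
  out[precision + recall == 0] <- NA_real_
  out
}

#' @rdname metricIdentities
#' @export
errorRateFromAccuracy <- function(accuracy) {
  if (any(accuracy < 0 | accuracy > 1)) stop("accuracy must lie in [0, 1]")
  (1 - accuracy) * 100
}

#' Method-by-mode metric grid
#'
#' Arranges per-(method, illumination-mode) metric sets into a long-format
#' table with the seven metrics as rows per combination, formats values at
#' 4 decimals, and flags the best cell per metric and method (maximum, or
#' minimum for the error rate). Undefined metrics propagate as `NA`.
#'
#' @param results named list; `results[[method]][[mode]]` is a [MetricSet].
#' @param file optional path; when given, the grid is written as CSV.
#' @return data.frame with columns `method`, `mode`, `metric`, `value`,
#'   `formatted`, `best`.
#' @export
reportMetricGrid <- function(results, file = NULL) {
  if (length(results) == 0L) stop("at least one result is required")
  rows <- list()
  for (method in names(results)) {
    for (mode in names(results[[method]])) {
      v <- metricValues(results[[method]][[mode]])
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, mode = mode, metric = names(v), value = unname(v),
        stringsAsFactors = FALSE)
    }
  }
  grid <- do.call(rbind, rows)
  grid$formatted <- ifelse(is.na(grid$value), NA, sprintf("%.4f", grid$value))
  grid$best <- FALSE
  for (method in unique(grid$method)) {
    for (metric in unique(grid$metric)) {
      sel <- grid$method == method & grid$metric == metric & !is.na(grid$value)
      if (!any(sel)) next
      v <- grid$value[sel]
      target <- if (metric == "error_rate") min(v) else max(v)
      grid$best[sel][v == target] <- TRUE
    }
  }
  if (!is.null(file)) utils::write.csv(grid, file, row.names = FALSE)
  grid
}
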