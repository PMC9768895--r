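#' Pixelwise confusion counts between two binary masks
#'
#' @param pred,truth binary arrays of identical shape (any dimensionality).
#' @return An object of class `confusion_counts` with integer fields `tp`,
#'   `tn`, `fp`, `fn` summing to the number of compared pixels.
#' @export
confusion <- function(pred, truth) {
  p <- as_vol_array(pred); g <- as_vol_array(truth)
  if (!identical(dim(p), dim(g)) || length(p) != length(g))
    stop("`pred` and `truth` must have the same shape")
  if (!all(p %in% c(0, 1)) || !all(g %in% c(0, 1)))
    stop("masks must be binary")
  tp <- sum(p == 1 & g == 1)
  tn <- sum(p == 0 & g == 0)
  fp <- sum(p == 1 & g == 0)
  fn <- sum(p == 0 & g == 1)
  structure(list(tp = as.integer(tp), tn = as.integer(tn),
                 fp = as.integer(fp), fn = as.integer(fn)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              x$tp, x$tn, x$fp, x$fn, x$tp + x$tn + x$fp + x$fn))
  invisible(x)
}

#' Intersection-over-union (Jaccard index)
#'
#' `TP / (TP + FP + FN)` between a predicted and a gold-standard mask; on
#' binary inputs this is exactly `1 - iou_loss()`. The degenerate
#' empty-vs-empty comparison is defined as 1 with a warning (an empty
#' prediction of an empty mask is a perfect prediction).
#'
#' @param x a `confusion_counts`, or a binary mask (then `y` is required).
#' @param y binary mask to compare with, when `x` is a mask.
#' @return Scalar in [0, 1].
#' @export
iou_metric <- function(x, y = NULL) {
  cc <- if (inherits(x, "confusion_counts")) x else confusion(x, y)
  denom <- cc$tp + cc$fp + cc$fn
  if (denom == 0) {
    warning("both masks empty: IoU defined as 1")
    return(1)
  }
  cc$tp / denom
}

#' F1-score from precision and sensitivity
#'
#' The harmonic mean `2 * precision * sensitivity / (precision +
#' sensitivity)`. Accepts fractions or percentages (both inputs on the same
#' scale); the result is on the input scale.
#'
#' @param precision,sensitivity the two rates.
#' @return F1 on the same scale, or `NA` if both rates are zero.
#' @export
f1_score <- function(precision, sensitivity) {
  if (is.na(precision) || is.na(sensitivity)) return(NA_real_)
  s <- precision + sensitivity
  if (s == 0) return(NA_real_)
  2 * precision * sensitivity / s
}

#' Full evaluation report from confusion counts
#'
#' Computes IoU `TP/(TP+FP+FN)`, accuracy `(TP+TN)/n`, specificity
#' `TN/(TN+FP)`, sensitivity `TP/(TP+FN)`, precision `TP/(TP+FP)` and the F1
#' harmonic mean of precision and sensitivity. Any metric whose denominator
#' is zero is reported as `NA` (never silently 0): empty-mask slices in
#' amyloid-negative cases routinely zero out denominators.
#'
#' @param counts a `confusion_counts` from [confusion()].
#' @param zone_id,plane optional labels carried into the report.
#' @param granularity `"pixel"` or `"case"`; a label recording what the
#'   counts were tallied over.
#' @return An object of class `metrics_report`: a list of the six metrics as
#'   fractions in [0, 1] plus the labels.
#' @export
metrics_report <- function(counts, zone_id = NA_character_,
                           plane = NA_character_,
                           granularity = c("pixel", "case")) {
  stopifnot(inherits(counts, "confusion_counts"))
  granularity <- match.arg(granularity)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  with(counts, {
    prec <- rate(tp, tp + fp)
    sens <- rate(tp, tp + fn)
    structure(list(
      iou = rate(tp, tp + fp + fn),
      accuracy = rate(tp + tn, tp + tn + fp + fn),
      specificity = rate(tn, tn + fp),
      sensitivity = sens,
      precision = prec,
      f1 = f1_score(prec, sens),
      zone_id = zone_id, plane = plane, granularity = granularity),
      class = "metrics_report")
  })
}

#' @export
print.metrics_report <- function(x, ...) {
  lab <- paste(stats::na.omit(c(x$zone_id, x$plane)), collapse = " / ")
  cat(sprintf("<metrics_report>%s (%s-level)\n",
              if (nzchar(lab)) paste0(" ", lab) else "", x$granularity))
  cat(sprintf("  IoU %.3f | accuracy %.1f%% | specificity %.1f%% | ",
              x$iou, 100 * x$accuracy, 100 * x$specificity))
  cat(sprintf("sensitivity %.1f%% | precision %.1f%% | F1 %.1f%%\n",
              100 * x$sensitivity, 100 * x$precision, 100 * x$f1))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(zone_id = x$zone_id, plane = x$plane,
             iou = x$iou, accuracy = x$accuracy,
             specificity = x$specificity, sensitivity = x$sensitivity,
             precision = x$precision, f1 = x$f1,
             granularity = x$granularity, stringsAsFactors = FALSE)
}

#' Aggregate per-zone metric reports
#'
#' Arithmetic mean, median, minimum and maximum of each metric across zones
#' (or cases), `NA`s removed per metric. The arithmetic mean across zones is
#' the headline "mean IoU" convention of segmentation studies.
#'
#' @param reports a list of [metrics_report()] objects, a data frame with
#'   metric columns, or a bare numeric vector (treated as one metric named
#'   `iou`).
#' @return A data frame with one row per statistic (`mean`, `median`, `min`,
#'   `max`) and one column per metric.
#' @export
aggregate_zones <- function(reports) {
  if (is.numeric(reports) && is.null(dim(reports)))
    reports <- data.frame(iou = reports)
  if (is.list(reports) && !is.data.frame(reports)) {
    if (length(reports) == 0L) stop("no reports to aggregate")
    reports <- do.call(rbind, lapply(reports, as.data.frame))
  }
  if (nrow(reports) == 0L) stop("no reports to aggregate")
  cols <- intersect(c("iou", "accuracy", "specificity", "sensitivity",
                      "precision", "f1"), names(reports))
  if (length(cols) == 0L) stop("no metric columns found")
  stat_rows <- list(mean = mean, median = stats::median, min = min,
                    max = max)
  out <- do.call(rbind, lapply(names(stat_rows), function(s) {
    vals <- vapply(cols, function(cn) {
      v <- reports[[cn]][!is.na(reports[[cn]])]
      if (length(v) == 0) NA_real_ else stat_rows[[s]](v)
    }, numeric(1))
    df <- as.data.frame(as.list(vals))
    names(df) <- cols
    cbind(data.frame(statistic = s, stringsAsFactors = FALSE), df)
  }))
  rownames(out) <- NULL
  out
}

#' Write metric reports to JSON
#'
#' One record per report, same fields as the CSV schema.
#'
#' @param reports list of [metrics_report()] objects.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(reports, path) {
  recs <- lapply(reports, function(r)
    r[c("zone_id", "plane", "iou", "accuracy", "specificity",
        "sensitivity", "precision", "f1", "granularity")])
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Write metric reports to CSV
#'
#' One row per (zone, plane) report with the schema
#' `zone, plane, iou, accuracy, specificity, sensitivity, precision, f1`.
#'
#' @param reports list of [metrics_report()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(reports, path) {
  df <- do.call(rbind, lapply(reports, as.data.frame))
  names(df)[names(df) == "zone_id"] <- "zone"
  utils::write.csv(df[, c("zone", "plane", "iou", "accuracy", "specificity",
                          "sensitivity", "precision", "f1")],
                   path, row.names = FALSE)
  invisible(path)
}
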