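# Binary-classification machinery for benchmarking stability predictors:
# labeling rules (ddG- or dTm-based, with explicit sign conventions),
# confusion counts, and sensitivity/specificity/precision/accuracy/F1.
# Undefined ratios (0/0) are reported as NA, never as 0, so they cannot
# silently deflate averages.

#' Label mutations as experimentally stabilizing
#'
#' Sign conventions are explicit: in `ddg` mode a mutation is stabilizing when
#' its folding free-energy change is at or below `-|threshold|` (negative =
#' stabilizing; default threshold 0); in `dtm` mode when its melting-
#' temperature change is at or above `threshold` (default 1.5 degrees C,
#' boundary inclusive).
#'
#' @param values numeric experimental values.
#' @param measure `"ddg"` or `"dtm"`.
#' @param threshold labeling cutoff; defaults 0 (ddg) / 1.5 (dtm).
#' @return logical vector, `TRUE` = stabilizing.
#' @export
label_stabilizing <- function(values, measure = c("ddg", "dtm"), threshold = NULL) {
  measure <- match.arg(measure)
  stopifnot(is.numeric(values))
  if (is.null(threshold)) threshold <- if (measure == "ddg") 0 else 1.5
  if (measure == "ddg") values <= -abs(threshold) else values >= threshold
}

#' Confusion counts
#'
#' @param predicted,actual logical vectors of equal length (`TRUE` =
#'   stabilizing).
#' @return an object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`; the four counts always sum to `length(predicted)`.
#' @export
confusion <- function(predicted, actual) {
  stopifnot(is.logical(predicted), is.logical(actual))
  if (length(predicted) != length(actual))
    stopf("predicted (%d) and actual (%d) label lengths differ",
          length(predicted), length(actual))
  structure(list(tp = sum(predicted & actual),
                 fp = sum(predicted & !actual),
                 tn = sum(!predicted & !actual),
                 fn = sum(!predicted & actual)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), precision = tp/(tp+fp),
#' accuracy = (tp+tn)/total, F1 = harmonic mean of precision and sensitivity.
#' A zero denominator yields `NA` rather than an error.
#'
#' @param counts a [confusion()] result.
#' @return data frame with columns `sensitivity`, `specificity`, `precision`,
#'   `accuracy`, `f1`.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp + counts$fp + counts$tn + counts$fn
  if (total == 0) stopf("all confusion counts are zero")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(counts$tp, counts$tp + counts$fn)
  prec <- ratio(counts$tp, counts$tp + counts$fp)
  # 2tp/(2tp+fp+fn) equals the harmonic mean of precision and sensitivity
  # whenever that is defined, and extends it to 0 when tp = 0 with errors
  f1 <- ratio(2 * counts$tp, 2 * counts$tp + counts$fp + counts$fn)
  data.frame(sensitivity = sens,
             specificity = ratio(counts$tn, counts$tn + counts$fp),
             precision = prec,
             accuracy = (counts$tp + counts$tn) / total,
             f1 = f1)
}

#' F1 score from precision and sensitivity
#'
#' The harmonic-mean identity `2 p s / (p + s)`, usable to verify reported
#' metric tables from their printed precision and sensitivity columns.
#'
#' @param precision,sensitivity rates in `[0, 1]` (NA propagates).
#' @return F1 in `[0, 1]`, or `NA` when undefined (both rates 0 or NA input).
#' @export
f1_from_rates <- function(precision, sensitivity) {
  if (is.na(precision) || is.na(sensitivity)) return(NA_real_)
  stopifnot(precision >= 0, precision <= 1, sensitivity >= 0, sensitivity <= 1)
  if (precision + sensitivity == 0) return(NA_real_)
  2 * precision * sensitivity / (precision + sensitivity)
}

#' Benchmark stability predictors on labeled data
#'
#' Scores each algorithm at its threshold (score at or below threshold =
#' predicted stabilizing, boundary inclusive) against the experimental labels,
#' and adds a `union` row in which a mutation is predicted stabilizing when
#' any algorithm selects it — the ensemble rule behind threshold-consensus
#' library design.
#'
#' @param data data frame with columns `experimental_value`, `measure`
#'   (`"ddg"` or `"dtm"`, constant), and one numeric score column per
#'   algorithm (`NA` = not scored, treated as not selected).
#' @param config a [threshold_config()] covering every algorithm column.
#' @param algorithms algorithm column names; default: every column of `data`
#'   that has a threshold in `config`.
#' @param experimental_threshold labeling cutoff passed to
#'   [label_stabilizing()].
#' @return data frame in reporting column order: `algorithm`, `threshold`,
#'   `sensitivity`, `specificity`, `precision`, `accuracy`, `f1`; one row per
#'   algorithm plus the final `union` row.
#' @export
benchmark_report <- function(data, config = threshold_config(),
                             algorithms = NULL, experimental_threshold = NULL) {
  stopifnot(all(c("experimental_value", "measure") %in% names(data)))
  measure <- unique(data$measure)
  if (length(measure) != 1)
    stopf("mixed experimental measures in one benchmark (found: %s)",
          paste(measure, collapse = ", "))
  if (is.null(algorithms))
    algorithms <- intersect(names(data), names(config$thresholds))
  if (length(algorithms) == 0) stopf("no scored algorithm columns found")
  missing_thr <- setdiff(algorithms, names(config$thresholds))
  if (length(missing_thr) > 0)
    stopf("no threshold configured for: %s", paste(missing_thr, collapse = ", "))
  actual <- label_stabilizing(data$experimental_value, measure,
                              threshold = experimental_threshold)
  predict_one <- function(al) {
    s <- data[[al]]
    p <- if (config$boundary_inclusive) s <= config$thresholds[[al]]
         else s < config$thresholds[[al]]
    p[is.na(p)] <- FALSE
    p
  }
  rows <- lapply(algorithms, function(al) {
    cbind(data.frame(algorithm = al, threshold = config$thresholds[[al]]),
          classification_metrics(confusion(predict_one(al), actual)))
  })
  union_pred <- Reduce(`|`, lapply(algorithms, predict_one))
  rows[[length(rows) + 1]] <-
    cbind(data.frame(algorithm = "union", threshold = NA_real_),
          classification_metrics(confusion(union_pred, actual)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published predictor benchmark metrics
#'
#' The published comparison of stability predictors (thresholded single-point
#' predictions on a ProTherm-derived set of 350 mutants): per-algorithm
#' threshold, sensitivity, specificity, precision, accuracy and F1. Shipped as
#' a reference table for verifying metric identities (see [f1_from_rates()]).
#'
#' @return data frame `algorithm`, `threshold`, `sensitivity`, `specificity`,
#'   `precision`, `accuracy`, `f1`.
#' @export
predictor_benchmark_metrics <- function() {
  utils::read.csv(system.file("extdata", "predictor_benchmark_metrics.csv",
                              package = "stabmut"),
                  stringsAsFactors = FALSE)
}
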