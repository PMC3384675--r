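#' Confusion counts over (query, scene) decisions
#'
#' Scores a table of detection decisions against ground truth.  Each
#' (query, scene) pair is one decision: a true positive when both the
#' truth and the detector say the query is in the scene, a true negative
#' when both say it is not, and so on.  Localization accuracy is scored
#' separately by [locate_report()], never folded into TP.
#'
#' @param detections Data frame with columns `query_id`, `scene_index`,
#'   `present` (logical decision).
#' @param truth Data frame with columns `query_id`, `scene_index`,
#'   `present` (logical ground truth).  Every detection row must have a
#'   matching truth row.
#' @return A list of class `confusion_counts`: `tp`, `tn`, `fp`, `fn`,
#'   `n`.
#' @examples
#' det <- data.frame(query_id = "q1", scene_index = 0:3,
#'                   present = c(TRUE, FALSE, FALSE, FALSE))
#' tru <- data.frame(query_id = "q1", scene_index = 0:3,
#'                   present = c(TRUE, FALSE, FALSE, FALSE))
#' score_detections(det, tru)  # tp = 1, tn = 3
#' @export
score_detections <- function(detections, truth) {
  key_d <- paste(detections$query_id, detections$scene_index)
  key_t <- paste(truth$query_id, truth$scene_index)
  idx <- match(key_d, key_t)
  if (anyNA(idx)) {
    miss <- key_d[is.na(idx)][1L]
    stop(sprintf("no ground truth for decision (%s)", miss), call. = FALSE)
  }
  pred <- detections$present
  act <- truth$present[idx]
  confusion_counts(tp = sum(pred & act), tn = sum(!pred & !act),
                   fp = sum(pred & !act), fn = sum(!pred & act))
}

#' @rdname score_detections
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 n = tp + tn + fp + fn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> n = %d: TP %d, TN %d, FP %d, FN %d\n",
              x$n, x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Statistical indexes of a confusion table
#'
#' Computes the four recognition indexes, in percent:
#' sensitivity `Se = 100 * TP / (TP + FN)` (ability to detect an object
#' that is in the scene), specificity `Sp = 100 * TN / (TN + FP)` (ability
#' to detect that it is not), exactitude `Ex = 100 * (TP + TN) / n`
#' (all correct decisions) and error `Er = 100 * (FP + FN) / n`, so that
#' `Ex + Er = 100`.  `Se` (resp. `Sp`) is `NA` when there are no positive
#' (resp. negative) decisions to score.
#'
#' @param counts A `confusion_counts` object.
#' @param noise_level Optional noise fraction carried into the report.
#' @return A one-row data frame of class `index_report` with columns
#'   `noise_level`, `se`, `sp`, `ex`, `er` (percent).
#' @examples
#' correlation_indexes(confusion_counts(tp = 300, fn = 3,
#'                                      tn = 29997, fp = 3))
#' @export
correlation_indexes <- function(counts, noise_level = NA_real_) {
  if (counts$n == 0L) stop("no decisions to score", call. = FALSE)
  se <- if (counts$tp + counts$fn > 0) 100 * counts$tp / (counts$tp + counts$fn)
        else NA_real_
  sp <- if (counts$tn + counts$fp > 0) 100 * counts$tn / (counts$tn + counts$fp)
        else NA_real_
  out <- data.frame(noise_level = noise_level, se = se, sp = sp,
                    ex = 100 * (counts$tp + counts$tn) / counts$n,
                    er = 100 * (counts$fp + counts$fn) / counts$n)
  class(out) <- c("index_report", "data.frame")
  out
}

#' Calibrate the peak-intensity decision threshold
#'
#' Chooses the presence threshold from labelled peak intensities: every
#' midpoint between consecutive distinct sorted intensities (plus minus
#' and plus infinity) is a candidate, and the candidate maximizing the
#' exactitude `Ex` is returned.  Ties are broken toward higher
#' specificity, then toward the higher threshold.  This mirrors the
#' heuristic single-threshold calibration of the original method (one
#' value fixed once and reused across noise levels); the absolute value
#' depends on the FFT normalization convention, so thresholds must always
#' be recalibrated rather than copied between implementations.
#'
#' @param intensity Numeric vector of peak intensities, one per
#'   (query, scene) decision.
#' @param truth_present Logical vector: is the query truly in that scene.
#' @param objective Only `"exactitude"` is implemented.
#' @return The threshold (numeric scalar) with attributes `exactitude`,
#'   `sensitivity`, `specificity` giving the calibration-set performance.
#' @export
calibrate_threshold <- function(intensity, truth_present,
                                objective = "exactitude") {
  objective <- match.arg(objective)
  stopifnot(length(intensity) == length(truth_present))
  if (!any(truth_present) || all(truth_present)) {
    stop("calibration needs at least one positive and one negative example",
         call. = FALSE)
  }
  u <- sort(unique(intensity))
  cand <- c(-Inf, (u[-length(u)] + u[-1L]) / 2, Inf)
  ## counts of positives/negatives at or below each candidate
  npos <- sum(truth_present)
  nneg <- length(truth_present) - npos
  iu <- match(intensity, u)
  pos_cum <- c(0, cumsum(tabulate(iu[truth_present], nbins = length(u))))
  neg_cum <- c(0, cumsum(tabulate(iu[!truth_present], nbins = length(u))))
  ## candidate i = cand[i] sits below u[i]; decisions: present <=> intensity > t
  ## -Inf: nothing below; midpoint i (between u[i], u[i+1]): u[1..i] below; Inf: all below
  below <- c(0, seq_along(u)[-length(u)], length(u))
  fn <- pos_cum[below + 1L]
  tn <- neg_cum[below + 1L]
  tp <- npos - fn
  fp <- nneg - tn
  ex <- (tp + tn) / (npos + nneg)
  sp <- tn / nneg
  best <- order(-ex, -sp, -cand)[1L]
  structure(cand[best],
            exactitude = 100 * ex[best],
            sensitivity = 100 * tp[best] / npos,
            specificity = 100 * sp[best])
}

#' Localization report for detected queries
#'
#' Classifies the estimated start position of each correctly detected
#' query (detection present and truly in the scene) as `exact`
#' (`est_start_base == true_start`), `one_row_shift` (absolute error of
#' exactly one image row, i.e. `width` bases — the raster-wrap artifact),
#' or `wrong` (anything else).  The three categories partition the scored
#' detections.
#'
#' @param detections Data frame with columns `query_id`, `scene_index`,
#'   `present`, `est_start_base`.
#' @param truth Data frame with columns `query_id`, `scene_index`,
#'   `present`, `true_start`.
#' @param width Scene width in pixels (bases per row).
#' @return A data frame of class `locate_report` with rows `exact`,
#'   `one_row_shift`, `wrong`, `total` and columns `n_objects`,
#'   `percentage`.
#' @export
locate_report <- function(detections, truth, width = 100L) {
  key_d <- paste(detections$query_id, detections$scene_index)
  key_t <- paste(truth$query_id, truth$scene_index)
  idx <- match(key_d, key_t)
  if (anyNA(idx)) stop("no ground truth for some detections", call. = FALSE)
  scored <- detections$present & truth$present[idx]
  err <- abs(detections$est_start_base[scored] -
               truth$true_start[idx][scored])
  n_exact <- sum(err == 0)
  n_shift <- sum(err == width)
  n_wrong <- sum(err != 0 & err != width)
  n <- length(err)
  out <- data.frame(
    n_objects = c(n_exact, n_shift, n_wrong, n),
    percentage = if (n > 0) 100 * c(n_exact, n_shift, n_wrong, n) / n
                 else rep(NA_real_, 4),
    row.names = c("exact", "one_row_shift", "wrong", "total"))
  class(out) <- c("locate_report", "data.frame")
  out
}

#' Format percentage tables with a choice of decimal mark
#'
#' Renders index or localization percentages to two decimals, with either
#' a point or a comma as decimal mark.
#'
#' @param x Numeric vector of percentages.
#' @param decimal_mark `"."` or `","`.
#' @return Character vector.
#' @export
format_percent <- function(x, decimal_mark = c(".", ",")) {
  decimal_mark <- match.arg(decimal_mark)
  formatC(x, format = "f", digits = 2, decimal.mark = decimal_mark)
}

#' Write benchmark report tables
#'
#' Emits the three TSV reports of a benchmark run: the per-noise-level
#' index table (`indexes.tsv`), the localization table for the clean
#' query set (`localization.tsv`), and the per-detection hits table
#' (`hits.tsv`).
#'
#' @param bench A `correlation_benchmark` from
#'   [run_correlation_benchmark()].
#' @param dir Output directory (created if needed).
#' @param decimal_mark Decimal mark for the percentage tables.
#' @return Named character vector of file paths, invisibly.
#' @export
write_benchmark_reports <- function(bench, dir, decimal_mark = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx_path <- file.path(dir, "indexes.tsv")
  loc_path <- file.path(dir, "localization.tsv")
  hit_path <- file.path(dir, "hits.tsv")
  idx <- bench$indexes
  for (colname in c("se", "sp", "ex", "er")) {
    idx[[colname]] <- format_percent(idx[[colname]], decimal_mark)
  }
  utils::write.table(idx, idx_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  loc <- bench$localization
  loc$percentage <- format_percent(loc$percentage, decimal_mark)
  utils::write.table(cbind(category = rownames(loc), loc), loc_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bench$hits, hit_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(indexes = idx_path, localization = loc_path,
              hits = hit_path))
}
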