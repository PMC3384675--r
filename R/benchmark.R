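## Fast inner loop shared by the benchmark and the search command: peak
## intensity of one filter against a list of precomputed scene FFTs.
## Returns max intensity per scene; positions are recomputed on demand.
peak_intensities <- function(scene_ffts, filt) {
  n <- length(filt)
  vapply(scene_ffts,
         function(S) max(Mod(stats::fft(S * filt, inverse = TRUE))) / n,
         0)
}

#' Run the full synthetic correlation benchmark
#'
#' Reproduces the complete experiment on synthetic data: generate a
#' uniform random database, tile it into non-overlapping scenes, extract
#' queries from within single scenes (so each query is truly present in
#' exactly one scene and absent from all others), mutate the query set at
#' each noise level, correlate every query against every scene with a
#' phase-only filter, calibrate the decision threshold on the 0%-noise
#' peaks by maximum exactitude, and score every (query, scene) decision
#' at every noise level with the threshold held fixed.
#'
#' The default geometry is a 1 Mbp database in 100 scenes of 100 x 100
#' pixels with 303 queries of 50–4,500 bp per level and noise levels
#' 0–60% in steps of 10% (2,121 query records).  Smaller runs for quick
#' checks simply scale `db_size`, `n_queries` and `noise_levels` down.
#'
#' @inheritParams build_benchmark
#' @param threshold `"auto"` to calibrate on the 0%-noise run (requires 0
#'   among `noise_levels`), or a fixed numeric threshold.
#' @param mapping A [gray_code()] mapping.
#' @param progress Print one line per noise level as it completes.
#' @return An object of class `correlation_benchmark` with fields:
#'   \describe{
#'     \item{`threshold`}{the decision threshold used (with calibration
#'       attributes when auto-calibrated).}
#'     \item{`indexes`}{per-noise-level data frame of `se`, `sp`, `ex`,
#'       `er` (percent) plus confusion counts.}
#'     \item{`localization`}{[locate_report()] of the 0%-noise set (or
#'       the lowest level run).}
#'     \item{`mean_positive_peak`}{mean peak intensity at the true scene
#'       per noise level.}
#'     \item{`hits`}{per-(query, scene) table for present decisions plus
#'       every true-scene pair.}
#'     \item{`bundle`}{the generated [build_benchmark()] inputs.}
#'   }
#' @seealso [calibrate_threshold()], [write_benchmark_reports()]
#' @export
run_correlation_benchmark <- function(db_size = 1e6, n_queries = 303L,
                                      noise_levels = seq(0, 0.6, by = 0.1),
                                      scene_width = 100L,
                                      scene_height = 100L,
                                      min_len = 50L, max_len = 4500L,
                                      threshold = "auto",
                                      mapping = gray_code(),
                                      seed = NULL, lenient = FALSE,
                                      progress = FALSE) {
  auto <- identical(threshold, "auto")
  if (auto && !any(noise_levels == 0)) {
    stop("threshold = \"auto\" requires noise level 0 for calibration",
         call. = FALSE)
  }
  bundle <- build_benchmark(db_size = db_size, n_queries = n_queries,
                            noise_levels = noise_levels,
                            scene_width = scene_width,
                            scene_height = scene_height,
                            min_len = min_len, max_len = max_len,
                            seed = seed, lenient = lenient)
  scenes <- tile_database(bundle$db, width = scene_width,
                          height = scene_height, overlap = 0L,
                          mapping = mapping)
  scene_ffts <- lapply(scenes, function(s) stats::fft(s$pixels))
  capacity <- scene_width * scene_height
  n_scenes <- length(scenes)

  base <- bundle$queries[bundle$queries$noise_level == min(noise_levels), ]
  src_scene <- base$true_start %/% capacity  # the one truly-positive scene

  ## peak intensity of every (query, scene) pair, one matrix per level,
  ## plus peak position at the true scene for localization
  levels_q <- split(bundle$queries, bundle$queries$noise_level)
  peaks <- list()
  loc <- list()
  for (lv in names(levels_q)) {
    qs <- levels_q[[lv]]
    pk <- matrix(0, nrow = nrow(qs), ncol = n_scenes)
    est <- numeric(nrow(qs))
    for (i in seq_len(nrow(qs))) {
      obj <- encode_object(qs$sequence[i], width = scene_width,
                           mapping = mapping)
      filt <- pof(obj, frame_width = scene_width,
                  frame_height = scene_height)
      pk[i, ] <- peak_intensities(scene_ffts, filt)
      p <- find_peak(correlate(scenes[[src_scene[i] + 1L]], filt))
      est[i] <- scenes[[src_scene[i] + 1L]]$db_offset +
        p$row * scene_width + p$col
    }
    peaks[[lv]] <- pk
    loc[[lv]] <- est
    if (progress) {
      message(sprintf("noise %s: %d queries x %d scenes done",
                      lv, nrow(qs), n_scenes))
    }
  }

  truth_mat <- matrix(FALSE, nrow = n_queries, ncol = n_scenes)
  truth_mat[cbind(seq_len(n_queries), src_scene + 1L)] <- TRUE

  if (auto) {
    p0 <- peaks[["0"]]
    threshold <- calibrate_threshold(as.vector(p0), as.vector(truth_mat))
  }

  rows <- lapply(names(levels_q), function(lv) {
    pred <- peaks[[lv]] > as.numeric(threshold)
    cc <- confusion_counts(tp = sum(pred & truth_mat),
                           tn = sum(!pred & !truth_mat),
                           fp = sum(pred & !truth_mat),
                           fn = sum(!pred & truth_mat))
    cbind(correlation_indexes(cc, noise_level = as.numeric(lv)),
          tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn)
  })
  indexes <- do.call(rbind, rows)
  indexes <- indexes[order(indexes$noise_level), ]
  rownames(indexes) <- NULL
  class(indexes) <- c("index_report", "data.frame")

  mean_pos <- vapply(names(levels_q), function(lv)
    mean(peaks[[lv]][truth_mat]), 0)
  mean_pos <- mean_pos[order(as.numeric(names(mean_pos)))]

  ## localization of the cleanest level, scored on above-threshold hits
  lv0 <- names(levels_q)[which.min(as.numeric(names(levels_q)))]
  q0 <- levels_q[[lv0]]
  det0 <- data.frame(query_id = q0$id, scene_index = src_scene,
                     present = peaks[[lv0]][truth_mat] >
                       as.numeric(threshold),
                     est_start_base = loc[[lv0]])
  tru0 <- data.frame(query_id = q0$id, scene_index = src_scene,
                     present = TRUE, true_start = q0$true_start)
  localization <- locate_report(det0, tru0, width = scene_width)

  hits <- do.call(rbind, lapply(names(levels_q), function(lv) {
    qs <- levels_q[[lv]]
    pred <- peaks[[lv]] > as.numeric(threshold)
    keep <- which(pred | truth_mat, arr.ind = TRUE)
    data.frame(query_id = qs$id[keep[, 1L]],
               noise_level = as.numeric(lv),
               scene_index = keep[, 2L] - 1L,
               peak_intensity = peaks[[lv]][keep],
               present = pred[keep],
               truth_present = truth_mat[keep])
  }))
  hits <- hits[order(hits$noise_level, hits$query_id, hits$scene_index), ]
  rownames(hits) <- NULL

  structure(
    list(threshold = threshold, indexes = indexes,
         localization = localization, mean_positive_peak = mean_pos,
         hits = hits, bundle = bundle,
         params = c(bundle$params,
                    list(scene_width = scene_width,
                         scene_height = scene_height,
                         n_scenes = n_scenes, auto_threshold = auto))),
    class = "correlation_benchmark")
}

#' @export
print.correlation_benchmark <- function(x, digits = 2, ...) {
  p <- x$params
  cat(sprintf(
    "Simulated optical-correlation benchmark\n  %s bp database, %d scenes of %d x %d, %d queries (%d-%d bp) per level\n",
    format(p$db_size, big.mark = ",", scientific = FALSE), p$n_scenes,
    x$params$scene_height, x$params$scene_width, p$n_queries,
    p$min_len, p$max_len))
  cat(sprintf("  decision threshold: %.4g%s\n", as.numeric(x$threshold),
              if (isTRUE(p$auto_threshold))
                sprintf(" (auto-calibrated at 0%% noise, Ex = %.2f%%)",
                        attr(x$threshold, "exactitude")) else ""))
  cat("\nStatistical indexes (%) by noise level:\n")
  tab <- x$indexes
  tab$noise_level <- paste0(100 * tab$noise_level, "%")
  print(format(tab, digits = digits, nsmall = digits), row.names = FALSE)
  cat("\nPeak localization (lowest noise level):\n")
  print(x$localization, digits = digits)
  invisible(x)
}

#' @export
summary.correlation_benchmark <- function(object, ...) {
  print(object, ...)
  cat("\nMean positive peak intensity by noise level:\n")
  print(round(object$mean_positive_peak, 1))
  invisible(object)
}
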