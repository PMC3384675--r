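#' Phase-only filter of an object image
#'
#' Builds the frequency-plane filter of the simulated Vander-Lugt
#' correlator.  The object image is zero-padded into the top-left corner of
#' a `frame_height` x `frame_width` canvas, its 2-D discrete Fourier
#' transform `G` is taken, and the phase-only filter (POF)
#' `conj(G) / |G|` is returned.  Frequencies where `|G| = 0` (which arise
#' only for degenerate objects) are set to 0 and flagged via the
#' `"zero_frequencies"` attribute.
#'
#' The POF keeps only the spectral phase of the object, which whitens the
#' object spectrum and produces much sharper correlation peaks than the
#' classical matched filter `conj(G)` at full luminous efficiency — the
#' property that makes it the filter of choice in optical correlation.
#'
#' @param object An `object_image` from [encode_object()], or a plain
#'   numeric matrix.
#' @param frame_width,frame_height Dimensions of the scene frame the filter
#'   will be applied to.  The object must fit inside the frame.
#' @return A `frame_height` x `frame_width` complex matrix with
#'   `|POF| = 1` wherever `|G| > 0`.
#' @seealso [correlate()], [detect()]
#' @export
pof <- function(object, frame_width = 100L, frame_height = 100L) {
  px <- if (is.matrix(object)) object else object$pixels
  if (nrow(px) > frame_height || ncol(px) > frame_width) {
    stop(sprintf("object (%d x %d) does not fit in the %d x %d frame",
                 nrow(px), ncol(px), frame_height, frame_width),
         call. = FALSE)
  }
  canvas <- matrix(0, nrow = frame_height, ncol = frame_width)
  canvas[seq_len(nrow(px)), seq_len(ncol(px))] <- px
  G <- stats::fft(canvas)
  mag <- Mod(G)
  zero <- mag <= max(mag) * .Machine$double.eps * length(mag)
  filt <- matrix(0i, frame_height, frame_width)
  filt[!zero] <- Conj(G[!zero]) / mag[!zero]
  if (all(zero)) {
    warning("all-zero object: phase-only filter is identically zero",
            call. = FALSE)
  }
  attr(filt, "zero_frequencies") <- sum(zero)
  filt
}

#' Classical matched filter of an object image
#'
#' The un-normalized frequency-plane mask `conj(G)`: correlation with it is
#' plain circular cross-correlation with the object.  Provided for
#' cross-checks against the spatial-domain definition; the search pipeline
#' uses [pof()].
#'
#' @inheritParams pof
#' @return A complex matrix of the frame dimensions.
#' @export
cmf <- function(object, frame_width = 100L, frame_height = 100L) {
  px <- if (is.matrix(object)) object else object$pixels
  if (nrow(px) > frame_height || ncol(px) > frame_width) {
    stop(sprintf("object (%d x %d) does not fit in the %d x %d frame",
                 nrow(px), ncol(px), frame_height, frame_width),
         call. = FALSE)
  }
  canvas <- matrix(0, nrow = frame_height, ncol = frame_width)
  canvas[seq_len(nrow(px)), seq_len(ncol(px))] <- px
  Conj(stats::fft(canvas))
}

#' Correlate a scene with a frequency-plane filter
#'
#' Simulates the optical correlation: the scene's 2-D Fourier transform is
#' multiplied elementwise by the filter and inverse-transformed; the
#' correlation plane is the complex magnitude of the result (the optical
#' intensity analogue).  The product implements circular (wraparound)
#' correlation — no extra zero-padding of the frame — so content spanning a
#' scene boundary is handled by tiling overlap, not by linear-correlation
#' padding.  The inverse transform is normalized by the frame size
#' `W * H`; the forward transform is unnormalized.
#'
#' @param scene A `scene_image` or a plain numeric matrix.
#' @param filter A complex matrix with the scene's dimensions, e.g. from
#'   [pof()].
#' @return A `correlation_plane` object: fields `values` (non-negative
#'   matrix of the scene's dimensions) and `scene_index` (provenance; `NA`
#'   for a bare matrix input).
#' @export
correlate <- function(scene, filter) {
  px <- if (is.matrix(scene)) scene else scene$pixels
  if (!identical(dim(px), dim(filter))) {
    stop(sprintf("filter is %d x %d but scene is %d x %d",
                 nrow(filter), ncol(filter), nrow(px), ncol(px)),
         call. = FALSE)
  }
  vals <- Mod(stats::fft(stats::fft(px) * filter, inverse = TRUE)) /
    length(px)
  structure(
    list(values = vals,
         scene_index = if (is.list(scene)) scene$scene_index else NA_integer_),
    class = "correlation_plane")
}

#' Locate the correlation peak
#'
#' Returns the global maximum of a correlation plane and its 0-based pixel
#' coordinate, read in natural (unshifted) index order so that (0, 0)
#' corresponds to zero displacement.  Ties are broken toward the smallest
#' row, then the smallest column.
#'
#' @param plane A `correlation_plane` or a numeric matrix.
#' @return A list of class `peak` with fields `intensity`, `row`, `col`
#'   (0-based).
#' @export
find_peak <- function(plane) {
  v <- if (is.matrix(plane)) plane else plane$values
  if (length(v) == 0L) stop("empty correlation plane", call. = FALSE)
  m <- max(v)
  idx <- which(v == m)           # column-major linear indices
  rows <- (idx - 1L) %% nrow(v)
  cols <- (idx - 1L) %/% nrow(v)
  ord <- order(rows, cols)[1L]   # lexicographic (row, col) tie-break
  structure(list(intensity = m, row = rows[ord], col = cols[ord]),
            class = "peak")
}

#' @export
print.peak <- function(x, ...) {
  cat(sprintf("<peak> intensity %.4g at pixel (%d, %d)\n",
              x$intensity, x$row, x$col))
  invisible(x)
}

## Number of object cells that wrap past the row end when the object is
## placed at column `col` of a width-`width` raster.  The row-major layout
## splits a placed object between the 2-D circular shifts (r, col) and
## (r + 1, col); the peak lands on whichever alignment carries more
## pixels.  When the wrapped part dominates, the estimated start is one
## row (= `width` bases) beyond the true start.
wrapped_cells <- function(length, col, width) {
  k <- seq_len(length) - 1L
  sum((k %% width) >= (width - col))
}

#' Detect an object in one scene
#'
#' Runs the full per-pair pipeline — phase-only filter, frequency-domain
#' correlation, peak extraction — and thresholds the peak intensity: the
#' object is declared present when the peak strictly exceeds `threshold`.
#' The estimated database start of the match is
#' `db_offset + row * width + col`.
#'
#' Because the raster layout wraps rows, a match starting in the right half
#' of a scene row yields a peak one row below the true start (an error of
#' exactly `width` bases).  `shift_flag` marks detections where the wrapped
#' alignment dominates (peak column and object length imply more wrapped
#' than unwrapped pixels); with `shift_correct = TRUE` one row's worth of
#' bases is subtracted from `est_start_base` when flagged.
#'
#' @param scene A `scene_image`.
#' @param object An `object_image`, or a precomputed filter passed via
#'   `filter`.
#' @param threshold Non-negative decision threshold on peak intensity (see
#'   [calibrate_threshold()]).
#' @param shift_correct Apply the one-row correction when `shift_flag` is
#'   set.  Off by default.
#' @param filter Optional precomputed filter matrix (overrides `object`'s
#'   encoding; `object$length` is still used for the wrap rule).
#' @return A `detection`: fields `present`, `peak`, `est_start_base`,
#'   `shift_flag`, `scene_index`.
#' @export
detect <- function(scene, object, threshold, shift_correct = FALSE,
                   filter = NULL) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  if (is.null(filter)) {
    filter <- pof(object, frame_width = scene$width,
                  frame_height = scene$height)
  }
  pk <- find_peak(correlate(scene, filter))
  est <- scene$db_offset + pk$row * scene$width + pk$col
  flag <- wrapped_cells(object$length, pk$col, scene$width) >
    object$length / 2
  if (shift_correct && flag) est <- est - scene$width
  structure(
    list(present = pk$intensity > threshold, peak = pk,
         est_start_base = est, shift_flag = flag,
         scene_index = scene$scene_index),
    class = "detection")
}

#' @export
print.detection <- function(x, ...) {
  cat(sprintf("<detection> scene %d: %s (peak %.4g at (%d, %d), est. start %d%s)\n",
              x$scene_index, if (x$present) "PRESENT" else "absent",
              x$peak$intensity, x$peak$row, x$peak$col, x$est_start_base,
              if (x$shift_flag) ", row-shift flagged" else ""))
  invisible(x)
}

#' Search an object across a tiled database
#'
#' Correlates one object against every scene in turn (the object's filter
#' is computed once; the scenes change until the whole database has been
#' correlated).  Requires the tiling overlap to be at least the object
#' length so no occurrence can straddle a scene boundary unseen.  In
#' overlap regions the same database start can be hit from two scenes;
#' such duplicates are reduced to the higher-intensity detection, the
#' other being demoted to absent.
#'
#' @param scenes List of `scene_image`s from [tile_database()] (scene
#'   order preserved).
#' @param object An `object_image`.
#' @param threshold Decision threshold on peak intensity.
#' @param shift_correct As in [detect()].
#' @return A list of `detection`s, one per scene, in scene order.
#' @export
search_scenes <- function(scenes, object, threshold, shift_correct = FALSE) {
  if (length(scenes) == 0L) return(list())
  capacity <- scenes[[1L]]$width * scenes[[1L]]$height
  if (length(scenes) > 1L) {
    stride <- scenes[[2L]]$db_offset - scenes[[1L]]$db_offset
    if (capacity - stride < object$length) {
      stop(sprintf(
        "tiling overlap (%d) is smaller than the object length (%d): a hit could span a scene boundary",
        capacity - stride, object$length), call. = FALSE)
    }
  }
  filt <- pof(object, frame_width = scenes[[1L]]$width,
              frame_height = scenes[[1L]]$height)
  hits <- lapply(scenes, detect, object = object, threshold = threshold,
                 shift_correct = shift_correct, filter = filt)
  ## deduplicate present hits that resolve to the same database start
  present <- which(vapply(hits, `[[`, TRUE, "present"))
  if (length(present) > 1L) {
    starts <- vapply(hits[present], `[[`, 0, "est_start_base")
    ints <- vapply(hits[present], function(h) h$peak$intensity, 0)
    for (s in unique(starts[duplicated(starts)])) {
      grp <- present[starts == s]
      keep <- grp[which.max(ints[starts == s])]
      for (i in setdiff(grp, keep)) hits[[i]]$present <- FALSE
    }
  }
  hits
}

#' Tabulate detections
#'
#' Flattens a list of `detection`s (e.g. from [search_scenes()]) into a
#' data frame with one row per scene.
#'
#' @param detections List of `detection` objects.
#' @param query_id Optional id recycled into a leading column.
#' @return A data frame with columns `query_id` (if given), `scene_index`,
#'   `peak_intensity`, `peak_row`, `peak_col`, `present`,
#'   `est_start_base`, `shift_flag`.
#' @export
hits_table <- function(detections, query_id = NULL) {
  df <- data.frame(
    scene_index = vapply(detections, `[[`, 0L, "scene_index"),
    peak_intensity = vapply(detections, function(h) h$peak$intensity, 0),
    peak_row = vapply(detections, function(h) h$peak$row, 0),
    peak_col = vapply(detections, function(h) h$peak$col, 0),
    present = vapply(detections, `[[`, TRUE, "present"),
    est_start_base = vapply(detections, `[[`, 0, "est_start_base"),
    shift_flag = vapply(detections, `[[`, TRUE, "shift_flag"))
  if (!is.null(query_id)) df <- cbind(query_id = query_id, df)
  df
}
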