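#' Code a DNA sequence as a grayscale object image
#'
#' Converts a query sequence into the padded gray image ("object") searched
#' for inside database scenes.  Base `i` (0-based) is written row-major at
#' row `floor(i / width)`, column `i %% width`, so a displacement of one
#' image row corresponds to exactly `width` bases.  Cells after the last
#' base in the final row are filled with `pad_value`.
#'
#' @param sequence A single DNA string (A/C/G/T; case-insensitive).
#' @param width Image width in pixels (bases per row).
#' @param mapping A [gray_code()] mapping.
#' @param pad_value Gray level used for trailing cells of the last row.
#' @param ambiguity Policy for symbols outside the A/C/G/T alphabet:
#'   `"strict"` raises an error naming the first offending position,
#'   `"mask"` replaces them with `pad_value`.
#' @return An object of class `object_image` with fields `pixels`
#'   (h x width numeric matrix), `length` (true base count), `width`,
#'   and `pad_value`.
#' @examples
#' obj <- encode_object("ACGT", width = 4)
#' obj$pixels  # one row: 0 85 170 255
#' @seealso [decode_image()], [tile_database()]
#' @export
encode_object <- function(sequence, width = 100L, mapping = gray_code(),
                          pad_value = 0,
                          ambiguity = c("strict", "mask")) {
  ambiguity <- match.arg(ambiguity)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  if (n == 0L) stop("sequence is empty", call. = FALSE)
  width <- as.integer(width)
  if (width < 1L) stop("width must be positive", call. = FALSE)
  vals <- gray_lut(mapping)[utf8ToInt(sequence) + 1L]
  if (anyNA(vals)) {
    if (ambiguity == "strict") {
      pos <- which(is.na(vals))[1L]
      stop(sprintf("symbol '%s' at position %d is outside the A/C/G/T alphabet",
                   substr(sequence, pos, pos), pos), call. = FALSE)
    }
    vals[is.na(vals)] <- pad_value
  }
  h <- ceiling(n / width)
  cells <- rep(pad_value, h * width)
  cells[seq_len(n)] <- vals
  structure(
    list(pixels = matrix(cells, nrow = h, ncol = width, byrow = TRUE),
         length = n, width = width, pad_value = pad_value),
    class = "object_image")
}

#' @export
print.object_image <- function(x, ...) {
  cat(sprintf("<object_image> %d bases in %d x %d pixels (pad = %g)\n",
              x$length, nrow(x$pixels), x$width, x$pad_value))
  invisible(x)
}

#' Recover the DNA sequence from an encoded image
#'
#' Inverse of [encode_object()]: reads the first `length` row-major cells
#' and maps gray levels back to bases, ignoring any padding beyond
#' `length`.
#'
#' @param image An `object_image`, `scene_image`, or a plain numeric matrix
#'   of gray levels.
#' @param length Number of bases to read; defaults to the image's own
#'   `length` field when present.
#' @param mapping The [gray_code()] mapping used to encode.
#' @return A DNA string.
#' @export
decode_image <- function(image, length = NULL, mapping = gray_code()) {
  px <- if (is.matrix(image)) image else image$pixels
  if (is.null(length)) {
    length <- if (is.list(image) && !is.null(image$length)) image$length
              else base::length(px)
  }
  if (length > base::length(px)) {
    stop("`length` exceeds image capacity", call. = FALSE)
  }
  cells <- as.vector(t(px))[seq_len(length)]  # row-major order
  idx <- match(cells, as.numeric(mapping))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    r <- (bad - 1L) %/% ncol(px)
    c <- (bad - 1L) %% ncol(px)
    stop(sprintf("pixel (%d, %d) holds %g, not a gray-code level",
                 r, c, cells[bad]), call. = FALSE)
  }
  paste(names(mapping)[idx], collapse = "")
}

#' Tile a database sequence into fixed-size scene images
#'
#' Splits the database into consecutive `width` x `height` scenes with a
#' base overlap between neighbours.  With `overlap` at least the query
#' length, every query occurrence lies wholly inside at least one scene, so
#' a scene-by-scene search cannot miss a hit that spans a tile boundary.
#' The final scene is padded with `pad_value` when the database tail does
#' not fill it.
#'
#' @param db A single DNA string.
#' @param width,height Scene dimensions in pixels; capacity is
#'   `width * height` bases (default 100 x 100 = 10,000).
#' @param overlap Number of bases shared by consecutive scenes
#'   (`0 <= overlap < width * height`); the tiling stride is
#'   `capacity - overlap`.
#' @param mapping,pad_value,ambiguity As in [encode_object()].
#' @return A list of `scene_image` objects, each with fields `pixels`
#'   (height x width matrix), `db_offset` (0-based index of the scene's
#'   first base), `scene_index` (0-based ordinal), `width`, `height`.
#' @examples
#' scenes <- tile_database(strrep("ACGT", 50), width = 10, height = 10)
#' length(scenes)  # 2 scenes of 100 bases each
#' @export
tile_database <- function(db, width = 100L, height = 100L, overlap = 0L,
                          mapping = gray_code(), pad_value = 0,
                          ambiguity = c("strict", "mask")) {
  ambiguity <- match.arg(ambiguity)
  stopifnot(is.character(db), length(db) == 1L)
  n <- nchar(db)
  if (n < 1L) stop("database is empty", call. = FALSE)
  capacity <- as.integer(width) * as.integer(height)
  overlap <- as.integer(overlap)
  if (overlap < 0L || overlap >= capacity) {
    stop("`overlap` must satisfy 0 <= overlap < width * height",
         call. = FALSE)
  }
  stride <- capacity - overlap
  offsets <- seq.int(0L, max(n - 1L, 0L), by = stride)
  ## drop offsets that only re-cover bases already inside the previous scene
  keep <- c(TRUE, offsets[-1L] + overlap < n)
  offsets <- offsets[keep]
  lut <- gray_lut(mapping)
  lapply(seq_along(offsets), function(k) {
    off <- offsets[k]
    chunk <- substr(db, off + 1L, min(off + capacity, n))
    vals <- lut[utf8ToInt(chunk) + 1L]
    if (anyNA(vals)) {
      if (ambiguity == "strict") {
        pos <- which(is.na(vals))[1L]
        stop(sprintf("symbol at database position %d is outside the A/C/G/T alphabet",
                     off + pos), call. = FALSE)
      }
      vals[is.na(vals)] <- pad_value
    }
    cells <- rep(pad_value, capacity)
    cells[seq_along(vals)] <- vals
    structure(
      list(pixels = matrix(cells, nrow = height, ncol = width, byrow = TRUE),
           db_offset = off, scene_index = k - 1L,
           width = as.integer(width), height = as.integer(height)),
      class = "scene_image")
  })
}

#' @export
print.scene_image <- function(x, ...) {
  cat(sprintf("<scene_image> #%d: %d x %d pixels, database offset %d\n",
              x$scene_index, x$height, x$width, x$db_offset))
  invisible(x)
}

#' Display an encoded image
#'
#' Renders an object or scene image in grayscale, mainly for eyeballing the
#' codification (cf. the side-by-side object/scene panels in the method's
#' illustrations).
#'
#' @param x An `object_image` or `scene_image`.
#' @param ... Passed on to [graphics::image()].
#' @export
plot.object_image <- function(x, ...) plot_gray(x$pixels, ...)

#' @rdname plot.object_image
#' @export
plot.scene_image <- function(x, ...) plot_gray(x$pixels, ...)

plot_gray <- function(px, ...) {
  ## flip rows so row 0 is drawn at the top
  m <- t(px[rev(seq_len(nrow(px))), , drop = FALSE])
  graphics::image(m, col = gray.colors(256, start = 0, end = 1),
                  axes = FALSE, asp = nrow(px) / ncol(px), ...)
  invisible(NULL)
}

#' Export an encoded image as 8-bit grayscale PNG
#'
#' @param x An `object_image` or `scene_image`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(x, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG export", call. = FALSE)
  }
  px <- if (is.matrix(x)) x else x$pixels
  png::writePNG(px / 255, target = path)
  invisible(path)
}

#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings FASTA I/O returning plain named
#' character vectors, which is the sequence representation used throughout
#' this package.
#'
#' @param path FASTA file path.
#' @return `read_fasta`: a named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))  # keep the record id only
  out
}

#' @rdname read_fasta
#' @param sequences Named character vector of sequences.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
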