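#' Nucleotide-to-gray-level mapping
#'
#' Builds the mapping used to code DNA bases as pixel intensities.  Each of
#' the four bases is assigned one 8-bit gray level; the correlator operates
#' on images built from these levels, so the mapping is the only point where
#' sequence space touches image space.
#'
#' Two presets are provided:
#' \describe{
#'   \item{`"equispaced"`}{A=0, C=85, G=170, T=255 — the unique four-level
#'     partition of \[0, 255\] with constant separation between adjacent
#'     levels, assigned in alphabetical base order.  This is the default.}
#'   \item{`"ascii"`}{A=65, C=67, G=71, T=84 — the ASCII codes of the base
#'     letters, which lets raw sequence bytes double as pixel values at the
#'     cost of compressing the dynamic range.}
#' }
#'
#' @param preset Name of a built-in mapping, or `"custom"` when `levels`
#'   is supplied.
#' @param levels Named numeric vector of four distinct gray levels in
#'   \[0, 255\] with names `A`, `C`, `G`, `T`.  Overrides `preset`.
#' @return An object of class `gray_code`: a named numeric vector of length
#'   four.
#' @examples
#' gray_code()
#' gray_code("ascii")
#' gray_code(levels = c(A = 10, C = 60, G = 110, T = 160))
#' @export
gray_code <- function(preset = c("equispaced", "ascii", "custom"),
                      levels = NULL) {
  if (is.null(levels)) {
    preset <- match.arg(preset)
    levels <- switch(preset,
      equispaced = c(A = 0, C = 85, G = 170, T = 255),
      ascii      = c(A = 65, C = 67, G = 71, T = 84),
      custom     = stop("preset \"custom\" requires `levels`", call. = FALSE)
    )
  } else {
    levels <- unlist(levels)
    if (length(levels) != 4L ||
        !setequal(names(levels), c("A", "C", "G", "T"))) {
      stop("`levels` must be a named vector with entries A, C, G, T",
           call. = FALSE)
    }
    levels <- levels[c("A", "C", "G", "T")]
    if (anyDuplicated(levels)) {
      stop("gray levels must be distinct", call. = FALSE)
    }
    if (any(levels < 0 | levels > 255)) {
      stop("gray levels must lie in [0, 255]", call. = FALSE)
    }
  }
  structure(as.numeric(levels), names = c("A", "C", "G", "T"),
            class = "gray_code")
}

#' @export
print.gray_code <- function(x, ...) {
  cat("<gray_code> base -> gray level\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

## 256-slot lookup table indexed by byte value + 1; NA for non-alphabet bytes
gray_lut <- function(mapping) {
  lut <- rep(NA_real_, 256L)
  lut[utf8ToInt(paste(names(mapping), collapse = "")) + 1L] <- as.numeric(mapping)
  ## accept lower case
  lut[utf8ToInt(tolower(paste(names(mapping), collapse = ""))) + 1L] <-
    as.numeric(mapping)
  lut
}
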