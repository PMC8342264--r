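# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Printed agreement tables in this field round percentages half-up
#' (e.g. 88.46 -> 88.5), whereas base [round()] rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
#' @examples
#' round_half_up(c(88.45, 93.75), 1)
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Scalar positive number check used by constructors.
check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
  invisible(x)
}

# A section image is a [height, width] matrix or [height, width, 3] array of
# 8-bit intensities (0..255).
section_dim <- function(img) {
  d <- dim(img)
  c(height = d[1], width = d[2])
}

section_channel <- function(img, channel = c("green", "red", "blue")) {
  channel <- match.arg(channel)
  if (length(dim(img)) == 2L) return(img)
  idx <- match(channel, c("red", "green", "blue"))
  img[, , idx]
}

# Convert a [y, x] matrix to an EBImage Image ([x, y]) and back.
as_eb <- function(mat) EBImage::Image(t(mat))
from_eb <- function(img) t(EBImage::imageData(img))

`%||%` <- function(a, b) if (is.null(a)) b else a
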