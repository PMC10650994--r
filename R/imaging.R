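# Background-removed canopy images: PNG loading, gray conversion, gradation
# arrays (256-bin intensity histograms of foreground pixels) and cumulative
# gradation curves.

CHANNELS <- c("R", "G", "B", "Y")

#' Construct a canopy image from channel matrices and a foreground mask
#'
#' @param r,g,b integer matrices (same dimensions) of 0-255 intensities.
#' @param mask logical matrix, TRUE for foreground (leaf) pixels. Defaults
#'   to all-foreground.
#' @return A `canopy_image` object.
#' @export
canopy_image <- function(r, g, b, mask = NULL) {
  stopifnot(is.matrix(r), is.matrix(g), is.matrix(b))
  if (!all(dim(r) == dim(g)) || !all(dim(r) == dim(b))) {
    stop("channel matrices must share dimensions", call. = FALSE)
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(r), ncol(r))
  stopifnot(is.logical(mask), all(dim(mask) == dim(r)))
  for (ch in list(r, g, b)) {
    v <- ch[mask]
    if (any(v < 0 | v > 255 | v != floor(v))) {
      stop("intensities must be integers in 0..255", call. = FALSE)
    }
  }
  if (!any(mask)) {
    stop("image has no foreground pixels", call. = FALSE)
  }
  structure(list(r = r, g = g, b = b, mask = mask,
                 width = ncol(r), height = nrow(r)),
            class = "canopy_image")
}

#' @export
print.canopy_image <- function(x, ...) {
  cat(sprintf("<canopy_image %dx%d, %d foreground pixels (%.1f%%)>\n",
              x$width, x$height, sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' Number of foreground pixels in a canopy image
#' @param image a [canopy_image()].
#' @return integer count.
#' @export
n_foreground <- function(image) {
  stopifnot(inherits(image, "canopy_image"))
  sum(image$mask)
}

#' Load a background-removed PNG canopy image
#'
#' The background-removal convention is an alpha mask: pixels with
#' `alpha > alpha_threshold` are foreground (leaf), the rest background.
#' A PNG without an alpha channel is treated as all-foreground.
#'
#' @param path path to a PNG file (RGB, RGBA, or gray).
#' @param alpha_threshold alpha cut on the 0-255 scale (default 0, i.e.
#'   any non-transparent pixel is foreground).
#' @return A [canopy_image()].
#' @export
load_masked_image <- function(path, alpha_threshold = 0) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  arr <- tryCatch(png::readPNG(path),
                  error = function(e) stop("not a readable PNG: ", path,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
  if (length(dim(arr)) == 2L) {            # grayscale PNG
    arr <- array(rep(arr, 3L), dim = c(dim(arr), 3L))
  }
  nch <- dim(arr)[3]
  to255 <- function(m) {
    out <- round(m * 255)
    storage.mode(out) <- "integer"
    out
  }
  r <- to255(arr[, , 1])
  g <- to255(arr[, , 2])
  b <- to255(arr[, , 3])
  if (nch >= 4L) {
    mask <- to255(arr[, , 4]) > alpha_threshold
  } else {
    mask <- matrix(TRUE, nrow(r), ncol(r))
  }
  if (!any(mask)) {
    stop("image ", path, " has no foreground pixels ",
         "(all alpha <= ", alpha_threshold, ")", call. = FALSE)
  }
  canopy_image(r, g, b, mask)
}

# Round half away from zero (the rounding used by the rgb2gray convention);
# intensities are non-negative so this is floor(x + 0.5).
round_half_away <- function(x) floor(x + 0.5)

#' Gray-level (Y) channel of a canopy image
#'
#' Luma conversion with the classic rgb2gray weights:
#' `Y = round(0.2989 R + 0.5870 G + 0.1140 B)`, rounding half away from
#' zero. This is the single supported gray dialect.
#'
#' @param image a [canopy_image()].
#' @return integer matrix of 0-255 gray intensities (full frame; apply the
#'   image mask for foreground-only values).
#' @export
gray_channel <- function(image) {
  stopifnot(inherits(image, "canopy_image"))
  y <- round_half_away(0.2989 * image$r + 0.5870 * image$g + 0.1140 * image$b)
  storage.mode(y) <- "integer"
  y
}

# Foreground intensity vector for one channel.
channel_values <- function(image, channel = c("R", "G", "B", "Y")) {
  channel <- match.arg(channel)
  m <- switch(channel, R = image$r, G = image$g, B = image$b,
              Y = gray_channel(image))
  as.integer(m[image$mask])
}

#' Gradation array: 256-bin intensity histogram of foreground pixels
#'
#' `counts[v + 1]` is the number of foreground pixels with intensity level
#' `v` (0..255) in the requested channel; background pixels are excluded
#' from all counts.
#'
#' @param image a [canopy_image()].
#' @param channel one of `"R"`, `"G"`, `"B"`, `"Y"`.
#' @return A `gradation_array`: list with `channel`, `counts` (length 256),
#'   and `n` (total foreground pixels).
#' @export
gradation_array <- function(image, channel = c("R", "G", "B", "Y")) {
  channel <- match.arg(channel)
  v <- channel_values(image, channel)
  counts <- tabulate(v + 1L, nbins = 256L)
  structure(list(channel = channel, counts = counts, n = length(v)),
            class = "gradation_array")
}

#' Cumulative gradation curve
#'
#' The cumulative relative frequency of intensity levels:
#' `curve[v + 1] = sum(counts[0..v]) / n`. Non-decreasing with final
#' value 1; this is the curve drawn in gradation cumulative histograms.
#'
#' @param g a [gradation_array()].
#' @return A `cumulative_curve`: list with `channel` and `cum_freq`
#'   (length 256 in \[0, 1\]).
#' @export
cumulative_curve <- function(g) {
  stopifnot(inherits(g, "gradation_array"))
  structure(list(channel = g$channel, cum_freq = cumsum(g$counts) / g$n),
            class = "cumulative_curve")
}

#' Export a gradation array (or cumulative curve) as a data.frame
#'
#' @param x a `gradation_array` or `cumulative_curve`.
#' @param ... unused.
#' @return data.frame with `level` (0..255) and `count` or `cum_freq`.
#' @export
as.data.frame.gradation_array <- function(x, ...) {
  data.frame(level = 0:255, count = x$counts)
}

#' @rdname as.data.frame.gradation_array
#' @export
as.data.frame.cumulative_curve <- function(x, ...) {
  data.frame(level = 0:255, cum_freq = x$cum_freq)
}

#' Write a canopy image as an RGBA PNG
#'
#' Background pixels get alpha 0, foreground alpha 1, matching the
#' background-removed convention read by [load_masked_image()].
#'
#' @param image a [canopy_image()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_canopy_png <- function(image, path) {
  stopifnot(inherits(image, "canopy_image"))
  h <- image$height; w <- image$width
  arr <- array(0, dim = c(h, w, 4))
  arr[, , 1] <- image$r / 255
  arr[, , 2] <- image$g / 255
  arr[, , 3] <- image$b / 255
  arr[, , 4] <- ifelse(image$mask, 1, 0)
  png::writePNG(arr, path)
  invisible(path)
}
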