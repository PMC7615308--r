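#' Multichannel image stack with pixel calibration
#'
#' A thin container for named 2D channels of identical shape plus the
#' micrometre-per-pixel calibration that converts pixel counts into the
#' um^2 areas reported downstream.
#'
#' @param channels named list of numeric matrices (e.g. DAPI, MINUS, PLUS,
#'   MARKER), all the same shape
#' @param pixel_size micrometres per pixel (isotropic)
#' @return an object of class `image_stack`
#' @export
image_stack <- function(channels, pixel_size) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), all(nzchar(names(channels))))
  dims <- lapply(channels, dim)
  if (!all(vapply(channels, is.matrix, logical(1))) ||
      length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("all channels must be matrices of identical shape")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("'pixel_size' must be a finite positive number")
  structure(list(channels = channels, pixel_size = pixel_size),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("image_stack: %d channel(s) [%s], %d x %d px, %.4g um/px\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1L], d[2L], x$pixel_size))
  invisible(x)
}

#' Read or write an image stack as multi-page TIFF
#'
#' Channels map to TIFF pages in the order of `channel_names`. Intensities
#' are written as 32-bit float; values outside `[0, 1]` are clipped at write
#' time (the in-memory stack is never clipped).
#'
#' @param stack an [image_stack()]
#' @param path TIFF file path
#' @return `write_image_stack()` returns `path` invisibly
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  pages <- lapply(stack$channels, function(m) pmax(pmin(m, 1), 0))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_image_stack
#' @param channel_names names for the TIFF pages, in page order
#' @param pixel_size micrometres per pixel of the stored image
#' @export
read_image_stack <- function(path, channel_names, pixel_size) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(channel_names))
    stop(sprintf("TIFF has %d page(s) but %d channel name(s) were given",
                 length(pages), length(channel_names)))
  image_stack(setNames(lapply(pages, as.matrix), channel_names), pixel_size)
}
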