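#' Imaging field container
#'
#' A `field` holds the per-channel rasters of one imaging field together with
#' its acquisition metadata. Channels are plain numeric matrices indexed
#' `[row, col]` (1-based, pixel centers at integer coordinates) and share
#' identical dimensions. Intensities are nonnegative reals on the acquisition
#' scale (default 8-bit, \[0, 255\]).
#'
#' @param channels named list of numeric matrices; conventional names are
#'   `"blue"` (DAPI), `"green"`, `"red"`, and optionally `"membrane"`.
#' @param um_per_px physical pixel size in micrometres per pixel (> 0).
#' @param field_id character identifier for the field.
#' @param group_id experimental group / condition label.
#' @param is_isotype logical; `TRUE` for an isotype-control field.
#'
#' @return an object of class `field`.
#' @export
field <- function(channels, um_per_px, field_id = "field", group_id = NA_character_,
                  is_isotype = FALSE) {
  if (!is.list(channels) || is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("`channels` must be a named list of matrices")
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1L)
    stop("all channels must share identical dimensions")
  if (!is.numeric(um_per_px) || length(um_per_px) != 1L || um_per_px <= 0)
    stop("`um_per_px` must be a single positive number")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.matrix(ch) || !is.numeric(ch))
      stop(sprintf("channel '%s' is not a numeric matrix", nm))
    if (any(ch < 0)) stop(sprintf("channel '%s' contains negative intensities", nm))
  }
  structure(
    list(channels = channels, um_per_px = um_per_px, field_id = field_id,
         group_id = group_id, is_isotype = isTRUE(is_isotype)),
    class = "field"
  )
}

#' @export
print.field <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<field '%s'> %d x %d px, %.3g um/px, channels: %s%s\n",
              x$field_id, d[1], d[2], x$um_per_px,
              paste(names(x$channels), collapse = ", "),
              if (x$is_isotype) " [isotype]" else ""))
  invisible(x)
}

#' @export
dim.field <- function(x) dim(x$channels[[1]])

#' Split an RGB raster (or named channel stack) into a field
#'
#' Maps the blue plane of an RGB image to the DAPI channel, as done when
#' nuclei are isolated from an RGB export of a confocal image. For grayscale
#' stacks a `channel_map` naming each plane is required.
#'
#' @param image either a 3-d numeric array `[row, col, 3]` (RGB order) or a
#'   named list of 2-d matrices.
#' @param um_per_px micrometres per pixel.
#' @param channel_map for array input, a character vector naming the planes in
#'   order (default `c("red", "green", "blue")`); required for unnamed input.
#' @param ... passed on to [field()] (`field_id`, `group_id`, `is_isotype`).
#'
#' @return a [field()] whose `"blue"` channel is the DAPI plane.
#' @export
split_channels <- function(image, um_per_px, channel_map = NULL, ...) {
  if (is.list(image)) {
    if (is.null(names(image)) || any(!nzchar(names(image))))
      stop("grayscale channel list requires channel names (channel map missing)")
    return(field(image, um_per_px, ...))
  }
  if (!is.array(image) || length(dim(image)) != 3L)
    stop("`image` must be a [row, col, channel] array or a named list of matrices")
  nch <- dim(image)[3]
  if (is.null(channel_map)) {
    if (nch != 3L)
      stop(sprintf("expected 3 channels (RGB), got %d and no channel map", nch))
    channel_map <- c("red", "green", "blue")
  }
  if (length(channel_map) != nch)
    stop("channel map length does not match channel count")
  chans <- stats::setNames(
    lapply(seq_len(nch), function(k) image[, , k, drop = TRUE]),
    channel_map
  )
  field(chans, um_per_px, ...)
}

#' Write a field to disk
#'
#' Writes one grayscale TIFF per channel (`<prefix>_<channel>.tif`, 8-bit
#' after clipping to `max_intensity`) and, when red/green/blue channels are
#' all present, an RGB PNG composite (`<prefix>_rgb.png`).
#'
#' @param x a [field()].
#' @param prefix path prefix (directory must exist).
#' @param max_intensity intensity mapped to white (default 255).
#' @return invisibly, the character vector of files written.
#' @export
write_field <- function(x, prefix, max_intensity = 255) {
  stopifnot(inherits(x, "field"))
  files <- character(0)
  for (nm in names(x$channels)) {
    f <- paste0(prefix, "_", nm, ".tif")
    tiff::writeTIFF(pmin(x$channels[[nm]] / max_intensity, 1), f,
                    bits.per.sample = 8L)
    files <- c(files, f)
  }
  if (all(c("red", "green", "blue") %in% names(x$channels))) {
    d <- dim(x$channels[[1]])
    rgb <- array(0, c(d, 3L))
    rgb[, , 1] <- pmin(x$channels$red   / max_intensity, 1)
    rgb[, , 2] <- pmin(x$channels$green / max_intensity, 1)
    rgb[, , 3] <- pmin(x$channels$blue  / max_intensity, 1)
    f <- paste0(prefix, "_rgb.png")
    png::writePNG(rgb, f)
    files <- c(files, f)
  }
  invisible(files)
}

#' Read a field written by [write_field()]
#'
#' @param prefix path prefix used when writing.
#' @param channels channel names to read.
#' @param um_per_px micrometres per pixel of the acquisition.
#' @param max_intensity intensity scale to restore (default 255).
#' @param ... passed on to [field()].
#' @return a [field()].
#' @export
read_field <- function(prefix, channels = c("blue", "green", "red"), um_per_px,
                       max_intensity = 255, ...) {
  chans <- stats::setNames(lapply(channels, function(nm) {
    f <- paste0(prefix, "_", nm, ".tif")
    if (!file.exists(f)) stop(sprintf("channel file not found: %s", f))
    m <- tiff::readTIFF(f)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m * max_intensity
  }), channels)
  field(chans, um_per_px, ...)
}
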