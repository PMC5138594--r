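## Photographic edge-profile transects.
##
## To characterise edge enhancement in animal photographs, intensities are
## linearised (inverting a display gamma of 2.2) and sampled along a line
## crossing a pattern boundary, averaging all three channels over a small
## disc at each sample. Edge-enhanced boundaries show an overshoot /
## undershoot pair flanking the step.

#' Linearise 8-bit image intensities
#'
#' Maps each channel value v to `(v/255)^2.2` (equivalently `v^2.2` for
#' images already scaled to [0, 1], as returned by [read_image()]).
#'
#' @param image numeric array or matrix; values in [0, 255] (8-bit) or
#'   [0, 1].
#' @return array of linearised intensities in [0, 1].
#' @export
linearize <- function(image) {
  stopifnot(is.numeric(image))
  if (max(image) > 1) image <- image / 255
  image^2.2
}

#' Read a raster image
#'
#' Reads PNG (always) or TIFF (if the tiff package is installed) into a
#' numeric array scaled to [0, 1].
#'
#' @param path image path.
#' @return numeric array (`h x w` or `h x w x channels`).
#' @export
read_image <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("read_image: reading TIFF requires the tiff package")
    }
    return(tiff::readTIFF(path))
  }
  png::readPNG(path)
}

## Integer (dy, dx) offsets of pixel centres within Euclidean radius
## diameter/2 of the disc centre.
disc_offsets <- function(diameter) {
  r <- diameter / 2
  k <- floor(r)
  g <- expand.grid(dy = -k:k, dx = -k:k)
  g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
}

#' Disc-averaged luminance transect
#'
#' Samples the linearised image at 1-px steps along the segment from
#' `start` to `end` (both `c(x, y)` in pixel coordinates, x = column,
#' y = row). Each sample is the mean over all channels of every pixel whose
#' centre lies within `diameter/2` of the sample point (nearest-pixel disc
#' centres, no interpolation). Discs reaching past the image border are
#' truncated and the profile is flagged.
#'
#' @param image a linearised image (matrix or `h x w x 3` array, values in
#'   [0, 1]); see [linearize()].
#' @param start,end segment endpoints `c(x, y)`, inside the image.
#' @param diameter averaging-disc diameter in px (odd).
#' @return a `transect_profile` data frame with columns `position` (px along
#'   the segment) and `intensity` (in [0, 1]), and attribute `truncated`
#'   (logical: did any disc leave the image?).
#' @export
transect_profile <- function(image, start, end, diameter = 7) {
  stopifnot(length(start) == 2, length(end) == 2, diameter >= 1)
  if (diameter %% 2 != 1) stop("transect_profile: diameter must be odd")
  if (length(dim(image)) == 2) {
    image <- array(image, dim = c(dim(image), 1))
  }
  h <- dim(image)[1]; w <- dim(image)[2]; nc <- dim(image)[3]
  inside <- function(p) p[1] >= 1 && p[1] <= w && p[2] >= 1 && p[2] <= h
  if (!inside(start) || !inside(end)) {
    stop("transect_profile: transect endpoints must lie inside the image")
  }
  len <- sqrt(sum((end - start)^2))
  n <- floor(len) + 1
  ts <- if (n == 1) 0 else (seq_len(n) - 1) / (n - 1)
  off <- disc_offsets(diameter)
  truncated <- FALSE
  intensity <- vapply(ts, function(t) {
    cx <- round(start[1] + t * (end[1] - start[1]))
    cy <- round(start[2] + t * (end[2] - start[2]))
    ys <- cy + off$dy; xs <- cx + off$dx
    keep <- ys >= 1 & ys <= h & xs >= 1 & xs <= w
    if (!all(keep)) truncated <<- TRUE
    mean(image[cbind(rep(ys[keep], nc), rep(xs[keep], nc),
                     rep(seq_len(nc), each = sum(keep)))])
  }, numeric(1))
  structure(data.frame(position = ts * len, intensity = intensity),
            truncated = truncated, class = c("transect_profile",
                                             "data.frame"))
}

#' Write a transect profile as CSV
#'
#' @param profile a `transect_profile`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_transect <- function(profile, path) {
  write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' @export
plot.transect_profile <- function(x, ...) {
  plot(x$position, x$intensity, type = "l", xlab = "position (px)",
       ylab = "linearised intensity", ylim = c(0, 1), ...)
  invisible(x)
}
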