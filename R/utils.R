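## Shared helpers: angular scale, seeding, gamma encoding, raster IO.

#' Pixel / visual-angle conversion
#'
#' The large-screen experiments use a fixed small-angle scale of
#' 20 px = 0.62 degrees of visual angle (0.031 deg/px); the monitor-based
#' depth-judgement experiment uses 350 px = 13.30 degrees. Conversions are
#' linear in this regime.
#'
#' @param px,deg values to convert.
#' @param px_per_deg pixels per degree of visual angle; defaults to the
#'   large-screen scale `20 / 0.62`.
#' @return converted numeric vector.
#' @examples
#' px_to_deg(16)  # 0.496 -> prints as 0.50 deg
#' px_to_deg(8)   # 0.248 -> 0.25 deg
#' @export
px_to_deg <- function(px, px_per_deg = exp1_px_per_deg()) {
  stopifnot(px_per_deg > 0)
  px / px_per_deg
}

#' @rdname px_to_deg
#' @export
deg_to_px <- function(deg, px_per_deg = exp1_px_per_deg()) {
  stopifnot(px_per_deg > 0)
  deg * px_per_deg
}

#' @rdname px_to_deg
#' @export
exp1_px_per_deg <- function() 20 / 0.62

#' @rdname px_to_deg
#' @export
exp3_px_per_deg <- function() 350 / 13.30

## Evaluate `expr` under `seed` without disturbing the caller's RNG stream;
## seed = NULL uses the current stream.
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

## sRGB transfer functions (IEC 61966-2-1), linear <-> gamma-encoded.
srgb_encode <- function(x) {
  x <- clip01(x)
  ifelse(x <= 0.0031308, 12.92 * x, 1.055 * x^(1 / 2.4) - 0.055)
}

srgb_decode <- function(x) {
  ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
}

#' Write a scene to PNG with a JSON sidecar
#'
#' Linear-RGB canvases are gamma-encoded with the sRGB transfer function and
#' written as 8-bit PNG. Generation parameters passed in `meta` are echoed to
#' `<path>.json` so every image is reproducible from its sidecar.
#'
#' @param canvas a [scene_canvas()] (or bare `h x w x 3` linear-RGB array).
#' @param path output PNG path.
#' @param meta named list of parameters to record; `NULL` skips the sidecar.
#' @return `path`, invisibly.
#' @export
write_scene_png <- function(canvas, path, meta = NULL) {
  px <- if (is.list(canvas)) canvas$pixels else canvas
  png::writePNG(srgb_encode(px), path)
  if (!is.null(meta)) {
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}
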