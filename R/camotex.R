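## Disruptive camouflage textures.
##
## The pattern is white noise band-pass filtered in the Fourier domain,
## posterised at its median into a dark and a light patch colour, and
## optionally edge-enhanced: a luminance ramp from the patch colour towards
## the most-contrasting value at the patch boundary, parameterised by an
## offset (delta CIE-L) and a width (px). The points where light and dark
## patches meet are then the regions of highest contrast.

#' Band-pass filter specification
#'
#' The radial amplitude filter applied to white noise in the Fourier domain:
#' `A(d) = exp(-(d - mu)^2 / (2 * bandwidth^2))` with `d` the radial spatial
#' frequency in cycles/px. The spectral centre `mu = 0.048` cycles/px puts
#' the pass-band peak wavelength at `1/mu ~ 21` px, the scale of the leaf
#' pattern. `sigma` is the width parameter as originally printed and is kept
#' verbatim as metadata; it maps to the working bandwidth through the
#' documented default rule `bandwidth = 3 / (2 * sigma)` (0.0125 cycles/px
#' for sigma = 120), calibrated once so that the posterised patch breadth
#' matches the pass-band wavelength while DC leakage stays negligible.
#' Supply `bandwidth` directly to override the rule.
#'
#' @param mu spectral centre, cycles/px.
#' @param sigma stored width parameter (dimensionless, metadata).
#' @param bandwidth Gaussian half-width of the amplitude filter, cycles/px;
#'   `NULL` applies the default mapping rule.
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(mu = 0.048, sigma = 120, bandwidth = NULL) {
  stopifnot(mu > 0, sigma > 0)
  if (is.null(bandwidth)) bandwidth <- 3 / (2 * sigma)
  stopifnot(bandwidth > 0)
  structure(list(mu = mu, sigma = sigma, bandwidth = bandwidth),
            class = "filter_spec")
}

#' @rdname filter_spec
#' @param filt a `filter_spec`.
#' @param d radial spatial frequency, cycles/px.
#' @return `filter_amplitude()`: the filter's amplitude at `d`.
#' @export
filter_amplitude <- function(filt, d) {
  stopifnot(inherits(filt, "filter_spec"))
  exp(-(d - filt$mu)^2 / (2 * filt$bandwidth^2))
}

## FFT frequency coordinates in cycles/px for an n-point axis.
fft_freq <- function(n) ifelse(0:(n - 1) <= n / 2, 0:(n - 1), 0:(n - 1) - n) / n

#' Generate band-pass filtered noise
#'
#' White Gaussian noise is transformed to the Fourier domain, multiplied by
#' the radial amplitude filter, and transformed back; the result is centred
#' to mean zero. Its radially averaged amplitude spectrum peaks at the
#' filter's spectral centre.
#'
#' @param shape `c(height, width)` in px, both >= 64.
#' @param filt a [filter_spec()].
#' @param seed optional integer seed.
#' @return a real-valued `height x width` matrix with mean 0.
#' @export
bandpass_noise <- function(shape, filt = filter_spec(), seed = NULL) {
  stopifnot(length(shape) == 2, inherits(filt, "filter_spec"))
  h <- shape[1]; w <- shape[2]
  if (h < 64 || w < 64) {
    stop("bandpass_noise: image must be at least 64 x 64 px")
  }
  with_seed_or_not(seed, {
    z <- matrix(rnorm(h * w), h, w)
    fx <- matrix(rep(fft_freq(w), each = h), h, w)
    fy <- matrix(rep(fft_freq(h), times = w), h, w)
    A <- filter_amplitude(filt, sqrt(fx^2 + fy^2))
    out <- Re(fft(fft(z) * A, inverse = TRUE)) / (h * w)
    out - mean(out)
  })
}

#' Distance to the patch boundary
#'
#' Per-pixel Euclidean distance to the nearest opposite-label pixel, minus
#' the one-pixel boundary offset, so pixels immediately adjacent to the
#' other patch sit at distance 0. This is the coordinate along which the
#' edge-enhancement luminance ramp runs.
#'
#' @param labels binary matrix (0/1 or logical); both classes must be
#'   present.
#' @return numeric matrix of distances, >= 0.
#' @export
boundary_distance <- function(labels) {
  lab <- matrix(as.numeric(labels), nrow(labels), ncol(labels))
  if (all(lab == lab[1])) {
    stop("boundary_distance: both patch classes must be present")
  }
  ## distmap gives, for each non-zero pixel, the Euclidean distance to the
  ## nearest zero pixel; summing both polarities covers every pixel.
  d_opp <- EBImage::distmap(lab, metric = "euclidean") +
    EBImage::distmap(1 - lab, metric = "euclidean")
  pmax(as.matrix(d_opp) - 1, 0)
}

#' Posterise a texture into two patch colours
#'
#' Thresholds the texture at its median: values at or below the median take
#' the dark colour, values above take the light colour (ties go to dark, so
#' the split is deterministic). On grids with an even pixel count and no
#' ties each class holds exactly 50% of the pixels.
#'
#' @param tex real-valued matrix (e.g. from [bandpass_noise()]).
#' @param dark,light [lab_color()]s for the two patches.
#' @return list with `patch_map` (list of `labels` 0/1 matrix, 1 = light,
#'   and `dist`, the [boundary_distance()] map) and `lab`, the
#'   `h x w x 3` posterised CIE-LAB image.
#' @export
posterise <- function(tex, dark, light) {
  stopifnot(is.matrix(tex), inherits(dark, "lab_color"),
            inherits(light, "lab_color"))
  if (max(tex) == min(tex)) {
    stop("posterise: degenerate texture (constant image)")
  }
  labels <- matrix(as.numeric(tex > median(tex)), nrow(tex), ncol(tex))
  pm <- list(labels = labels, dist = boundary_distance(labels))
  lab <- array(0, dim = c(nrow(tex), ncol(tex), 3))
  for (ch in 1:3) {
    lab[, , ch] <- ifelse(labels == 1, light[ch], dark[ch])
  }
  list(patch_map = pm, lab = lab)
}

#' Patch breadth of a posterised pattern
#'
#' The dominant spatial period of the two-tone pattern, measured as twice
#' the median chord (run) length over all rows and columns: one dark plus
#' one light chord make up a full period, which for a narrow-band texture
#' equals the pass-band wavelength `1/mu`.
#'
#' @param labels binary matrix.
#' @return breadth in px.
#' @export
patch_breadth <- function(labels) {
  runs <- c(unlist(apply(labels, 1, function(v) rle(v)$lengths)),
            unlist(apply(labels, 2, function(v) rle(v)$lengths)))
  2 * median(runs)
}

#' Edge-enhancement profile
#'
#' The two-parameter edge-enhancement model: at the boundary between
#' patches, lightness moves from the patch value towards the
#' most-contrasting value, by `offset` CIE-L units, over `width` px.
#' Variants: `"both"` ramps light patches up and dark patches down;
#' `"no_low"` ramps only the light patches (no dark band); `"no_high"` ramps
#' only the dark patches (no light band); `"square"` applies the full offset
#' as a constant band with no gradient; `"none"` leaves the pattern
#' untouched.
#'
#' @param variant one of `"none"`, `"both"`, `"no_low"`, `"no_high"`,
#'   `"square"`.
#' @param offset luminance offset, CIE-L units (>= 0).
#' @param width ramp width, px (>= 1 for non-none variants).
#' @return an `edge_profile` list.
#' @export
edge_profile <- function(variant = c("none", "both", "no_low", "no_high",
                                     "square"),
                         offset = 0, width = 1) {
  variant <- match.arg(variant)
  stopifnot(offset >= 0)
  if (variant != "none" && width < 1) {
    stop("edge_profile: width must be >= 1 px for variant '", variant, "'")
  }
  structure(list(variant = variant, offset = offset, width = width),
            class = "edge_profile")
}

#' Apply edge enhancement to a posterised pattern
#'
#' Modifies only the L channel; A and B keep the patch colour everywhere.
#' For ramp variants L changes linearly from the full offset at the patch
#' boundary (distance 0) back to the patch value at `dist >= width`:
#' `L(dist) = patch_L +/- offset * max(0, 1 - dist / width)`. Light patches
#' move up (+offset), dark patches down (-offset), per variant. The
#' `"square"` variant applies the constant `patch_L +/- offset` wherever
#' `dist < width`. L is clipped to [0, 100]; clipping sets the
#' `"gamut_clipped"` attribute rather than failing.
#'
#' @param pm a patch map (list with `labels` and `dist`) from [posterise()].
#' @param dark,light the patch [lab_color()]s.
#' @param prof an [edge_profile()].
#' @return `h x w x 3` CIE-LAB array with attribute `gamut_clipped`
#'   (logical scalar).
#' @export
apply_edge_enhancement <- function(pm, dark, light, prof) {
  stopifnot(is.list(pm), !is.null(pm$labels), !is.null(pm$dist),
            inherits(prof, "edge_profile"))
  labels <- pm$labels; dist <- pm$dist
  is_light <- labels == 1
  L <- ifelse(is_light, light["L"], dark["L"])
  ramp <- pmax(0, 1 - dist / prof$width)
  delta <- switch(prof$variant,
    none = 0,
    both = ifelse(is_light, prof$offset, -prof$offset) * ramp,
    no_low = ifelse(is_light, prof$offset * ramp, 0),
    no_high = ifelse(is_light, 0, -prof$offset * ramp),
    square = ifelse(dist < prof$width,
                    ifelse(is_light, prof$offset, -prof$offset), 0))
  Lnew <- L + delta
  clipped <- any(Lnew < 0 | Lnew > 100)
  Lnew <- pmin(pmax(Lnew, 0), 100)
  out <- array(0, dim = c(nrow(labels), ncol(labels), 3))
  out[, , 1] <- Lnew
  out[, , 2] <- ifelse(is_light, light["A"], dark["A"])
  out[, , 3] <- ifelse(is_light, light["B"], dark["B"])
  attr(out, "gamut_clipped") <- clipped
  out
}

#' Rasterise a snake-shaped target mask
#'
#' A sinusoidal tube: the body centre line undulates through `periods` full
#' sine cycles along the major axis, with body width a fixed fraction of the
#' length and elliptically tapered ends. Only the length and the overall
#' snake-like silhouette are constrained by the stimulus design; the tube
#' realises them with a single connected component whose major-axis extent
#' equals `length` within a pixel.
#'
#' @param length extent along the major axis, px.
#' @param orientation rotation in radians (0 = horizontal).
#' @param width_frac body width as a fraction of length.
#' @param periods number of undulation cycles.
#' @param amp_frac undulation amplitude as a fraction of length.
#' @return logical mask matrix, tightly cropped, snake centred.
#' @export
snake_mask <- function(length = 350, orientation = 0, width_frac = 0.12,
                       periods = 2, amp_frac = 0.04) {
  stopifnot(length >= 20, width_frac > 0, width_frac < 1)
  W <- width_frac * length
  A <- amp_frac * length
  rasterize_profile(length, A + W / 2, orientation,
    half_width_fun = function(xp) {
      t <- pmin(pmax(2 * xp / length, -1), 1)
      (W / 2) * sqrt(pmax(0, 1 - t^2))
    },
    center_fun = function(xp) A * sin(2 * pi * periods * xp / length))
}

#' Generate a camouflaged snake target
#'
#' Draws the two patch colours from the population, synthesises a band-pass
#' noise texture over the snake's bounding box, posterises it, applies edge
#' enhancement, and crops the result to a snake-shaped mask.
#'
#' @param pop a filtered [color_population()].
#' @param rule a [patch_color_rule()].
#' @param filt a [filter_spec()].
#' @param prof an [edge_profile()].
#' @param length snake length along its major axis, px.
#' @param orientation rotation in radians.
#' @param seed optional integer seed; the target is seed-deterministic.
#' @return list with `mask` (logical matrix), `lab` (the edge-enhanced
#'   CIE-LAB texture, same size as `mask`), `colors` (the sampled dark and
#'   light [lab_color()]s) and `prof`.
#' @export
make_target <- function(pop, rule = patch_color_rule(),
                        filt = filter_spec(), prof = edge_profile(),
                        length = 350, orientation = 0, seed = NULL) {
  with_seed_or_not(seed, {
    cols <- sample_patch_colors(pop, rule)
    mask <- snake_mask(length, orientation)
    shape <- pmax(dim(mask), 64)
    tex <- bandpass_noise(shape, filt)[seq_len(nrow(mask)),
                                       seq_len(ncol(mask)), drop = FALSE]
    post <- posterise(tex, cols$dark, cols$light)
    lab <- apply_edge_enhancement(post$patch_map, cols$dark, cols$light, prof)
    list(mask = mask, lab = lab, colors = cols, prof = prof)
  })
}

## Pixel bounds (x0, x1, y0, y1) of grid cell `cell` on a 4-column x 2-row
## partition of the canvas.
cell_bounds <- function(canvas, cell) {
  stopifnot(cell %in% 1:8)
  col <- (cell - 1) %% 4
  row <- (cell - 1) %/% 4
  cw <- canvas$width / 4; chh <- canvas$height / 2
  c(x0 = floor(col * cw) + 1, x1 = floor((col + 1) * cw),
    y0 = floor(row * chh) + 1, y1 = floor((row + 1) * chh))
}

#' Composite a target into a background scene
#'
#' Copies the target's texture onto the background wherever its mask is set
#' (no blending), at a uniformly random position inside the requested grid
#' cell (the canvas is divided into 8 equal rectangles, 4 columns x 2 rows),
#' or centred when `cell = 0`.
#'
#' @param bg a rendered [scene_canvas()].
#' @param target a target from [make_target()].
#' @param cell region index 1-8, or 0 for centre placement.
#' @param seed optional integer seed for the placement.
#' @return a `stimulus_image`: list with `canvas`, `target_bbox`
#'   (`c(x0, x1, y0, y1)`), `target_cell` and `condition` (the target's
#'   [edge_profile()]).
#' @export
compose_stimulus <- function(bg, target, cell = 0, seed = NULL) {
  stopifnot(inherits(bg, "scene_canvas"))
  mh <- nrow(target$mask); mw <- ncol(target$mask)
  b <- if (cell == 0) c(1, bg$width, 1, bg$height)
       else unname(cell_bounds(bg, cell))
  if (mw > b[2] - b[1] + 1 || mh > b[4] - b[3] + 1) {
    stop("compose_stimulus: target (", mw, " x ", mh,
         " px) does not fit inside cell ", cell)
  }
  pos <- with_seed_or_not(seed, {
    if (cell == 0) {
      c(x = floor((b[1] + b[2] - mw) / 2), y = floor((b[3] + b[4] - mh) / 2))
    } else {
      c(x = b[1] + sample.int(b[2] - b[1] - mw + 2, 1) - 1,
        y = b[3] + sample.int(b[4] - b[3] - mh + 2, 1) - 1)
    }
  })
  rgb <- lab_to_display(cbind(as.vector(target$lab[, , 1]),
                              as.vector(target$lab[, , 2]),
                              as.vector(target$lab[, , 3])))
  px <- bg$pixels
  idx <- which(target$mask, arr.ind = TRUE)
  rows <- pos["y"] + idx[, 1] - 1
  cols <- pos["x"] + idx[, 2] - 1
  flat <- (idx[, 2] - 1) * mh + idx[, 1]
  for (ch in 1:3) px[cbind(rows, cols, ch)] <- rgb[flat, ch]
  bg$pixels <- px
  structure(list(canvas = bg,
                 target_bbox = c(x0 = unname(pos["x"]),
                                 x1 = unname(pos["x"]) + mw - 1,
                                 y0 = unname(pos["y"]),
                                 y1 = unname(pos["y"]) + mh - 1),
                 target_cell = cell,
                 condition = target$prof),
            class = "stimulus_image")
}
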