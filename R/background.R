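## Leaf-litter background scenes.
##
## Scenes are built by sequentially stamping randomly oriented leaf-shaped
## masks at random locations; later stamps occlude earlier ones, and each
## leaf may first cast a flat multiplicative shadow to its left, as if the
## scene were lit from over the viewer's right shoulder.

#' Leaf-size distribution parameters
#'
#' Leaf lengths follow a positively skewed distribution with a hard minimum
#' of 20 px, a mode of 21 px and a 95th percentile of 46 px; widths are
#' roughly 20% of a length drawn from the same distribution.
#'
#' @param min_len hard minimum length, px.
#' @param mode_len modal length, px.
#' @param p95_len 95th-percentile length, px.
#' @param width_fraction leaf width as a fraction of length.
#' @return a `leaf_shape_params` list.
#' @export
leaf_shape_params <- function(min_len = 20, mode_len = 21, p95_len = 46,
                              width_fraction = 0.2) {
  stopifnot(min_len <= mode_len, mode_len < p95_len,
            width_fraction > 0, width_fraction < 1)
  structure(list(min_len = min_len, mode_len = mode_len, p95_len = p95_len,
                 width_fraction = width_fraction),
            class = "leaf_shape_params")
}

## Calibrate the shifted gamma realising (min, mode, p95): the shift is the
## hard minimum, the mode pins (shape - 1) * scale = mode - min, and the p95
## constraint is solved for the shape by uniroot.
leaf_gamma <- function(params) {
  m <- params$mode_len - params$min_len
  q <- params$p95_len - params$min_len
  f <- function(k) qgamma(0.95, k, scale = m / (k - 1)) - q
  k <- uniroot(f, c(1 + 1e-6, 50), tol = 1e-10)$root
  list(shape = k, scale = m / (k - 1))
}

#' Sample leaf lengths
#'
#' Draws from the calibrated shifted-gamma length distribution (see
#' [leaf_shape_params()]); all draws are `>= min_len`.
#'
#' @param n number of lengths to draw.
#' @param params a [leaf_shape_params()].
#' @param seed optional integer seed.
#' @return numeric vector of lengths in px.
#' @export
sample_leaf_length <- function(n = 1, params = leaf_shape_params(),
                               seed = NULL) {
  stopifnot(inherits(params, "leaf_shape_params"))
  g <- leaf_gamma(params)
  with_seed_or_not(seed,
    params$min_len + rgamma(n, shape = g$shape, scale = g$scale))
}

#' Shadow model parameters
#'
#' Shadow widths are drawn as the absolute value of a normal with mean 2.4 px
#' and SD 3 px; the shadowed area has its linear intensity reduced by the
#' darkening fraction (default 0.70, i.e. shadow pixels keep 30% of their
#' unshadowed value).
#'
#' @param width_mean,width_sd parameters of the underlying normal, px.
#' @param darkening fraction of linear intensity removed, in [0, 1].
#' @return a `shadow_spec` list.
#' @export
shadow_spec <- function(width_mean = 2.4, width_sd = 3, darkening = 0.70) {
  stopifnot(width_sd > 0, darkening >= 0, darkening <= 1)
  structure(list(width_mean = width_mean, width_sd = width_sd,
                 darkening = darkening), class = "shadow_spec")
}

#' Sample shadow widths
#'
#' @param n number of widths.
#' @param spec a [shadow_spec()].
#' @param seed optional integer seed.
#' @return numeric vector of non-negative widths in px.
#' @export
sample_shadow_width <- function(n = 1, spec = shadow_spec(), seed = NULL) {
  stopifnot(inherits(spec, "shadow_spec"))
  with_seed_or_not(seed, abs(rnorm(n, spec$width_mean, spec$width_sd)))
}

#' Allocate a scene canvas
#'
#' A linear-RGB raster plus its pixel/degree scale. The default size is the
#' large-screen search field: 3500 x 1170 px at 20 px = 0.62 deg, on which
#' the 350-px target spans a tenth of the long axis.
#'
#' @param width,height canvas size in px.
#' @param px_per_deg pixels per degree of visual angle.
#' @param fill initial linear-RGB fill value(s), length 1 or 3, in [0, 1].
#' @return a `scene_canvas`: list with `pixels` (`height x width x 3` array),
#'   `width`, `height`, `px_per_deg`.
#' @export
scene_canvas <- function(width = 3500, height = 1170,
                         px_per_deg = exp1_px_per_deg(), fill = 0.5) {
  stopifnot(width >= 1, height >= 1, px_per_deg > 0,
            all(fill >= 0 & fill <= 1), length(fill) %in% c(1, 3))
  px <- array(rep(fill, each = width * height), dim = c(height, width, 3))
  structure(list(pixels = px, width = width, height = height,
                 px_per_deg = px_per_deg), class = "scene_canvas")
}

#' @export
print.scene_canvas <- function(x, ...) {
  cat(sprintf("<scene_canvas> %d x %d px (%.2f x %.2f deg)\n", x$width,
              x$height, x$width / x$px_per_deg, x$height / x$px_per_deg))
  invisible(x)
}

## Rasterise a shape given in its own (x', y') frame, rotated by `orientation`
## radians. `half_width_fun(xp)` returns the half-width of the shape at
## signed position xp along the major axis (NA/negative outside). Returns a
## logical mask matrix (rows = y, cols = x) tightly cropped to the rotated
## bounding box, with the shape centre at its centre.
rasterize_profile <- function(len, max_half_width, orientation,
                              half_width_fun, center_fun = function(xp) 0) {
  co <- cos(orientation); si <- sin(orientation)
  hw <- ceiling(abs(co) * len / 2 + abs(si) * max_half_width) + 1
  hh <- ceiling(abs(si) * len / 2 + abs(co) * max_half_width) + 1
  xs <- seq(-hw, hw); ys <- seq(-hh, hh)
  x <- matrix(rep(xs, each = length(ys)), nrow = length(ys))
  y <- matrix(rep(ys, times = length(xs)), nrow = length(ys))
  xp <- x * co + y * si
  yp <- -x * si + y * co
  b <- half_width_fun(xp)
  mask <- abs(xp) <= len / 2 & !is.na(b) & b > 0 &
    abs(yp - center_fun(xp)) <= b
  mask
}

#' Rasterise a leaf-shaped mask
#'
#' Leaves are pointed lenses: the half-width profile is
#' `(width/2) * (1 - (2x/length)^2)`, a parabolic lens that is widest at the
#' centre and pointed at both tips, then rotated to the requested
#' orientation.
#'
#' @param length leaf length along the major axis, px (>= 2).
#' @param width leaf width, px (>= 1).
#' @param orientation rotation in radians.
#' @return logical mask matrix (rows = y, cols = x), tightly cropped, with
#'   the leaf centred.
#' @export
leaf_mask <- function(length, width, orientation = 0) {
  if (length < 2 || width < 1) {
    stop("leaf_mask: degenerate size (need length >= 2, width >= 1)")
  }
  rasterize_profile(length, width / 2, orientation,
                    function(xp) (width / 2) * (1 - (2 * xp / length)^2))
}

## Stamp `rgb` (length-3 linear colour) through `mask` centred at (cx, cy)
## on the canvas pixel array; returns modified array. `painted` is updated
## by reference semantics via the returned list.
stamp_mask <- function(px, mask, cx, cy, rgb = NULL, scale = NULL) {
  h <- dim(px)[1]; w <- dim(px)[2]
  mh <- nrow(mask); mw <- ncol(mask)
  y0 <- round(cy) - (mh + 1) %/% 2; x0 <- round(cx) - (mw + 1) %/% 2
  ys <- (y0 + 1):(y0 + mh); xs <- (x0 + 1):(x0 + mw)
  iy <- ys >= 1 & ys <= h; ix <- xs >= 1 & xs <= w
  if (!any(iy) || !any(ix)) return(list(px = px, hit = NULL))
  sub <- mask[iy, ix, drop = FALSE]
  if (!any(sub)) return(list(px = px, hit = NULL))
  ry <- ys[iy]; rx <- xs[ix]
  idx <- which(sub, arr.ind = TRUE)
  rows <- ry[idx[, 1]]; cols <- rx[idx[, 2]]
  for (ch in 1:3) {
    lin <- cbind(rows, cols, ch)
    if (!is.null(rgb)) px[lin] <- rgb[ch]
    if (!is.null(scale)) px[lin] <- px[lin] * scale
  }
  list(px = px, hit = cbind(rows, cols))
}

#' Render a leaf-litter background
#'
#' Sequentially stamps `n_leaves` randomly oriented, randomly coloured leaf
#' masks at uniform random positions; later leaves occlude earlier ones.
#' With `shadows = TRUE` each leaf first darkens the region to its left
#' (its own silhouette translated left by a sampled shadow width, minus the
#' leaf itself) by the shadow darkening fraction, then is stamped on top.
#'
#' @param canvas a [scene_canvas()].
#' @param n_leaves number of leaf stamps (0 returns the canvas unchanged).
#' @param pop a filtered [color_population()] supplying leaf colours.
#' @param shadows logical; cast leftward shadows?
#' @param spec a [shadow_spec()].
#' @param leaf_params a [leaf_shape_params()].
#' @param keepout optional numeric `c(x0, x1, y0, y1)`: leaves whose mask
#'   would touch this rectangle are skipped (used for the leaf-free band
#'   around the depth-judgement target).
#' @param seed optional integer seed; the render is bit-reproducible.
#' @return the canvas with leaves stamped; attribute `"painted"` is a logical
#'   matrix marking every pixel ever covered by a leaf (not shadows), and
#'   attribute `"n_stamped"` counts leaves actually drawn.
#' @export
render_background <- function(canvas, n_leaves, pop, shadows = FALSE,
                              spec = shadow_spec(),
                              leaf_params = leaf_shape_params(),
                              keepout = NULL, seed = NULL) {
  stopifnot(inherits(canvas, "scene_canvas"),
            inherits(pop, "color_population"))
  if (n_leaves < 0) stop("render_background: n_leaves must be >= 0")
  if (n_leaves == 0) return(canvas)
  g <- leaf_gamma(leaf_params)
  painted <- matrix(FALSE, canvas$height, canvas$width)
  px <- canvas$pixels
  rgb_pop <- lab_to_display(as.data.frame(pop)[, c("L", "A", "B")])
  n_stamped <- 0L
  px <- with_seed_or_not(seed, {
    for (i in seq_len(n_leaves)) {
      len <- leaf_params$min_len + rgamma(1, g$shape, scale = g$scale)
      wid <- max(1, leaf_params$width_fraction *
                   (leaf_params$min_len + rgamma(1, g$shape, scale = g$scale)))
      ori <- runif(1, 0, 2 * pi)
      cx <- runif(1, 1, canvas$width)
      cy <- runif(1, 1, canvas$height)
      col_i <- sample.int(nrow(pop), 1)
      sw <- if (shadows) abs(rnorm(1, spec$width_mean, spec$width_sd)) else 0
      mask <- leaf_mask(len, wid, ori)
      if (!is.null(keepout)) {
        ext <- c(round(cx) - ncol(mask) / 2, round(cx) + ncol(mask) / 2,
                 round(cy) - nrow(mask) / 2, round(cy) + nrow(mask) / 2)
        if (ext[2] >= keepout[1] && ext[1] <= keepout[2] &&
            ext[4] >= keepout[3] && ext[3] <= keepout[4]) next
      }
      if (shadows && sw >= 0.5) {
        ## shadow = silhouette shifted left, minus the leaf itself
        sh <- round(sw)
        smask <- cbind(mask, matrix(FALSE, nrow(mask), sh)) &
                 !cbind(matrix(FALSE, nrow(mask), sh), mask)
        res <- stamp_mask(px, smask, cx - sh / 2, cy,
                          scale = 1 - spec$darkening)
        px <- res$px
      }
      res <- stamp_mask(px, mask, cx, cy, rgb = rgb_pop[col_i, ])
      px <- res$px
      if (!is.null(res$hit)) {
        painted[res$hit] <- TRUE
        n_stamped <- n_stamped + 1L
      }
    }
    px
  })
  canvas$pixels <- px
  attr(canvas, "painted") <- painted
  attr(canvas, "n_stamped") <- n_stamped
  canvas
}
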