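## CIE-LAB colour populations for leaves and camouflage patches.
##
## Both the background leaves and the two camouflage patch colours are drawn
## from one constrained colour population: chroma outliers (beyond k SD on
## the A and B opponent axes) are excluded, and the two patch colours come
## from disjoint lightness-percentile bands so the pattern has internal
## contrast while still matching the background's colour statistics.

#' Construct a CIE-LAB colour
#'
#' @param L lightness, 0-100.
#' @param A green-red opponent value.
#' @param B blue-yellow opponent value.
#' @return a `lab_color`: named numeric vector of length 3.
#' @export
lab_color <- function(L, A, B) {
  stopifnot(is.numeric(L), is.numeric(A), is.numeric(B),
            length(L) == 1, length(A) == 1, length(B) == 1, is.finite(L))
  if (L < 0 || L > 100) stop("lab_color: L must lie in [0, 100], got ", L)
  structure(c(L = L, A = A, B = B), class = "lab_color")
}

#' Construct a colour population
#'
#' @param L,A,B numeric vectors of equal length (CIE-LAB coordinates), or a
#'   data frame with columns `L`, `A`, `B` passed as `L`.
#' @param origin provenance tag, `"synthetic"` or `"image-derived"`.
#' @return a `color_population` data frame with columns `L`, `A`, `B`.
#' @export
color_population <- function(L, A = NULL, B = NULL,
                             origin = c("synthetic", "image-derived")) {
  origin <- match.arg(origin)
  if (is.data.frame(L)) {
    stopifnot(all(c("L", "A", "B") %in% names(L)))
    df <- data.frame(L = L$L, A = L$A, B = L$B)
  } else {
    stopifnot(length(L) == length(A), length(A) == length(B))
    df <- data.frame(L = L, A = A, B = B)
  }
  if (nrow(df) == 0) stop("color_population: population must be non-empty")
  if (any(df$L < 0 | df$L > 100)) {
    stop("color_population: all L values must lie in [0, 100]")
  }
  structure(df, origin = origin, class = c("color_population", "data.frame"))
}

#' @export
print.color_population <- function(x, ...) {
  cat(sprintf("<color_population> %d colours (%s)\n", nrow(x),
              attr(x, "origin")))
  cat(sprintf("  L: %.1f-%.1f  A: %.1f-%.1f  B: %.1f-%.1f\n",
              min(x$L), max(x$L), min(x$A), max(x$A), min(x$B), max(x$B)))
  invisible(x)
}

#' Exclude chroma outliers from a colour population
#'
#' Removes every colour lying beyond `k_sd` sample standard deviations from
#' the population mean on the A or B axis. The mean and SD are computed once
#' on the input population (a single exclusion pass; filtering the result
#' again with statistics recomputed may remove further colours). Colours at
#' exactly `k_sd` SD are retained.
#'
#' @param pop a [color_population()] with at least 2 colours.
#' @param k_sd exclusion threshold in sample SDs (default 1).
#' @return the filtered `color_population`, order preserved.
#' @export
filter_population <- function(pop, k_sd = 1) {
  stopifnot(inherits(pop, "color_population"), k_sd > 0)
  if (nrow(pop) < 2) {
    stop("filter_population: need >= 2 colours for the SD to be defined")
  }
  keep <- abs(pop$A - mean(pop$A)) <= k_sd * sd(pop$A) &
          abs(pop$B - mean(pop$B)) <= k_sd * sd(pop$B)
  ## zero-spread axes (sd = 0) exclude nothing
  keep[is.na(keep)] <- TRUE
  out <- pop[keep, , drop = FALSE]
  if (nrow(out) == 0) stop("filter_population: no colours survive the filter")
  structure(out, origin = attr(pop, "origin"),
            class = c("color_population", "data.frame"))
}

#' Lightness-percentile rule for the two camouflage patch colours
#'
#' The dark patch colour is drawn from the 35th-45th lightness percentile
#' band of the population and the light patch colour from the 55th-65th, so
#' the pattern contrasts internally while matching the background overall.
#'
#' @param dark_percentile_range,light_percentile_range length-2 numeric
#'   percentile bounds (inclusive).
#' @return a `patch_color_rule`.
#' @export
patch_color_rule <- function(dark_percentile_range = c(35, 45),
                             light_percentile_range = c(55, 65)) {
  d <- dark_percentile_range; l <- light_percentile_range
  stopifnot(length(d) == 2, length(l) == 2, d[1] < d[2], l[1] < l[2])
  if (d[2] >= l[1]) {
    stop("patch_color_rule: dark band must lie strictly below the light band")
  }
  structure(list(dark = d, light = l), class = "patch_color_rule")
}

## Percentile rank on the empirical CDF: midpoint convention with average
## ranks for ties, so band membership is deterministic and endpoint-inclusive.
percentile_rank <- function(x) {
  100 * (rank(x, ties.method = "average") - 0.5) / length(x)
}

#' Sample the dark and light camouflage patch colours
#'
#' Draws one colour uniformly from each lightness-percentile band of the
#' population.
#'
#' @param pop a [color_population()].
#' @param rule a [patch_color_rule()].
#' @param seed optional integer; fixes the draw without disturbing the
#'   caller's RNG stream.
#' @return list with elements `dark` and `light`, both [lab_color()]s, with
#'   `light$L > dark$L`.
#' @export
sample_patch_colors <- function(pop, rule = patch_color_rule(), seed = NULL) {
  stopifnot(inherits(pop, "color_population"),
            inherits(rule, "patch_color_rule"))
  p <- percentile_rank(pop$L)
  dark_idx <- which(p >= rule$dark[1] & p <= rule$dark[2])
  light_idx <- which(p >= rule$light[1] & p <= rule$light[2])
  if (length(dark_idx) == 0 || length(light_idx) == 0) {
    stop("sample_patch_colors: degenerate population, an L-percentile band ",
         "is empty")
  }
  with_seed_or_not(seed, {
    di <- dark_idx[sample.int(length(dark_idx), 1)]
    li <- light_idx[sample.int(length(light_idx), 1)]
    dark <- lab_color(pop$L[di], pop$A[di], pop$B[di])
    light <- lab_color(pop$L[li], pop$A[li], pop$B[li])
    if (light["L"] <= dark["L"]) {
      stop("sample_patch_colors: degenerate population, no lightness ",
           "contrast between percentile bands")
    }
    list(dark = dark, light = light)
  })
}

#' Synthetic forest-floor colour population
#'
#' A parametric stand-in for a calibrated photograph of tropical forest-floor
#' leaf litter. Colours are drawn from a two-component CIE-LAB mixture: a
#' dominant warm brown litter cluster and a smaller, darker and greener
#' shadow/moss component that supplies the chroma outliers a real image
#' contains (and that the 1-SD chroma filter then prunes). L is clipped to
#' [0, 100].
#'
#' @param n number of colours (>= 100 so percentile bands are reliable).
#' @param seed optional integer seed.
#' @param litter_frac mixture weight of the litter cluster.
#' @param litter_mean,litter_sd length-3 (L, A, B) location and spread of the
#'   litter cluster.
#' @param shadow_mean,shadow_sd same for the shadow/moss component.
#' @return a [color_population()] with origin `"synthetic"`.
#' @export
synth_forest_population <- function(n, seed = NULL, litter_frac = 0.8,
                                    litter_mean = c(45, 10, 22),
                                    litter_sd = c(14, 4, 6),
                                    shadow_mean = c(30, -5, 10),
                                    shadow_sd = c(15, 12, 14)) {
  stopifnot(is.numeric(n), length(n) == 1)
  if (n < 100) {
    stop("synth_forest_population: n must be >= 100 for usable percentile ",
         "bands, got ", n)
  }
  with_seed_or_not(seed, {
    litter <- runif(n) < litter_frac
    draw <- function(i) {
      ifelse(litter, rnorm(n, litter_mean[i], litter_sd[i]),
             rnorm(n, shadow_mean[i], shadow_sd[i]))
    }
    color_population(L = pmin(pmax(draw(1), 0), 100), A = draw(2),
                     B = draw(3), origin = "synthetic")
  })
}

## CIE-LAB <-> linear sRGB (D65 reference white).
.d65 <- c(X = 0.95047, Y = 1.0, Z = 1.08883)
.xyz_to_rgb <- matrix(c(3.2404542, -1.5371385, -0.4985314,
                        -0.9692660, 1.8760108, 0.0415560,
                        0.0556434, -0.2040259, 1.0572252),
                      nrow = 3, byrow = TRUE)
.rgb_to_xyz <- solve(.xyz_to_rgb)

#' Convert CIE-LAB colours to linear display RGB (and back)
#'
#' Standard CIE-LAB to XYZ to linear sRGB conversion under D65. Out-of-gamut
#' results are clipped channel-wise to [0, 1] and flagged via the
#' `"gamut_clipped"` attribute (a logical vector, one per colour); clipping
#' is never an error because edge enhancement can legitimately push L near
#' the gamut boundary.
#'
#' @param color a [lab_color()], or an `n x 3` matrix / data frame of L, A, B
#'   rows.
#' @return an `n x 3` matrix of linear RGB in [0, 1] (a single colour gives a
#'   1 x 3 matrix), with attribute `gamut_clipped`.
#' @export
lab_to_display <- function(color) {
  lab <- if (inherits(color, "lab_color")) matrix(unclass(color), nrow = 1)
         else as.matrix(as.data.frame(color))
  stopifnot(ncol(lab) == 3)
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  finv <- function(t) ifelse(t > 6 / 29, t^3, 3 * (6 / 29)^2 * (t - 4 / 29))
  xyz <- cbind(.d65[1] * finv(fx), .d65[2] * finv(fy), .d65[3] * finv(fz))
  rgb <- xyz %*% t(.xyz_to_rgb)
  clipped <- rowSums(rgb < 0 | rgb > 1) > 0
  out <- clip01(rgb)
  colnames(out) <- c("R", "G", "B")
  attr(out, "gamut_clipped") <- clipped
  out
}

#' @rdname lab_to_display
#' @param rgb an `n x 3` matrix (or length-3 vector) of linear RGB in [0, 1].
#' @export
display_to_lab <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, nrow = 1)
  stopifnot(ncol(rgb) == 3)
  xyz <- rgb %*% t(.rgb_to_xyz)
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3),
                          t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(xyz[, 1] / .d65[1])
  fy <- f(xyz[, 2] / .d65[2])
  fz <- f(xyz[, 3] / .d65[3])
  out <- cbind(L = 116 * fy - 16, A = 500 * (fx - fy), B = 200 * (fy - fz))
  out
}

#' Read / write colour populations as CSV
#'
#' CSV with columns `L`, `A`, `B`, so populations derived from calibrated
#' photographs can be supplied externally.
#'
#' @param path CSV file path.
#' @param pop a [color_population()].
#' @param origin provenance tag recorded on read.
#' @return `read_population()` returns a [color_population()];
#'   `write_population()` returns `path` invisibly.
#' @export
read_population <- function(path, origin = "image-derived") {
  color_population(read.csv(path), origin = origin)
}

#' @rdname read_population
#' @export
write_population <- function(pop, path) {
  stopifnot(inherits(pop, "color_population"))
  write.csv(as.data.frame(pop)[, c("L", "A", "B")], path, row.names = FALSE)
  invisible(path)
}
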