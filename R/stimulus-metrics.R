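#' Load a greyscale luminance matrix
#'
#' Images enter the contrast metrics as plain numeric matrices of
#' luminance.  PNG files are read via the png package (if installed); RGB
#' input is collapsed to luminance with Rec. 601 weights
#' (0.299 R + 0.587 G + 0.114 B), matching the greyscale presentation of
#' the stimuli.
#'
#' @param x a numeric matrix (returned as-is), a 3D array (h x w x channels),
#'   or a path to a PNG file.
#' @return Numeric luminance matrix.
#' @export
as_luminance <- function(x) {
  if (is.character(x)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("as_luminance: reading PNG files requires the png package")
    x <- png::readPNG(x)
  }
  if (is.matrix(x)) return(x)
  if (is.array(x) && length(dim(x)) == 3) {
    ch <- dim(x)[3]
    if (ch == 1) return(x[, , 1])
    return(0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3])
  }
  stop("as_luminance: expected a matrix, 3D array or file path")
}

#' Global RMS contrast
#'
#' Standard deviation of luminance divided by mean luminance (population
#' SD, so the value depends only on the pixel distribution).  Scale
#' invariant: multiplying all luminances by k > 0 leaves it unchanged.
#'
#' @param image luminance input accepted by [as_luminance()]; nonzero mean.
#' @return Nonnegative scalar.
#' @export
global_rms_contrast <- function(image) {
  l <- as.numeric(as_luminance(image))
  m <- mean(l)
  if (m == 0) stop("global_rms_contrast: zero-mean image")
  sqrt(mean((l - m)^2)) / m
}

#' Local RMS contrast
#'
#' The image is tiled into non-overlapping windows and the RMS contrast
#' (population SD / mean) of each window is averaged.  The default window
#' is 10% of the image's smaller dimension; as the window grows to the full
#' image the value converges to [global_rms_contrast()].  Edge windows
#' smaller than `window_px` are included as-is.
#'
#' @param image luminance input accepted by [as_luminance()].
#' @param window_px window side in pixels; default `max(2, round(min(dim)/10))`.
#' @return Nonnegative scalar.
#' @export
local_rms_contrast <- function(image, window_px = NULL) {
  img <- as_luminance(image)
  d <- dim(img)
  if (is.null(window_px)) window_px <- max(2, round(min(d) / 10))
  if (window_px < 1 || window_px > min(d))
    stop("local_rms_contrast: window must be between 1 px and the image size")
  row_starts <- seq(1, d[1], by = window_px)
  col_starts <- seq(1, d[2], by = window_px)
  vals <- numeric(0)
  for (r0 in row_starts) for (c0 in col_starts) {
    w <- img[r0:min(r0 + window_px - 1, d[1]),
             c0:min(c0 + window_px - 1, d[2]), drop = FALSE]
    m <- mean(w)
    if (m == 0) stop("local_rms_contrast: zero-mean window")
    vals <- c(vals, sqrt(mean((w - m)^2)) / m)
  }
  mean(vals)
}

#' Grid-scramble an image into a block mosaic
#'
#' Partitions the image into `block_px` x `block_px` tiles and permutes the
#' tiles uniformly at random, producing a control stimulus that preserves
#' the pixel multiset (hence luminance mean, global SD, histogram) while
#' destroying recognizable structure.  Edge tiles smaller than the block
#' are permuted only among tiles of the same shape, so the output has
#' exactly the input's dimensions.
#'
#' @param image luminance input accepted by [as_luminance()]; both
#'   dimensions at least `block_px`.
#' @param block_px tile side in pixels (default 10).
#' @param seed integer seed making the permutation reproducible.
#' @return Scrambled matrix of the same dimensions.
#' @export
grid_scramble <- function(image, block_px = 10, seed) {
  img <- as_luminance(image)
  d <- dim(img)
  stopifnot(all(d >= block_px), block_px >= 1)
  row_starts <- seq(1, d[1], by = block_px)
  col_starts <- seq(1, d[2], by = block_px)
  tiles <- expand.grid(r0 = row_starts, c0 = col_starts)
  tiles$r1 <- pmin(tiles$r0 + block_px - 1, d[1])
  tiles$c1 <- pmin(tiles$c0 + block_px - 1, d[2])
  tiles$shape <- paste(tiles$r1 - tiles$r0, tiles$c1 - tiles$c0)
  out <- img
  if (!missing(seed)) set.seed(seed)
  for (shp in unique(tiles$shape)) {
    grp <- which(tiles$shape == shp)
    perm <- grp[sample.int(length(grp))]
    for (k in seq_along(grp)) {
      src <- tiles[perm[k], ]; dst <- tiles[grp[k], ]
      out[dst$r0:dst$r1, dst$c0:dst$c1] <- img[src$r0:src$r1, src$c0:src$c1]
    }
  }
  out
}

#' Paired ratio matching test
#'
#' For each social/nonsocial stimulus pair, the ratio of a matching
#' parameter (arousal, valence, contrast, saliency) is computed, and the
#' ratios are tested against 1 with a two-tailed one-sample t test.  The
#' pair set counts as matched on that parameter when the 95% confidence
#' interval of the mean ratio overlaps 1.
#'
#' @param values_social,values_nonsocial positive paired values, n >= 3.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return list with `ratios`, `mean_ratio`, `ci` (length 2), `statistic`,
#'   `df`, `p`, `matched`.
#' @export
ratio_matching_test <- function(values_social, values_nonsocial,
                                conf_level = 0.95) {
  stopifnot(length(values_social) == length(values_nonsocial),
            length(values_social) >= 3)
  if (any(values_social <= 0) || any(values_nonsocial <= 0))
    stop("ratio_matching_test: values must be positive")
  ratios <- values_social / values_nonsocial
  if (stats::sd(ratios) == 0) {
    ci <- c(mean(ratios), mean(ratios))
    return(list(ratios = ratios, mean_ratio = mean(ratios), ci = ci,
                statistic = 0, df = length(ratios) - 1,
                p = if (mean(ratios) == 1) 1 else 0,
                matched = mean(ratios) == 1))
  }
  tt <- stats::t.test(ratios, mu = 1, conf.level = conf_level)
  ci <- unname(tt$conf.int)
  list(ratios = ratios, mean_ratio = mean(ratios), ci = ci,
       statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, matched = ci[1] <= 1 && ci[2] >= 1)
}
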