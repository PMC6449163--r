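#' Mean gray value of a rectangular ROI
#'
#' Arithmetic mean of the pixel values inside an axis-aligned rectangle.
#' Pixel coordinates are 1-based; `rect = c(x, y, w, h)` with `x` the
#' column and `y` the row of the top-left corner. On the acquisition
#' scale, 0 is black and lighter signal indicates more protein.
#'
#' @param img A [gray_image()].
#' @param rect Integer vector `c(x, y, w, h)` in pixels.
#' @return Mean gray value (arbitrary units).
#' @export
roi_mean_gray <- function(img, rect) {
  stopifnot(inherits(img, "gray_image"))
  if (length(rect) != 4L || any(!is.finite(rect)))
    stop("roi_mean_gray: rect must be c(x, y, w, h)")
  x <- rect[1]; y <- rect[2]; w <- rect[3]; h <- rect[4]
  if (w < 1 || h < 1) stop("roi_mean_gray: rect has non-positive size")
  if (x < 1 || y < 1 || x + w - 1 > ncol(img$pixels) ||
      y + h - 1 > nrow(img$pixels))
    stop("roi_mean_gray: rect extends outside the image")
  mean(img$pixels[y:(y + h - 1), x:(x + w - 1)])
}

# Internal: bilinear interpolation of image values at continuous
# (x = column, y = row) positions; 1-based pixel-center coordinates.
# Positions outside the image return NA.
bilinear_sample <- function(px, x, y) {
  nr <- nrow(px); nc <- ncol(px)
  out <- rep(NA_real_, length(x))
  ok <- x >= 1 & x <= nc & y >= 1 & y <= nr
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]
  x0 <- pmin(floor(x), nc - 1L); y0 <- pmin(floor(y), nr - 1L)
  fx <- x - x0; fy <- y - y0
  v00 <- px[cbind(y0, x0)]
  v01 <- px[cbind(y0, x0 + 1L)]
  v10 <- px[cbind(y0 + 1L, x0)]
  v11 <- px[cbind(y0 + 1L, x0 + 1L)]
  out[ok] <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
    fy * ((1 - fx) * v10 + fx * v11)
  out
}

#' Binned intensity profile along a somatodendritic path
#'
#' Samples the image by bilinear interpolation at stations spaced
#' `station_spacing` pixels along the polyline `path`, averaging across
#' `width` perpendicular offsets (1-pixel spacing, centered on the
#' path). The normalized arc length \[0, 1\] is partitioned into
#' `n_bins` equal half-open bins (the last closed) and the mean
#' intensity per bin is reported. The canonical path direction is from
#' the alveus to the hippocampal fissure, so stratum oriens lands in
#' the first bins and stratum lacunosum-moleculare in the last;
#' reversing the path reverses the bin order. Samples falling outside
#' the image are dropped.
#'
#' @param img A [gray_image()].
#' @param path Numeric matrix with columns x, y (>= 2 points, pixels).
#' @param width Profile width in pixels (number of perpendicular
#'   offsets, >= 1).
#' @param n_bins Number of bins (default 20).
#' @param station_spacing Station spacing along the path in pixels.
#' @param dark_offset Constant dark-frame value subtracted from every
#'   sample before binning (default 0; no background correction).
#' @return Object of class `"radial_profile"`: list with `bin_means`
#'   (length `n_bins`), `path_length` (pixels), `n_bins`.
#' @export
radial_profile <- function(img, path, width = 1, n_bins = 20,
                           station_spacing = 1, dark_offset = 0) {
  stopifnot(inherits(img, "gray_image"))
  path <- as.matrix(path)
  if (nrow(path) < 2L || ncol(path) != 2L)
    stop("radial_profile: path must be a matrix of >= 2 (x, y) points")
  if (width < 1) stop("radial_profile: width must be >= 1")
  seg_d <- sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)
  total <- sum(seg_d)
  if (total <= 0) stop("radial_profile: degenerate (zero-length) path")
  cum <- c(0, cumsum(seg_d))
  # stations at midpoints of equal subintervals, count a multiple of
  # n_bins: bins receive equally many stations, none sits on a bin
  # edge, and reversing the path maps stations onto stations
  n_st <- max(n_bins, ceiling(total / station_spacing))
  n_st <- as.integer(ceiling(n_st / n_bins) * n_bins)
  s <- (seq_len(n_st) - 0.5) * total / n_st
  seg_i <- pmin(findInterval(s, cum, rightmost.closed = TRUE),
                length(seg_d))
  frac <- (s - cum[seg_i]) / seg_d[seg_i]
  sx <- path[seg_i, 1] + frac * (path[seg_i + 1, 1] - path[seg_i, 1])
  sy <- path[seg_i, 2] + frac * (path[seg_i + 1, 2] - path[seg_i, 2])
  # unit normals of the containing segment
  tx <- (path[seg_i + 1, 1] - path[seg_i, 1]) / seg_d[seg_i]
  ty <- (path[seg_i + 1, 2] - path[seg_i, 2]) / seg_d[seg_i]
  offsets <- seq_len(width) - (width + 1) / 2
  station_vals <- rep(0, n_st)
  station_n <- rep(0L, n_st)
  for (o in offsets) {
    v <- bilinear_sample(img$pixels, sx - o * ty, sy + o * tx)
    hit <- !is.na(v)
    station_vals[hit] <- station_vals[hit] + v[hit]
    station_n <- station_n + hit
  }
  keep <- station_n > 0L
  vals <- station_vals[keep] / station_n[keep] - dark_offset
  norm_s <- s[keep] / total
  bin <- pmin(floor(norm_s * n_bins) + 1L, n_bins)
  bin_means <- vapply(seq_len(n_bins), function(b) {
    if (any(bin == b)) mean(vals[bin == b]) else NA_real_
  }, numeric(1))
  structure(list(bin_means = bin_means, path_length = total,
                 n_bins = n_bins),
            class = "radial_profile")
}
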