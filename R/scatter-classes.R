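#' Off-diagonal ROI classification in SON-vs-LMNB1 scatter space
#'
#' Classifies genomic bins by their position in the SON versus LMNB1
#' TSA-seq scatterplot. ROI bins fall strictly below the line
#' `LMNB1 = -1.5 * SON - 1.3`; within the ROI, C2 bins fall strictly
#' below `LMNB1 = -1.5 * SON - 2.2` and C1 bins are the remainder.
#' Points exactly on a line are excluded (strict inequalities).
#'
#' @param son,lmnb1 numeric vectors of TSA-seq scores.
#' @param slope,c1_intercept,c2_intercept line parameters; defaults are
#'   the published H1 values.
#' @return character vector in `c("ROI_C1", "ROI_C2", "none")`.
#' @export
classify_h1_roi <- function(son, lmnb1, slope = -1.5,
                            c1_intercept = -1.3, c2_intercept = -2.2) {
  roi <- lmnb1 < slope * son + c1_intercept
  c2 <- lmnb1 < slope * son + c2_intercept
  ifelse(roi & c2, "ROI_C2", ifelse(roi, "ROI_C1", "none"))
}

#' Quadrant classification of LAD bins
#'
#' Divides LAD bins into four clusters at a fixed center of the SON
#' versus LMNB1 scatterplot: C1 = top-left, C2 = top-right, C3 =
#' bottom-left, C4 = bottom-right. Boundary convention: a bin exactly at
#' the center value counts as right (`son >= center`) and top
#' (`lmnb1 >= center`).
#'
#' @param son,lmnb1 numeric vectors of scores for LAD bins.
#' @param center length-2 numeric `(son, lmnb1)` quadrant center;
#'   default is the published HCT116 center `(-3.0, 0.25)`.
#' @return character vector in `c("C1","C2","C3","C4")`.
#' @export
classify_quadrant <- function(son, lmnb1, center = c(-3.0, 0.25)) {
  left <- son < center[1]
  top <- lmnb1 >= center[2]
  ifelse(top, ifelse(left, "C1", "C2"), ifelse(left, "C3", "C4"))
}

#' Equatorial versus non-equatorial LAD classification
#'
#' Splits LAD bins into the equatorial cluster (high lamina TSA-seq,
#' `lmnb1 > lmnb1_thresh`) and the non-equatorial cluster (low speckle
#' TSA-seq, `son < son_thresh`). When both conditions hold the
#' equatorial label takes precedence; bins meeting neither are `"none"`.
#' Calling this on non-LAD bins is a contract violation.
#'
#' @param son,lmnb1 scores of LAD bins.
#' @param is_lad logical vector; must be all `TRUE`.
#' @param lmnb1_thresh,son_thresh published HFF thresholds.
#' @return character vector in `c("EQ_cluster1","nonEQ_cluster2","none")`.
#' @export
classify_eq_lads <- function(son, lmnb1, is_lad = TRUE,
                             lmnb1_thresh = 0.75, son_thresh = 0.98) {
  if (!all(is_lad)) stop2("classify_eq_lads applies only to LAD bins")
  ifelse(lmnb1 > lmnb1_thresh, "EQ_cluster1",
         ifelse(son < son_thresh, "nonEQ_cluster2", "none"))
}

#' Count-thresholded 2D overlay histogram
#'
#' Bins points into square pixels, counting genomic bins per pixel and
#' averaging an overlay value (e.g. a ChIP percentile or a delta) per
#' pixel. Pixel means are reported only where the count reaches
#' `min_count`; masked pixels keep their counts. Pixel edges are snapped
#' to multiples of `pixel`.
#'
#' @param x,y point coordinates.
#' @param value overlay value per point (optional; `NULL` for
#'   counts-only grids).
#' @param pixel pixel side length (> 0).
#' @param min_count minimum points per pixel for the mean to be shown.
#' @return list with `x_edges`, `y_edges`, `count` and `mean` matrices
#'   (x by y), and `min_count`; class `OverlayGrid`.
#' @export
overlay_histogram <- function(x, y, value = NULL, pixel = 0.1, min_count = 10) {
  check_scalar_number(pixel, "pixel", lower = 0, strict_lower = TRUE)
  if (length(x) == 0) {
    return(structure(list(x_edges = numeric(0), y_edges = numeric(0),
                          count = matrix(0, 0, 0), mean = matrix(NA_real_, 0, 0),
                          min_count = min_count), class = "OverlayGrid"))
  }
  ix <- floor(x / pixel); iy <- floor(y / pixel)
  xr <- min(ix):max(ix); yr <- min(iy):max(iy)
  count <- matrix(0L, length(xr), length(yr))
  sums <- matrix(0, length(xr), length(yr))
  px <- match(ix, xr); py <- match(iy, yr)
  for (k in seq_along(px)) {
    count[px[k], py[k]] <- count[px[k], py[k]] + 1L
    if (!is.null(value)) sums[px[k], py[k]] <- sums[px[k], py[k]] + value[k]
  }
  mn <- matrix(NA_real_, length(xr), length(yr))
  show <- count >= min_count
  if (!is.null(value)) mn[show] <- sums[show] / count[show]
  structure(list(x_edges = c(xr, max(xr) + 1) * pixel,
                 y_edges = c(yr, max(yr) + 1) * pixel,
                 count = count, mean = mn, min_count = min_count),
            class = "OverlayGrid")
}
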