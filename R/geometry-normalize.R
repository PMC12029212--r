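#' Normalize a nucleus' probe cloud into the reference cuboid
#'
#' Aligns and rescales the chromatin-tracing probes of one nucleus so
#' nuclei of different sizes and orientations are comparable: the x-y
#' coordinates are centered and rotated by their 2D PCA eigenbasis so
#' the nuclear long axis (PC1) maps to X and the width (PC2) to Y, then
#' each axis is min-max normalized into a 4 x 2 x 1 (X, Y, Z) cuboid.
#' Axis signs are fixed deterministically: on each axis the probe of
#' maximum absolute coordinate is made positive, resolving the
#' reflection ambiguity of PCA.
#'
#' @param probes data.frame with columns `x_nm`, `y_nm`, `z_nm` (rows of
#'   one nucleus; >= 3 probes with non-collinear x-y positions).
#' @return the data.frame with added columns `x_norm`, `y_norm`,
#'   `z_norm` in `[0,4] x [0,2] x [0,1]`; pre-normalization centroid in
#'   `attr(, "centroid_nm")`.
#' @export
normalize_nucleus <- function(probes) {
  if (nrow(probes) < 3) stop2("need >= 3 probes to normalize a nucleus")
  xy <- cbind(probes$x_nm, probes$y_nm)
  ctr <- colMeans(xy)
  xyc <- sweep(xy, 2, ctr)
  cv <- crossprod(xyc) / nrow(xyc)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[2] < 1e-12 * max(eg$values[1], 1))
    stop2("degenerate (collinear) probe cloud; cannot orient nucleus")
  rot <- xyc %*% eg$vectors            # PC1 -> X, PC2 -> Y
  for (j in 1:2) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  z <- probes$z_nm
  mm <- function(v, hi) {
    r <- range(v)
    if (r[2] == r[1]) rep(hi / 2, length(v))
    else (v - r[1]) / (r[2] - r[1]) * hi
  }
  probes$x_norm <- mm(rot[, 1], 4)
  probes$y_norm <- mm(rot[, 2], 2)
  probes$z_norm <- mm(z, 1)
  attr(probes, "centroid_nm") <- c(x = ctr[1], y = ctr[2], z = mean(z))
  probes
}

#' Polarity metrics of normalized probes
#'
#' Distance of each probe to the equatorial plane of the normalized
#' nucleus (`|z_norm - 0.5|`) and the projected x-y distance to the
#' nuclear center, both in normalized cuboid units (center `(2, 1)`)
#' and, when raw coordinates are present, in nm from the
#' pre-normalization x-y centroid.
#'
#' @param probes a [normalize_nucleus()] result.
#' @return data.frame with `eq_dist`, `center_dist`, and `center_dist_nm`
#'   (if raw coordinates available).
#' @export
polarity_metrics <- function(probes) {
  if (is.null(probes$z_norm)) stop2("probes are not normalized")
  out <- data.frame(
    eq_dist = abs(probes$z_norm - 0.5),
    center_dist = sqrt((probes$x_norm - 2)^2 + (probes$y_norm - 1)^2))
  ctr <- attr(probes, "centroid_nm")
  if (!is.null(ctr) && !is.null(probes$x_nm))
    out$center_dist_nm <- sqrt((probes$x_nm - ctr["x"])^2 +
                               (probes$y_nm - ctr["y"])^2)
  out
}

#' Genomic distance of probes to the centromere
#'
#' Distance (Mbp) from each probe's genomic midpoint to the nearest edge
#' of its chromosome's merged centromeric (`acen`) interval; probes
#' inside the centromere score 0, probes on chromosomes lacking an
#' `acen` annotation are `NA`.
#'
#' @param probes data.frame with `chrom`, `start`, `end` (bp).
#' @param bands an [interval_set()] of cytogenetic bands whose `label`
#'   column holds the Giemsa stain (containing `"acen"` for centromeric
#'   bands).
#' @return numeric vector of distances in Mbp.
#' @export
centromere_distance <- function(probes, bands) {
  acen <- bands[grepl("acen", bands$label), , drop = FALSE]
  cen <- lapply(split(acen, acen$chrom),
                function(d) c(min(d$start), max(d$end)))
  mid <- (probes$start + probes$end) / 2
  vapply(seq_len(nrow(probes)), function(i) {
    ce <- cen[[probes$chrom[i]]]
    if (is.null(ce)) return(NA_real_)
    if (mid[i] < ce[1]) (ce[1] - mid[i]) / 1e6
    else if (mid[i] > ce[2]) (mid[i] - ce[2]) / 1e6
    else 0
  }, 1.0)
}

#' PCA of per-nucleus morphology metrics
#'
#' Standardizes each metric to mean 0, sd 1 and eigen-decomposes the
#' correlation matrix, giving per-nucleus scores, metric loadings and
#' the fraction of variance per component — the morphology-space map in
#' which cell types cluster. Zero-variance metrics are dropped with a
#' warning.
#'
#' @param features numeric matrix (nuclei x metrics), no missing values.
#' @return list with `scores`, `loadings`, `var_explained`.
#' @export
morphology_pca <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2 || ncol(features) < 2)
    stop2("need >= 2 nuclei and >= 2 metrics")
  if (anyNA(features)) stop2("missing cells in the feature matrix")
  sds <- apply(features, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance metric(s): ",
            paste(colnames(features)[sds == 0], collapse = ", "),
            call. = FALSE)
    features <- features[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  zs <- scale(features)
  eg <- eigen(stats::cor(features), symmetric = TRUE)
  list(scores = zs %*% eg$vectors,
       loadings = structure(eg$vectors,
                            dimnames = list(colnames(features),
                                            paste0("PC", seq_along(sds)))),
       var_explained = eg$values / sum(eg$values))
}
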