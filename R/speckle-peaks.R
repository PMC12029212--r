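#' Local maximum filter
#'
#' Sliding-window maximum: `out[i]` is the maximum of `values` over the
#' centered window `[i - w, i + w]`, clipped at the vector ends. Missing
#' values are ignored inside windows; a window with no usable value
#' yields `NA`. This records, for each locus, the maximum smoothed
#' speckle TSA-seq score within its neighborhood.
#'
#' @param values numeric vector.
#' @param w window half-width in bins (>= 1); the full window spans
#'   `2*w + 1` bins.
#' @return numeric vector of window maxima.
#' @export
max_filter <- function(values, w) {
  check_scalar_number(w, "w", lower = 1)
  w <- as.integer(w)
  n <- length(values)
  if (n == 0) return(values)
  out <- values
  for (s in c(-(w:1), 1:w)) {
    if (s > 0) shifted <- c(values[-seq_len(s)], rep(NA_real_, min(s, n)))
    else shifted <- c(rep(NA_real_, min(-s, n)), values[seq_len(max(0, n + s))])
    out <- pmax(out, shifted[seq_len(n)], na.rm = TRUE)
  }
  out[is.na(values) & is.na(out)] <- NA_real_
  ifelse(is.infinite(out), NA_real_, out)
}

# find apex plateaus: runs of consecutive bins whose smoothed value
# equals the window max and is a strict local maximum within +/- w.
# Values within a small relative tolerance are treated as equal so that
# floating-point ripple from the smoother cannot fabricate peaks.
find_apexes <- function(sm, w) {
  n <- length(sm)
  mf <- max_filter(sm, w)
  eps <- 1e-8 * max(1e-12, max(abs(sm), na.rm = TRUE))
  cand <- which(!is.na(sm) & sm >= mf - eps)
  if (!length(cand)) return(integer(0))
  # group into plateaus of adjacent equal-valued candidates
  brk <- c(TRUE, diff(cand) != 1L |
             abs(sm[cand[-1]] - sm[cand[-length(cand)]]) > eps)
  grp <- cumsum(brk)
  apexes <- integer(0)
  for (g in unique(grp)) {
    idx <- cand[grp == g]
    a <- idx[1]; b <- idx[length(idx)]
    if (a == 1L || b == n) next          # boundary maxima are not peaks
    win <- max(1L, a - w):min(n, b + w)
    other <- setdiff(win, a:b)
    vals <- sm[other]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) next
    if (max(vals) < sm[a] - eps)         # strict reduction off the apex
      apexes <- c(apexes, as.integer(round(mean(c(a, b)))))
  }
  apexes
}

#' Call speckle TSA-seq peaks
#'
#' The peak caller pipeline: LOESS-smooth the track, apply a local
#' maximum filter of half-width `w`, and keep a bin as an apex iff its
#' smoothed value equals the window maximum and every other value within
#' the window is strictly smaller (the max-filtered minus smoothed
#' difference is zero at the apex and negative elsewhere — a true local
#' peak). Plateaus of equal values yield one apex at the plateau
#' centroid.
#'
#' @param track a [binned_track()] (or an already smoothed one, see
#'   `presmoothed`).
#' @param span LOESS span (fraction of chromosome bins).
#' @param w maximum-filter half-width in bins.
#' @param presmoothed set `TRUE` when `track` is already smoothed, to
#'   skip the LOESS step (used by the parameter grid search).
#' @return A `PeakSet`: data.frame of (chrom, apex_bin, apex_bp, score,
#'   type) with parameters in attributes. `apex_bin` is 1-based;
#'   `apex_bp` is the apex bin midpoint.
#' @export
call_peaks <- function(track, span = 0.005, w = 50, presmoothed = FALSE) {
  w <- as.integer(w)
  sm <- if (presmoothed) track else loess_smooth(track, span)
  short <- vapply(sm$scores, length, 1L) < 2L * w + 1L
  if (any(short))
    warning("chromosome(s) shorter than 2w+1 bins processed with clipped windows: ",
            paste(names(sm$scores)[short], collapse = ", "), call. = FALSE)
  out <- list()
  for (chr in names(sm$scores)) {
    v <- sm$scores[[chr]]
    ap <- find_apexes(v, w)
    if (length(ap))
      out[[chr]] <- data.frame(
        chrom = chr, apex_bin = ap,
        apex_bp = (ap - 0.5) * sm$bin_size,
        score = v[ap], type = "unclassified", stringsAsFactors = FALSE)
  }
  ps <- if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE)))
        else data.frame(chrom = character(0), apex_bin = integer(0),
                        apex_bp = numeric(0), score = numeric(0),
                        type = character(0), stringsAsFactors = FALSE)
  structure(ps, class = c("PeakSet", "data.frame"),
            span = span, w = w, bin_size = track$bin_size)
}

#' Replicate agreement between two peak sets
#'
#' Greedy nearest-first one-to-one matching of apexes within `tol` bins
#' (per chromosome), scored as Jaccard on matched pairs:
#' `matched / (|a| + |b| - matched)`. Returns 0 when both sets are empty.
#'
#' @param a,b `PeakSet`s called at the same bin size.
#' @param tol matching tolerance in bins.
#' @return agreement in \[0, 1\].
#' @export
peak_agreement <- function(a, b, tol = 2) {
  na <- nrow(a); nb <- nrow(b)
  if (na + nb == 0) return(0)
  matched <- 0L
  for (chr in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- a$apex_bin[a$chrom == chr]
    bi <- b$apex_bin[b$chrom == chr]
    d <- abs(outer(ai, bi, "-"))
    pairs <- which(d <= tol, arr.ind = TRUE)
    if (!nrow(pairs)) next
    pairs <- pairs[order(d[pairs], pairs[, 1], pairs[, 2]), , drop = FALSE]
    used_a <- logical(length(ai)); used_b <- logical(length(bi))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (!used_a[i] && !used_b[j]) {
        used_a[i] <- used_b[j] <- TRUE
        matched <- matched + 1L
      }
    }
  }
  matched / (na + nb - matched)
}

#' Optimize peak-caller parameters by replicate agreement
#'
#' Exhaustive grid search over (span, w): peaks are called in both
#' replicates at every grid point and the pair maximizing
#' [peak_agreement()] is returned. Ties break toward larger span, then
#' larger w (smoother fits, fewer calls).
#'
#' @param rep1,rep2 replicate [binned_track()]s.
#' @param span_grid,w_grid non-empty parameter grids.
#' @param tol matching tolerance in bins.
#' @return list with `span`, `w`, `agreement`, and the full agreement
#'   `surface` (spans x ws).
#' @export
optimize_parameters <- function(rep1, rep2, span_grid = c(0.002, 0.005, 0.01),
                                w_grid = c(10, 25, 50), tol = 2) {
  if (!length(span_grid) || !length(w_grid)) stop2("grids must be non-empty")
  span_grid <- sort(span_grid); w_grid <- sort(w_grid)
  surface <- matrix(NA_real_, length(span_grid), length(w_grid),
                    dimnames = list(span = span_grid, w = w_grid))
  best <- list(span = NA_real_, w = NA_real_, agreement = -Inf)
  for (si in seq_along(span_grid)) {
    sm1 <- loess_smooth(rep1, span_grid[si])
    sm2 <- loess_smooth(rep2, span_grid[si])
    for (wi in seq_along(w_grid)) {
      p1 <- call_peaks(sm1, span_grid[si], w_grid[wi], presmoothed = TRUE)
      p2 <- call_peaks(sm2, span_grid[si], w_grid[wi], presmoothed = TRUE)
      agr <- peak_agreement(p1, p2, tol)
      surface[si, wi] <- agr
      if (agr >= best$agreement)  # >= with sorted grids: last tie wins
        best <- list(span = span_grid[si], w = w_grid[wi], agreement = agr)
    }
  }
  best$surface <- surface
  best
}

#' Classify peaks by Hi-C subcompartment overlap
#'
#' Assigns Type I to apexes overlapping A1 subcompartments and Type II to
#' those overlapping A2 or B1; apexes in unannotated gaps or other
#' labels stay unclassified.
#'
#' @param peaks a `PeakSet`.
#' @param subcompartments an [interval_set()] with labels among
#'   A1/A2/B1/B2/B3, non-overlapping.
#' @return The `PeakSet` with its `type` column filled.
#' @export
classify_peaks <- function(peaks, subcompartments) {
  ok <- c("A1", "A2", "B1", "B2", "B3")
  if (!all(subcompartments$label %in% ok))
    stop2("subcompartment labels must be among: ", paste(ok, collapse = ", "))
  if (isTRUE(intervals_overlap(subcompartments)))
    stop2("subcompartment annotation intervals overlap")
  for (r in seq_len(nrow(peaks))) {
    hit <- subcompartments$chrom == peaks$chrom[r] &
      subcompartments$start <= peaks$apex_bp[r] &
      subcompartments$end > peaks$apex_bp[r]
    lab <- subcompartments$label[hit]
    peaks$type[r] <- if (!length(lab)) "unclassified"
      else if (lab[1] == "A1") "I"
      else if (lab[1] %in% c("A2", "B1")) "II"
      else "unclassified"
  }
  peaks
}
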