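#' Binned genomic signal track
#'
#' The central container for per-bin scores of one assay in one cell
#' type: a named list of per-chromosome numeric vectors on a fixed bin
#' grid. Bin `i` (1-based) covers the 0-based half-open interval
#' `[(i-1)*bin_size, i*bin_size)`. Missing data are explicit `NA`s and
#' propagate through every transform; they are never silently zero.
#'
#' @param scores named list of numeric vectors, one per chromosome.
#' @param bin_size bin width in bp.
#' @param assay assay label, e.g. `"SON_TSA"`, `"LMNB1_DamID"`.
#' @param cell_type cell-type label.
#' @return An object of class `BinnedTrack`.
#' @export
binned_track <- function(scores, bin_size, assay = NA_character_,
                         cell_type = NA_character_) {
  if (!is.list(scores) || length(scores) == 0 || is.null(names(scores)))
    stop2("`scores` must be a non-empty named list of numeric vectors")
  check_scalar_number(bin_size, "bin_size", lower = 1)
  scores <- lapply(scores, function(v) {
    if (!is.numeric(v) && !all(is.na(v))) stop2("scores must be numeric")
    as.numeric(v)
  })
  structure(
    list(scores = scores, bin_size = bin_size,
         assay = assay, cell_type = cell_type),
    class = "BinnedTrack"
  )
}

#' @export
print.BinnedTrack <- function(x, ...) {
  n <- sum(vapply(x$scores, length, 1L))
  miss <- sum(vapply(x$scores, function(v) sum(is.na(v)), 1L))
  cat(sprintf("BinnedTrack <%s / %s>: %d chromosome(s), %d bins of %s bp (%d missing)\n",
              x$assay, x$cell_type, length(x$scores), n,
              format(x$bin_size, big.mark = ","), miss))
  invisible(x)
}

#' @export
as.data.frame.BinnedTrack <- function(x, ...) {
  out <- lapply(names(x$scores), function(chr) {
    v <- x$scores[[chr]]
    data.frame(chrom = chr,
               start = (seq_along(v) - 1) * x$bin_size,
               end = seq_along(v) * x$bin_size,
               value = v,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pooled non-missing values of a track
#' @param track a [binned_track()].
#' @return numeric vector of all non-`NA` bin values, genome order.
#' @export
track_values <- function(track) {
  v <- unlist(track$scores, use.names = FALSE)
  v[!is.na(v)]
}

# apply a per-chromosome function, preserving structure and metadata
track_map <- function(track, f, ...) {
  track$scores <- lapply(track$scores, f, ...)
  track
}

#' Interval annotation set
#'
#' Plain-table representation of labelled genomic intervals (LAD calls,
#' Hi-C subcompartments, chromosome bands): 0-based half-open
#' coordinates, sorted within chromosome.
#'
#' @param chrom,start,end,label,score vectors of equal length (`label`
#'   and `score` optional).
#' @return A `data.frame` with class `IntervalSet` prepended.
#' @export
interval_set <- function(chrom, start, end, label = NA_character_,
                         score = NA_real_) {
  n <- length(chrom)
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end),
                   label = rep_len(as.character(label), n),
                   score = rep_len(as.numeric(score), n),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop2("intervals must satisfy start < end")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("IntervalSet", "data.frame")
  df
}

# TRUE if any two intervals of the same chromosome overlap; returns the
# first offending pair as attribute
intervals_overlap <- function(df) {
  for (chr in unique(df$chrom)) {
    d <- df[df$chrom == chr, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1) {
      bad <- which(d$start[-1] < d$end[-nrow(d)])
      if (length(bad))
        return(structure(TRUE, pair = d[c(bad[1], bad[1] + 1L), ]))
    }
  }
  FALSE
}
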