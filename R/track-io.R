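#' Read a signal track and re-bin it to a fixed grid
#'
#' Imports a bedGraph or bigWig track via `rtracklayer` and projects it
#' onto a fixed bin grid by coverage-weighted mean: each bin's value is
#' the mean of the source values over the covered base pairs. Bins with
#' no coverage are missing; bins only partially covered are flagged in
#' the `"partial"` attribute of each chromosome vector.
#'
#' @param path file path.
#' @param format `"bedgraph"` or `"bigwig"`.
#' @param bin_size target bin width in bp.
#' @param assay,cell_type metadata labels for the returned track.
#' @return A [binned_track()].
#' @export
read_track <- function(path, format = c("bedgraph", "bigwig"), bin_size,
                       assay = NA_character_, cell_type = NA_character_) {
  format <- match.arg(format)
  check_scalar_number(bin_size, "bin_size", lower = 1)
  gr <- switch(format,
    bedgraph = rtracklayer::import(path, format = "bedGraph"),
    bigwig   = rtracklayer::import(path, format = "BigWig"))
  if (length(gr) == 0) {
    warning("empty track file: ", path, call. = FALSE)
    return(structure(list(scores = stats::setNames(list(), character(0)),
                          bin_size = bin_size, assay = assay,
                          cell_type = cell_type),
                     class = "BinnedTrack"))
  }
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,  # to 0-based
                   end = GenomicRanges::end(gr),
                   value = gr$score, stringsAsFactors = FALSE)
  ov <- intervals_overlap(df)
  if (isTRUE(ov)) {
    p <- attr(ov, "pair")
    stop2(sprintf("overlapping source intervals: %s:%d-%d and %s:%d-%d",
                  p$chrom[1], p$start[1], p$end[1],
                  p$chrom[2], p$start[2], p$end[2]))
  }
  scores <- lapply(split(df, df$chrom), function(d) {
    n <- as.integer(ceiling(max(d$end) / bin_size))
    num <- numeric(n); cov <- numeric(n)
    for (r in seq_len(nrow(d))) {
      b0 <- floor(d$start[r] / bin_size)
      b1 <- ceiling(d$end[r] / bin_size) - 1
      for (b in b0:b1) {
        o <- min(d$end[r], (b + 1) * bin_size) - max(d$start[r], b * bin_size)
        num[b + 1] <- num[b + 1] + o * d$value[r]
        cov[b + 1] <- cov[b + 1] + o
      }
    }
    v <- ifelse(cov > 0, num / pmax(cov, 1), NA_real_)
    attr(v, "partial") <- which(cov > 0 & cov < bin_size)
    v
  })
  tr <- binned_track(scores, bin_size, assay, cell_type)
  for (chr in names(scores)) { # re-bin flags survive the constructor
    p <- attr(scores[[chr]], "partial")
    if (length(p)) attr(tr$scores[[chr]], "partial") <- p
  }
  tr
}

#' Write a track as bedGraph
#'
#' Emits one record per non-missing bin, 0-based half-open, sorted by
#' (chrom, start). Round-trips with [read_track()] at matching bin size.
#'
#' @param track a [binned_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  df <- as.data.frame(track)
  df <- df[!is.na(df$value), , drop = FALSE]
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED4/BED5 file as an interval set
#' @param path BED file path (chrom, start, end, name\[, score\]).
#' @return An [interval_set()].
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  interval_set(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1L,
               GenomicRanges::end(gr),
               label = if (!is.null(gr$name)) gr$name else NA_character_,
               score = if (!is.null(gr$score)) gr$score else NA_real_)
}

#' Write an interval set as BED4/BED5
#' @param x an [interval_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- data.frame(chrom = x$chrom, start = format(x$start, scientific = FALSE, trim = TRUE),
                   end = format(x$end, scientific = FALSE, trim = TRUE),
                   name = ifelse(is.na(x$label), ".", x$label))
  if (any(!is.na(x$score))) df$score <- ifelse(is.na(x$score), 0, x$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
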