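#' Write a peak set as BED5 with a parameter sidecar
#'
#' Each apex is written as its bin interval with the smoothed apex score
#' and the Type I/II label as name; the calling parameters (span, w,
#' bin size) go to a JSON sidecar next to the BED file.
#'
#' @param peaks a `PeakSet` from [call_peaks()].
#' @param path output BED path; the sidecar is `<path>.json`.
#' @return invisible character vector of files written.
#' @export
write_peaks <- function(peaks, path) {
  bs <- attr(peaks, "bin_size") %||% NA_real_
  iv <- interval_set(peaks$chrom, (peaks$apex_bin - 1) * bs,
                     peaks$apex_bin * bs,
                     label = peaks$type, score = peaks$score)
  write_bed(iv, path)
  side <- paste0(path, ".json")
  jsonlite::write_json(list(span = attr(peaks, "span"), w = attr(peaks, "w"),
                            bin_size = bs, n_peaks = nrow(peaks)),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(c(path, side))
}

#' Write an overlay grid as TSV matrices
#'
#' Emits the per-pixel counts and masked means of an
#' [overlay_histogram()] as tab-separated matrices prefixed by a header
#' of pixel edges.
#'
#' @param grid an `OverlayGrid`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_overlay_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# x_edges\t", paste(grid$x_edges, collapse = "\t")),
               paste0("# y_edges\t", paste(grid$y_edges, collapse = "\t")),
               paste0("# min_count\t", grid$min_count),
               "# count matrix (rows = x pixels)"), con)
  utils::write.table(grid$count, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines("# mean matrix (NA where count < min_count)", con)
  utils::write.table(grid$mean, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
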