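#' Define a synthetic genome
#'
#' A genome specification names chromosomes, fixes their lengths and the
#' bin size used by every binned track derived from it, and carries the
#' seed that makes all downstream generators deterministic.
#'
#' Chromosome lengths are truncated down to whole multiples of `bin_size`,
#' so generated tracks tile each chromosome exactly.
#'
#' @param chrom_sizes named numeric vector, chromosome name -> length (bp).
#' @param bin_size bin width in bp (default 25000, the working resolution
#'   for TSA-seq and DamID tracks).
#' @param seed integer seed that fully determines every dataset generated
#'   from this spec.
#' @return An object of class `GenomeSpec`.
#' @export
genome_spec <- function(chrom_sizes, bin_size = 25000, seed = 1L) {
  if (length(chrom_sizes) == 0 || is.null(names(chrom_sizes)) ||
      any(!nzchar(names(chrom_sizes))))
    stop2("`chrom_sizes` must be a non-empty named vector")
  if (any(!is.finite(chrom_sizes)) || any(chrom_sizes <= 0))
    stop2("all chromosome lengths must be positive")
  check_scalar_number(bin_size, "bin_size", lower = 1)
  sizes <- floor(chrom_sizes / bin_size) * bin_size
  if (any(sizes <= 0))
    stop2("chromosome shorter than one bin: ",
          paste(names(chrom_sizes)[sizes <= 0], collapse = ", "))
  structure(
    list(chrom_sizes = sizes, bin_size = bin_size, seed = as.integer(seed)),
    class = "GenomeSpec"
  )
}

#' @export
print.GenomeSpec <- function(x, ...) {
  cat("GenomeSpec:", length(x$chrom_sizes), "chromosome(s),",
      format(x$bin_size, big.mark = ","), "bp bins, seed", x$seed, "\n")
  invisible(x)
}

# bins per chromosome implied by a spec
spec_n_bins <- function(spec) {
  as.integer(spec$chrom_sizes / spec$bin_size)
}
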