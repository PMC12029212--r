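#' Planted lamina domains
#'
#' Builds the ground-truth table for a synthetic DamID genome: each
#' domain carries a genomic interval, a true three-way class (LAD,
#' peak-within-valley facultative iLAD, or valley facultative iLAD), the
#' DamID score offset it adds over the baseline, and an optional
#' per-cell-type class map for facultative behavior across cell types.
#'
#' The class mean of the `damid_mean` offsets must be ordered
#' LAD > pwv_fiLAD > v_fiLAD within one genome; individual domains may
#' deviate (real LADs vary widely in lamina contact strength).
#'
#' @param chrom,start,end interval columns (bp, 0-based half-open).
#' @param true_class one of `"LAD"`, `"pwv_fiLAD"`, `"v_fiLAD"` per domain.
#' @param damid_mean score offset added over the track baseline.
#' @param per_celltype_class optional data.frame of per-cell-type classes
#'   (one column per cell type, same row order).
#' @return data.frame with class `PlantedDomains`.
#' @export
planted_domains <- function(chrom, start, end, true_class, damid_mean,
                            per_celltype_class = NULL) {
  classes <- c("LAD", "pwv_fiLAD", "v_fiLAD")
  if (!all(true_class %in% classes))
    stop2("true_class must be one of: ", paste(classes, collapse = ", "))
  if (any(end <= start)) stop2("domains must satisfy end > start")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   true_class = true_class, damid_mean = damid_mean,
                   stringsAsFactors = FALSE)
  cm <- tapply(df$damid_mean, factor(df$true_class, classes), mean)
  got <- cm[!is.na(cm)]
  if (length(got) > 1 && any(diff(got) >= 0))
    stop2("class mean damid offsets must be ordered LAD > pwv_fiLAD > v_fiLAD")
  if (!is.null(per_celltype_class)) {
    stopifnot(nrow(per_celltype_class) == nrow(df))
    for (ct in names(per_celltype_class)) {
      if (!all(per_celltype_class[[ct]] %in% classes))
        stop2("per-cell-type classes must use the three-class vocabulary")
      df[[paste0("class_", ct)]] <- per_celltype_class[[ct]]
    }
  }
  class(df) <- c("PlantedDomains", "data.frame")
  df
}

#' Planted speckle peaks
#'
#' Ground truth for a synthetic SON TSA-seq genome: Gaussian bump apexes
#' with amplitude, width, and a true Type I/II label. Type I peaks are
#' generated with stochastically larger amplitudes than Type II,
#' mirroring the higher speckle TSA-seq of A1-overlapping peaks.
#'
#' @param chrom,apex_bp,amplitude,width_bp,true_type per-peak columns;
#'   `width_bp` is the Gaussian sigma in bp, `true_type` in `c("I","II")`.
#' @return data.frame with class `PlantedPeaks`.
#' @export
planted_peaks <- function(chrom, apex_bp, amplitude, width_bp, true_type = "I") {
  if (any(amplitude <= 0)) stop2("amplitude must be > 0")
  if (any(width_bp <= 0)) stop2("width_bp must be > 0")
  if (!all(true_type %in% c("I", "II"))) stop2("true_type must be 'I' or 'II'")
  df <- data.frame(chrom = as.character(chrom), apex_bp = apex_bp,
                   amplitude = amplitude, width_bp = width_bp,
                   true_type = true_type, stringsAsFactors = FALSE)
  class(df) <- c("PlantedPeaks", "data.frame")
  df
}

# domain offset vector for one chromosome: offset added to bins whose
# midpoint falls inside a domain
domain_offsets <- function(n, bin_size, domains, offsets) {
  out <- numeric(n)
  if (!nrow(domains)) return(out)
  mid <- bin_midpoints(n, bin_size)
  for (r in seq_len(nrow(domains))) {
    inside <- mid >= domains$start[r] & mid < domains$end[r]
    out[inside] <- out[inside] + offsets[r]
  }
  out
}

# AR(1) noise with stationary sd `sd` and lag-1 coefficient `rho`
ar1_noise <- function(n, sd, rho) {
  if (sd == 0 || n == 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - rho^2)
  x <- numeric(n)
  e <- stats::rnorm(n)
  x[1] <- e[1] * sd
  if (n > 1) for (i in 2:n) x[i] <- rho * x[i - 1] + innov_sd * e[i]
  x
}

#' Generate a synthetic lamina DamID track
#'
#' Produces a DamID-like log-ratio track: a baseline of -1 (detached
#' chromatin), plus the planted per-domain offsets, plus AR(1) noise with
#' a chosen lag-1 autocorrelation — DamID log-ratios are regionally
#' smooth, and domain-boundary tests need realistic boundary blur.
#' Output is bit-identical for identical inputs and seed.
#'
#' @param spec a [genome_spec()]; its seed drives the noise.
#' @param domains a [planted_domains()] table (non-overlapping per
#'   chromosome); the `offset_col` column supplies per-domain offsets.
#' @param noise_sd stationary sd of the AR(1) noise.
#' @param autocorr lag-1 autocorrelation in \[0, 1).
#' @param baseline baseline score of non-domain bins.
#' @param offset_col column of `domains` holding score offsets.
#' @param stream extra label kept apart from other generators drawing on
#'   the same spec seed.
#' @return A [binned_track()] with the truth table attached as
#'   `attr(, "truth")`.
#' @export
make_damid_track <- function(spec, domains, noise_sd = 0.4, autocorr = 0.3,
                             baseline = -1, offset_col = "damid_mean",
                             stream = "damid") {
  stopifnot(inherits(spec, "GenomeSpec"))
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  check_scalar_number(autocorr, "autocorr", lower = 0, upper = 1 - 1e-12)
  ov <- intervals_overlap(domains)
  if (isTRUE(ov)) {
    p <- attr(ov, "pair")
    stop2(sprintf(
      "overlapping planted domains: %s:%d-%d and %s:%d-%d",
      p$chrom[1], p$start[1], p$end[1], p$chrom[2], p$start[2], p$end[2]))
  }
  nb <- spec_n_bins(spec)
  scores <- with_seed(sub_seed(spec$seed, stream), {
    out <- list()
    for (ci in seq_along(spec$chrom_sizes)) {
      chr <- names(spec$chrom_sizes)[ci]
      d <- domains[domains$chrom == chr, , drop = FALSE]
      sig <- baseline +
        domain_offsets(nb[ci], spec$bin_size, d, d[[offset_col]])
      out[[chr]] <- sig + ar1_noise(nb[ci], noise_sd, autocorr)
    }
    out
  })
  tr <- binned_track(scores, spec$bin_size, assay = "LMNB1_DamID")
  attr(tr, "truth") <- domains
  tr
}

#' Generate replicated synthetic speckle TSA-seq tracks
#'
#' Each replicate is the same deterministic signal — a sum of Gaussian
#' bumps at the planted apexes over a zero baseline — plus independent
#' white noise, emulating a pair of SON TSA-seq replicates.
#'
#' @param spec a [genome_spec()].
#' @param peaks a [planted_peaks()] table.
#' @param rep_noise_sd white-noise sd per replicate.
#' @param n_reps number of replicates (>= 1).
#' @return list of [binned_track()]s, truth attached to each.
#' @export
make_tsa_replicates <- function(spec, peaks, rep_noise_sd = 0.5, n_reps = 2) {
  stopifnot(inherits(spec, "GenomeSpec"))
  check_scalar_number(n_reps, "n_reps", lower = 1)
  nb <- spec_n_bins(spec)
  signal <- list()
  for (ci in seq_along(spec$chrom_sizes)) {
    chr <- names(spec$chrom_sizes)[ci]
    mid <- bin_midpoints(nb[ci], spec$bin_size)
    sig <- numeric(nb[ci])
    p <- peaks[peaks$chrom == chr, , drop = FALSE]
    for (r in seq_len(nrow(p)))
      sig <- sig + p$amplitude[r] *
        exp(-(mid - p$apex_bp[r])^2 / (2 * p$width_bp[r]^2))
    signal[[chr]] <- sig
  }
  lapply(seq_len(n_reps), function(rep) {
    scores <- with_seed(sub_seed(spec$seed, "tsa", rep), {
      lapply(signal, function(sig) sig + stats::rnorm(length(sig), 0, rep_noise_sd))
    })
    tr <- binned_track(scores, spec$bin_size, assay = "SON_TSA")
    attr(tr, "truth") <- peaks
    tr
  })
}

#' Write a generated dataset's planted truth sidecar
#'
#' Emits the planted-truth table attached to a synthetic track as BED
#' (intervals, name = class/type) plus a JSON sidecar with generator
#' parameters, so recovery tests never re-derive truth.
#'
#' @param track a synthetic track carrying `attr(, "truth")`.
#' @param prefix output path prefix (writes `<prefix>.bed`,
#'   `<prefix>.json`).
#' @param params named list of generator parameters to record.
#' @return invisible character vector of paths written.
#' @export
write_truth_sidecar <- function(track, prefix, params = list()) {
  truth <- attr(track, "truth")
  if (is.null(truth)) stop2("track carries no planted truth")
  bed <- paste0(prefix, ".bed")
  js <- paste0(prefix, ".json")
  if (!is.null(truth$apex_bp)) {
    iv <- interval_set(truth$chrom, truth$apex_bp - 1, truth$apex_bp + 1,
                       label = truth$true_type)
  } else {
    iv <- interval_set(truth$chrom, truth$start, truth$end,
                       label = truth$true_class)
  }
  write_bed(iv, bed)
  jsonlite::write_json(list(params = params, truth = truth), js,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(bed, js))
}
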