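#' Early/late replication log-ratio
#'
#' Two-fraction Repli-seq timing score: `log2((E + pc) / (L + pc))` per
#' bin. Positive values replicate early.
#'
#' @param early,late [binned_track()]s on matching bins.
#' @param pseudocount added to both fractions before the ratio.
#' @return A [binned_track()] of log2 ratios.
#' @export
el_log_ratio <- function(early, late, pseudocount = 1) {
  if (!identical(names(early$scores), names(late$scores)) ||
      early$bin_size != late$bin_size ||
      !identical(lengths(early$scores), lengths(late$scores)))
    stop2("early and late tracks must share the same bins")
  bad <- function(t) any(unlist(t$scores) < 0, na.rm = TRUE)
  if (bad(early) || bad(late)) stop2("Repli-seq fraction counts must be >= 0")
  out <- early
  out$scores <- Map(function(e, l) log2((e + pseudocount) / (l + pseudocount)),
                    early$scores, late$scores)
  out$assay <- "RepliEL"
  out
}

#' Replication timing and timing variability from a fraction profile
#'
#' Computes Trep (the S-phase fraction, in \[0,1\], at which a locus
#' reaches half its total replication) and Twidth (the spread of its
#' replication timing) from a multi-fraction Repli-seq profile. Fraction
#' `i` of `n` occupies the S-phase coordinate interval
#' `[(i-1)/n, i/n)`; the profile is normalized to sum 1, its cumulative
#' distribution interpolated linearly within fractions, and Trep read at
#' cumulative 0.5 with Twidth the `q_high - q_low` quantile span
#' (quartile width by default).
#'
#' @param fractions numeric vector (one profile) or matrix (bins x
#'   fractions) of non-negative incorporation values.
#' @param q_low,q_high quantiles bounding the Twidth span.
#' @return A data.frame with columns `trep` and `twidth` (one row per
#'   profile); all-zero profiles yield `NA`.
#' @export
trep_twidth <- function(fractions, q_low = 0.25, q_high = 0.75) {
  if (is.null(dim(fractions))) fractions <- matrix(fractions, nrow = 1)
  if (any(fractions < 0, na.rm = TRUE)) stop2("fraction values must be >= 0")
  n <- ncol(fractions)
  qat <- function(cum, q) {
    # linearly interpolated S-phase coordinate where the cumulative hits q
    i <- which(cum >= q - 1e-12)[1]
    lo <- if (i == 1) 0 else cum[i - 1]
    f <- cum[i] - lo
    ((i - 1) + if (f > 0) (q - lo) / f else 0.5) / n
  }
  out <- t(apply(fractions, 1, function(p) {
    s <- sum(p)
    if (!is.finite(s) || s <= 0) return(c(NA_real_, NA_real_))
    cum <- cumsum(p / s)
    c(qat(cum, 0.5), qat(cum, q_high) - qat(cum, q_low))
  }))
  data.frame(trep = out[, 1], twidth = out[, 2])
}

#' Generate synthetic multi-fraction Repli-seq profiles
#'
#' Each bin's incorporation profile is a Gaussian in S-phase coordinate
#' with median `trep` and quartile width scaled to `twidth`
#' (`sigma = twidth / (2 * qnorm(0.75))`), integrated over the
#' `n_fractions` S-phase intervals and normalized to sum 1. Optional
#' multinomial count noise resamples each profile at `counts` reads.
#'
#' @param trep,twidth numeric vectors of per-bin true values
#'   (`trep` in \[0,1\], `twidth > 0`).
#' @param n_fractions number of S-phase fractions (default 16).
#' @param counts if finite, multinomial read count per bin; `Inf` (the
#'   default) gives noiseless profiles.
#' @param seed RNG seed for the count noise.
#' @return matrix (bins x fractions), rows summing to 1, with the truth
#'   attached as `attr(, "truth")`.
#' @export
make_repli_profiles <- function(trep, twidth, n_fractions = 16,
                                counts = Inf, seed = 1L) {
  if (length(trep) != length(twidth))
    stop2("trep and twidth must have the same length")
  if (any(twidth <= 0)) stop2("twidth must be > 0")
  if (any(trep < 0 | trep > 1)) stop2("trep must lie in [0, 1]")
  n <- length(trep)
  edges <- seq(0, 1, length.out = n_fractions + 1)
  sigma <- twidth / (2 * stats::qnorm(0.75))
  prof <- matrix(0, n, n_fractions)
  for (i in seq_len(n)) {
    cdf <- stats::pnorm(edges, trep[i], sigma[i])
    p <- diff(cdf)
    prof[i, ] <- p / sum(p)
  }
  if (is.finite(counts)) {
    prof <- with_seed(seed, {
      t(apply(prof, 1, function(p) {
        k <- stats::rmultinom(1, counts, p)[, 1]
        k / sum(k)
      }))
    })
  }
  attr(prof, "truth") <- data.frame(trep = trep, twidth = twidth)
  prof
}

#' Call DNA replication initiation zones
#'
#' IZs are local maxima of replication earliness: the peak caller is run
#' on the `1 - Trep` track derived from multi-fraction profiles.
#'
#' @param profiles matrix (bins x fractions) for a single chromosome, or
#'   a list of such matrices named by chromosome.
#' @param bin_size bin width in bp.
#' @param span,w peak-caller parameters (see [call_peaks()]).
#' @return A `PeakSet` of IZ centers, with apex `trep` in the `score_trep`
#'   column.
#' @export
call_izs <- function(profiles, bin_size = 25000, span = 0.02, w = 10) {
  if (!is.list(profiles)) profiles <- list(chr1 = profiles)
  tt <- lapply(profiles, function(m) trep_twidth(m)$trep)
  earliness <- binned_track(lapply(tt, function(v) 1 - v), bin_size,
                            assay = "Repli_earliness")
  izs <- call_peaks(earliness, span = span, w = w)
  izs$score_trep <- unlist(Map(function(chr, bin) tt[[chr]][bin],
                               izs$chrom, izs$apex_bin), use.names = FALSE) %||% numeric(0)
  izs
}

#' Quartile timing classes of initiation zones
#'
#' Splits IZs into early / early-mid / late-mid / late classes at the
#' quartiles of their apex Trep values; ties at quartile edges go to the
#' earlier class.
#'
#' @param trep_at_apex numeric vector of apex Trep values.
#' @return factor of classes, same length.
#' @export
iz_timing_classes <- function(trep_at_apex) {
  lv <- c("early", "early-mid", "late-mid", "late")
  n <- length(trep_at_apex)
  if (n < 4) {
    warning("fewer than 4 IZs; all assigned class 'early'", call. = FALSE)
    return(factor(rep("early", n), levels = lv))
  }
  q <- stats::quantile(trep_at_apex, c(0.25, 0.5, 0.75), names = FALSE)
  cls <- ifelse(trep_at_apex <= q[1], lv[1],
         ifelse(trep_at_apex <= q[2], lv[2],
         ifelse(trep_at_apex <= q[3], lv[3], lv[4])))
  factor(cls, levels = lv)
}
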