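# Hartigan's dip statistic and a Monte-Carlo bimodality test.
#
# The dip of an empirical distribution function is the smallest sup-norm
# distance between the ECDF and any unimodal distribution function. It
# is computed by the classic iterative construction: the greatest convex
# minorant (GCM) and least concave majorant (LCM) of the ECDF are fit on
# a shrinking candidate modal interval; the maximum one-sided deviations
# of the ECDF from the GCM (left tail) and LCM (right tail) accumulate
# into the dip, and the interval shrinks to where the two hulls diverge
# most, until the hull gap no longer exceeds the accumulated deviation.

# lower convex hull touch indices of points (x[idx], idx), idx ascending
gcm_touch <- function(x, idx) {
  st <- idx[1]
  for (j in idx[-1]) {
    while (length(st) >= 2) {
      a <- st[length(st) - 1]; b <- st[length(st)]
      # pop b while slope(a,b) >= slope(b,j)  (cross-multiplied)
      if ((b - a) * (x[j] - x[b]) >= (j - b) * (x[b] - x[a])) st <- st[-length(st)]
      else break
    }
    st <- c(st, j)
  }
  st
}

# upper concave hull touch indices
lcm_touch <- function(x, idx) {
  st <- idx[1]
  for (j in idx[-1]) {
    while (length(st) >= 2) {
      a <- st[length(st) - 1]; b <- st[length(st)]
      if ((b - a) * (x[j] - x[b]) <= (j - b) * (x[b] - x[a])) st <- st[-length(st)]
      else break
    }
    st <- c(st, j)
  }
  st
}

# interpolate the hull through (x[touch], touch) at every index lo..hi,
# in count units
hull_interp <- function(x, touch, lo, hi) {
  idx <- lo:hi
  out <- numeric(length(idx))
  for (k in seq_len(length(touch) - 1)) {
    a <- touch[k]; b <- touch[k + 1]
    span <- idx >= a & idx <= b
    if (x[b] > x[a])
      out[span] <- a + (b - a) * (x[idx[span]] - x[a]) / (x[b] - x[a])
    else out[span] <- a  # tied x: vertical segment, use lower count
  }
  out[match(touch, idx)] <- touch
  out
}

#' Hartigan's dip statistic
#'
#' Maximum deviation between the sample ECDF and the nearest unimodal
#' distribution function, computed by the iterative greatest-convex-
#' minorant / least-concave-majorant construction. For a sample of
#' distinct values the dip lies in `[1/(2n), 0.25]`; an all-equal sample
#' (a point mass, itself unimodal) has dip 0.
#'
#' @param x numeric sample, `n >= 4`.
#' @return the dip statistic.
#' @export
dip_statistic <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n < 4) stop2("dip requires n >= 4")
  if (x[1] == x[n]) return(0)
  lo <- 1L; hi <- n; D <- 0  # D in count units
  repeat {
    g <- gcm_touch(x, lo:hi)
    l <- lcm_touch(x, lo:hi)
    Ghat <- hull_interp(x, g, lo, hi)  # counts of the minorant (fit to i)
    Lhat <- hull_interp(x, l, lo, hi)
    # gap between LCM (fit to upper corners i) and GCM (fit to lower
    # corners i-1): Lhat - (Ghat - 1)
    gap <- Lhat - Ghat + 1
    m <- lo - 1L + which.max(gap)
    d <- gap[m - lo + 1L]
    if (d <= D + 1e-12) break
    if (m %in% g && !(m %in% l)) {
      ig <- m
      ih <- l[l >= m][1]
    } else if (m %in% l && !(m %in% g)) {
      ih <- m
      ig <- rev(g[g <= m])[1]
    } else {        # touch of both hulls: modal interval collapses here
      ig <- ih <- m
    }
    idxL <- lo:ig
    dl <- max(idxL - Ghat[idxL - lo + 1L] + 1)
    idxR <- ih:hi
    du <- max(Lhat[idxR - lo + 1L] - idxR + 1)
    D <- max(D, dl, du)
    if (ig == lo && ih == hi) break  # cannot shrink further
    lo <- ig; hi <- ih
  }
  D / (2 * n)
}

#' Monte-Carlo null distribution of the dip
#'
#' Dip statistics of `n_boot` uniform samples of size `n` — the
#' calibration null for the dip test (the uniform is the least
#' favorable unimodal distribution). Computing this once and passing it
#' to [dip_bimodality()] amortizes the cost over many tests of
#' equally-sized samples.
#'
#' @param n sample size.
#' @param n_boot number of null replicates.
#' @param seed RNG seed.
#' @return numeric vector of `n_boot` null dips.
#' @export
dip_null <- function(n, n_boot = 2000, seed = 1L) {
  with_seed(sub_seed(seed, "dipnull", n),
            vapply(seq_len(n_boot),
                   function(i) dip_statistic(stats::runif(n)), 1.0))
}

#' Dip test of unimodality
#'
#' Hartigan's dip test with a seeded Monte-Carlo p-value: the observed
#' dip is compared against dips of uniform null samples of the same
#' size. Small p-values indicate departure from unimodality (e.g. a
#' bimodal speckle-distance distribution).
#'
#' @param sample numeric sample, `n >= 4`.
#' @param n_boot Monte-Carlo replicates for the p-value.
#' @param seed RNG seed.
#' @param null_dips optional precomputed [dip_null()] vector (must match
#'   `length(sample)`); overrides `n_boot`/`seed`.
#' @return list with `dip`, `p_value`, `n`, `n_boot`.
#' @export
dip_bimodality <- function(sample, n_boot = 2000, seed = 1L,
                           null_dips = NULL) {
  d <- dip_statistic(sample)
  nd <- null_dips %||% dip_null(length(sample[!is.na(sample)]), n_boot, seed)
  p <- (1 + sum(nd >= d)) / (length(nd) + 1)
  list(dip = d, p_value = p, n = length(sample[!is.na(sample)]),
       n_boot = length(nd))
}
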