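#' Genome-wide z-normalization
#'
#' Centers and scales a track by its genome-wide mean and population
#' standard deviation over non-missing bins. Whole-genome tracks are the
#' full population of bins, hence the population (not sample) sd
#' convention. Missing bins stay missing.
#'
#' @param track a [binned_track()] with at least two non-missing bins.
#' @return The z-normalized `BinnedTrack`.
#' @export
znormalize <- function(track) {
  v <- track_values(track)
  if (length(v) < 2) stop2("znormalize needs >= 2 non-missing bins")
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s == 0) stop2("znormalize: zero variance track")
  track_map(track, function(x) (x - m) / s)
}

#' Genome-wide percentile transform
#'
#' Converts bin scores to percentiles in \[0, 100\] across all
#' non-missing bins of the genome, using the average-rank convention for
#' ties (`rank * 100 / n`). This is the transform applied to ChIP
#' fold-change tracks before overlaying them on scatterplots.
#'
#' @param track a [binned_track()].
#' @return `BinnedTrack` of percentile values.
#' @export
percentile_transform <- function(track) {
  v <- unlist(track$scores, use.names = FALSE)
  ok <- !is.na(v)
  if (!any(ok)) stop2("percentile_transform needs >= 1 non-missing bin")
  p <- rep(NA_real_, length(v))
  p[ok] <- rank(v[ok], ties.method = "average") / sum(ok) * 100
  lens <- vapply(track$scores, length, 1L)
  track$scores <- stats::setNames(
    split(p, rep(seq_along(lens), lens)), names(track$scores))
  track
}

#' Aggregate a track to coarser bins
#'
#' Re-bins to an integer multiple of the current bin size by averaging
#' the constituent non-missing fine bins; groups that are fully missing
#' stay missing. Used e.g. to move from the 25 kb assay resolution to the
#' 100 kb resolution of cLAD scoring.
#'
#' @param track a [binned_track()].
#' @param new_bin_size target bin width, an integer multiple of the
#'   current one.
#' @return The re-binned `BinnedTrack`.
#' @export
rebin <- function(track, new_bin_size) {
  check_scalar_number(new_bin_size, "new_bin_size", lower = track$bin_size)
  f <- new_bin_size / track$bin_size
  if (abs(f - round(f)) > 1e-9)
    stop2("`new_bin_size` must be an integer multiple of bin_size")
  f <- as.integer(round(f))
  if (f == 1L) return(track)
  track$scores <- lapply(track$scores, function(v) {
    grp <- (seq_along(v) - 1L) %/% f
    out <- tapply(v, grp, function(g) {
      g <- g[!is.na(g)]
      if (length(g)) mean(g) else NA_real_
    })
    as.numeric(out)
  })
  track$bin_size <- new_bin_size
  track
}

# Tricube-weighted local-linear fit at position i over window indices win
# of series y; returns fitted value, or y[i] when fewer than 3 usable
# neighbors are available.
loess_fit_one <- function(y, i, win) {
  yj <- y[win]
  use <- !is.na(yj)
  if (sum(use) < 3) return(structure(y[i], passthrough = TRUE))
  xj <- win[use]; yj <- yj[use]
  d <- abs(xj - i)
  dmax <- max(d)
  w <- if (dmax == 0) rep(1, length(d)) else (1 - pmin(1, d / dmax)^3)^3
  if (sum(w) <= 0) w <- rep(1, length(d))
  sw <- sum(w)
  xb <- sum(w * xj) / sw
  yb <- sum(w * yj) / sw
  sxx <- sum(w * (xj - xb)^2)
  b <- if (sxx > 0) sum(w * (xj - xb) * (yj - yb)) / sxx else 0
  yb + b * (i - xb)
}

loess_smooth_vec <- function(y, span) {
  n <- length(y)
  k <- max(3L, as.integer(ceiling(span * n)))
  if (k %% 2L == 0L) k <- k + 1L       # symmetric neighborhoods
  if (k > n) k <- n - (1L - n %% 2L)   # largest odd window <= n
  if (k < 3L) return(structure(y, passthrough = sum(!is.na(y))))
  h <- (k - 1L) %/% 2L
  out <- rep(NA_real_, n)
  has_na <- anyNA(y)
  interior <- (h + 1L):(n - h)
  if (!has_na && length(interior)) {
    # interior bins: symmetric window => local-linear fit reduces to a
    # tricube-weighted moving average (the slope term vanishes at center)
    d <- abs(seq(-h, h))
    w <- (1 - pmin(1, d / h)^3)^3
    w <- w / sum(w)
    sm <- stats::filter(y, w, sides = 2)
    out[interior] <- as.numeric(sm)[interior]
    edge <- setdiff(seq_len(n), interior)
  } else {
    edge <- seq_len(n)
  }
  n_pass <- 0L
  for (i in edge) {
    if (is.na(y[i])) next               # missing bins stay missing
    lo <- min(max(1L, i - h), n - k + 1L)
    v <- loess_fit_one(y, i, lo:(lo + k - 1L))
    if (isTRUE(attr(v, "passthrough"))) n_pass <- n_pass + 1L
    out[i] <- as.numeric(v)
  }
  structure(out, passthrough = n_pass)
}

#' LOESS smoothing of a binned track
#'
#' Classic locally weighted regression: each bin's value is replaced by a
#' tricube-weighted local linear fit over its `span * n` nearest bins
#' (rounded up to an odd count so interior neighborhoods are symmetric),
#' where `n` is the chromosome's bin count. Smoothing is strictly
#' per-chromosome and never crosses chromosome ends. Missing bins are
#' excluded from fits and stay missing; a bin with fewer than 3 usable
#' neighbors passes through unsmoothed with a warning.
#'
#' @param track a [binned_track()].
#' @param span fraction of the chromosome's bins forming each local
#'   neighborhood, in (0, 1].
#' @return Smoothed `BinnedTrack`.
#' @export
loess_smooth <- function(track, span) {
  check_scalar_number(span, "span", lower = 0, upper = 1, strict_lower = TRUE)
  n_pass <- 0L
  track$scores <- lapply(track$scores, function(v) {
    out <- loess_smooth_vec(v, span)
    n_pass <<- n_pass + (attr(out, "passthrough") %||% 0L)
    as.numeric(out)
  })
  if (n_pass > 0)
    warning(n_pass, " bin(s) had < 3 usable neighbors and passed through unsmoothed",
            call. = FALSE)
  track
}
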