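# Independent brute-force oracles used across tests. These deliberately
# re-derive results by the most literal method available so they stay
# independent of the package's implementation paths.

# windowed maximum by direct enumeration
oracle_max_filter <- function(v, w) {
  n <- length(v)
  vapply(seq_len(n), function(i) {
    win <- v[max(1, i - w):min(n, i + w)]
    win <- win[!is.na(win)]
    if (!length(win)) NA_real_ else max(win)
  }, 1.0)
}

# tricube local-linear regression by direct weighted least squares
oracle_loess <- function(y, span) {
  n <- length(y)
  k <- max(3L, as.integer(ceiling(span * n)))
  if (k %% 2L == 0L) k <- k + 1L
  if (k > n) k <- n - (1L - n %% 2L)
  h <- (k - 1L) %/% 2L
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(y[i])) next
    lo <- min(max(1L, i - h), n - k + 1L)
    win <- lo:(lo + k - 1L)
    use <- win[!is.na(y[win])]
    if (length(use) < 3) { out[i] <- y[i]; next }
    d <- abs(use - i); dmax <- max(d)
    wgt <- if (dmax == 0) rep(1, length(d)) else (1 - pmin(1, d / dmax)^3)^3
    fit <- stats::lm.wfit(cbind(1, use), y[use], wgt)
    out[i] <- sum(fit$coefficients * c(1, i))
  }
  out
}

# dip by exhaustive lattice search over unimodal CDF candidates: monotone
# lattice values whose chord-slope sequence rises then falls
oracle_dip_lattice <- function(x, m = 30) {
  x <- sort(x); n <- length(x)
  lat <- seq(0, 1, length.out = m + 1)
  grid <- as.matrix(expand.grid(rep(list(lat), n)))
  mono <- rowSums(grid[, -1, drop = FALSE] >= grid[, -n, drop = FALSE]) == n - 1
  grid <- grid[mono, , drop = FALSE]
  dx <- diff(x); iidx <- seq_len(n); best <- Inf
  for (r in seq_len(nrow(grid))) {
    u <- grid[r, ]
    dc <- diff(diff(u) / dx)
    ok <- FALSE
    for (p in 0:length(dc)) {
      if ((p == 0 || all(dc[1:p] >= -1e-12)) &&
          (p == length(dc) || all(dc[(p + 1):length(dc)] <= 1e-12))) {
        ok <- TRUE; break
      }
    }
    if (!ok) next
    best <- min(best, max(pmax(iidx / n - u, u - (iidx - 1) / n)))
  }
  best
}

# digitized sphere mask of radius r voxels
sphere_mask <- function(r, pad = 3) {
  d <- 2 * r + 2 * pad + 1
  ax <- (1:d) - (d + 1) / 2
  outer(outer(ax^2, ax^2, "+"), ax^2, "+") <= r^2
}

# direct-sum truncated-kernel convolution oracle (double loop over
# source voxels and all voxels)
oracle_convolve <- function(mask, voxel_nm, B = 5.86, R = 3,
                            cutoff_frac = 0.01) {
  sp <- rep(voxel_nm, length.out = 3) / 1000
  half <- floor((log(1 / cutoff_frac) / R) / sp)
  out <- array(0, dim(mask))
  co <- arrayInd(seq_along(mask), dim(mask))
  for (i in which(mask)) {
    ci <- co[i, ]
    d <- sqrt(((co[, 1] - ci[1]) * sp[1])^2 + ((co[, 2] - ci[2]) * sp[2])^2 +
                ((co[, 3] - ci[3]) * sp[3])^2)
    k <- B * exp(-R * d)
    k[k < cutoff_frac * B] <- 0
    k[abs(co[, 1] - ci[1]) > half[1] | abs(co[, 2] - ci[2]) > half[2] |
        abs(co[, 3] - ci[3]) > half[3]] <- 0
    out <- out + array(k, dim(mask))
  }
  out
}

# quick genome for track tests
tiny_spec <- function(seed = 1, n_mb = 50, bin = 25000)
  genome_spec(c(chr1 = n_mb * 1e6), bin, seed = seed)
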