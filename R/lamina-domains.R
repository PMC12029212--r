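# Two-state Gaussian-emission HMM for LAD segmentation.
#
# Fit genome-wide by EM with a deterministic initialization (sign split
# at 0), decoded per chromosome by Viterbi. Missing bins contribute a
# flat emission likelihood. State 2 is constrained to the higher mean
# (lamina-associated), state 1 the lower (detached).

hmm_em <- function(chrom_values, tol = 1e-4, max_iter = 300,
                   var_floor = 1e-6) {
  all_v <- unlist(chrom_values, use.names = FALSE)
  obs <- all_v[!is.na(all_v)]
  if (length(obs) < 10) stop2("need >= 10 non-missing bins to fit the HMM")
  pos <- obs > 0
  if (!any(pos) || all(pos)) {
    # single-population genome: split at the median so EM can still run
    pos <- obs > stats::median(obs)
    if (!any(pos) || all(pos)) pos <- seq_along(obs) > length(obs) / 2
  }
  mu <- c(mean(obs[!pos]), mean(obs[pos]))
  sd2 <- c(stats::sd(obs[!pos]), stats::sd(obs[pos]))^2
  sd2[!is.finite(sd2) | sd2 < var_floor] <- max(var_floor, stats::var(obs) / 4)
  trans <- matrix(c(0.98, 0.02, 0.02, 0.98), 2, 2, byrow = TRUE)
  init <- c(mean(!pos), mean(pos))
  floored <- FALSE

  emis <- function(v) {
    # n x 2 emission densities; NA bins emit 1 in both states
    e <- cbind(stats::dnorm(v, mu[1], sqrt(sd2[1])),
               stats::dnorm(v, mu[2], sqrt(sd2[2])))
    e[is.na(v), ] <- 1
    pmax(e, 1e-300)
  }

  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    ll <- 0
    g_sum <- numeric(2); g_mu <- numeric(2); g_m2 <- numeric(2)
    xi <- matrix(0, 2, 2); init_acc <- numeric(2)
    for (v in chrom_values) {
      n <- length(v)
      if (n == 0) next
      e <- emis(v)
      alpha <- matrix(0, n, 2); beta <- matrix(0, n, 2); cvec <- numeric(n)
      a <- init * e[1, ]
      cvec[1] <- sum(a); alpha[1, ] <- a / cvec[1]
      if (n > 1) for (t in 2:n) {
        a <- (alpha[t - 1, ] %*% trans) * e[t, ]
        cvec[t] <- sum(a); alpha[t, ] <- a / cvec[t]
      }
      beta[n, ] <- 1
      if (n > 1) for (t in (n - 1):1)
        beta[t, ] <- (trans %*% (e[t + 1, ] * beta[t + 1, ])) / cvec[t + 1]
      ll <- ll + sum(log(cvec))
      gam <- alpha * beta
      gam <- gam / rowSums(gam)
      ok <- !is.na(v)
      g_sum <- g_sum + colSums(gam[ok, , drop = FALSE])
      g_mu <- g_mu + colSums(gam[ok, , drop = FALSE] * v[ok])
      g_m2 <- g_m2 + colSums(gam[ok, , drop = FALSE] * v[ok]^2)
      init_acc <- init_acc + gam[1, ]
      if (n > 1) for (t in 2:n) {
        x <- (alpha[t - 1, ] %o% (e[t, ] * beta[t, ])) * trans
        xi <- xi + x / sum(x)
      }
    }
    mu_new <- g_mu / g_sum
    sd2_new <- g_m2 / g_sum - mu_new^2
    if (any(sd2_new < var_floor)) {
      sd2_new <- pmax(sd2_new, var_floor)
      floored <- TRUE
    }
    mu <- mu_new; sd2 <- sd2_new
    trans <- xi / rowSums(xi)
    init <- init_acc / sum(init_acc)
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
  }
  if (floored)
    warning("HMM emission variance floored at ", var_floor, call. = FALSE)
  if (mu[1] > mu[2]) {  # enforce state 2 = higher mean
    mu <- rev(mu); sd2 <- rev(sd2); init <- rev(init)
    trans <- trans[2:1, 2:1]
  }
  list(mu = mu, sd2 = sd2, trans = trans, init = init, loglik = ll)
}

hmm_viterbi <- function(v, fit) {
  n <- length(v)
  if (n == 0) return(integer(0))
  e <- cbind(stats::dnorm(v, fit$mu[1], sqrt(fit$sd2[1])),
             stats::dnorm(v, fit$mu[2], sqrt(fit$sd2[2])))
  e[is.na(v), ] <- 1
  le <- log(pmax(e, 1e-300))
  lt <- log(fit$trans)
  delta <- matrix(-Inf, n, 2); psi <- matrix(1L, n, 2)
  delta[1, ] <- log(pmax(fit$init, 1e-300)) + le[1, ]
  if (n > 1) for (t in 2:n) for (s in 1:2) {
    cand <- delta[t - 1, ] + lt[, s]
    psi[t, s] <- which.max(cand)
    delta[t, s] <- cand[psi[t, s]] + le[t, s]
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

#' Call lamina-associated domains from a DamID track
#'
#' Fits a two-state Gaussian hidden Markov model to the genome-wide
#' LMNB1 DamID log-ratios (EM from a deterministic sign-split
#' initialization, so results are seed-free), Viterbi-decodes each
#' chromosome, and reports runs of the higher-mean state as LADs. Runs
#' shorter than `min_bins` are dropped; adjacent LADs separated by a
#' single bin are merged.
#'
#' @param damid a [binned_track()] of DamID log-ratios.
#' @param min_bins minimum LAD length in bins.
#' @return A `DomainSet`: [interval_set()] with `label = "LAD"` and the
#'   HMM fit in `attr(, "fit")`.
#' @export
call_lads_hmm <- function(damid, min_bins = 4) {
  fit <- hmm_em(damid$scores)
  bs <- damid$bin_size
  out <- list()
  # LADs are defined by positive DamID: a genome whose higher-mean state
  # is still non-positive has no lamina-associated state at all
  lad_state_ok <- fit$mu[2] > 0
  for (chr in if (lad_state_ok) names(damid$scores) else character(0)) {
    v <- damid$scores[[chr]]
    path <- hmm_viterbi(v, fit)
    lad <- path == 2L
    r <- rle(lad)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    iv <- cbind(starts[r$values], ends[r$values])
    if (!nrow(iv)) next
    # merge LADs separated by < 2 bins, then drop short runs
    if (nrow(iv) > 1) {
      keep <- list(iv[1, ])
      for (k in 2:nrow(iv)) {
        last <- keep[[length(keep)]]
        if (iv[k, 1] - last[2] - 1L < 2L) keep[[length(keep)]] <- c(last[1], iv[k, 2])
        else keep[[length(keep) + 1L]] <- iv[k, ]
      }
      iv <- do.call(rbind, keep)
    }
    iv <- iv[iv[, 2] - iv[, 1] + 1L >= min_bins, , drop = FALSE]
    if (nrow(iv))
      out[[chr]] <- data.frame(chrom = chr, start = (iv[, 1] - 1) * bs,
                               end = iv[, 2] * bs)
  }
  df <- if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE)))
        else data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  ds <- interval_set(df$chrom, df$start, df$end, label = "LAD")
  attr(ds, "fit") <- fit
  class(ds) <- c("DomainSet", class(ds))
  ds
}

#' Build a cross-cell-type LAD consensus
#'
#' The consensus set is the union of all chromosome regions that are a
#' LAD in at least one cell type; overlapping or bookended intervals are
#' merged. Each consensus domain is annotated per cell type as `"LAD"`
#' (>= 50% reciprocal overlap with one of that cell type's LADs, by
#' default) or `"fiLAD_candidate"`.
#'
#' @param lad_sets named list (cell type -> `DomainSet` of LAD calls).
#' @param reciprocal minimum reciprocal overlap fraction for LAD status.
#' @return A `ConsensusSet`: data.frame of (chrom, start, end) plus one
#'   `status_<cell type>` column per cell type; contributing cell types
#'   recorded in `attr(, "cell_types")`.
#' @export
build_consensus <- function(lad_sets, reciprocal = 0.5) {
  if (!length(lad_sets) || is.null(names(lad_sets)))
    stop2("`lad_sets` must be a non-empty named list")
  grl <- lapply(lad_sets, function(d)
    GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start + 1, d$end)))
  merged <- GenomicRanges::reduce(do.call(c, unname(grl)))
  cons <- data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
                     start = GenomicRanges::start(merged) - 1,
                     end = GenomicRanges::end(merged),
                     stringsAsFactors = FALSE)
  for (ct in names(lad_sets)) {
    hits <- GenomicRanges::findOverlaps(merged, grl[[ct]])
    ov <- GenomicRanges::pintersect(merged[S4Vectors::queryHits(hits)],
                                    grl[[ct]][S4Vectors::subjectHits(hits)])
    wd <- GenomicRanges::width(ov)
    okq <- wd >= reciprocal * GenomicRanges::width(merged[S4Vectors::queryHits(hits)])
    oks <- wd >= reciprocal * GenomicRanges::width(grl[[ct]][S4Vectors::subjectHits(hits)])
    is_lad <- unique(S4Vectors::queryHits(hits)[okq & oks])
    cons[[paste0("status_", ct)]] <- "fiLAD_candidate"
    cons[[paste0("status_", ct)]][is_lad] <- "LAD"
  }
  cons <- cons[order(cons$chrom, cons$start), , drop = FALSE]
  rownames(cons) <- NULL
  structure(cons, class = c("ConsensusSet", "data.frame"),
            cell_types = names(lad_sets))
}

#' Local DamID enrichment of a domain over its flanks
#'
#' Enrichment is the mean DamID score over the domain's bins minus the
#' mean over its flanking bins. Each flank extends
#' `min(flank_factor * domain length, flank_cap)` bp, is truncated at
#' chromosome ends, and excludes bins inside other consensus domains.
#'
#' @param damid a [binned_track()].
#' @param chrom,start,end the domain (bp, 0-based half-open).
#' @param flank_factor,flank_cap flank extent parameters.
#' @param exclude optional data.frame of intervals (e.g. the other
#'   consensus domains) whose bins are removed from flanks.
#' @return enrichment score, or `NA` (with the `"flagged"` attribute)
#'   when no usable flank bin exists.
#' @export
local_enrichment <- function(damid, chrom, start, end, flank_factor = 1,
                             flank_cap = 1e6, exclude = NULL) {
  v <- damid$scores[[chrom]]
  if (is.null(v)) stop2("chromosome not in track: ", chrom)
  bs <- damid$bin_size
  n <- length(v)
  mid <- bin_midpoints(n, bs)
  inside <- mid >= start & mid < end
  flen <- min(flank_factor * (end - start), flank_cap)
  fl <- (mid >= start - flen & mid < start) | (mid >= end & mid < end + flen)
  if (!is.null(exclude) && nrow(exclude)) {
    ex <- exclude[exclude$chrom == chrom & !(exclude$start == start & exclude$end == end), , drop = FALSE]
    for (r in seq_len(nrow(ex)))
      fl[mid >= ex$start[r] & mid < ex$end[r]] <- FALSE
  }
  dv <- v[inside]; fv <- v[fl]
  dv <- dv[!is.na(dv)]; fv <- fv[!is.na(fv)]
  if (!length(dv) || !length(fv))
    return(structure(NA_real_, flagged = TRUE))
  mean(dv) - mean(fv)
}

#' Classify consensus domains per cell type
#'
#' Applies the three-class scheme to every consensus domain in every
#' cell type: a domain called LAD in that cell type keeps class `LAD`;
#' the remaining (facultative iLAD) domains are `v_fiLAD` when their
#' local enrichment falls below the `quantile` level of that cell type's
#' LAD enrichment distribution ("lower than 95% of the LADs" at the 0.05
#' default), and `pwv_fiLAD` otherwise.
#'
#' @param consensus a [build_consensus()] result.
#' @param damid_tracks named list (cell type -> DamID [binned_track()]).
#' @param quantile v-fiLAD threshold level of the LAD enrichment
#'   distribution.
#' @param flank_factor,flank_cap passed to [local_enrichment()].
#' @param exclude_other_domains when `TRUE`, flank bins inside other
#'   consensus domains are excluded from enrichment flanks. The default
#'   keeps them: a LAD inside a LAD cluster then shows elevated flanks
#'   and hence the low local enrichment that gives the LAD enrichment
#'   distribution its broad lower tail — the regime in which
#'   peak-within-valley fiLADs show intermediate (above-threshold)
#'   enrichment. Excluding neighbors inflates every LAD's enrichment and
#'   collapses pwv into v.
#' @return named list (cell type -> `DomainSet` with classes and
#'   enrichments); thresholds in `attr(, "thresholds")`.
#' @export
classify_consensus <- function(consensus, damid_tracks, quantile = 0.05,
                               flank_factor = 1, flank_cap = 1e6,
                               exclude_other_domains = FALSE) {
  cts <- attr(consensus, "cell_types")
  if (!all(cts %in% names(damid_tracks)))
    stop2("damid_tracks must cover every consensus cell type")
  out <- list(); thresholds <- numeric(0)
  for (ct in cts) {
    enr <- vapply(seq_len(nrow(consensus)), function(i)
      as.numeric(local_enrichment(damid_tracks[[ct]], consensus$chrom[i],
                                  consensus$start[i], consensus$end[i],
                                  flank_factor, flank_cap,
                                  exclude = if (exclude_other_domains)
                                    consensus else NULL)), 1.0)
    is_lad <- consensus[[paste0("status_", ct)]] == "LAD"
    lad_enr <- enr[is_lad & !is.na(enr)]
    if (length(lad_enr) < 20)
      warning("cell type ", ct, ": only ", length(lad_enr),
              " LADs; v-fiLAD threshold is unstable", call. = FALSE)
    thr <- stats::quantile(lad_enr, quantile, names = FALSE)
    thresholds[ct] <- thr
    cls <- ifelse(is_lad, "LAD",
                  ifelse(!is.na(enr) & enr < thr, "v_fiLAD", "pwv_fiLAD"))
    ds <- interval_set(consensus$chrom, consensus$start, consensus$end,
                       label = cls, score = enr)
    ds$cell_type <- ct
    class(ds) <- c("DomainSet", class(ds))
    out[[ct]] <- ds
  }
  attr(out, "thresholds") <- thresholds
  out
}

#' Constitutive-LAD (cLAD) score
#'
#' Counts, for each bin of a coarse grid (100 kb by default), the number
#' of cell lines whose LAD calls cover the bin midpoint. Bins outside
#' the union of all LAD calls score 0 and are flagged non-union. The
#' count is invariant to the order of cell types.
#'
#' @param lad_sets named list (up to 7 cell lines -> LAD `DomainSet`).
#' @param chrom_sizes named vector of chromosome lengths (bp).
#' @param bin_size counting grid width (bp).
#' @return A [binned_track()] of integer counts with a `"non_union"`
#'   attribute per chromosome.
#' @export
clad_score <- function(lad_sets, chrom_sizes, bin_size = 1e5) {
  if (!length(lad_sets) || length(lad_sets) > 7)
    stop2("clad_score takes 1 to 7 cell lines")
  scores <- list()
  for (chr in names(chrom_sizes)) {
    n <- as.integer(ceiling(chrom_sizes[[chr]] / bin_size))
    mid <- bin_midpoints(n, bin_size)
    cnt <- integer(n)
    for (ds in lad_sets) {
      d <- ds[ds$chrom == chr, , drop = FALSE]
      covered <- logical(n)
      for (r in seq_len(nrow(d)))
        covered <- covered | (mid >= d$start[r] & mid < d$end[r])
      cnt <- cnt + covered
    }
    scores[[chr]] <- as.numeric(cnt)
  }
  tr <- binned_track(scores, bin_size, assay = "cLAD")
  attr(tr, "non_union") <- lapply(tr$scores, function(v) which(v == 0))
  tr
}
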