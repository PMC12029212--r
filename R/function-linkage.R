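#' Per-gene deltas between two cell types
#'
#' Builds the table relating changes in locale proximity to changes in
#' expression and replication timing for a cell-type pair (A, B): for
#' every gene, the z-normalized TSA-seq score differences (A - B) for
#' SON, LMNB1 and MKI67IP at the gene's bin, the expression change
#' `log2((fpkmA + 1) / (fpkmB + 1))`, and optionally the change in the
#' two-fraction replication-timing log-ratio.
#'
#' @param tracks_a,tracks_b named lists of [binned_track()]s per cell
#'   type, with elements `SON_TSA`, `LMNB1_TSA`, `MKI67IP_TSA` (raw
#'   scores; z-normalization is applied here) and optionally `RepliEL`.
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `fpkm_a`, `fpkm_b`. The TSS is `start` on `+` and
#'   `end - 1` on `-` strands.
#' @param mode gene-to-bin assignment: `"tss"` (the TSS-containing bin)
#'   or `"overlap"` (mean delta over all bins the gene overlaps).
#' @return A `DeltaTable` data.frame with one row per usable gene;
#'   dropped-gene count in `attr(, "n_dropped")`.
#' @export
build_delta_table <- function(tracks_a, tracks_b, genes,
                              mode = c("tss", "overlap")) {
  mode <- match.arg(mode)
  assays <- c(d_son = "SON_TSA", d_lmnb1 = "LMNB1_TSA", d_mki67ip = "MKI67IP_TSA")
  for (a in assays)
    if (is.null(tracks_a[[a]]) || is.null(tracks_b[[a]]))
      stop2("both cell types need track: ", a)
  bs <- tracks_a[[1]]$bin_size
  all_tracks <- c(tracks_a, tracks_b)
  if (any(vapply(all_tracks, function(t) t$bin_size, 1.0) != bs))
    stop2("mismatched bin sizes between tracks")
  za <- lapply(tracks_a[assays], znormalize)
  zb <- lapply(tracks_b[assays], znormalize)
  names(za) <- names(zb) <- names(assays)

  tss <- ifelse(genes$strand == "-", genes$end - 1, genes$start)
  delta_at <- function(zt_a, zt_b, g) {
    va <- zt_a$scores[[genes$chrom[g]]]; vb <- zt_b$scores[[genes$chrom[g]]]
    if (is.null(va)) return(NA_real_)
    if (mode == "tss") {
      b <- pos_to_bin(tss[g], bs)
      if (b > length(va)) return(NA_real_)
      va[b] - vb[b]
    } else {
      b0 <- pos_to_bin(genes$start[g], bs)
      b1 <- min(pos_to_bin(genes$end[g] - 1, bs), length(va))
      if (b0 > length(va)) return(NA_real_)
      d <- va[b0:b1] - vb[b0:b1]
      if (all(is.na(d))) NA_real_ else mean(d, na.rm = TRUE)
    }
  }
  n <- nrow(genes)
  tab <- data.frame(
    gene_id = genes$gene_id,
    d_son = vapply(seq_len(n), function(g) delta_at(za$d_son, zb$d_son, g), 1.0),
    d_lmnb1 = vapply(seq_len(n), function(g) delta_at(za$d_lmnb1, zb$d_lmnb1, g), 1.0),
    d_mki67ip = vapply(seq_len(n), function(g) delta_at(za$d_mki67ip, zb$d_mki67ip, g), 1.0),
    d_expr = log2((genes$fpkm_a + 1) / (genes$fpkm_b + 1)),
    stringsAsFactors = FALSE)
  if (!is.null(tracks_a$RepliEL) && !is.null(tracks_b$RepliEL)) {
    ea <- tracks_a$RepliEL; eb <- tracks_b$RepliEL
    tab$d_timing <- vapply(seq_len(n), function(g) delta_at(ea, eb, g), 1.0)
  }
  keep <- stats::complete.cases(tab[c("d_son", "d_lmnb1", "d_mki67ip")])
  dropped <- sum(!keep)
  if (dropped) message(dropped, " gene(s) on missing bins dropped")
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("DeltaTable", "data.frame"), n_dropped = dropped)
}

#' Linear model of functional change on positioning change
#'
#' Ordinary least squares of an expression or timing delta on the three
#' TSA-seq deltas, with intercept and classical standard errors. The
#' design is rank-checked first: collinear predictor columns are
#' reported by name rather than silently dropped. A row subset (e.g. LAD
#' bins only) can be supplied for stratified fits.
#'
#' @param table a [build_delta_table()] result.
#' @param response `"d_expr"` or `"d_timing"`.
#' @param predictors predictor column names.
#' @param subset optional logical vector selecting rows.
#' @param subset_label label stored with the fit.
#' @return list with `coefficients` (data.frame: estimate, se, ci_lo,
#'   ci_hi per term), `n`, `sigma`, `r_squared`, `subset`.
#' @export
fit_linear_model <- function(table, response = "d_expr",
                             predictors = c("d_son", "d_lmnb1", "d_mki67ip"),
                             subset = NULL, subset_label = "all") {
  if (!response %in% names(table)) stop2("response column missing: ", response)
  dat <- as.data.frame(table)[c(response, predictors)]
  if (!is.null(subset)) dat <- dat[subset, , drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < 10) stop2("need >= 10 complete rows to fit")
  X <- as.matrix(cbind(`(Intercept)` = 1, dat[predictors]))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop2("rank-deficient design; collinear column(s): ",
          paste(bad, collapse = ", "))
  }
  fml <- stats::reformulate(predictors, response)
  fit <- stats::lm(fml, data = dat)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = 0.95)
  co <- data.frame(term = rownames(sm$coefficients),
                   estimate = sm$coefficients[, 1],
                   se = sm$coefficients[, 2],
                   ci_lo = ci[, 1], ci_hi = ci[, 2],
                   row.names = NULL, stringsAsFactors = FALSE)
  list(coefficients = co, n = nrow(dat), sigma = sm$sigma,
       r_squared = sm$r.squared, subset = subset_label)
}

#' Fraction of distances below an association threshold
#'
#' The speckle association fraction: the proportion of distances
#' strictly below `threshold` (a distance exactly at the threshold is
#' not associated).
#'
#' @param distances non-negative distances in nm.
#' @param threshold association cutoff in nm.
#' @return fraction in \[0, 1\]; `NA` for empty input.
#' @export
association_fraction <- function(distances, threshold = 250) {
  if (any(distances < 0, na.rm = TRUE)) stop2("distances must be >= 0")
  d <- distances[!is.na(distances)]
  if (!length(d)) {
    warning("no distances supplied; association fraction undefined",
            call. = FALSE)
    return(NA_real_)
  }
  mean(d < threshold)
}
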