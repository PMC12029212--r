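test_that("HMM segments a noiseless step track at the exact boundaries", {
  v <- rep(-1, 100); v[31:70] <- 1
  tr <- binned_track(list(chr1 = v), 25000)
  suppressWarnings(lads <- call_lads_hmm(tr))
  expect_equal(nrow(lads), 1)
  expect_equal(lads$start, 30 * 25000)
  expect_equal(lads$end, 70 * 25000)
})

test_that("an all-negative genome has no lamina-associated state", {
  set.seed(12)
  tr <- binned_track(list(chr1 = stats::rnorm(300, -1, 0.3)), 25000)
  expect_equal(nrow(call_lads_hmm(tr)), 0)
})

test_that("short runs are dropped and near-adjacent LADs merged", {
  v <- rep(-2, 120)
  v[11:12] <- 2                 # 2-bin run: below min_bins
  v[41:60] <- 2; v[62:80] <- 2  # 1-bin gap: merged
  tr <- binned_track(list(chr1 = v), 25000)
  suppressWarnings(lads <- call_lads_hmm(tr, min_bins = 4))
  expect_equal(nrow(lads), 1)
  expect_equal(c(lads$start, lads$end) / 25000, c(40, 80))
})

test_that("HMM boundary recovery on planted noisy domains", {
  errs <- c()
  for (seed in 1:6) {
    spec <- genome_spec(c(chr1 = 5e7), 25000, seed = seed)
    dom <- place_domains(spec, cluster_frac = 0)
    d <- planted_domains(dom$chrom, dom$start, dom$end, "LAD", 2)
    tr <- make_damid_track(spec, d, noise_sd = 0.5, autocorr = 0.3)
    lads <- call_lads_hmm(tr)
    called <- c(lads$start, lads$end) / 25000
    for (b in c(d$start, d$end) / 25000)
      errs <- c(errs, min(abs(called - b)))
  }
  expect_gte(mean(errs <= 2), 0.9)
})

test_that("consensus is the merged union with reciprocal-overlap annotation", {
  mkds <- function(start, end) {
    ds <- interval_set("chr1", start, end, "LAD")
    class(ds) <- c("DomainSet", class(ds)); ds
  }
  one <- build_consensus(list(A = mkds(0, 10 * 25e3)))
  expect_equal(nrow(one), 1)
  expect_equal(one$status_A, "LAD")

  cons <- build_consensus(list(A = mkds(0, 10 * 25e3),
                               B = mkds(5 * 25e3, 15 * 25e3)))
  expect_equal(nrow(cons), 1)
  expect_equal(c(cons$start, cons$end), c(0, 15 * 25e3))

  disj <- build_consensus(list(A = mkds(0, 10 * 25e3),
                               B = mkds(40 * 25e3, 50 * 25e3)))
  expect_equal(nrow(disj), 2)
  expect_equal(disj$status_A, c("LAD", "fiLAD_candidate"))
  expect_equal(disj$status_B, c("fiLAD_candidate", "LAD"))
})

test_that("local enrichment is the domain-minus-flank mean difference", {
  flat <- binned_track(list(chr1 = rep(2, 40)), 25000)
  expect_equal(local_enrichment(flat, "chr1", 10 * 25e3, 20 * 25e3), 0)
  steps <- binned_track(list(chr1 = c(rep(0, 10), rep(1, 10), rep(0, 10))), 25000)
  expect_equal(local_enrichment(steps, "chr1", 10 * 25e3, 20 * 25e3), 1)
  hand <- binned_track(list(chr1 = c(0, 0, 1, 3, 2, 0)), 25000)
  expect_equal(local_enrichment(hand, "chr1", 2 * 25e3, 4 * 25e3,
                                flank_cap = 1e9), 1.5)
  # domain occupying the whole chromosome has no usable flank
  res <- local_enrichment(flat, "chr1", 0, 40 * 25e3)
  expect_true(is.na(res))
  expect_true(attr(res, "flagged"))
})

test_that("extreme fiLAD enrichments classify to the forced class", {
  # two cell types; domain 2 is a LAD only in A
  v_a <- rep(-1, 200); v_a[51:70] <- 1; v_a[121:140] <- 1
  v_b <- rep(-1, 200); v_b[51:70] <- 1
  mk <- function(v) binned_track(list(chr1 = v), 25000)
  suppressWarnings({
    lads <- list(A = call_lads_hmm(mk(v_a)), B = call_lads_hmm(mk(v_b)))
    cons <- build_consensus(lads)
  })
  # in B: with a flat valley at the fiLAD, enrichment 0 < every LAD's
  suppressWarnings(cls <- classify_consensus(cons, list(A = mk(v_a), B = mk(v_b))))
  d2 <- cls$B[cls$B$start == 120 * 25e3, ]
  expect_equal(d2$label, "v_fiLAD")
  # give the same domain a peak matching the LAD enrichment level -> pwv
  v_b2 <- v_b; v_b2[121:140] <- 1
  suppressWarnings({
    lads2 <- list(A = call_lads_hmm(mk(v_a)), B = call_lads_hmm(mk(v_b)))
    cls2 <- classify_consensus(build_consensus(lads2),
                               list(A = mk(v_a), B = mk(v_b2)))
  })
  d22 <- cls2$B[cls2$B$start == 120 * 25e3, ]
  expect_equal(d22$label, "pwv_fiLAD")
})

test_that("planted class recovery meets the study thresholds", {
  accs <- c(); paccs <- c()
  for (seed in 1:3) {
    spec <- genome_spec(c(chr1 = 5e7, chr2 = 5e7), 25000, seed = seed)
    g <- make_class_genome(spec)
    lads <- lapply(g$tracks, call_lads_hmm)
    suppressWarnings({
      cons <- build_consensus(lads)
      cls <- classify_consensus(cons, g$tracks)
    })
    ev <- evaluate_class_recovery(g$truth, cls)
    accs <- c(accs, ev$accuracy); paccs <- c(paccs, ev$accuracy_pwv_v)
  }
  expect_gte(mean(accs), 0.85)
  expect_gte(mean(paccs), 0.8)
})

test_that("enrichment separates the three classes in planted genomes", {
  pool <- list(LAD = c(), pwv_fiLAD = c(), v_fiLAD = c())
  for (seed in 1:3) {
    spec <- genome_spec(c(chr1 = 5e7), 25000, seed = seed + 50)
    g <- make_class_genome(spec)
    ct <- "A"
    tr <- g$truth
    planted <- tr[[paste0("class_", ct)]]
    enr <- vapply(seq_len(nrow(tr)), function(i)
      as.numeric(local_enrichment(g$tracks[[ct]], tr$chrom[i], tr$start[i],
                                  tr$end[i])), 1.0)
    for (cl in names(pool)) pool[[cl]] <- c(pool[[cl]], enr[planted == cl])
  }
  expect_gt(mean(pool$LAD), mean(pool$pwv_fiLAD))
  expect_gt(mean(pool$pwv_fiLAD), mean(pool$v_fiLAD))
  expect_lt(stats::wilcox.test(pool$LAD, pool$pwv_fiLAD,
                               alternative = "greater")$p.value, 0.01)
  expect_lt(stats::wilcox.test(pool$pwv_fiLAD, pool$v_fiLAD,
                               alternative = "greater")$p.value, 0.01)
})

test_that("cLAD scores count covering cell lines, order-free", {
  mkds <- function(start, end) {
    ds <- interval_set("chr1", start, end, "LAD")
    class(ds) <- c("DomainSet", class(ds)); ds
  }
  sets <- list(a = mkds(0, 1e6), b = mkds(0, 5e5), c = mkds(2e5, 1e6),
               d = mkds(0, 1e6), e = mkds(0, 1e6), f = mkds(0, 1e6),
               g = mkds(0, 1e6))
  cl <- clad_score(sets, c(chr1 = 2e6), bin_size = 1e5)
  v <- cl$scores$chr1
  expect_equal(v[1], 6)      # bin 1 midpoint 50 kb: all but c
  expect_equal(v[4], 7)      # 350 kb: covered by all seven
  expect_equal(v[8], 6)      # 750 kb: all but b
  expect_equal(v[15], 0)     # outside the union
  expect_equal(attr(cl, "non_union")$chr1, 11:20)
  perm <- clad_score(rev(sets), c(chr1 = 2e6), bin_size = 1e5)
  expect_identical(perm$scores, cl$scores)
  expect_error(clad_score(c(sets, sets), c(chr1 = 2e6)), "1 to 7")
})
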