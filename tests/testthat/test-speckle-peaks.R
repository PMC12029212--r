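test_that("max_filter matches brute-force window maxima", {
  expect_equal(max_filter(c(1, 5, 2, 0), 1), c(5, 5, 5, 2))
  v <- rep(4, 50)
  for (w in c(1, 7, 60)) expect_equal(max_filter(v, w), v)
  set.seed(17)
  v <- stats::rnorm(500)
  v[sample(500, 30)] <- NA
  expect_identical(max_filter(v, 7), oracle_max_filter(v, 7))
  expect_identical(max_filter(v, 50), oracle_max_filter(v, 50))
  expect_true(is.na(max_filter(c(NA, NA, NA), 1)[2]))
})

test_that("call_peaks finds isolated maxima and rejects monotone ramps", {
  y <- 5 * exp(-((1:200) - 100)^2 / (2 * 16))
  tr <- binned_track(list(chr1 = y), 25000)
  p <- call_peaks(tr, span = 0.05, w = 10)
  expect_equal(nrow(p), 1)
  expect_equal(p$apex_bin, 100)

  ramp <- call_peaks(binned_track(list(chr1 = 1:300), 25000),
                     span = 0.05, w = 10)
  expect_equal(nrow(ramp), 0)
  # plateau resolves to its centroid
  v <- c(rep(0, 20), rep(3, 5), rep(0, 20))
  pl <- find_apexes(v, 8)
  expect_equal(pl, 23L)
})

test_that("window exclusion suppresses the smaller of two nearby bumps", {
  x <- 1:400
  y <- 10 * exp(-(x - 200)^2 / (2 * 100)) + 3 * exp(-(x - 260)^2 / (2 * 100))
  tr <- binned_track(list(chr1 = y), 25000)
  wide <- call_peaks(tr, span = 0.02, w = 50)
  expect_equal(wide$apex_bin, 200, tolerance = 2)
  expect_equal(nrow(wide), 1)
  narrow <- call_peaks(tr, span = 0.02, w = 20)
  expect_equal(nrow(narrow), 2)
  expect_equal(narrow$apex_bin, c(200, 260), tolerance = 2)
})

test_that("peak count is non-increasing in the window half-width", {
  spec <- tiny_spec(seed = 31, n_mb = 75)
  pk <- planted_peaks("chr1", seq(5e6, 7e7, by = 5e6), 4, 2e5)
  tr <- make_tsa_replicates(spec, pk, rep_noise_sd = 0.6, n_reps = 1)[[1]]
  sm <- loess_smooth(tr, 0.01)
  counts <- vapply(c(5, 10, 20, 40, 80),
                   function(w) nrow(call_peaks(sm, w = w, presmoothed = TRUE)),
                   1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("peak agreement is a Jaccard on greedy nearest matches", {
  mk <- function(bins) structure(
    data.frame(chrom = rep("chr1", length(bins)), apex_bin = bins,
               apex_bp = (bins - 0.5) * 25000,
               score = rep(1, length(bins)),
               type = rep("unclassified", length(bins))),
    class = c("PeakSet", "data.frame"))
  a <- mk(c(10, 100)); b <- mk(c(11, 200))
  expect_equal(peak_agreement(a, b, tol = 2), 1 / 3)
  expect_equal(peak_agreement(a, a, tol = 2), 1)
  expect_equal(peak_agreement(mk(10), mk(500), tol = 2), 0)
  expect_equal(peak_agreement(mk(integer(0)), mk(integer(0))), 0)
  # symmetry over random sets
  set.seed(3)
  for (i in 1:5) {
    a <- mk(sort(sample(1000, 20))); b <- mk(sort(sample(1000, 25)))
    expect_equal(peak_agreement(a, b, 3), peak_agreement(b, a, 3))
  }
})

test_that("grid search ties break toward smoother parameters", {
  spec <- tiny_spec(seed = 13, n_mb = 50)
  pk <- planted_peaks("chr1", c(1e7, 3e7), c(5, 4), c(3e5, 3e5))
  reps <- make_tsa_replicates(spec, pk, rep_noise_sd = 0, n_reps = 2)
  res <- optimize_parameters(reps[[1]], reps[[2]],
                             span_grid = c(0.005, 0.01), w_grid = c(10, 25))
  expect_equal(res$agreement, 1)
  expect_true(all(res$surface == 1))
  expect_equal(res$span, 0.01)   # ties -> larger span
  expect_equal(res$w, 25)        # then larger w
  one <- optimize_parameters(reps[[1]], reps[[2]],
                             span_grid = 0.008, w_grid = 15)
  expect_equal(c(one$span, one$w), c(0.008, 15))
})

test_that("peaks classify by subcompartment of the apex bin", {
  mk <- function(bins) structure(
    data.frame(chrom = "chr1", apex_bin = bins, apex_bp = (bins - 0.5) * 25000,
               score = 1, type = "unclassified"),
    class = c("PeakSet", "data.frame"))
  sub <- interval_set(rep("chr1", 3), c(0, 1e6, 2e6), c(1e6, 2e6, 3e6),
                      c("A1", "B1", "B3"))
  p <- classify_peaks(mk(c(10, 50, 90, 150)), sub)
  expect_equal(p$type, c("I", "II", "unclassified", "unclassified"))
  bad <- interval_set(rep("chr1", 2), c(0, 5e5), c(1e6, 1.5e6), c("A1", "A2"))
  expect_error(classify_peaks(mk(10), bad), "overlap")
  expect_error(classify_peaks(mk(10),
                              interval_set("chr1", 0, 1e6, "Z9")), "labels")
})

test_that("peak sets export as BED5 with a parameter sidecar", {
  y <- 5 * exp(-((1:200) - 100)^2 / (2 * 16))
  p <- call_peaks(binned_track(list(chr1 = y), 25000), span = 0.05, w = 10)
  f <- tempfile(fileext = ".bed")
  files <- write_peaks(p, f)
  expect_true(all(file.exists(files)))
  back <- read_bed(f)
  expect_equal(back$start, (p$apex_bin - 1) * 25000)
  side <- jsonlite::read_json(files[2], simplifyVector = TRUE)
  expect_equal(side$w, 10)
  expect_equal(side$span, 0.05)
})

test_that("optimized caller recovers planted peaks with high fidelity", {
  # amplitude/noise = 3, well-separated peaks, a few seeds (the full
  # 20-seed sweep runs in the acceptance suite)
  sens <- c(); prec <- c()
  for (seed in 1:5) {
    spec <- genome_spec(c(chr1 = 1e8), 25000, seed = seed)
    apex_bins <- seq(100, 3900, length.out = 20)
    pk <- planted_peaks("chr1", (apex_bins - 0.5) * 25000, 3, 1.5e5)
    reps <- make_tsa_replicates(spec, pk, rep_noise_sd = 1, n_reps = 2)
    opt <- optimize_parameters(reps[[1]], reps[[2]],
                               span_grid = c(0.003, 0.006),
                               w_grid = c(15, 40, 100))
    called <- call_peaks(reps[[1]], opt$span, opt$w)
    hits <- vapply(apex_bins, function(b) any(abs(called$apex_bin - b) <= 2),
                   TRUE)
    claimed <- vapply(called$apex_bin,
                      function(b) any(abs(apex_bins - b) <= 2), TRUE)
    sens <- c(sens, mean(hits)); prec <- c(prec, mean(claimed))
  }
  expect_gte(mean(sens), 0.9)
  expect_gte(mean(prec), 0.9)
})
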