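test_that("zero-noise DamID track reproduces planted offsets exactly", {
  spec <- tiny_spec(seed = 3, n_mb = 5)
  d <- planted_domains("chr1", 1e6, 2e6, "LAD", 2)
  tr <- make_damid_track(spec, d, noise_sd = 0, autocorr = 0)
  v <- tr$scores$chr1
  inside <- 41:80   # bins whose midpoints lie in [1, 2) Mb
  expect_equal(unique(v[inside]), 1)
  expect_equal(unique(v[-inside]), -1)
})

test_that("generators are bit-identical under one seed", {
  spec <- tiny_spec(seed = 11, n_mb = 10)
  d <- planted_domains("chr1", 1e6, 2e6, "LAD", 2)
  t1 <- make_damid_track(spec, d, noise_sd = 0.5, autocorr = 0.4)
  t2 <- make_damid_track(spec, d, noise_sd = 0.5, autocorr = 0.4)
  expect_identical(t1$scores, t2$scores)
  p <- planted_peaks("chr1", 5e6, 4, 2e5)
  r1 <- make_tsa_replicates(spec, p, 0.5, 2)
  r2 <- make_tsa_replicates(spec, p, 0.5, 2)
  expect_identical(lapply(r1, `[[`, "scores"), lapply(r2, `[[`, "scores"))
  s1 <- make_nucleus_scene("flat", 250, seed = 4)
  s2 <- make_nucleus_scene("flat", 250, seed = 4)
  expect_identical(s1$masks, s2$masks)
  expect_identical(s1$probes, s2$probes)
})

test_that("AR(1) noise has the requested lag-1 autocorrelation", {
  spec <- genome_spec(c(chr1 = 2.5e8), 25000, seed = 5)  # 10,000 bins
  tr <- make_damid_track(spec, planted_domains(character(0), numeric(0),
                                               numeric(0), character(0),
                                               numeric(0)),
                         noise_sd = 1, autocorr = 0.8)
  x <- tr$scores$chr1
  expect_equal(length(x), 10000)
  r1 <- stats::cor(x[-1], x[-length(x)])
  expect_lt(abs(r1 - 0.8), 0.05)
  expect_lt(abs(stats::sd(x) - 1), 0.1)
})

test_that("overlapping planted domains are rejected with the offending pair", {
  spec <- tiny_spec(seed = 1, n_mb = 5)
  d <- planted_domains(c("chr1", "chr1"), c(1e6, 1.5e6), c(2e6, 2.5e6),
                       c("LAD", "LAD"), c(2, 2))
  expect_error(make_damid_track(spec, d), "overlapping.*1500000")
})

test_that("generated tracks tile every bin of the genome exactly once", {
  spec <- genome_spec(c(chr1 = 10.01e6, chr2 = 5e6), 25000, seed = 2)
  d <- planted_domains("chr1", 1e6, 2e6, "LAD", 2)
  tr <- make_damid_track(spec, d, noise_sd = 0.3, autocorr = 0.2)
  expect_identical(vapply(tr$scores, length, 1L),
                   c(chr1 = 400L, chr2 = 200L))  # lengths truncated to bins
  expect_false(anyNA(unlist(tr$scores)))
})

test_that("TSA replicates share signal and differ only by noise", {
  spec <- tiny_spec(seed = 7, n_mb = 40)
  # apex exactly at a bin midpoint so the noiseless maximum hits amplitude
  pk <- planted_peaks("chr1", c(5e6 + 12500, 2e7 + 12500), c(5, 3),
                      c(2e5, 2e5), c("I", "II"))
  noiseless <- make_tsa_replicates(spec, pk, rep_noise_sd = 0, n_reps = 2)
  expect_identical(noiseless[[1]]$scores, noiseless[[2]]$scores)
  v <- noiseless[[1]]$scores$chr1
  expect_equal(which.max(v), 201)
  expect_equal(max(v), 5, tolerance = 1e-6)

  # two bumps 2 Mb apart: replicates correlate strongly over the
  # bump-covered stretch despite noise
  pk2 <- planted_peaks("chr1", c(5e6 + 12500, 7e6 + 12500), c(6, 4),
                       c(3e5, 3e5), c("I", "II"))
  noisy <- make_tsa_replicates(spec, pk2, rep_noise_sd = 0.5, n_reps = 2)
  mid <- bin_midpoints(1600, 25000)
  covered <- mid > 4.4e6 & mid < 7.6e6
  r <- stats::cor(noisy[[1]]$scores$chr1[covered], noisy[[2]]$scores$chr1[covered])
  expect_gt(r, 0.9)
})

test_that("planted-domain constructor enforces the class vocabulary and ordering", {
  expect_error(planted_domains("chr1", 0, 1e6, "weird", 1), "true_class")
  expect_error(planted_domains("chr1", 0, 0, "LAD", 1), "end > start")
  expect_error(
    planted_domains(c("chr1", "chr1"), c(0, 2e6), c(1e6, 3e6),
                    c("LAD", "v_fiLAD"), c(0.5, 2)),
    "ordered")
  expect_s3_class(
    planted_domains(c("chr1", "chr1"), c(0, 2e6), c(1e6, 3e6),
                    c("LAD", "v_fiLAD"), c(2, 0)),
    "PlantedDomains")
})

test_that("synthetic nucleus matches ellipsoid geometry and degenerate inputs", {
  sc <- make_nucleus_scene(c(2, 4, 8), voxel_nm = 200, n_speckles = 6,
                           n_nucleoli = 2, seed = 9)
  V <- sum(sc$masks$nucleus) * prod(sc$voxel_nm) / 1e9
  expect_lt(abs(V / (4 / 3 * pi * 2 * 4 * 8) - 1), 0.05)
  empty <- make_nucleus_scene("flat", 250, n_speckles = 0, n_nucleoli = 0,
                              seed = 9)
  expect_equal(sum(empty$masks$speckle), 0)
  expect_equal(sum(empty$masks$nucleolus), 0)
  expect_error(make_nucleus_scene("flat", 400, n_speckles = 500, seed = 1),
               "packable")
})

test_that("unbiased probe placement is consistent with a volume-uniform null", {
  # |z - z_mid| of probes vs uniform sampling over the same nuclear mask
  obs <- c()
  for (s in 1:10) {
    sc <- make_nucleus_scene("flat", 300, n_speckles = 0, n_nucleoli = 0,
                             polarity_bias = 0, n_probes = 30, seed = s)
    obs <- c(obs, abs(sc$probes$z_nm))
  }
  sc1 <- make_nucleus_scene("flat", 300, n_speckles = 0, n_nucleoli = 0,
                            polarity_bias = 0, n_probes = 5, seed = 1)
  co <- which(sc1$masks$nucleus, arr.ind = TRUE)
  ctr_z <- (dim(sc1$masks$nucleus)[1] + 1) / 2
  null <- with_seed(99, {
    k <- sample(nrow(co), 4000, replace = TRUE)
    abs(co[k, 1] + stats::runif(4000, -0.5, 0.5) - ctr_z) * 300
  })
  p <- stats::wilcox.test(obs, null)$p.value
  expect_gt(p, 0.01)
})

test_that("truth sidecars round-trip the planted tables", {
  spec <- tiny_spec(seed = 2, n_mb = 10)
  d <- planted_domains("chr1", 1e6, 2e6, "LAD", 2)
  tr <- make_damid_track(spec, d)
  tmp <- file.path(tempdir(), "truth_test")
  files <- write_truth_sidecar(tr, tmp, params = list(noise_sd = 0.4))
  expect_true(all(file.exists(files)))
  js <- jsonlite::read_json(paste0(tmp, ".json"), simplifyVector = TRUE)
  expect_equal(js$truth$start, 1e6)
  expect_equal(js$params$noise_sd, 0.4)
  bed <- read_bed(paste0(tmp, ".bed"))
  expect_equal(bed$label, "LAD")
})
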