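test_that("digitized spheres reach analytic volume and surface area", {
  sc <- nucleus_scene(list(s = sphere_mask(10)), 100)
  m <- mask_morphology(sc, "s")
  expect_lt(abs(m$total$volume_um3 / (4 / 3 * pi) - 1), 0.05)
  expect_lt(abs(m$total$area_um2 / (4 * pi) - 1), 0.05)
  expect_equal(m$n_components, 1)
  # single voxel at 100 nm isotropic
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  v1 <- mask_morphology(nucleus_scene(list(s = one), 100), "s")
  expect_equal(v1$total$volume_um3, 1e-3)
  # two disjoint spheres: components count and volumes add
  m2 <- array(FALSE, c(27, 27, 54))
  m2[1:27, 1:27, 1:27] <- sphere_mask(10)
  m2[1:27, 1:27, 28:54] <- sphere_mask(10)
  r2 <- mask_morphology(nucleus_scene(list(s = m2), 100), "s")
  expect_equal(r2$n_components, 2)
  expect_equal(r2$total$volume_um3, 2 * r2$components$volume_um3[1])
  # empty mask: zero-count report
  r0 <- mask_morphology(nucleus_scene(list(s = array(FALSE, c(4, 4, 4))), 100), "s")
  expect_equal(r0$n_components, 0)
})

test_that("sphere accuracy tightens with radius", {
  sc <- nucleus_scene(list(s = sphere_mask(25)), 100)
  m <- mask_morphology(sc, "s")
  expect_lt(abs(m$total$volume_um3 / (4 / 3 * pi * 2.5^3) - 1), 0.02)
  expect_lt(abs(m$total$area_um2 / (4 * pi * 2.5^2) - 1), 0.02)
})

test_that("asymmetric distances are directional surface-to-surface minima", {
  dmv <- c(21, 21, 61)
  mk <- function(cx, r = 5) {
    a <- array(FALSE, dmv)
    idx <- arrayInd(seq_along(a), dmv)
    a[(idx[, 1] - 11)^2 + (idx[, 2] - 11)^2 + (idx[, 3] - cx)^2 <= r^2] <- TRUE
    a
  }
  s1 <- mk(11); s2 <- mk(41)
  sc <- nucleus_scene(list(a = s1, b = s2, both = s1 | s2), 100)
  expect_equal(asymmetric_distance(sc, "both", "both")$mean_nm, 0)
  d <- asymmetric_distance(sc, "a", "b")
  # centers 3 um apart, radii 0.5 um: surface gap 2 um +/- a voxel diagonal
  expect_lt(abs(d$mean_nm - 2000), sqrt(3) * 100)
  # 1-vs-2 component asymmetry
  sc2 <- nucleus_scene(list(one = mk(11), two = mk(31) | mk(51)), 100)
  fwd <- asymmetric_distance(sc2, "one", "two")
  rev <- asymmetric_distance(sc2, "two", "one")
  expect_equal(length(fwd$distances_nm), 1)
  expect_equal(length(rev$distances_nm), 2)
  expect_false(isTRUE(all.equal(fwd$mean_nm, rev$mean_nm)))
})

test_that("TSA convolution matches closed form and the direct-sum oracle", {
  m <- array(FALSE, c(31, 31, 31)); m[16, 16, 16] <- TRUE
  out <- tsa_convolve(m, voxel_nm = 100)
  expect_equal(out[16, 16, 16], 5.86, tolerance = 1e-9)
  expect_equal(out[16, 16, 26], 5.86 * exp(-3), tolerance = 1e-9)
  # linearity: two sources superpose
  m2 <- array(FALSE, dim(m)); m2[10, 16, 16] <- TRUE
  both <- tsa_convolve(m | m2, voxel_nm = 100)
  expect_equal(both, tsa_convolve(m, voxel_nm = 100) +
                       tsa_convolve(m2, voxel_nm = 100), tolerance = 1e-9)
  # scales linearly in B, non-negative, decreasing from a point source
  expect_equal(tsa_convolve(m, voxel_nm = 100, B = 11.72), 2 * out,
               tolerance = 1e-9)
  expect_true(all(out >= -1e-12))
  ray <- out[16, 16, 16:31]
  expect_true(all(diff(ray) <= 1e-12))
  expect_error(tsa_convolve(m, voxel_nm = 100, cutoff_frac = 1.5), "cutoff")
})

test_that("convolution equals the brute-force oracle on random masks", {
  set.seed(9)
  mm <- array(stats::runif(16^3) < 0.1, c(16, 16, 16))
  got <- tsa_convolve(mm, voxel_nm = 200)
  want <- oracle_convolve(mm, 200)
  expect_lt(max(abs(got - want)), 1e-6)
})

test_that("flat-nucleus lamina signal is highest at the equatorial rim", {
  # thin adherent nucleus (1.5 um thick): the tyramide kernel reaches
  # the side, top and bottom lamina at once at the equatorial periphery
  sc <- make_nucleus_scene("flat", voxel_nm = 125, n_speckles = 0,
                           n_nucleoli = 0, seed = 3,
                           semi_um = c(0.75, 4, 8))
  field <- tsa_convolve(sc, "NP")
  shell <- which(sc$masks$NP, arr.ind = TRUE)
  zmid <- mean(range(shell[, 1]))
  zdev <- abs(shell[, 1] - zmid)
  zext <- diff(range(shell[, 1])) / 2
  eq <- zdev < max(0.1 * zext, 1.01)  # at least the central shell layer
  pole <- zdev >= stats::quantile(zdev, 0.9)
  vals <- field[sc$masks$NP]
  expect_gt(mean(vals[eq]), mean(vals[pole]))
})

test_that("nucleus normalization is rotation-invariant, bounded, idempotent", {
  set.seed(2)
  pr <- data.frame(x_nm = stats::rnorm(150, 0, 3000),
                   y_nm = stats::rnorm(150, 0, 1200),
                   z_nm = stats::runif(150, -900, 900))
  nz <- normalize_nucleus(pr)
  expect_equal(range(nz$x_norm), c(0, 4))
  expect_equal(range(nz$y_norm), c(0, 2))
  expect_equal(range(nz$z_norm), c(0, 1))
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  xy <- as.matrix(pr[, 1:2]) %*% t(R)
  nz2 <- normalize_nucleus(data.frame(x_nm = xy[, 1], y_nm = xy[, 2],
                                      z_nm = pr$z_nm))
  expect_equal(nz2$x_norm, nz$x_norm, tolerance = 1e-9)
  expect_equal(nz2$y_norm, nz$y_norm, tolerance = 1e-9)
  renorm <- normalize_nucleus(transform(nz, x_nm = x_norm, y_nm = y_norm,
                                        z_nm = z_norm))
  expect_equal(renorm$x_norm, nz$x_norm, tolerance = 1e-9)
  # a cloud elongated along input-y maps its long axis to output X
  ylong <- data.frame(x_nm = stats::rnorm(200, 0, 400),
                      y_nm = stats::rnorm(200, 0, 4000),
                      z_nm = stats::runif(200))
  nzy <- normalize_nucleus(ylong)
  expect_gt(abs(stats::cor(nzy$x_norm, ylong$y_nm)), 0.99)
  flatxy <- data.frame(x_nm = 1:5, y_nm = 2 * (1:5) + 3, z_nm = stats::runif(5))
  expect_error(normalize_nucleus(flatxy), "collinear")
})

test_that("polarity metrics measure equatorial and radial displacement", {
  pr <- data.frame(x_norm = c(2, 2, 0), y_norm = c(1, 1, 0),
                   z_norm = c(0.5, 1, 0.25), z_nm = 1:3)
  pm <- polarity_metrics(pr)
  expect_equal(pm$eq_dist, c(0, 0.5, 0.25))
  expect_equal(pm$center_dist, c(0, 0, sqrt(5)))
})

test_that("probe clouds with polarity bias concentrate at the equator", {
  eq0 <- c(); eq1 <- c()
  for (s in 1:20) {
    s0 <- make_nucleus_scene("flat", 400, n_speckles = 0, n_nucleoli = 0,
                             polarity_bias = 0, n_probes = 40, seed = s)
    s1 <- make_nucleus_scene("flat", 400, n_speckles = 0, n_nucleoli = 0,
                             polarity_bias = 3, n_probes = 40,
                             seed = s, nucleus_id = 2)
    n0 <- polarity_metrics(normalize_nucleus(s0$probes))
    n1 <- polarity_metrics(normalize_nucleus(s1$probes))
    eq0 <- c(eq0, mean(n0$eq_dist)); eq1 <- c(eq1, mean(n1$eq_dist))
  }
  expect_lt(stats::wilcox.test(eq1, eq0, alternative = "less")$p.value, 0.01)
})

test_that("centromere distances use the nearest acen edge in Mbp", {
  bands <- interval_set(rep("chr4", 3), c(0, 4.8e7, 5.0e7),
                        c(4.8e7, 5.0e7, 5.2e7),
                        c("gneg", "acen", "acen"))
  probes <- data.frame(chrom = c("chr4", "chr4", "chr4", "chr9"),
                       start = c(3.8e7, 4.9e7, 6.2e7, 1e6),
                       end = c(3.8e7 + 2, 4.9e7 + 2, 6.2e7 + 2, 1e6 + 2))
  d <- centromere_distance(probes, bands)
  expect_equal(d[1], 10, tolerance = 1e-6)  # left arm -> acen start
  expect_equal(d[2], 0)                     # inside the centromere
  expect_equal(d[3], 10, tolerance = 1e-6)  # right arm -> acen end
  expect_true(is.na(d[4]))                  # no acen annotation
})

test_that("morphology PCA standardizes metrics and explains variance", {
  x <- stats::rnorm(50)
  perfect <- cbind(a = x, b = x)
  p <- morphology_pca(perfect)
  expect_equal(p$var_explained[1], 1, tolerance = 1e-9)
  set.seed(4)
  f <- cbind(v = stats::rnorm(40), s = stats::rnorm(40), r = stats::rnorm(40))
  p3 <- morphology_pca(f)
  expect_equal(sum(p3$var_explained), 1, tolerance = 1e-9)
  expect_warning(morphology_pca(cbind(f, const = 1)), "zero-variance")
  # two planted clusters separate on PC1 with zero overlap; the cluster
  # signal drives two correlated metrics so PC1 is cluster-aligned
  g <- rep(c(0, 10), each = 25)
  fc <- cbind(m1 = g + stats::rnorm(50, 0, 1),
              m2 = g + stats::rnorm(50, 0, 1),
              m3 = stats::rnorm(50))
  pc <- morphology_pca(fc)
  s1 <- pc$scores[1:25, 1]; s2 <- pc$scores[26:50, 1]
  expect_true(max(s1) < min(s2) || min(s1) > max(s2))
})

test_that("scenes round-trip through TIFF stacks and sidecars", {
  sc <- make_nucleus_scene("round", 400, n_speckles = 2, n_nucleoli = 1,
                           n_probes = 20, seed = 6)
  pre <- file.path(tempdir(), "scene_rt")
  write_scene(sc, pre)
  back <- read_scene(pre)
  expect_identical(back$masks, sc$masks)
  expect_equal(back$voxel_nm, sc$voxel_nm)
  expect_equal(back$probes$x_nm, sc$probes$x_nm, tolerance = 1e-9)
})
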