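#' Nucleus scene container
#'
#' Voxel masks and probe coordinates of one nucleus. Masks share one
#' shape in (z, y, x) axis order with physical voxel spacing in nm.
#'
#' @param masks named list of congruent 3D logical arrays (locales such
#'   as `nucleus`, `NP`, `speckle`, `nucleolus`).
#' @param voxel_nm numeric length 3 (z, y, x spacing) or scalar.
#' @param nucleus_id identifier.
#' @param probes optional probe table for this nucleus.
#' @return object of class `NucleusScene`.
#' @export
nucleus_scene <- function(masks, voxel_nm, nucleus_id = 1L, probes = NULL) {
  if (length(voxel_nm) == 1) voxel_nm <- rep(voxel_nm, 3)
  if (any(voxel_nm <= 0)) stop2("voxel_nm must be > 0")
  dms <- lapply(masks, dim)
  if (length(masks) && !all(vapply(dms, identical, TRUE, dms[[1]])))
    stop2("all masks must share one shape")
  structure(list(masks = masks, voxel_nm = voxel_nm,
                 nucleus_id = nucleus_id, probes = probes),
            class = "NucleusScene")
}

#' @export
print.NucleusScene <- function(x, ...) {
  cat(sprintf("NucleusScene #%s: %s voxels @ %s nm; locales: %s\n",
              x$nucleus_id, paste(dim(x$masks[[1]]), collapse = "x"),
              paste(x$voxel_nm, collapse = "/"),
              paste(names(x$masks), collapse = ", ")))
  invisible(x)
}

#' Generate a synthetic nucleus with locale masks and a probe cloud
#'
#' Builds a nucleus mask — `"round"` (an ellipsoid with near-equal
#' semi-axes, as in H1/K562), `"flat"` (an adherent pancake: constant
#' ~2 µm thickness over most of its footprint with a rounded rim, as in
#' HCT116/HFF), or an arbitrary ellipsoid given numeric semi-axes — with
#' a one-voxel lamina shell (`NP`), spherical nuclear speckles and
#' nucleoli placed uniformly inside the nucleus (concentrating toward
#' the equatorial z-plane when `polarity_bias > 0`), and a probe table
#' with the same equatorial bias. All outputs are deterministic under
#' `seed`.
#'
#' @param shape `"round"`, `"flat"`, or a length-3 numeric of ellipsoid
#'   semi-axes in µm (z, y, x).
#' @param semi_um optional semi-axis override (µm, z/y/x) applied to the
#'   named `shape` geometries, e.g. a thinner flat nucleus.
#' @param rim_radius_um corner rounding radius of the flat nucleus' rim.
#' @param voxel_nm isotropic voxel size in nm.
#' @param n_speckles,n_nucleoli locale counts.
#' @param polarity_bias equatorial concentration strength (0 = uniform
#'   in the nuclear volume); placement weight is
#'   `exp(-bias * |z - z_mid| / z_extent)`.
#' @param n_probes probe count.
#' @param seed RNG seed; combined with `nucleus_id` so per-nucleus
#'   streams are stable under reordering.
#' @param nucleus_id identifier.
#' @param speckle_radius_um,nucleolus_radius_um locale radii.
#' @return A [nucleus_scene()] with masks `nucleus`, `NP`, `speckle`,
#'   `nucleolus`, a probe table, and generation truth in
#'   `attr(, "truth")`.
#' @export
make_nucleus_scene <- function(shape = "flat", voxel_nm = 100,
                               n_speckles = 8, n_nucleoli = 2,
                               polarity_bias = 0, n_probes = 200,
                               seed = 1L, nucleus_id = 1L,
                               speckle_radius_um = 0.4,
                               nucleolus_radius_um = 0.8, semi_um = NULL,
                               rim_radius_um = 0.25) {
  check_scalar_number(voxel_nm, "voxel_nm", lower = 0, strict_lower = TRUE)
  pancake <- FALSE
  if (is.numeric(shape)) {
    semi_um <- shape
  } else {
    shape <- match.arg(shape, c("round", "flat"))
    if (shape == "round") semi_um <- semi_um %||% c(3.5, 4, 4.5)  # z, y, x
    else { semi_um <- semi_um %||% c(1, 4, 8); pancake <- TRUE }
  }
  vs <- voxel_nm / 1000
  semi <- semi_um / vs
  dm <- as.integer(ceiling(2 * semi + 5))
  ctr <- (dm + 1) / 2
  nucleus <- array(FALSE, dm)
  if (pancake) {
    # adherent-nucleus geometry: constant thickness 2c over an
    # elliptical footprint with a mostly vertical side wall and a
    # rounded rim corner (radius rim_radius_um); this is the regime in
    # which the lamina wraps loci at the equatorial periphery from the
    # side, top and bottom at once
    rho <- min(rim_radius_um / vs, semi[1] - 1)
    idx <- arrayInd(seq_len(prod(dm)), dm)
    dz <- abs(idx[, 1] - ctr[1])
    y <- idx[, 2] - ctr[2]; x <- idx[, 3] - ctr[3]
    re_full <- sqrt((y / semi[2])^2 + (x / semi[3])^2)
    re_core <- sqrt((y / (semi[2] - rho))^2 + (x / (semi[3] - rho))^2)
    rr <- sqrt(y^2 + x^2)
    dr <- pmax(0, (re_core - 1) * ifelse(re_core > 0, rr / re_core, 0))
    dzp <- pmax(0, dz - (semi[1] - rho))
    nucleus <- array(re_full <= 1 & dz <= semi[1] & dzp^2 + dr^2 <= rho^2, dm)
  } else {
    ax <- function(k) ((1:dm[k]) - ctr[k]) / semi[k]
    rxy2 <- outer(ax(2)^2, ax(3)^2, "+")                # (y, x) grid
    z2 <- ax(1)^2
    for (iz in seq_len(dm[1])) nucleus[iz, , ] <- z2[iz] + rxy2 <= 1
  }
  # NP: one-voxel shell = nucleus minus its 6-neighbour erosion
  shift_arr <- function(m, s) {
    dmm <- dim(m)
    src <- lapply(1:3, function(k) pmin(pmax((1:dmm[k]) + s[k], 1L), dmm[k]))
    m[src[[1]], src[[2]], src[[3]]]
  }
  er <- nucleus
  for (s in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)))
    er <- er & shift_arr(nucleus, s)
  np <- nucleus & !er

  inside_idx <- which(nucleus)
  co_inside <- arrayInd(inside_idx, dm)
  zext <- max(abs(co_inside[, 1] - ctr[1]))
  wts <- if (polarity_bias > 0)
    exp(-polarity_bias * abs(co_inside[, 1] - ctr[1]) / zext) else NULL

  fill_spheres <- function(centers, r_vox) {
    m <- array(FALSE, dm)
    for (i in seq_len(nrow(centers))) {
      rng <- lapply(1:3, function(k)
        max(1L, floor(centers[i, k] - r_vox)):min(dm[k], ceiling(centers[i, k] + r_vox)))
      d2 <- outer(outer((rng[[1]] - centers[i, 1])^2,
                        (rng[[2]] - centers[i, 2])^2, "+"),
                  (rng[[3]] - centers[i, 3])^2, "+")
      m[rng[[1]], rng[[2]], rng[[3]]] <- m[rng[[1]], rng[[2]], rng[[3]]] | (d2 <= r_vox^2)
    }
    m
  }
  sphere_fits <- function(ctr_vox, r_vox) {
    rng <- lapply(1:3, function(k) {
      lo <- floor(ctr_vox[k] - r_vox); hi <- ceiling(ctr_vox[k] + r_vox)
      if (lo < 1 || hi > dm[k]) return(NULL)
      lo:hi
    })
    if (any(vapply(rng, is.null, TRUE))) return(FALSE)
    d2 <- outer(outer((rng[[1]] - ctr_vox[1])^2, (rng[[2]] - ctr_vox[2])^2, "+"),
                (rng[[3]] - ctr_vox[3])^2, "+")
    all(nucleus[as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))[as.vector(d2 <= r_vox^2), , drop = FALSE]])
  }

  with_seed(sub_seed(seed, "nucleus", nucleus_id), {
    r_sp <- speckle_radius_um / vs
    r_no <- nucleolus_radius_um / vs
    need <- n_speckles * (4 / 3) * pi * r_sp^3 + n_nucleoli * (4 / 3) * pi * r_no^3
    if (need > 0.5 * length(inside_idx))
      stop2("locale counts exceed packable nuclear volume")
    place <- function(n, r_vox, biased, others = NULL, others_r = 0,
                      max_try = 400) {
      centers <- matrix(0, 0, 3)
      tries <- 0
      while (nrow(centers) < n) {
        tries <- tries + 1
        if (tries > max_try * max(n, 1))
          stop2("could not place locales; counts exceed packable volume")
        k <- if (biased && !is.null(wts))
          sample(nrow(co_inside), 1, prob = wts) else sample(nrow(co_inside), 1)
        cand <- co_inside[k, ] + stats::runif(3, -0.5, 0.5)
        if (!sphere_fits(cand, r_vox)) next
        if (nrow(centers) &&
            any(sqrt(rowSums(sweep(centers, 2, cand)^2)) <= 2 * r_vox)) next
        if (!is.null(others) && nrow(others) &&
            any(sqrt(rowSums(sweep(others, 2, cand)^2)) <= r_vox + others_r)) next
        centers <- rbind(centers, cand)
      }
      centers
    }
    nucleoli_c <- if (n_nucleoli > 0) place(n_nucleoli, r_no, FALSE)
                  else matrix(0, 0, 3)
    speckles_c <- if (n_speckles > 0)
      place(n_speckles, r_sp, TRUE, others = nucleoli_c, others_r = r_no)
      else matrix(0, 0, 3)
    speckle <- fill_spheres(speckles_c, r_sp)
    nucleolus <- fill_spheres(nucleoli_c, r_no)

    pk <- if (is.null(wts)) sample(nrow(co_inside), n_probes, replace = TRUE)
          else sample(nrow(co_inside), n_probes, replace = TRUE, prob = wts)
    pr <- co_inside[pk, , drop = FALSE] +
      matrix(stats::runif(3 * n_probes, -0.5, 0.5), ncol = 3)
    probes <- data.frame(
      probe_id = paste0("p", seq_len(n_probes)),
      chrom = "chr1",
      start = (seq_len(n_probes) - 1) * 1e5,
      end = seq_len(n_probes) * 1e5,
      nucleus_id = nucleus_id,
      x_nm = (pr[, 3] - ctr[3]) * voxel_nm,
      y_nm = (pr[, 2] - ctr[2]) * voxel_nm,
      z_nm = (pr[, 1] - ctr[1]) * voxel_nm,
      stringsAsFactors = FALSE)

    sc <- nucleus_scene(list(nucleus = nucleus, NP = np, speckle = speckle,
                             nucleolus = nucleolus),
                        voxel_nm, nucleus_id, probes)
    attr(sc, "truth") <- list(
      shape = if (pancake) "flat-pancake" else "ellipsoid",
      semi_axes_um = semi_um, polarity_bias = polarity_bias,
      speckle_centers_vox = speckles_c, nucleolus_centers_vox = nucleoli_c,
      center_vox = ctr, z_extent_vox = zext, seed = seed)
    sc
  })
}
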