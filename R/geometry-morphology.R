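# 3D binary-mask morphology: connected components, isosurface
# extraction, volume / surface-area statistics, and asymmetric
# locale-to-locale surface distances. Axis order is (z, y, x)
# throughout, with physical voxel spacing in nm.

# 26-connectivity component labelling by frontier expansion
label_components <- function(mask) {
  dm <- dim(mask)
  labels <- array(0L, dm)
  off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  todo <- which(mask)
  lab <- 0L
  while (length(todo)) {
    seed <- todo[1]
    lab <- lab + 1L
    frontier <- seed
    labels[seed] <- lab
    while (length(frontier)) {
      co <- arrayInd(frontier, dm)
      nb <- co[rep(seq_len(nrow(co)), each = nrow(off)), , drop = FALSE] +
        off[rep(seq_len(nrow(off)), nrow(co)), , drop = FALSE]
      ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
        nb[, 3] >= 1 & nb[, 3] <= dm[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- unique(nb[, 1] + dm[1] * (nb[, 2] - 1) + dm[1] * dm[2] * (nb[, 3] - 1))
      lin <- lin[mask[lin] & labels[lin] == 0L]
      labels[lin] <- lab
      frontier <- lin
    }
    todo <- todo[labels[todo] == 0L]
  }
  labels
}

# separable 3-tap binomial smoothing of a 3D array, `times` passes;
# used to reduce voxelization bias before isosurface extraction
smooth3 <- function(vol, times = 2) {
  k <- c(0.25, 0.5, 0.25)
  dm <- dim(vol)
  pad_filter <- function(v) {
    n <- length(v)
    vp <- c(v[1], v, v[n])
    k[1] * vp[1:n] + k[2] * vp[2:(n + 1)] + k[3] * vp[3:(n + 2)]
  }
  for (it in seq_len(times)) {
    vol <- apply(vol, c(2, 3), pad_filter)
    dim(vol) <- dm
    vol <- aperm(apply(vol, c(1, 3), pad_filter), c(2, 1, 3))
    vol <- aperm(apply(vol, c(1, 2), pad_filter), c(2, 3, 1))
  }
  vol
}

# Isosurface triangles of a scalar volume at `level` by marching
# tetrahedra (each grid cell split into 6 tetrahedra sharing the main
# diagonal). Returns a list of three (n_triangles x 3) vertex matrices
# in physical (z, y, x) nm coordinates, plus the total area.
isosurface <- function(vol, level = 0.5, spacing = c(1, 1, 1)) {
  dm <- dim(vol)
  # pad with a zero shell so surfaces close at the array border
  pv <- array(0, dm + 2L)
  pv[2:(dm[1] + 1), 2:(dm[2] + 1), 3:(dm[3] + 2) - 1] <- vol
  dm <- dim(pv)
  nz <- dm[1] - 1L; ny <- dm[2] - 1L; nx <- dm[3] - 1L
  corner_off <- rbind(c(0,0,0), c(0,0,1), c(0,1,0), c(0,1,1),
                      c(1,0,0), c(1,0,1), c(1,1,0), c(1,1,1))
  # cell corner values as 8 shifted sub-arrays, flattened per cell
  sub <- function(o) as.vector(pv[(1:nz) + o[1], (1:ny) + o[2], (1:nx) + o[3]])
  cv <- vapply(seq_len(8), function(c8) sub(corner_off[c8, ]), numeric(nz * ny * nx))
  inside <- cv > level
  mixed <- which(rowSums(inside) > 0 & rowSums(inside) < 8)
  if (!length(mixed))
    return(list(v1 = matrix(0, 0, 3), v2 = matrix(0, 0, 3),
                v3 = matrix(0, 0, 3), area = 0))
  cv <- cv[mixed, , drop = FALSE]
  inside <- inside[mixed, , drop = FALSE]
  base <- arrayInd(mixed, c(nz, ny, nx))  # cell corner-0 grid coords
  # physical coordinates of the 8 corners (centered on voxel centers of
  # the unpadded volume: padded index 2 corresponds to coordinate 0)
  corner_phys <- function(c8)
    cbind((base[, 1] + corner_off[c8, 1] - 2) * spacing[1],
          (base[, 2] + corner_off[c8, 2] - 2) * spacing[2],
          (base[, 3] + corner_off[c8, 3] - 2) * spacing[3])
  tets <- rbind(c(1, 2, 4, 8), c(1, 4, 3, 8), c(1, 3, 7, 8),
                c(1, 7, 5, 8), c(1, 5, 6, 8), c(1, 6, 2, 8))
  V1 <- V2 <- V3 <- list()
  interp <- function(ca, cb, rows) {
    va <- cv[cbind(rows, ca)]; vb <- cv[cbind(rows, cb)]
    t <- (level - va) / (vb - va)
    pa <- corner_phys(ca)[rows, , drop = FALSE]
    pb <- corner_phys(cb)[rows, , drop = FALSE]
    pa + t * (pb - pa)
  }
  for (ti in seq_len(nrow(tets))) {
    tc <- tets[ti, ]
    ins <- inside[, tc, drop = FALSE]
    nin <- rowSums(ins)
    # one corner on its own side of the surface -> one triangle
    for (k in 1:4) {
      solo_in <- which(nin == 1 & ins[, k])
      solo_out <- which(nin == 3 & !ins[, k])
      rows <- c(solo_in, solo_out)
      if (!length(rows)) next
      others <- tc[-k]
      V1[[length(V1) + 1]] <- interp(tc[k], others[1], rows)
      V2[[length(V2) + 1]] <- interp(tc[k], others[2], rows)
      V3[[length(V3) + 1]] <- interp(tc[k], others[3], rows)
    }
    # two-and-two -> quad -> two triangles
    pairs <- utils::combn(4, 2)
    for (pi in seq_len(ncol(pairs))) {
      a <- pairs[1, pi]; b <- pairs[2, pi]
      rows <- which(nin == 2 & ins[, a] & ins[, b])
      if (!length(rows)) next
      cd <- setdiff(1:4, c(a, b))
      pac <- interp(tc[a], tc[cd[1]], rows)
      pad_ <- interp(tc[a], tc[cd[2]], rows)
      pbd <- interp(tc[b], tc[cd[2]], rows)
      pbc <- interp(tc[b], tc[cd[1]], rows)
      V1[[length(V1) + 1]] <- pac; V2[[length(V2) + 1]] <- pad_
      V3[[length(V3) + 1]] <- pbd
      V1[[length(V1) + 1]] <- pac; V2[[length(V2) + 1]] <- pbd
      V3[[length(V3) + 1]] <- pbc
    }
  }
  v1 <- do.call(rbind, V1); v2 <- do.call(rbind, V2); v3 <- do.call(rbind, V3)
  e1 <- v2 - v1; e2 <- v3 - v1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- 0.5 * sum(sqrt(rowSums(cr^2)))
  list(v1 = v1, v2 = v2, v3 = v3, area = area)
}

# surface mesh of one binary component, pre-smoothed to reduce
# voxelization bias; vertices in physical nm
component_surface <- function(mask, spacing, smooth_passes = 2) {
  vol <- smooth3(array(as.numeric(mask), dim(mask)), times = smooth_passes)
  isosurface(vol, 0.5, spacing)
}

#' Morphology of a locale mask
#'
#' Per-nucleus morphology statistics of one locale: connected components
#' (26-connectivity), volume (voxel count times voxel volume), surface
#' area (marching-tetrahedra isosurface at level 0.5 after light
#' binomial pre-smoothing, which removes most voxelization bias), and
#' the SA/V roundness ratio. Units: µm³, µm², µm⁻¹.
#'
#' @param scene a [nucleus_scene()].
#' @param locale mask name, e.g. `"nucleus"`, `"speckle"`, `"nucleolus"`.
#' @param smooth_passes binomial smoothing passes before meshing.
#' @return list with `n_components`, `total` (volume, area, sa_v) and
#'   `components` (per-component data.frame). Empty masks yield a
#'   zero-count report.
#' @export
mask_morphology <- function(scene, locale, smooth_passes = 2) {
  mask <- scene$masks[[locale]]
  if (is.null(mask)) stop2("no such locale mask: ", locale)
  if (!any(mask))
    return(list(n_components = 0L, total = NULL,
                components = data.frame(volume_um3 = numeric(0),
                                        area_um2 = numeric(0),
                                        sa_v = numeric(0))))
  sp <- scene$voxel_nm
  vox_um3 <- prod(sp) / 1e9
  labels <- label_components(mask)
  n_comp <- max(labels)
  comp <- data.frame(volume_um3 = numeric(n_comp), area_um2 = numeric(n_comp))
  for (k in seq_len(n_comp)) {
    cm <- labels == k
    comp$volume_um3[k] <- sum(cm) * vox_um3
    surf <- component_surface(crop_mask(cm), sp, smooth_passes)
    comp$area_um2[k] <- surf$area / 1e6
  }
  comp$sa_v <- comp$area_um2 / comp$volume_um3
  tot_v <- sum(comp$volume_um3); tot_a <- sum(comp$area_um2)
  list(n_components = n_comp,
       total = list(volume_um3 = tot_v, area_um2 = tot_a,
                    sa_v = tot_a / tot_v),
       components = comp)
}

# crop a logical array to its bounding box plus one voxel of margin
crop_mask <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  dm <- dim(mask)
  lo <- pmax(apply(idx, 2, min) - 1L, 1L)
  hi <- pmin(apply(idx, 2, max) + 1L, dm)
  out <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  array(out, hi - lo + 1L)
}

#' Asymmetric locale-to-locale surface distances
#'
#' For each connected component of the `from` locale, the minimum
#' Euclidean distance (nm) from its surface-mesh vertices to any surface
#' vertex of the `to` locale. The summary mean over `from` components is
#' directional: speckle-to-nucleolus generally differs from
#' nucleolus-to-speckle when component counts differ.
#'
#' @param scene a [nucleus_scene()].
#' @param from,to locale mask names.
#' @return list with `distances_nm` (one per `from` component) and
#'   `mean_nm`.
#' @export
asymmetric_distance <- function(scene, from, to) {
  mf <- scene$masks[[from]]; mt <- scene$masks[[to]]
  if (is.null(mf) || is.null(mt)) stop2("unknown locale mask")
  if (!any(mf) || !any(mt)) stop2("both locale masks must be non-empty")
  sp <- scene$voxel_nm
  # target vertices: mesh the full `to` mask (cropping must not shift
  # coordinates, so build in place with an offset)
  vert_of <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    lo <- pmax(apply(idx, 2, min) - 1L, 1L)
    hi <- pmin(apply(idx, 2, max) + 1L, dim(mask))
    sub <- array(mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]], hi - lo + 1L)
    surf <- component_surface(sub, sp)
    v <- rbind(surf$v1, surf$v2, surf$v3)
    sweep(v, 2, (lo - 1L) * sp, "+")
  }
  vt <- unique(round(vert_of(mt), 3))
  labf <- label_components(mf)
  out <- numeric(max(labf))
  for (k in seq_len(max(labf))) {
    vf <- unique(round(vert_of(labf == k), 3))
    dmin <- Inf
    step <- max(1L, floor(2e7 / nrow(vt)))
    for (i0 in seq(1, nrow(vf), by = step)) {
      ii <- i0:min(i0 + step - 1L, nrow(vf))
      d2 <- outer(rowSums(vf[ii, , drop = FALSE]^2), rowSums(vt^2), "+") -
        2 * vf[ii, , drop = FALSE] %*% t(vt)
      dmin <- min(dmin, min(d2))
    }
    out[k] <- sqrt(max(dmin, 0))
  }
  list(distances_nm = out, mean_nm = mean(out))
}
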