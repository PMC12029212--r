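#' Tyramide-diffusion TSA signal simulation
#'
#' Convolves a binary source-locale mask with a symmetric 3D kernel
#' following the exponential decay of the TSA biotinylation signal,
#' `B * exp(-R * d)`, where `d` is the distance (µm) to the kernel
#' center, `B` the amplitude at the source and `R` the decay constant
#' (per µm; `R = 3` gives a ~333 nm decay length). The kernel is
#' truncated where it falls below `cutoff_frac * B`
#' (radius `ln(1/cutoff_frac)/R`). The convolution is exact within the
#' truncated support (FFT-based, accumulating every source voxel's
#' kernel contribution).
#'
#' @param scene a [nucleus_scene()], or a 3D logical array (then supply
#'   `voxel_nm`).
#' @param source_locale mask name when `scene` is a scene.
#' @param B kernel amplitude at distance 0.
#' @param R decay constant per µm.
#' @param cutoff_frac truncation level as a fraction of `B`, in (0, 1).
#' @param voxel_nm (z, y, x) voxel spacing in nm when `scene` is an
#'   array.
#' @return 3D numeric array of simulated TSA signal, same shape as the
#'   mask.
#' @export
tsa_convolve <- function(scene, source_locale = "NP", B = 5.86, R = 3,
                         cutoff_frac = 0.01, voxel_nm = NULL) {
  if (inherits(scene, "NucleusScene")) {
    mask <- scene$masks[[source_locale]]
    if (is.null(mask)) stop2("no such locale mask: ", source_locale)
    voxel_nm <- scene$voxel_nm
  } else mask <- scene
  check_scalar_number(B, "B", lower = 0, strict_lower = TRUE)
  check_scalar_number(R, "R", lower = 0, strict_lower = TRUE)
  if (!is.numeric(cutoff_frac) || length(cutoff_frac) != 1 ||
      cutoff_frac <= 0 || cutoff_frac >= 1)
    stop2("`cutoff_frac` must lie strictly in (0, 1)")
  if (is.null(voxel_nm)) stop2("voxel spacing unknown")
  if (length(voxel_nm) == 1) voxel_nm <- rep(voxel_nm, 3)
  sp_um <- voxel_nm / 1000
  r_um <- log(1 / cutoff_frac) / R
  half <- pmax(0L, floor(r_um / sp_um))
  kz <- (-half[1]):half[1]; ky <- (-half[2]):half[2]; kx <- (-half[3]):half[3]
  d <- sqrt(outer(outer((kz * sp_um[1])^2, (ky * sp_um[2])^2, "+"),
                  (kx * sp_um[3])^2, "+"))
  kern <- B * exp(-R * d)
  kern[kern < cutoff_frac * B] <- 0
  conv3_fft(array(as.numeric(mask), dim(mask)), kern)
}

# zero-padded 3D FFT convolution, "same" output, kernel centered
conv3_fft <- function(vol, kern) {
  dv <- dim(vol); dk <- dim(kern)
  dp <- dv + dk - 1L
  pv <- array(0, dp); pk <- array(0, dp)
  pv[seq_len(dv[1]), seq_len(dv[2]), seq_len(dv[3])] <- vol
  pk[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- kern
  full <- Re(stats::fft(stats::fft(pv) * stats::fft(pk), inverse = TRUE)) / prod(dp)
  ctr <- (dk + 1L) %/% 2L
  full[ctr[1]:(ctr[1] + dv[1] - 1L),
       ctr[2]:(ctr[2] + dv[2] - 1L),
       ctr[3]:(ctr[3] + dv[3] - 1L)]
}
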