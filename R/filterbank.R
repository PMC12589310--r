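# Image filter bank: one-level stationary 3D wavelet decomposition and
# Laplacian-of-Gaussian responses, feeding the radiomic feature extractor.

## Coiflet-1 decomposition filters (orthonormal; high-pass by the
## quadrature-mirror relation g[k] = (-1)^(k+1) h[N-1-k]).
coif1_lo <- c(-0.015655728135465,
              -0.072732619512854,
              0.384864846864203,
              0.852572020212255,
              0.337897662457809,
              -0.072732619512854)
coif1_hi <- rev(coif1_lo) * c(-1, 1, -1, 1, -1, 1)

## Symmetric (half-sample reflected) padding of a vector.
pad_sym <- function(v, k) {
  n <- length(v)
  left <- v[pmin(pmax(k:1, 1), n)]
  right <- v[pmax(pmin(n:(n - k + 1), n), 1)]
  c(left, v, right)
}

## 1D convolution of every line of a 3D array along one axis, symmetric
## boundary, output aligned with the input grid.
conv_axis <- function(vol, kernel, axis) {
  nd <- dim(vol)
  n <- nd[axis]
  L <- length(kernel)
  k_half <- (L - 1) %/% 2
  pad_left <- k_half
  pad_right <- L - 1 - k_half
  perm <- c(axis, setdiff(1:3, axis))
  v <- aperm(vol, perm)
  m <- matrix(v, nrow = n)
  np <- n + pad_left + pad_right
  mp <- matrix(0, nrow = np, ncol = ncol(m))
  mp[(pad_left + 1):(pad_left + n), ] <- m
  ## reflect without repeating the edge sample (whole-sample symmetric)
  if (pad_left > 0) {
    ref <- pmin(1 + (1:pad_left), n)
    mp[pad_left:1, ] <- m[ref, , drop = FALSE]
  }
  if (pad_right > 0) {
    ref <- pmax(n - (1:pad_right), 1)
    mp[(pad_left + n + 1):np, ] <- m[ref, , drop = FALSE]
  }
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (j in seq_len(L)) {
    out <- out + kernel[j] * mp[(j):(j + n - 1), , drop = FALSE]
  }
  out <- array(out, dim = c(n, nd[perm[2]], nd[perm[3]]))
  aperm(out, order(perm))
}

#' One-level stationary 3D wavelet decomposition
#'
#' Separable undecimated (a-trous) coiflet-1 decomposition: the low- or
#' high-pass filter is applied along each axis, yielding the eight
#' sub-bands LLL, HLL, LHL, HHL, LLH, HLH, LHH, HHH (letter order = x, y,
#' z axis filter). Undecimated filtering preserves grid alignment with the
#' region mask.
#'
#' @param volume 3D numeric array.
#' @return Named list of eight 3D arrays.
#' @export
wavelet_bands <- function(volume) {
  stop_if(!is.array(volume) || length(dim(volume)) != 3L,
          "volume must be a 3D array")
  bands <- list()
  for (fz in c("L", "H")) {
    vz <- conv_axis(volume, if (fz == "L") coif1_lo else coif1_hi, 3)
    for (fy in c("L", "H")) {
      vy <- conv_axis(vz, if (fy == "L") coif1_lo else coif1_hi, 2)
      for (fx in c("L", "H")) {
        vx <- conv_axis(vy, if (fx == "L") coif1_lo else coif1_hi, 1)
        bands[[paste0(fx, fy, fz)]] <- vx
      }
    }
  }
  bands[c("LLL", "HLL", "LHL", "HHL", "LLH", "HLH", "LHH", "HHH")]
}

gaussian_kernel_1d <- function(sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

#' Laplacian-of-Gaussian response of a 3D volume
#'
#' Separable Gaussian smoothing at scale \code{sigma_mm} (converted to
#' voxels per axis via \code{spacing}) followed by the 6-neighbour discrete
#' Laplacian in physical units. The interior response of a linear ramp is
#' zero.
#'
#' @param volume 3D numeric array.
#' @param sigma_mm Gaussian scale in mm (> 0).
#' @param spacing Voxel spacing in mm.
#' @return 3D array of the same dimensions.
#' @export
log_response <- function(volume, sigma_mm, spacing = c(1, 1, 1)) {
  stop_if(!is_scalar_number(sigma_mm) || sigma_mm <= 0, "sigma must be > 0")
  sm <- volume
  for (axis in 1:3) {
    sm <- conv_axis(sm, gaussian_kernel_1d(sigma_mm / spacing[axis]), axis)
  }
  out <- array(0, dim = dim(sm))
  for (axis in 1:3) {
    plus <- shift_axis(sm, axis, 1L)
    minus <- shift_axis(sm, axis, -1L)
    out <- out + (plus + minus - 2 * sm) / spacing[axis]^2
  }
  out
}

## Shift a 3D array by one voxel along an axis, replicating the edge.
shift_axis <- function(vol, axis, by) {
  nd <- dim(vol)
  n <- nd[axis]
  idx <- pmin(pmax(seq_len(n) + by, 1L), n)
  if (axis == 1) vol[idx, , , drop = FALSE]
  else if (axis == 2) vol[, idx, , drop = FALSE]
  else vol[, , idx, drop = FALSE]
}

#' Build the radiomic filter bank for one volume
#'
#' Original image, eight stationary coiflet-1 wavelet sub-bands and one
#' Laplacian-of-Gaussian response per configured sigma.
#'
#' @param volume 3D numeric array.
#' @param spacing Voxel spacing (mm), used by the LoG stage.
#' @param log_sigmas_mm Numeric vector of LoG scales (mm), all > 0.
#' @return Named list of 3D arrays: \code{original},
#'   \code{wavelet.<band>}, \code{log.sigma.<s>}.
#' @export
filter_bank <- function(volume, spacing = c(1, 1, 1),
                        log_sigmas_mm = c(1, 3)) {
  stop_if(any(log_sigmas_mm <= 0), "LoG sigma must be > 0")
  out <- list(original = volume)
  wb <- wavelet_bands(volume)
  names(wb) <- paste0("wavelet.", names(wb))
  out <- c(out, wb)
  for (s in log_sigmas_mm) {
    out[[sprintf("log.sigma.%g", s)]] <- log_response(volume, s, spacing)
  }
  out
}
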