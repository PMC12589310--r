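#' Preprocessing configuration
#'
#' Settings for the five-stage image preprocessing pipeline: intensity
#' normalization, spatial registration (an interface hook; phantom volumes
#' are generated co-registered), resampling to an isotropic grid,
#' super-resolution upsampling, and intensity discretization.
#'
#' @param target_spacing Target voxel spacing in mm (length 3).
#' @param sr_factor Super-resolution upsampling factor, one of 1, 2, 4.
#' @param normalization One of \code{"none"}, \code{"zscore"} (VOI mean 0,
#'   SD 1) or \code{"minmax"} (VOI range mapped to [0, 1]).
#' @param pet_bin_width Discretization bin width for PET (SUV).
#' @param ct_bin_width Discretization bin width for CT (HU).
#' @return An object of class \code{preprocess_config}.
#' @export
preprocess_config <- function(target_spacing = c(1, 1, 1), sr_factor = 1L,
                              normalization = "none",
                              pet_bin_width = 0.25, ct_bin_width = 25) {
  stop_if(!sr_factor %in% c(1L, 2L, 4L), "sr_factor must be 1, 2 or 4")
  stop_if(any(target_spacing <= 0), "target_spacing must be positive")
  stop_if(pet_bin_width <= 0 || ct_bin_width <= 0, "bin widths must be > 0")
  normalization <- match.arg(normalization, c("none", "zscore", "minmax"))
  structure(list(target_spacing = as.numeric(target_spacing),
                 sr_factor = as.integer(sr_factor),
                 normalization = normalization,
                 pet_bin_width = pet_bin_width,
                 ct_bin_width = ct_bin_width),
            class = "preprocess_config")
}

## Trilinear interpolation of a 3D array at fractional 0-based index
## coordinates (matrix q, one row per point). Coordinates are clamped to
## the grid, so boundary queries replicate edge values.
interp_trilinear <- function(vol, q) {
  nd <- dim(vol)
  for (k in 1:3) q[, k] <- pmin(pmax(q[, k], 0), nd[k] - 1)
  hi <- matrix(rep(pmax(nd - 2, 0), each = nrow(q)), ncol = 3)
  i0 <- pmax(pmin(floor(q), hi), 0)
  fr <- q - i0
  i0 <- i0 + 1  # 1-based lower corner; upper corner stays in range
  i1 <- pmin(i0 + 1, matrix(rep(nd, each = nrow(q)), ncol = 3))
  g <- function(a, b, c) vol[cbind(a, b, c)]
  v000 <- g(i0[, 1], i0[, 2], i0[, 3]); v100 <- g(i1[, 1], i0[, 2], i0[, 3])
  v010 <- g(i0[, 1], i1[, 2], i0[, 3]); v110 <- g(i1[, 1], i1[, 2], i0[, 3])
  v001 <- g(i0[, 1], i0[, 2], i1[, 3]); v101 <- g(i1[, 1], i0[, 2], i1[, 3])
  v011 <- g(i0[, 1], i1[, 2], i1[, 3]); v111 <- g(i1[, 1], i1[, 2], i1[, 3])
  fx <- fr[, 1]; fy <- fr[, 2]; fz <- fr[, 3]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

## Nearest-neighbour interpolation (for masks). floor(q + 0.5) rather than
## round() so half-grid points resolve consistently upward.
interp_nearest <- function(vol, q) {
  nd <- dim(vol)
  for (k in 1:3) q[, k] <- pmin(pmax(floor(q[, k] + 0.5), 0), nd[k] - 1)
  vol[q + 1]
}

#' Resample a volume pair to a target grid spacing
#'
#' Images are interpolated trilinearly, the mask by nearest neighbour (so it
#' remains binary). The new grid spans the same physical extent as the old
#' one (to within one voxel) with the same origin.
#'
#' @param pair A \code{volume_pair}.
#' @param target_spacing Length-3 positive spacing in mm.
#' @return A resampled \code{volume_pair}.
#' @export
resample_to_grid <- function(pair, target_spacing) {
  stopifnot(inherits(pair, "volume_pair"))
  stop_if(any(!is.finite(target_spacing)) || any(target_spacing <= 0),
          "target_spacing must be positive")
  old_sp <- pair$spacing
  nd <- dim(pair$pet)
  if (isTRUE(all.equal(old_sp, as.numeric(target_spacing)))) return(pair)
  ## number of new voxels whose centres fall within the old centre extent
  n_new <- pmax(2L, as.integer(floor((nd - 1) * old_sp / target_spacing)) + 1L)
  gx <- axis_coords(n_new[1], target_spacing[1], 0) / old_sp[1]
  gy <- axis_coords(n_new[2], target_spacing[2], 0) / old_sp[2]
  gz <- axis_coords(n_new[3], target_spacing[3], 0) / old_sp[3]
  q <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  pet <- array(interp_trilinear(pair$pet, q), dim = n_new)
  ct <- array(interp_trilinear(pair$ct, q), dim = n_new)
  mask <- array(as.integer(interp_nearest(pair$voi_mask, q)), dim = n_new)
  stop_if(sum(mask) == 0L, "VOI vanished under resampling")
  volume_pair(pet, ct, mask, spacing = as.numeric(target_spacing),
              origin = pair$origin)
}

## Natural cubic spline interpolation along one array axis at new 0-based
## fractional indices xout.
spline_axis <- function(vol, axis, xout) {
  nd <- dim(vol)
  n <- nd[axis]
  perm <- c(axis, setdiff(1:3, axis))
  v <- aperm(vol, perm)
  m <- matrix(v, nrow = n)
  out <- apply(m, 2, function(col)
    stats::spline(x = 0:(n - 1), y = col, xout = xout,
                  method = "natural")$y)
  out <- array(out, dim = c(length(xout), nd[perm[2]], nd[perm[3]]))
  aperm(out, order(perm))
}

#' Super-resolution upsampling of a 3D volume
#'
#' Deterministic stand-in for a learned super-resolution stage: separable
#' natural cubic-spline upsampling by an integer factor per axis. Factor 1
#' is the identity. New voxel centres sit at old (0-based) index coordinates
#' \code{j / factor}, so existing voxel centres are interpolated exactly.
#'
#' @param volume 3D numeric array.
#' @param factor Integer upsampling factor, one of 1, 2, 4.
#' @return A 3D array with \code{factor}-times denser sampling per axis.
#' @export
super_resolve <- function(volume, factor) {
  stop_if(!is.array(volume) || length(dim(volume)) != 3L,
          "volume must be a 3D array")
  stop_if(!factor %in% c(1, 2, 4), "factor must be 1, 2 or 4")
  if (factor == 1) return(volume)
  out <- volume
  for (axis in 1:3) {
    n <- dim(out)[axis]
    xout <- (seq_len(n * factor) - 1) / factor
    out <- spline_axis(out, axis, xout)
  }
  out
}

#' Intensity normalization over the VOI
#'
#' Applies an affine map defined by the VOI voxels to the whole volume:
#' \code{"zscore"} gives VOI mean 0 / population SD 1, \code{"minmax"} maps
#' the VOI range to [0, 1], \code{"none"} is the identity.
#'
#' @param volume 3D numeric array.
#' @param mask 3D binary array (nonempty for VOI-based modes).
#' @param mode One of \code{"none"}, \code{"zscore"}, \code{"minmax"}.
#' @return The transformed volume.
#' @export
normalize_intensity <- function(volume, mask, mode = "zscore") {
  mode <- match.arg(mode, c("none", "zscore", "minmax"))
  if (mode == "none") return(volume)
  v <- volume[mask != 0]
  stop_if(length(v) == 0, "empty VOI")
  if (mode == "zscore") {
    s <- pop_sd(v)
    stop_if(s == 0, "zero VOI variance under z-score normalization")
    return((volume - mean(v)) / s)
  }
  rng <- range(v)
  stop_if(diff(rng) == 0, "zero VOI range under min-max normalization")
  (volume - rng[1]) / diff(rng)
}

#' Fixed-bin-width intensity discretization
#'
#' Bin index \code{floor((v - min_value) / bin_width) + 1}; indices start at
#' 1 and the map is order-preserving. Values below \code{min_value} are
#' clamped into bin 1.
#'
#' @param values Numeric vector.
#' @param bin_width Positive bin width.
#' @param min_value Anchor (lower edge of bin 1); defaults to
#'   \code{min(values)}.
#' @return Integer bin indices.
#' @export
discretize <- function(values, bin_width, min_value = min(values)) {
  stop_if(!is_scalar_number(bin_width) || bin_width <= 0,
          "bin_width must be > 0")
  idx <- floor((values - min_value) / bin_width) + 1
  as.integer(pmax(idx, 1))
}

#' Run the five-stage preprocessing pipeline on a volume pair
#'
#' Stages in order: intensity normalization (per channel, over the VOI),
#' spatial registration (no-op hook for co-registered input), resampling to
#' the target spacing, super-resolution upsampling of both channels (the
#' mask is upsampled by nearest neighbour). Discretization is deferred to
#' feature extraction, which is where binned intensities are consumed.
#'
#' @param pair A \code{volume_pair}.
#' @param config A \code{preprocess_config}.
#' @return A preprocessed \code{volume_pair}.
#' @export
preprocess_pair <- function(pair, config = preprocess_config()) {
  stopifnot(inherits(pair, "volume_pair"), inherits(config, "preprocess_config"))
  pet <- normalize_intensity(pair$pet, pair$voi_mask, config$normalization)
  ct <- normalize_intensity(pair$ct, pair$voi_mask, config$normalization)
  pair <- volume_pair(pet, ct, pair$voi_mask, pair$spacing, pair$origin)
  ## registration hook: phantom volumes are generated co-registered
  pair <- resample_to_grid(pair, config$target_spacing)
  if (config$sr_factor > 1) {
    f <- config$sr_factor
    pet <- super_resolve(pair$pet, f)
    ct <- super_resolve(pair$ct, f)
    nd <- dim(pet)
    q <- as.matrix(expand.grid(x = (seq_len(nd[1]) - 1) / f,
                               y = (seq_len(nd[2]) - 1) / f,
                               z = (seq_len(nd[3]) - 1) / f))
    mask <- array(as.integer(interp_nearest(pair$voi_mask, q)), dim = nd)
    pair <- volume_pair(pet, ct, mask, spacing = pair$spacing / f,
                        origin = pair$origin)
  }
  pair
}
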