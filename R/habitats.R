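#' Otsu threshold of a set of intensity values
#'
#' Builds an \code{n_bins}-bin histogram spanning the value range and
#' returns the bin boundary maximizing the between-class variance
#' \eqn{\sigma^2_b(t) = \omega_0 \omega_1 (\mu_0 - \mu_1)^2}. Only splits
#' with both classes nonempty are candidates; among ties the smallest
#' threshold is returned. "High" membership downstream means strictly
#' greater than the returned threshold (the upper edge of the selected
#' bin).
#'
#' @param values Numeric vector with at least two distinct values.
#' @param n_bins Number of histogram bins (>= 2), default 128.
#' @return The threshold value (scalar), with attribute \code{"bin"} giving
#'   the index of the last low-class bin.
#' @export
otsu_threshold <- function(values, n_bins = 128L) {
  stop_if(length(values) < 2 || !all(is.finite(values)),
          "need at least two finite values")
  rng <- range(values)
  stop_if(diff(rng) == 0, "degenerate input: all values identical")
  stop_if(n_bins < 2, "n_bins must be >= 2")
  bw <- diff(rng) / n_bins
  bin <- pmin(pmax(floor((values - rng[1]) / bw) + 1, 1), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  p <- counts / sum(counts)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) * bw
  w0 <- cumsum(p)
  mu_c <- cumsum(p * mids)
  mu_t <- mu_c[n_bins]
  ## between-class variance for split after bin t (t = 1..n_bins-1)
  t <- seq_len(n_bins - 1)
  w0t <- w0[t]
  valid <- w0t > 0 & w0t < 1
  sigma_b <- rep(-Inf, n_bins - 1)
  sigma_b[valid] <- (mu_t * w0t[valid] - mu_c[t][valid])^2 /
    (w0t[valid] * (1 - w0t[valid]))
  stop_if(!any(valid), "degenerate input: cannot split histogram")
  best <- which.max(sigma_b)  # ties -> smallest index
  thr <- rng[1] + best * bw
  attr(thr, "bin") <- as.integer(best)
  thr
}

#' Segment the VOI into four metabolic habitats
#'
#' Applies \code{\link{otsu_threshold}} independently to the PET and CT
#' intensities inside the VOI and labels every VOI voxel by the four-way
#' intersection: 1 = PET-high/CT-high (high-glycolytic/high-density),
#' 2 = PET-low/CT-low, 3 = PET-low/CT-high, 4 = PET-high/CT-low. "High"
#' means strictly greater than the modality threshold.
#'
#' @param pair A \code{volume_pair} whose VOI holds at least two distinct
#'   PET values and two distinct CT values.
#' @param n_bins Histogram bins for the Otsu search.
#' @return An object of class \code{habitat_map}: list with \code{labels}
#'   (3D integer array, 0 outside VOI), \code{pet_threshold},
#'   \code{ct_threshold}, \code{voxel_counts} (length-4), \code{spacing}.
#' @export
segment_habitats <- function(pair, n_bins = 128L) {
  stopifnot(inherits(pair, "volume_pair"))
  idx <- which(pair$voi_mask == 1L)
  pet_v <- pair$pet[idx]
  ct_v <- pair$ct[idx]
  if (length(unique(pet_v)) < 2)
    stop("degenerate PET channel: VOI intensities are constant", call. = FALSE)
  if (length(unique(ct_v)) < 2)
    stop("degenerate CT channel: VOI intensities are constant", call. = FALSE)
  thr_pet <- otsu_threshold(pet_v, n_bins)
  thr_ct <- otsu_threshold(ct_v, n_bins)
  pet_high <- pet_v > as.numeric(thr_pet)
  ct_high <- ct_v > as.numeric(thr_ct)
  lab <- integer(length(idx))
  lab[pet_high & ct_high] <- 1L
  lab[!pet_high & !ct_high] <- 2L
  lab[!pet_high & ct_high] <- 3L
  lab[pet_high & !ct_high] <- 4L
  labels <- array(0L, dim = dim(pair$pet))
  labels[idx] <- lab
  structure(list(labels = labels,
                 pet_threshold = as.numeric(thr_pet),
                 ct_threshold = as.numeric(thr_ct),
                 voxel_counts = tabulate(lab, nbins = 4L),
                 spacing = pair$spacing),
            class = "habitat_map")
}

#' @export
print.habitat_map <- function(x, ...) {
  cat("<habitat_map> thresholds: PET >", signif(x$pet_threshold, 4),
      "SUV, CT >", signif(x$ct_threshold, 4), "HU\n")
  cat("  voxels per habitat:", paste(x$voxel_counts, collapse = ", "),
      "(total", sum(x$voxel_counts), ")\n")
  invisible(x)
}

#' Binary mask of one habitat (or the whole VOI)
#'
#' @param map A \code{habitat_map}.
#' @param habitat Habitat label 1-4, or \code{"all"} for the whole VOI.
#' @return 3D integer 0/1 array.
#' @export
habitat_mask <- function(map, habitat) {
  stopifnot(inherits(map, "habitat_map"))
  if (identical(habitat, "all"))
    return(array(as.integer(map$labels > 0L), dim = dim(map$labels)))
  stop_if(!habitat %in% 1:4, "habitat must be 1..4 or \"all\"")
  array(as.integer(map$labels == as.integer(habitat)), dim = dim(map$labels))
}

#' Write a habitat map as NIfTI with a JSON sidecar
#'
#' @param map A \code{habitat_map}.
#' @param prefix Output path prefix.
#' @return Invisibly, the NIfTI path.
#' @export
write_habitat_map <- function(map, prefix) {
  stopifnot(inherits(map, "habitat_map"))
  path <- paste0(prefix, "_habitats.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(map$labels, pixdim = map$spacing), path)
  side <- list(pet_threshold = map$pet_threshold,
               ct_threshold = map$ct_threshold,
               voxel_counts = as.list(stats::setNames(map$voxel_counts,
                                                      paste0("habitat", 1:4))))
  jsonlite::write_json(side, paste0(prefix, "_habitats.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
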