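#' Conventional PET metabolic parameters over a region
#'
#' Computes SUVmax, SUVmean, metabolic tumour volume (MTV, in mL) and total
#' lesion glycolysis (TLG = SUVmean x MTV) over the voxels of a region
#' mask. An empty region returns a summary flagged empty with
#' \code{n_voxels = 0} and \code{NA} intensity fields rather than failing:
#' a habitat subregion may legitimately vanish in extreme lesions.
#'
#' @param pet 3D numeric array (SUV).
#' @param region_mask 3D binary array, same dimensions as \code{pet}.
#' @param spacing Voxel spacing in mm.
#' @param region_id Optional region label stored in the result.
#' @return An object of class \code{metabolic_summary} (a one-row
#'   data.frame with columns \code{region_id}, \code{n_voxels},
#'   \code{suv_max}, \code{suv_mean}, \code{mtv_ml}, \code{tlg},
#'   \code{empty}).
#' @export
metabolic_summary <- function(pet, region_mask, spacing = c(1, 1, 1),
                              region_id = "region") {
  stop_if(!identical(dim(pet), dim(region_mask)),
          "pet and region_mask dimensions differ")
  v <- pet[region_mask != 0]
  voxel_ml <- prod(spacing) / 1000
  if (length(v) == 0) {
    out <- data.frame(region_id = region_id, n_voxels = 0L,
                      suv_max = NA_real_, suv_mean = NA_real_,
                      mtv_ml = 0, tlg = NA_real_, empty = TRUE,
                      stringsAsFactors = FALSE)
  } else {
    mtv <- length(v) * voxel_ml
    out <- data.frame(region_id = region_id, n_voxels = length(v),
                      suv_max = max(v), suv_mean = mean(v),
                      mtv_ml = mtv, tlg = mean(v) * mtv, empty = FALSE,
                      stringsAsFactors = FALSE)
  }
  class(out) <- c("metabolic_summary", class(out))
  out
}

#' Metabolic parameters for the whole tumour and each habitat
#'
#' @param pair A \code{volume_pair} (PET channel is used).
#' @param map The \code{habitat_map} of the same grid.
#' @return A five-row data.frame (whole tumour + habitats 1-4).
#' @export
region_metabolics <- function(pair, map) {
  stopifnot(inherits(pair, "volume_pair"), inherits(map, "habitat_map"))
  rows <- list(metabolic_summary(pair$pet, habitat_mask(map, "all"),
                                 pair$spacing, "whole_tumor"))
  for (h in 1:4) {
    rows[[h + 1]] <- metabolic_summary(pair$pet, habitat_mask(map, h),
                                       pair$spacing, paste0("habitat", h))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Habitat spatial characteristics
#'
#' Per-habitat voxel count, kilovoxels (count / 1000, the unit used when
#' regressing PD-L1 status on habitat size) and volume fraction of the VOI.
#' Empty habitats contribute zeros; fractions sum to 1.
#'
#' @param map A \code{habitat_map}.
#' @return A four-row data.frame with columns \code{habitat},
#'   \code{n_voxels}, \code{kilovoxels}, \code{volume_fraction}.
#' @export
spatial_characteristics <- function(map) {
  stopifnot(inherits(map, "habitat_map"))
  counts <- map$voxel_counts
  total <- sum(counts)
  data.frame(habitat = 1:4,
             n_voxels = as.integer(counts),
             kilovoxels = counts / 1000,
             volume_fraction = if (total > 0) counts / total else rep(0, 4))
}

#' Per-subject habitat metabolic and spatial feature table
#'
#' A compact feature set for cohort-scale modelling: for the whole tumour
#' and each habitat, SUVmax, SUVmean, MTV and TLG, plus the four habitat
#' volume fractions (25 columns). Empty habitats contribute zeros. This is
#' the lightweight counterpart of the full radiomic inventory, suitable for
#' large simulated cohorts.
#'
#' @param cohort List of rasterized \code{synthetic_subject}s, or of lists
#'   with elements \code{subject_id} and \code{pair}.
#' @param n_bins Otsu histogram bins for segmentation.
#' @return data.frame, one row per subject; first column
#'   \code{subject_id}.
#' @export
cohort_summary_features <- function(cohort, n_bins = 128L) {
  regions <- c("wt", paste0("h", 1:4))
  rows <- lapply(cohort, function(s) {
    pair <- if (inherits(s, "synthetic_subject")) subject_pair(s) else s$pair
    map <- segment_habitats(pair, n_bins)
    met <- region_metabolics(pair, map)
    sc <- spatial_characteristics(map)
    v <- c(met$suv_max, met$suv_mean, met$mtv_ml, met$tlg,
           sc$volume_fraction)
    v[!is.finite(v)] <- 0
    names(v) <- c(paste0(rep(c("suvmax", "suvmean", "mtv", "tlg"),
                             each = 5), "_", rep(regions, 4)),
                  paste0("frac_h", 1:4))
    cbind(data.frame(subject_id = s$subject_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(v)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
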