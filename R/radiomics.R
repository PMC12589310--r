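#' Radiomic feature extraction configuration
#'
#' The default inventory is 14 shape features computed once on the mask
#' plus 91 features (18 first-order, 22 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM,
#' 5 NGTDM) for each of 11 image types (original, 8 stationary coiflet-1
#' wavelet sub-bands, Laplacian-of-Gaussian at sigma 1 and 3 mm), for a
#' total of 14 + 11 x 91 = 1015 uniquely named features per region.
#'
#' Discretization: the original image uses a fixed bin width anchored at
#' the region minimum (IBSI-preferred for PET); filtered images, whose
#' intensity scales are filter-dependent, use a fixed bin count over the
#' region range. Grey levels are capped at \code{max_levels} to bound the
#' texture matrices.
#'
#' @param bin_width Fixed bin width for the original image (SUV for the
#'   PET channel, HU for CT).
#' @param n_bins_filtered Fixed bin count for filtered images.
#' @param log_sigmas_mm LoG scales in mm.
#' @param min_voxels Minimum region size; smaller regions yield a
#'   missing-value vector with a reason code.
#' @param max_levels Grey-level cap for texture matrices.
#' @param image_types Character vector of image types to extract from;
#'   default all 11. Reducing this shrinks the inventory proportionally
#'   (14 + 91 per type) for quick runs.
#' @return An object of class \code{feature_config}.
#' @export
feature_config <- function(bin_width = 0.25, n_bins_filtered = 32L,
                           log_sigmas_mm = c(1, 3), min_voxels = 8L,
                           max_levels = 128L, image_types = NULL) {
  stop_if(bin_width <= 0, "bin_width must be > 0")
  stop_if(any(log_sigmas_mm <= 0), "LoG sigma must be > 0")
  all_types <- c("original",
                 paste0("wavelet.", c("LLL", "HLL", "LHL", "HHL",
                                      "LLH", "HLH", "LHH", "HHH")),
                 sprintf("log.sigma.%g", log_sigmas_mm))
  if (is.null(image_types)) image_types <- all_types
  stop_if(!all(image_types %in% all_types), "unknown image type")
  structure(list(bin_width = bin_width,
                 n_bins_filtered = as.integer(n_bins_filtered),
                 log_sigmas_mm = log_sigmas_mm,
                 min_voxels = as.integer(min_voxels),
                 max_levels = as.integer(max_levels),
                 image_types = image_types),
            class = "feature_config")
}

#' Names of all features produced under a configuration
#' @param config A \code{feature_config}.
#' @return Character vector (length 1015 under the default configuration).
#' @export
feature_names <- function(config = feature_config()) {
  shape <- paste0("shape_", names(shape_features(array(1L, c(2, 2, 2)),
                                                 c(1, 1, 1))))
  fam <- c(paste0("firstorder_", names(firstorder_features(c(1, 2), c(1L, 2L), 2L))),
           paste0("glcm_", glcm_feature_names()),
           paste0("glrlm_", glrlm_feature_names()),
           paste0("glszm_", glszm_feature_names()),
           paste0("gldm_", gldm_feature_names()),
           paste0("ngtdm_", c("Coarseness", "Contrast", "Busyness",
                              "Complexity", "Strength")))
  c(shape, as.vector(t(outer(config$image_types, fam, paste, sep = "_"))))
}

## Crop a volume and mask to the mask bounding box plus a margin.
crop_to_region <- function(volume, mask, margin = 4L) {
  nd <- dim(mask)
  idx <- arrayInd(which(mask != 0), nd)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, nd)
  list(volume = volume[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
       mask = mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE])
}

## Discretize one image over the region per the config rules.
discretize_region <- function(img, in_region, type, config) {
  v <- img[in_region]
  if (type == "original") {
    lev <- discretize(v, config$bin_width, min_value = min(v))
  } else {
    rng <- range(v)
    if (diff(rng) == 0) {
      lev <- rep(1L, length(v))
    } else {
      bw <- diff(rng) / config$n_bins_filtered
      lev <- pmin(discretize(v, bw, min_value = rng[1]),
                  config$n_bins_filtered)
    }
  }
  as.integer(pmin(lev, config$max_levels))
}

texture_features_for_image <- function(img, region_mask, type, config,
                                       voxel_volume) {
  in_region <- region_mask != 0
  x <- img[in_region]
  lev_vec <- discretize_region(img, in_region, type, config)
  n_levels <- max(lev_vec)
  levels_arr <- array(NA_integer_, dim = dim(img))
  levels_arr[in_region] <- lev_vec
  n_vox <- length(x)

  fo <- firstorder_features(x, lev_vec, n_levels)
  fo["TotalEnergy"] <- voxel_volume * fo[["Energy"]]

  P <- glcm_matrix(levels_arr, n_levels)
  R <- glrlm_matrix(levels_arr, n_levels)
  Z <- glszm_matrix(levels_arr, n_levels)
  ns <- neighbour_stats(levels_arr)
  D <- gldm_matrix(levels_arr, n_levels, stats = ns)
  Ntab <- ngtdm_table(levels_arr, n_levels, stats = ns)

  c(stats::setNames(fo, paste0("firstorder_", names(fo))),
    stats::setNames(glcm_features(P), paste0("glcm_", glcm_feature_names())),
    stats::setNames(rl_style_features(R, n_vox, glrlm_feature_names(),
                                      extra_denominator = nrow(DIRECTIONS_3D)),
                    paste0("glrlm_", glrlm_feature_names())),
    stats::setNames(rl_style_features(Z, n_vox, glszm_feature_names()),
                    paste0("glszm_", glszm_feature_names())),
    stats::setNames(gldm_features(D, n_vox),
                    paste0("gldm_", gldm_feature_names())),
    {
      ng <- ngtdm_features(Ntab, n_vox)
      stats::setNames(ng, paste0("ngtdm_", names(ng)))
    })
}

#' Extract the radiomic feature vector of one region
#'
#' Computes the configured feature inventory (1015 features by default) on
#' one image channel of a volume pair, restricted to a region mask. Shape
#' features are computed on the mask; intensity and texture features are
#' computed per image type on intensities discretized within the region.
#' Regions below \code{min_voxels} return an all-\code{NA} vector with a
#' \code{"reason"} attribute instead of failing.
#'
#' @param pair A \code{volume_pair}.
#' @param region_mask 3D binary array on the pair's grid.
#' @param config A \code{feature_config}.
#' @param channel \code{"pet"} or \code{"ct"}: which image channel the
#'   intensity/texture features are computed on.
#' @return Named numeric vector of features, deterministic order.
#' @export
extract_features <- function(pair, region_mask, config = feature_config(),
                             channel = c("pet", "ct")) {
  stopifnot(inherits(pair, "volume_pair"), inherits(config, "feature_config"))
  channel <- match.arg(channel)
  stop_if(!identical(dim(region_mask), dim(pair$pet)),
          "region_mask is not on the pair's grid")
  nm <- feature_names(config)
  n_region <- sum(region_mask != 0)
  if (n_region < config$min_voxels) {
    out <- stats::setNames(rep(NA_real_, length(nm)), nm)
    attr(out, "reason") <- sprintf("region has %d voxels (minimum %d)",
                                   n_region, config$min_voxels)
    return(out)
  }
  vol <- if (channel == "pet") pair$pet else pair$ct
  cr <- crop_to_region(vol, region_mask, margin = 6L)
  voxel_volume <- prod(pair$spacing)

  shape <- shape_features(cr$mask, pair$spacing)
  res <- stats::setNames(shape, paste0("shape_", names(shape)))

  bank <- filter_bank(cr$volume, pair$spacing, config$log_sigmas_mm)
  for (type in config$image_types) {
    fv <- texture_features_for_image(bank[[type]], cr$mask, type, config,
                                     voxel_volume)
    res <- c(res, stats::setNames(fv, paste0(type, "_", names(fv))))
  }
  stopifnot(identical(names(res), nm))
  res
}

#' Extract the cohort feature matrix
#'
#' Runs \code{\link{extract_features}} for each subject over the whole
#' tumour and the four habitat subregions, on one or both channels, and
#' returns a subjects-by-features data.frame with region/channel-namespaced
#' column names (e.g. \code{habitat1_pet_original_glcm_Contrast}).
#'
#' @param cohort List of \code{synthetic_subject}s (rasterized), or a list
#'   of lists with elements \code{pair} and \code{map}.
#' @param config A \code{feature_config}.
#' @param regions Character vector among \code{"whole_tumor"},
#'   \code{"habitat1"} ... \code{"habitat4"}.
#' @param channels One or both of \code{"pet"}, \code{"ct"}.
#' @param n_bins Otsu histogram bins for habitat segmentation.
#' @return data.frame with a \code{subject_id} column and one column per
#'   feature.
#' @export
cohort_features <- function(cohort, config = feature_config(),
                            regions = c("whole_tumor", paste0("habitat", 1:4)),
                            channels = "pet", n_bins = 128L) {
  rows <- lapply(cohort, function(s) {
    if (inherits(s, "synthetic_subject")) {
      pair <- subject_pair(s)
      id <- s$subject_id
    } else {
      pair <- s$pair
      id <- s$subject_id
    }
    map <- segment_habitats(pair, n_bins)
    vals <- list()
    for (reg in regions) {
      msk <- if (reg == "whole_tumor") habitat_mask(map, "all")
        else habitat_mask(map, as.integer(sub("habitat", "", reg)))
      for (ch in channels) {
        fv <- extract_features(pair, msk, config, channel = ch)
        names(fv) <- paste(reg, ch, names(fv), sep = "_")
        vals[[paste(reg, ch)]] <- fv
      }
    }
    c(list(subject_id = id), as.list(do.call(c, unname(vals))))
  })
  nm <- names(rows[[1]])
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
  rownames(df) <- NULL
  df
}
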