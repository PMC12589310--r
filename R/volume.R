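#' Co-registered PET/CT volume pair with a tumour VOI mask
#'
#' Container for one subject's imaging data: a PET volume in SUV units, a CT
#' volume in Hounsfield units and a binary volume-of-interest mask, all on a
#' single grid. Voxel indices are 0-based and world coordinates follow
#' \code{world = origin + index * spacing} (voxel-centre convention).
#'
#' @param pet 3D numeric array, SUV.
#' @param ct 3D numeric array, HU; same dimensions as \code{pet}.
#' @param voi_mask 3D array coercible to 0/1; same dimensions as \code{pet}.
#' @param spacing Numeric length-3, voxel spacing in mm (all > 0).
#' @param origin Numeric length-3, world position of voxel (0,0,0) in mm.
#'
#' @return An object of class \code{volume_pair}.
#' @export
volume_pair <- function(pet, ct, voi_mask, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)) {
  stop_if(!is.array(pet) || length(dim(pet)) != 3L, "pet must be a 3D array")
  stop_if(!identical(dim(pet), dim(ct)), "pet and ct dimensions differ")
  stop_if(!identical(dim(pet), dim(voi_mask)),
          "pet and voi_mask dimensions differ")
  stop_if(length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0),
          "spacing must be three positive numbers (mm)")
  stop_if(length(origin) != 3L || any(!is.finite(origin)),
          "origin must be three finite numbers (mm)")
  m <- array(as.integer(voi_mask != 0), dim = dim(pet))
  stop_if(sum(m) == 0L, "voi_mask is empty")
  structure(list(pet = pet, ct = ct, voi_mask = m,
                 spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "volume_pair")
}

#' @export
print.volume_pair <- function(x, ...) {
  d <- dim(x$pet)
  cat("<volume_pair> ", paste(d, collapse = "x"),
      " voxels @ ", paste(signif(x$spacing, 4), collapse = "x"), " mm\n",
      "  VOI: ", sum(x$voi_mask), " voxels (",
      signif(sum(x$voi_mask) * prod(x$spacing) / 1000, 4), " mL)\n",
      "  PET in VOI: [", signif(min(x$pet[x$voi_mask == 1]), 4), ", ",
      signif(max(x$pet[x$voi_mask == 1]), 4), "] SUV;",
      "  CT in VOI: [", signif(min(x$ct[x$voi_mask == 1]), 4), ", ",
      signif(max(x$ct[x$voi_mask == 1]), 4), "] HU\n", sep = "")
  invisible(x)
}

#' Write a subject's volumes as NIfTI files
#'
#' Writes \code{<prefix>_pet.nii.gz}, \code{<prefix>_ct.nii.gz} and
#' \code{<prefix>_mask.nii.gz} with the pair's voxel spacing.
#'
#' @param pair A \code{volume_pair}.
#' @param prefix Output path prefix (directory must exist).
#' @return Invisibly, the three file paths.
#' @export
write_volume_pair <- function(pair, prefix) {
  stopifnot(inherits(pair, "volume_pair"))
  paths <- paste0(prefix, c("_pet.nii.gz", "_ct.nii.gz", "_mask.nii.gz"))
  vols <- list(pair$pet, pair$ct, pair$voi_mask)
  for (i in 1:3) {
    img <- RNifti::asNifti(vols[[i]], pixdim = pair$spacing)
    RNifti::writeNifti(img, paths[i])
  }
  invisible(paths)
}

#' Read a subject's volumes from NIfTI files written by write_volume_pair
#'
#' @param prefix Path prefix used when writing.
#' @param origin World origin to attach (mm); NIfTI orientation metadata is
#'   not interpreted beyond voxel spacing.
#' @return A \code{volume_pair}.
#' @export
read_volume_pair <- function(prefix, origin = c(0, 0, 0)) {
  pet <- RNifti::readNifti(paste0(prefix, "_pet.nii.gz"))
  ct <- RNifti::readNifti(paste0(prefix, "_ct.nii.gz"))
  mask <- RNifti::readNifti(paste0(prefix, "_mask.nii.gz"))
  sp <- RNifti::pixdim(pet)[1:3]
  volume_pair(array(as.numeric(pet), dim = dim(pet)),
              array(as.numeric(ct), dim = dim(ct)),
              array(as.numeric(mask), dim = dim(mask)),
              spacing = sp, origin = origin)
}
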