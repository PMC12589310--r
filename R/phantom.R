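#' Configuration for the synthetic PET/CT phantom cohort
#'
#' Defines the generative model for seeded phantom cohorts: ellipsoidal
#' lesions whose voxels carry one of four ground-truth habitat labels
#' (contiguous blobs grown from seeded nuclei), PET/CT intensities drawn
#' from two well-separated modes per modality, clinical covariates with
#' planted effects, and a PD-L1 label drawn from a logistic model on the
#' habitat-1 volume fraction plus clinical terms.
#'
#' Defaults encode the study conditions the package is exercised under:
#' a 64x64x32 grid at 1 mm isotropic spacing; PET modes 2.0/8.0 SUV
#' (SD 0.4); CT modes -20/60 HU (SD 8); habitat fractions drawn from a
#' symmetric Dirichlet(0.4) so fractions vary widely across lesions;
#' a habitat-1 volume-fraction log-odds slope of 6 (about 1.8-fold odds per
#' 10-percentage-point increase in the habitat-1 fraction), chosen so the
#' planted habitat signal supports held-out discrimination around AUC 0.8,
#' with intercept -1.3 giving roughly balanced PD-L1 prevalence; clinical
#' effects: histology (LUAD vs LUSC) odds ratio 0.535 and elevated NSE odds
#' ratio 1.735. The slope is freely settable, e.g. to a literature odds
#' ratio such as \code{log(8.84)}, for parameter-recovery studies.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param grid_dim Integer length-3 grid dimensions.
#' @param spacing Voxel spacing in mm.
#' @param radius_range Range (mm) for ellipsoid semi-axes.
#' @param pet_means,pet_sd Low/high PET mode means (SUV) and common SD.
#' @param ct_means,ct_sd Low/high CT mode means (HU) and common SD.
#' @param fraction_alpha Dirichlet concentration (length 4) for the
#'   ground-truth habitat fraction sampler.
#' @param beta0,beta1 Intercept and habitat-1 volume-fraction slope of the
#'   PD-L1 logistic model (log-odds scale).
#' @param or_histology Odds ratio for LUAD (vs LUSC) histology.
#' @param or_nse Odds ratio for elevated NSE.
#' @param p_luad,p_nse_elevated Covariate prevalences.
#' @param seed Integer seed; fans out to per-subject substreams.
#'
#' @return An object of class \code{phantom_config}.
#' @export
phantom_config <- function(n_subjects = 60,
                           grid_dim = c(64L, 64L, 32L),
                           spacing = c(1, 1, 1),
                           radius_range = c(8, 14),
                           pet_means = c(2, 8), pet_sd = 0.4,
                           ct_means = c(-20, 60), ct_sd = 8,
                           fraction_alpha = rep(0.4, 4),
                           beta0 = -1.3, beta1 = 6,
                           or_histology = 0.535, or_nse = 1.735,
                           p_luad = 0.457, p_nse_elevated = 0.3,
                           seed = 1L) {
  stop_if(n_subjects < 2, "n_subjects must be >= 2")
  stop_if(pet_means[2] <= pet_means[1],
          "PET high-mode mean must exceed low-mode mean")
  stop_if(ct_means[2] <= ct_means[1],
          "CT high-mode mean must exceed low-mode mean")
  ## Mode separability: intensity gap must exceed 4 SD so Otsu splits are
  ## well defined on phantoms.
  stop_if(diff(pet_means) <= 4 * pet_sd,
          "PET modes not separable: mean gap must exceed 4*SD")
  stop_if(diff(ct_means) <= 4 * ct_sd,
          "CT modes not separable: mean gap must exceed 4*SD")
  stop_if(length(fraction_alpha) != 4 || any(fraction_alpha <= 0),
          "fraction_alpha must be 4 positive numbers")
  stop_if(length(radius_range) != 2 || radius_range[1] > radius_range[2] ||
            radius_range[1] <= 0, "bad radius_range")
  structure(list(
    n_subjects = as.integer(n_subjects), grid_dim = as.integer(grid_dim),
    spacing = as.numeric(spacing), radius_range = radius_range,
    pet_means = pet_means, pet_sd = pet_sd,
    ct_means = ct_means, ct_sd = ct_sd,
    fraction_alpha = fraction_alpha,
    beta0 = beta0, beta1 = beta1,
    or_histology = or_histology, or_nse = or_nse,
    p_luad = p_luad, p_nse_elevated = p_nse_elevated,
    seed = as.integer(seed)), class = "phantom_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

## Latent truth for one subject: habitat fractions, clinical covariates and
## PD-L1 label. Uses the current RNG stream.
sample_subject_truth <- function(config) {
  f <- rdirichlet1(config$fraction_alpha)
  histology <- if (stats::runif(1) < config$p_luad) "LUAD" else "LUSC"
  nse_elevated <- as.integer(stats::runif(1) < config$p_nse_elevated)
  age <- round(stats::rnorm(1, 63, 10))
  sex <- if (stats::runif(1) < 0.79) "M" else "F"
  smoking <- as.integer(stats::runif(1) < 0.61)
  eta <- config$beta0 + config$beta1 * f[1] +
    log(config$or_histology) * (histology == "LUAD") +
    log(config$or_nse) * nse_elevated
  pdl1 <- stats::runif(1) < stats::plogis(eta)
  list(fractions = f, histology = histology, nse_elevated = nse_elevated,
       age = age, sex = sex, smoking = smoking, pdl1_positive = pdl1)
}

## Rasterize one subject: ellipsoidal VOI, contiguous habitat blobs grown
## from seeded nuclei matched to the latent fraction vector, then mode-based
## PET/CT intensities.
rasterize_subject <- function(truth, config) {
  nd <- config$grid_dim
  sp <- config$spacing
  semi <- stats::runif(3, config$radius_range[1], config$radius_range[2])
  ## keep the lesion inside the grid
  ctr_mm <- (nd - 1) * sp / 2 + stats::runif(3, -2, 2)
  cx <- axis_coords(nd[1], sp[1], 0)
  cy <- axis_coords(nd[2], sp[2], 0)
  cz <- axis_coords(nd[3], sp[3], 0)
  dx2 <- ((cx - ctr_mm[1]) / semi[1])^2
  dy2 <- ((cy - ctr_mm[2]) / semi[2])^2
  dz2 <- ((cz - ctr_mm[3]) / semi[3])^2
  r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  voi <- array(as.integer(r2 <= 1), dim = nd)
  idx <- which(voi == 1L)
  n_voi <- length(idx)

  ## world coordinates of VOI voxels
  arr_ind <- arrayInd(idx, nd)
  wc <- cbind(cx[arr_ind[, 1]], cy[arr_ind[, 2]], cz[arr_ind[, 3]])

  ## target voxel counts per habitat from the latent fractions
  counts <- floor(truth$fractions * n_voi)
  rem <- n_voi - sum(counts)
  if (rem > 0) {
    give <- order(truth$fractions * n_voi - counts, decreasing = TRUE)[seq_len(rem)]
    counts[give] <- counts[give] + 1L
  }

  ## grow contiguous blobs: habitat h claims its counts[h] unassigned voxels
  ## nearest to a randomly seeded nucleus
  nuclei <- wc[sample.int(n_voi, 4, replace = n_voi < 4), , drop = FALSE]
  lab <- integer(n_voi)
  unassigned <- rep(TRUE, n_voi)
  for (h in 1:4) {
    if (counts[h] == 0) next
    cand <- which(unassigned)
    d2 <- (wc[cand, 1] - nuclei[h, 1])^2 + (wc[cand, 2] - nuclei[h, 2])^2 +
      (wc[cand, 3] - nuclei[h, 3])^2
    take <- cand[order(d2)[seq_len(min(counts[h], length(cand)))]]
    lab[take] <- h
    unassigned[take] <- FALSE
  }
  lab[lab == 0L] <- 4L

  true_habitat <- array(0L, dim = nd)
  true_habitat[idx] <- lab

  pet <- array(stats::rnorm(prod(nd), 0.5, 0.2), dim = nd)
  ct <- array(stats::rnorm(prod(nd), -800, 20), dim = nd)
  pet_high <- lab %in% c(1L, 4L)
  ct_high <- lab %in% c(1L, 3L)
  pet[idx] <- stats::rnorm(n_voi, ifelse(pet_high, config$pet_means[2],
                                         config$pet_means[1]), config$pet_sd)
  ct[idx] <- stats::rnorm(n_voi, ifelse(ct_high, config$ct_means[2],
                                        config$ct_means[1]), config$ct_sd)
  pet[pet < 0] <- 0
  list(pet = pet, ct = ct, voi_mask = voi, true_habitat = true_habitat)
}

#' Generate a seeded synthetic PET/CT cohort
#'
#' Draws \code{n_subjects} phantom lesions under the generative model in
#' \code{\link{phantom_config}}. Each subject receives an independent RNG
#' substream derived from the global seed, so subject k is identical
#' regardless of cohort size.
#'
#' @param config A \code{phantom_config}.
#' @param rasterize If \code{FALSE}, skip voxel rasterization and return
#'   latent truth only (habitat fractions, clinical covariates, PD-L1
#'   label). Intended for large-n statistical studies of the planted
#'   logistic model where voxel volumes are not needed.
#' @return A list of subjects of class \code{synthetic_subject}; each has
#'   \code{subject_id}, \code{clinical}, \code{pdl1_positive},
#'   \code{true_fractions} and (when rasterized) \code{pet}, \code{ct},
#'   \code{voi_mask}, \code{true_habitat}, \code{spacing}.
#' @export
generate_cohort <- function(config, rasterize = TRUE) {
  stopifnot(inherits(config, "phantom_config"))
  lapply(seq_len(config$n_subjects), function(i) {
    set.seed(substream_seed(config$seed, i))
    truth <- sample_subject_truth(config)
    subj <- list(
      subject_id = sprintf("S%04d", i),
      clinical = list(histology = truth$histology,
                      nse_elevated = truth$nse_elevated,
                      age = truth$age, sex = truth$sex,
                      smoking = truth$smoking),
      pdl1_positive = truth$pdl1_positive,
      true_fractions = truth$fractions,
      spacing = config$spacing)
    if (rasterize) {
      vols <- rasterize_subject(truth, config)
      subj <- c(subj, vols)
    }
    class(subj) <- "synthetic_subject"
    subj
  })
}

#' Cohort clinical table
#'
#' Flattens a generated cohort into one row per subject (id, clinical
#' covariates, PD-L1 label, true habitat fractions).
#'
#' @param cohort Output of \code{\link{generate_cohort}}.
#' @return A data.frame.
#' @export
cohort_table <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s) {
    data.frame(subject_id = s$subject_id,
               histology = s$clinical$histology,
               nse_elevated = s$clinical$nse_elevated,
               age = s$clinical$age, sex = s$clinical$sex,
               smoking = s$clinical$smoking,
               pdl1_positive = as.integer(s$pdl1_positive),
               f1 = s$true_fractions[1], f2 = s$true_fractions[2],
               f3 = s$true_fractions[3], f4 = s$true_fractions[4],
               stringsAsFactors = FALSE)
  }))
}

#' Write a phantom cohort to disk
#'
#' Per-subject NIfTI volumes (PET, CT, mask) plus a cohort CSV.
#'
#' @param cohort Output of \code{\link{generate_cohort}} (rasterized).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the cohort CSV path.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in cohort) {
    stop_if(is.null(s$pet), "cohort was generated with rasterize = FALSE")
    pair <- volume_pair(s$pet, s$ct, s$voi_mask, spacing = s$spacing)
    write_volume_pair(pair, file.path(dir, s$subject_id))
  }
  csv <- file.path(dir, "cohort.csv")
  utils::write.csv(cohort_table(cohort), csv, row.names = FALSE)
  invisible(csv)
}

#' Extract the VolumePair of one synthetic subject
#' @param subject A \code{synthetic_subject} with rasterized volumes.
#' @return A \code{volume_pair}.
#' @export
subject_pair <- function(subject) {
  stop_if(is.null(subject$pet), "subject has no rasterized volumes")
  volume_pair(subject$pet, subject$ct, subject$voi_mask,
              spacing = subject$spacing)
}
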