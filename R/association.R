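#' Univariate logistic association of habitat spatial characteristics with
#' PD-L1 status
#'
#' For each habitat (1-4) and each spatial characteristic (voxel count in
#' kilovoxel units, i.e. counts divided by 1000 before fitting, and volume
#' fraction), fits a univariate logistic regression of the binary PD-L1
#' label on that scalar alone and reports the Wald odds ratio, 95% CI and
#' two-sided p-value. A zero-variance characteristic yields a row flagged
#' not estimable.
#'
#' @param spatial data.frame with one row per subject and columns
#'   \code{habitat<h>_voxels} and \code{habitat<h>_fraction} for h = 1..4
#'   (as produced by \code{\link{cohort_spatial}}).
#' @param labels Binary PD-L1 status, one per subject.
#' @return An object of class \code{spatial_association} (a data.frame
#'   with columns \code{habitat}, \code{characteristic}, \code{or},
#'   \code{lower}, \code{upper}, \code{p}, \code{estimable}).
#' @export
habitat_association <- function(spatial, labels) {
  y <- as.integer(as.logical(labels))
  stop_if(sum(y == 1) < 2 || sum(y == 0) < 2,
          "need at least two subjects per class")
  spatial <- as.data.frame(spatial)
  rows <- list()
  for (h in 1:4) {
    for (char in c("kilovoxels", "volume_fraction")) {
      col <- if (char == "kilovoxels") sprintf("habitat%d_voxels", h)
        else sprintf("habitat%d_fraction", h)
      stop_if(!col %in% names(spatial), paste("missing column", col))
      x <- as.numeric(spatial[[col]])
      if (char == "kilovoxels") x <- x / 1000
      if (stats::sd(x) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          habitat = h, characteristic = char, or = NA_real_,
          lower = NA_real_, upper = NA_real_, p = NA_real_,
          estimable = FALSE)
        next
      }
      fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
      co <- summary(fit)$coefficients
      est <- co[2, 1]; se <- co[2, 2]
      z <- stats::qnorm(0.975)
      rows[[length(rows) + 1]] <- data.frame(
        habitat = h, characteristic = char, or = exp(est),
        lower = exp(est - z * se), upper = exp(est + z * se),
        p = co[2, 4], estimable = TRUE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("spatial_association", class(out))
  out
}

#' Per-subject habitat spatial characteristics for a cohort
#'
#' Segments each subject's VOI into habitats and returns one row per
#' subject with per-habitat voxel counts and volume fractions, in the wide
#' layout \code{\link{habitat_association}} consumes.
#'
#' @param cohort List of rasterized \code{synthetic_subject}s, or of lists
#'   with a \code{pair} element.
#' @param n_bins Otsu histogram bins.
#' @return data.frame with \code{subject_id}, \code{habitat<h>_voxels},
#'   \code{habitat<h>_fraction}.
#' @export
cohort_spatial <- function(cohort, n_bins = 128L) {
  rows <- lapply(cohort, function(s) {
    pair <- if (inherits(s, "synthetic_subject")) subject_pair(s) else s$pair
    map <- segment_habitats(pair, n_bins)
    sc <- spatial_characteristics(map)
    row <- data.frame(subject_id = s$subject_id, stringsAsFactors = FALSE)
    for (h in 1:4) {
      row[[sprintf("habitat%d_voxels", h)]] <- sc$n_voxels[h]
      row[[sprintf("habitat%d_fraction", h)]] <- sc$volume_fraction[h]
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
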