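# Per-family radiomic feature calculators. Each returns a named numeric
# vector with a fixed name set and order; the inventory is
# 14 shape + 11 image types x (18 first-order + 22 GLCM + 16 GLRLM +
# 16 GLSZM + 14 GLDM + 5 NGTDM) = 1015 features.

firstorder_features <- function(x, levels_in_region, n_levels) {
  n <- length(x)
  p <- tabulate(levels_in_region, nbins = n_levels)
  p <- p / sum(p)
  mu <- mean(x)
  sdev <- pop_sd(x)
  q <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE,
                       type = 7)
  inner <- x[x >= q[1] & x <= q[5]]
  c(Energy = sum(x^2),
    TotalEnergy = NA_real_,  # filled by caller (needs voxel volume)
    Entropy = -sum(xlog2(p)),
    Minimum = min(x),
    Percentile10 = q[1],
    Percentile90 = q[5],
    Maximum = max(x),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(inner)) mean(abs(inner - mean(inner))) else 0,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (sdev > 0) mean((x - mu)^3) / sdev^3 else 0,
    Kurtosis = if (sdev > 0) mean((x - mu)^4) / sdev^4 else 0,
    Variance = pop_var(x),
    Uniformity = sum(p^2))
}

glcm_features <- function(P) {
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  if (sum(P) == 0) return(stats::setNames(rep(0, 22), glcm_feature_names()))
  px <- rowSums(P)
  mu_x <- sum(seq_len(ng) * px)
  sd_x <- sqrt(sum((seq_len(ng) - mu_x)^2 * px))
  ## symmetric matrix: x and y marginals coincide
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(P[i + j == k]), numeric(1))
  k_diff <- 0:(ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  DA <- sum(k_diff * p_diff)
  HXY <- -sum(xlog2(P))
  pxy <- px[i] * px[j]
  HXY1 <- -sum(ifelse(pxy > 0, P * log2(pxy), 0))
  HXY2 <- -sum(xlog2(pxy))
  HX <- -sum(xlog2(px))
  corr <- if (sd_x > 0) (sum(i * j * P) - mu_x^2) / sd_x^2 else 1
  imc1 <- if (HX > 0) (HXY - HXY1) / HX else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY))))
  od <- abs(i - j) > 0
  stats::setNames(c(
    sum(i * j * P),                                   # Autocorrelation
    mu_x,                                             # JointAverage
    sum((i + j - 2 * mu_x)^4 * P),                    # ClusterProminence
    sum((i + j - 2 * mu_x)^3 * P),                    # ClusterShade
    sum((i + j - 2 * mu_x)^2 * P),                    # ClusterTendency
    sum((i - j)^2 * P),                               # Contrast
    corr,                                             # Correlation
    DA,                                               # DifferenceAverage
    -sum(xlog2(p_diff)),                              # DifferenceEntropy
    sum((k_diff - DA)^2 * p_diff),                    # DifferenceVariance
    sum(P^2),                                         # JointEnergy
    HXY,                                              # JointEntropy
    imc1,                                             # Imc1
    imc2,                                             # Imc2
    sum(P / (1 + (i - j)^2)),                         # Idm
    sum(P / (1 + ((i - j) / ng)^2)),                  # Idmn
    sum(P / (1 + abs(i - j))),                        # Id
    sum(P / (1 + abs(i - j) / ng)),                   # Idn
    sum(P[od] / (i[od] - j[od])^2),                   # InverseVariance
    max(P),                                           # MaximumProbability
    -sum(xlog2(p_sum)),                               # SumEntropy
    sum((i - mu_x)^2 * P)                             # SumSquares
  ), glcm_feature_names())
}

glcm_feature_names <- function() c(
  "Autocorrelation", "JointAverage", "ClusterProminence", "ClusterShade",
  "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
  "DifferenceEntropy", "DifferenceVariance", "JointEnergy", "JointEntropy",
  "Imc1", "Imc2", "Idm", "Idmn", "Id", "Idn", "InverseVariance",
  "MaximumProbability", "SumEntropy", "SumSquares")

## Shared run-length / size-zone style statistics: M[level, size] counts.
rl_style_features <- function(M, n_voxels, names_out,
                              extra_denominator = 1) {
  Nr <- sum(M)
  if (Nr == 0) return(stats::setNames(rep(0, length(names_out)), names_out))
  i <- row(M); l <- col(M)
  p <- M / Nr
  ri <- rowSums(M)  # per grey level
  rl <- colSums(M)  # per size
  mu_i <- sum(i * p)
  mu_l <- sum(l * p)
  vals <- c(
    sum(M / col(M)^2) / Nr,                 # small emphasis
    sum(M * col(M)^2) / Nr,                 # large emphasis
    sum(ri^2) / Nr,                         # grey-level non-uniformity
    sum(ri^2) / Nr^2,                       # ... normalized
    sum(rl^2) / Nr,                         # size non-uniformity
    sum(rl^2) / Nr^2,                       # ... normalized
    Nr / (n_voxels * extra_denominator),    # percentage
    sum((i - mu_i)^2 * p),                  # grey-level variance
    sum((l - mu_l)^2 * p),                  # size variance
    -sum(xlog2(p)),                         # entropy
    sum(M / row(M)^2) / Nr,                 # low grey-level emphasis
    sum(M * row(M)^2) / Nr,                 # high grey-level emphasis
    sum(M / (row(M)^2 * col(M)^2)) / Nr,    # small + low
    sum(M * row(M)^2 / col(M)^2) / Nr,      # small + high
    sum(M * col(M)^2 / row(M)^2) / Nr,      # large + low
    sum(M * row(M)^2 * col(M)^2) / Nr)      # large + high
  stats::setNames(vals, names_out)
}

glrlm_feature_names <- function() c(
  "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage",
  "GrayLevelVariance", "RunVariance", "RunEntropy",
  "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
  "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
  "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")

glszm_feature_names <- function() c(
  "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage",
  "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
  "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
  "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
  "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")

gldm_features <- function(D, n_voxels) {
  names_out <- gldm_feature_names()
  Nd <- sum(D)
  if (Nd == 0) return(stats::setNames(rep(0, 14), names_out))
  i <- row(D); k <- col(D)
  p <- D / Nd
  di <- rowSums(D)
  dk <- colSums(D)
  mu_i <- sum(i * p)
  mu_k <- sum(k * p)
  stats::setNames(c(
    sum(D / col(D)^2) / Nd,
    sum(D * col(D)^2) / Nd,
    sum(di^2) / Nd,
    sum(dk^2) / Nd,
    sum(dk^2) / Nd^2,
    sum((i - mu_i)^2 * p),
    sum((k - mu_k)^2 * p),
    -sum(xlog2(p)),
    sum(D / row(D)^2) / Nd,
    sum(D * row(D)^2) / Nd,
    sum(D / (row(D)^2 * col(D)^2)) / Nd,
    sum(D * row(D)^2 / col(D)^2) / Nd,
    sum(D * col(D)^2 / row(D)^2) / Nd,
    sum(D * row(D)^2 * col(D)^2) / Nd), names_out)
}

gldm_feature_names <- function() c(
  "SmallDependenceEmphasis", "LargeDependenceEmphasis",
  "GrayLevelNonUniformity", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "GrayLevelVariance",
  "DependenceVariance", "DependenceEntropy",
  "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
  "SmallDependenceLowGrayLevelEmphasis",
  "SmallDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis",
  "LargeDependenceHighGrayLevelEmphasis")

ngtdm_features <- function(tab, n_voxels) {
  names_out <- c("Coarseness", "Contrast", "Busyness", "Complexity",
                 "Strength")
  nz <- tab$p > 0
  if (!any(nz)) return(stats::setNames(rep(0, 5), names_out))
  i <- tab$level[nz]; p <- tab$p[nz]; s <- tab$s[nz]
  ngp <- sum(nz)
  ps <- sum(p * s)
  coarseness <- if (ps > 0) 1 / ps else 1e6
  if (ngp > 1) {
    ii <- outer(i, i, function(a, b) (a - b)^2)
    pp <- outer(p, p)
    contrast <- sum(pp * ii) / (ngp * (ngp - 1)) * sum(s) / n_voxels
  } else contrast <- 0
  denom_b <- sum(abs(outer(i * p, i * p, "-")))
  busyness <- if (denom_b > 0) ps / denom_b else 0
  ## complexity and strength over nonzero-probability level pairs
  absdiff <- abs(outer(i, i, "-"))
  psum <- outer(p, p, "+")
  s_i <- s
  cross <- outer(p * s_i, rep(1, ngp)) + outer(rep(1, ngp), p * s_i)
  complexity <- sum(absdiff * cross / psum) / n_voxels
  strength <- if (sum(s) > 0) sum(psum * (outer(i, i, "-"))^2) / sum(s) else 0
  stats::setNames(c(coarseness, contrast, busyness, complexity, strength),
                  names_out)
}

shape_features <- function(mask, spacing) {
  idx <- which(mask != 0)
  nd <- dim(mask)
  n <- length(idx)
  voxvol <- prod(spacing)
  V <- n * voxvol
  ## surface area from exposed faces
  A <- 0
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  for (axis in 1:3) {
    for (sgn in c(-1L, 1L)) {
      nb <- shift_axis(mask, axis, sgn)
      ## at the array edge shift replicates; treat outside as background
      edge <- array(FALSE, nd)
      if (sgn == 1L) {
        if (axis == 1) edge[nd[1], , ] <- TRUE
        if (axis == 2) edge[, nd[2], ] <- TRUE
        if (axis == 3) edge[, , nd[3]] <- TRUE
      } else {
        if (axis == 1) edge[1, , ] <- TRUE
        if (axis == 2) edge[, 1, ] <- TRUE
        if (axis == 3) edge[, , 1] <- TRUE
      }
      exposed <- (mask != 0) & ((nb == 0) | edge)
      A <- A + sum(exposed) * face_area[axis]
    }
  }
  sphericity <- if (A > 0) (36 * pi * V^2)^(1 / 3) / A else 0
  ## surface voxels in world coordinates
  co <- arrayInd(idx, nd)
  wc <- sweep(co - 1, 2, spacing, "*")
  interior <- rep(TRUE, n)
  surf_sel <- surface_voxels(mask)
  ws <- sweep(arrayInd(surf_sel, nd) - 1, 2, spacing, "*")
  if (nrow(ws) > 1500) ws <- ws[seq(1, nrow(ws), length.out = 1500), ]
  d3 <- max_pairwise_dist(ws)
  d_slice <- max_planar_diameter(ws, drop_axis = 3)
  d_col <- max_planar_diameter(ws, drop_axis = 2)
  d_row <- max_planar_diameter(ws, drop_axis = 1)
  ## principal axes from the voxel-centre covariance
  if (n > 1) {
    ev <- sort(eigen(stats::cov(wc), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev[ev < 0] <- 0
  } else ev <- c(0, 0, 0)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2]); least <- 4 * sqrt(ev[3])
  bbox <- apply(co, 2, function(v) diff(range(v)) + 1)
  extent <- n / prod(bbox)
  c(VoxelVolume = V,
    SurfaceArea = A,
    SurfaceVolumeRatio = if (V > 0) A / V else 0,
    Sphericity = sphericity,
    Maximum3DDiameter = d3,
    Maximum2DDiameterSlice = d_slice,
    Maximum2DDiameterColumn = d_col,
    Maximum2DDiameterRow = d_row,
    MajorAxisLength = major,
    MinorAxisLength = minor,
    LeastAxisLength = least,
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0,
    Extent = extent)
}

surface_voxels <- function(mask) {
  nd <- dim(mask)
  exposed <- array(FALSE, nd)
  for (axis in 1:3) {
    for (sgn in c(-1L, 1L)) {
      nb <- shift_axis(mask, axis, sgn)
      edge <- array(FALSE, nd)
      if (sgn == 1L) {
        if (axis == 1) edge[nd[1], , ] <- TRUE
        if (axis == 2) edge[, nd[2], ] <- TRUE
        if (axis == 3) edge[, , nd[3]] <- TRUE
      } else {
        if (axis == 1) edge[1, , ] <- TRUE
        if (axis == 2) edge[, 1, ] <- TRUE
        if (axis == 3) edge[, , 1] <- TRUE
      }
      exposed <- exposed | ((mask != 0) & ((nb == 0) | edge))
    }
  }
  which(exposed)
}

max_pairwise_dist <- function(pts) {
  if (nrow(pts) < 2) return(0)
  max(stats::dist(pts))
}

max_planar_diameter <- function(pts, drop_axis) {
  if (nrow(pts) < 2) return(0)
  keep <- setdiff(1:3, drop_axis)
  group <- pts[, drop_axis]
  best <- 0
  for (g in unique(group)) {
    sub <- pts[group == g, keep, drop = FALSE]
    if (nrow(sub) >= 2) best <- max(best, max(stats::dist(sub)))
  }
  best
}
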