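# Texture matrix construction on discretized 3D regions. All builders take
# a 3D integer "levels" array (NA outside the region) cropped to a bounding
# box, and use the 13 unique directions of the 26-neighbourhood
# (Chebyshev distance 1), aggregating by direction merging.

## Linear indices of (src, dst) voxel pairs one step apart along direction
## d within the box; both ends anywhere in the box.
pair_indices <- function(nd, d) {
  xs <- seq_len(nd[1] - abs(d[1])) + max(0, -d[1])
  ys <- seq_len(nd[2] - abs(d[2])) + max(0, -d[2])
  zs <- seq_len(nd[3] - abs(d[3])) + max(0, -d[3])
  if (!length(xs) || !length(ys) || !length(zs)) return(NULL)
  src <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dst <- sweep(src, 2, d, "+")
  lin <- function(m) (m[, 3] - 1) * nd[1] * nd[2] + (m[, 2] - 1) * nd[1] + m[, 1]
  cbind(lin(src), lin(dst))
}

#' Grey-level co-occurrence matrix of a discretized region
#'
#' Symmetric, direction-merged GLCM at Chebyshev distance 1 (13 unique 3D
#' directions, each pair counted in both orders), normalized to sum 1.
#' Only pairs with both ends inside the region are counted.
#'
#' @param levels 3D integer array of bin indices, \code{NA} outside the
#'   region.
#' @param n_levels Number of grey levels (matrix dimension).
#' @param directions Integer matrix of direction offsets (rows), default
#'   the 13 unique 26-neighbourhood directions.
#' @return \code{n_levels x n_levels} matrix summing to 1 (all zeros if the
#'   region has no valid pairs).
#' @export
glcm_matrix <- function(levels, n_levels = max(levels, na.rm = TRUE),
                        directions = DIRECTIONS_3D) {
  nd <- dim(levels)
  acc <- matrix(0, n_levels, n_levels)
  for (r in seq_len(nrow(directions))) {
    pr <- pair_indices(nd, directions[r, ])
    if (is.null(pr)) next
    a <- levels[pr[, 1]]
    b <- levels[pr[, 2]]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    code <- a[ok] + (b[ok] - 1L) * n_levels
    cnt <- tabulate(code, nbins = n_levels * n_levels)
    acc <- acc + matrix(cnt, n_levels, n_levels)
  }
  acc <- acc + t(acc)
  s <- sum(acc)
  if (s > 0) acc / s else acc
}

## Run-length matrix R[level, run_length], merged over the 13 directions.
glrlm_matrix <- function(levels, n_levels = max(levels, na.rm = TRUE),
                         directions = DIRECTIONS_3D) {
  nd <- dim(levels)
  nvox <- prod(nd)
  coords <- arrayInd(seq_len(nvox), nd)
  vals <- as.integer(levels)
  max_run <- max(nd)
  ## upper bound on run length along any direction
  acc <- matrix(0, n_levels, sum(nd))
  for (r in seq_len(nrow(directions))) {
    d <- directions[r, ]
    ## steps back to the line start for each voxel
    s <- rep(Inf, nvox)
    for (k in 1:3) {
      if (d[k] > 0) s <- pmin(s, coords[, k] - 1)
      else if (d[k] < 0) s <- pmin(s, nd[k] - coords[, k])
    }
    start <- coords - s * matrix(d, nvox, 3, byrow = TRUE)
    key <- (start[, 3] - 1) * nd[1] * nd[2] + (start[, 2] - 1) * nd[1] + start[, 1]
    o <- order(key, s)
    v <- vals[o]
    k2 <- key[o]
    ## new run at line change or value change (NA breaks runs)
    vprev <- c(NA_integer_, v[-nvox])
    kprev <- c(-1, k2[-nvox])
    newrun <- (k2 != kprev) | is.na(v) | is.na(vprev) | (v != vprev)
    newrun[is.na(newrun)] <- TRUE
    rid <- cumsum(newrun)
    rl <- tabulate(rid)
    rlev <- v[newrun]
    keep <- !is.na(rlev)
    if (!any(keep)) next
    code <- rlev[keep] + (rl[keep] - 1L) * n_levels
    cnt <- tabulate(code, nbins = n_levels * ncol(acc))
    acc <- acc + matrix(cnt, n_levels, ncol(acc))
  }
  used <- which(colSums(acc) > 0)
  if (length(used)) acc[, seq_len(max(used)), drop = FALSE] else acc[, 1, drop = FALSE]
}

## Size-zone matrix Z[level, zone_size]: zones are 26-connected components
## of equal grey level (single matrix, no direction dependence).
glszm_matrix <- function(levels, n_levels = max(levels, na.rm = TRUE)) {
  nd <- dim(levels)
  in_region <- which(!is.na(levels))
  nv <- length(in_region)
  if (nv == 0) return(matrix(0, n_levels, 1))
  vid <- integer(prod(nd))
  vid[in_region] <- seq_len(nv)
  edges <- list()
  for (r in seq_len(nrow(DIRECTIONS_3D))) {
    pr <- pair_indices(nd, DIRECTIONS_3D[r, ])
    if (is.null(pr)) next
    a <- levels[pr[, 1]]
    b <- levels[pr[, 2]]
    ok <- !is.na(a) & !is.na(b) & a == b
    if (!any(ok)) next
    edges[[length(edges) + 1]] <- cbind(vid[pr[ok, 1]], vid[pr[ok, 2]])
  }
  if (length(edges)) {
    el <- do.call(rbind, edges)
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, nv - igraph::vcount(g)))
    comp <- igraph::components(g)
    zone_of <- comp$membership
  } else {
    zone_of <- seq_len(nv)
  }
  zsize <- tabulate(zone_of)
  zlev <- integer(length(zsize))
  zlev[zone_of] <- levels[in_region]
  code <- zlev + (zsize - 1L) * n_levels
  max_s <- max(zsize)
  cnt <- tabulate(code, nbins = n_levels * max_s)
  matrix(cnt, n_levels, max_s)
}

## Count, for every region voxel, its 26-neighbours inside the region and
## those with the same grey level; also neighbour value sums (for NGTDM).
neighbour_stats <- function(levels) {
  nd <- dim(levels)
  n_same <- array(0, nd)
  n_valid <- array(0, nd)
  v_sum <- array(0, nd)
  vals0 <- levels
  vals0[is.na(vals0)] <- 0
  inr <- !is.na(levels)
  for (r in seq_len(nrow(DIRECTIONS_3D))) {
    for (sgn in c(1L, -1L)) {
      d <- DIRECTIONS_3D[r, ] * sgn
      pr <- pair_indices(nd, d)
      if (is.null(pr)) next
      src <- pr[, 1]; dst <- pr[, 2]
      ok <- inr[src] & inr[dst]
      if (!any(ok)) next
      s <- src[ok]; t <- dst[ok]
      n_valid[s] <- n_valid[s] + 1
      v_sum[s] <- v_sum[s] + vals0[t]
      same <- levels[s] == levels[t]
      n_same[s] <- n_same[s] + as.numeric(same)
    }
  }
  list(n_same = n_same, n_valid = n_valid, v_sum = v_sum)
}

## Dependence matrix D[level, k]: k = 1 + number of 26-neighbours within
## the region having the same level (alpha = 0).
gldm_matrix <- function(levels, n_levels = max(levels, na.rm = TRUE),
                        stats = NULL) {
  if (is.null(stats)) stats <- neighbour_stats(levels)
  inr <- !is.na(levels)
  dep <- stats$n_same[inr] + 1
  lev <- levels[inr]
  max_d <- max(dep)
  cnt <- tabulate(lev + (dep - 1) * n_levels, nbins = n_levels * max_d)
  matrix(cnt, n_levels, max_d)
}

## NGTDM per-level table: n_i, p_i and s_i = sum over voxels of level i of
## |i - mean(valid neighbour levels)|. Voxels with no valid neighbours are
## excluded from s_i (their neighbourhood tone is undefined).
ngtdm_table <- function(levels, n_levels = max(levels, na.rm = TRUE),
                        stats = NULL) {
  if (is.null(stats)) stats <- neighbour_stats(levels)
  inr <- !is.na(levels)
  lev <- levels[inr]
  nvld <- stats$n_valid[inr]
  vsum <- stats$v_sum[inr]
  nb_mean <- ifelse(nvld > 0, vsum / nvld, NA_real_)
  dev <- abs(lev - nb_mean)
  n_i <- tabulate(lev, nbins = n_levels)
  s_i <- numeric(n_levels)
  ok <- !is.na(dev)
  if (any(ok)) {
    s_i <- as.numeric(tapply(dev[ok], factor(lev[ok], levels = seq_len(n_levels)),
                             sum))
    s_i[is.na(s_i)] <- 0
  }
  data.frame(level = seq_len(n_levels), n = n_i, p = n_i / sum(n_i), s = s_i)
}
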