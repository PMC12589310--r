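# Fixtures built in code: tiny deterministic volumes and a small phantom
# configuration reused across tests.

## A pair whose VOI holds an x-aligned linear PET ramp and constant CT.
ramp_pair <- function(n = c(12L, 8L, 6L), spacing = c(1, 1, 1)) {
  pet <- array(0, n)
  for (x in seq_len(n[1])) pet[x, , ] <- x - 1
  ct <- pet * 3 - 10
  mask <- array(0L, n)
  mask[3:(n[1] - 2), 2:(n[2] - 1), 2:(n[3] - 1)] <- 1L
  volume_pair(pet, ct, mask, spacing = spacing)
}

## Small, fast phantom config (desk-scale grid).
small_phantom <- function(n_subjects = 2, seed = 1, ...) {
  phantom_config(n_subjects = n_subjects,
                 grid_dim = c(28L, 28L, 18L),
                 radius_range = c(5, 8),
                 seed = seed, ...)
}

## Independent brute-force Otsu: exhaustive split search using class means
## computed directly from the histogram.
brute_otsu_bin <- function(values, n_bins = 128L) {
  rng <- range(values)
  bw <- diff(rng) / n_bins
  bin <- pmin(pmax(floor((values - rng[1]) / bw) + 1, 1), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) * bw
  best <- NA_integer_
  best_v <- -Inf
  for (t in seq_len(n_bins - 1)) {
    n0 <- sum(counts[1:t]); n1 <- sum(counts) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:t] * mids[1:t]) / n0
    mu1 <- sum(counts[(t + 1):n_bins] * mids[(t + 1):n_bins]) / n1
    w0 <- n0 / sum(counts); w1 <- 1 - w0
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best_v + 1e-15) { best_v <- v; best <- t }
  }
  best
}

## Exact two-sided Mann-Whitney p by full enumeration of label
## assignments (distinct values, no ties).
enum_mwu_p <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  combs <- utils::combn(m + n, m)
  u_all <- apply(combs, 2, function(ix) {
    xs <- pooled[ix]; ys <- pooled[-ix]
    sum(outer(xs, ys, ">"))
  })
  u_obs <- sum(outer(x, y, ">"))
  mid <- m * n / 2
  p <- if (u_obs > mid) mean(u_all >= u_obs) else mean(u_all <= u_obs)
  min(2 * p, 1)
}

## Brute-force step-up BH adjustment.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

## All-pairs AUC with half credit for ties.
brute_auc <- function(scores, labels) {
  y <- as.logical(labels)
  sp <- scores[y]; sn <- scores[!y]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
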