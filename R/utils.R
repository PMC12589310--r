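# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Derive a reproducible 31-bit substream seed from a parent seed and an index.
## Subject-level streams must not depend on cohort size, so each subject gets
## an independent seed computed arithmetically from (seed, index).
substream_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271 + as.double(index) * 69621 + 11) %% 2147483647
  as.integer(x)
}

stop_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

## Coordinates (mm) of voxel centres: world = origin + index * spacing,
## 0-based indices (fixed package-wide convention).
axis_coords <- function(n, spacing, origin) {
  origin + (seq_len(n) - 1) * spacing
}

## log2 with 0 * log(0) = 0, for entropy sums.
xlog2 <- function(p) {
  out <- numeric(length(p))
  nz <- p > 0
  out[nz] <- p[nz] * log2(p[nz])
  out
}

## Population variance / SD (denominator n).
pop_var <- function(x) mean((x - mean(x))^2)
pop_sd <- function(x) sqrt(pop_var(x))

## 13 unique 3D direction offsets covering the 26-neighbourhood half-space.
DIRECTIONS_3D <- matrix(c(
  1, 0, 0,
  0, 1, 0,
  0, 0, 1,
  1, 1, 0,
  1, -1, 0,
  1, 0, 1,
  1, 0, -1,
  0, 1, 1,
  0, 1, -1,
  1, 1, 1,
  1, 1, -1,
  1, -1, 1,
  1, -1, -1), ncol = 3, byrow = TRUE)
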