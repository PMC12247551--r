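# Shared independent oracles and small fixture builders.

# Standardize a vector to zero mean, unit Euclidean norm.
std_vec <- function(x) {
  x <- x - mean(x)
  x / sqrt(sum(x^2))
}

# Inertia of a fixed 2-partition under correlation distance, using the
# optimal (re-standardized mean) centroid for each part. Written against the
# definition, independently of the package's Lloyd implementation.
partition_inertia_2 <- function(xs, idx) {
  tot <- 0
  for (g in 0:1) {
    cols <- which(idx == g)
    if (!length(cols)) return(Inf)
    m <- rowMeans(xs[, cols, drop = FALSE])
    m <- m - mean(m)
    nrm <- sqrt(sum(m^2))
    if (nrm == 0) {
      tot <- tot + length(cols)
    } else {
      tot <- tot + sum(1 - crossprod(m / nrm, xs[, cols, drop = FALSE]))
    }
  }
  tot
}

# Global-minimum inertia over all 2-partitions by exhaustive enumeration.
enumerate_best_inertia_2 <- function(x) {
  xs <- apply(x, 2, std_vec)
  n <- ncol(x)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    idx <- as.integer(intToBits(code))[1:n]
    best <- min(best, partition_inertia_2(xs, idx))
  }
  best
}

# Proportion of pooled volumes whose cluster label matches the planted label
# after greedy state matching.
label_agreement <- function(truth, est, k) {
  tab <- table(factor(truth, levels = 1:k), factor(est, levels = 1:k))
  perm <- apply(tab, 1, which.max)
  mean(est == perm[truth])
}

# A small box-shaped cluster of exactly `n` voxels near `at` (voxel coords).
place_cluster <- function(arr, at, n) {
  dm <- dim(arr)
  side <- ceiling(n^(1 / 3))
  coords <- as.matrix(expand.grid(0:(side), 0:(side), 0:(side)))
  coords <- coords[order(rowSums(coords^2)), , drop = FALSE][1:n, , drop = FALSE]
  idx <- sweep(coords, 2, at, `+`)
  stopifnot(all(idx >= 1), all(sweep(idx, 2, dm, `<=`)))
  arr[idx] <- 1L
  arr
}

# Compact default configs used across tests.
tiny_bold_config <- function(seed = 7, n = 40) {
  generator_config(n_participants = n, seed = seed, n_parcels = 60,
                   volumes_range = c(60L, 80L))
}
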