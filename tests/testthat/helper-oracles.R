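# Independent oracles and small fixture builders shared across tests.

# O(N^2) nearest-zero-pixel search: the reference for the Euclidean
# distance transform.
brute_force_edt <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  bg <- which(!mask, arr.ind = TRUE)
  out <- matrix(0, H, W)
  if (nrow(bg) == 0) return(matrix(Inf, H, W))
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      if (mask[i, j])
        out[i, j] <- sqrt(min((bg[, 1] - i)^2 + (bg[, 2] - j)^2))
    }
  }
  out
}

# exhaustive 8-connected local-maxima search on a small raster (strict
# maxima only; used on rasters built without plateaus)
brute_force_peaks <- function(dmap, min_height) {
  H <- nrow(dmap); W <- ncol(dmap)
  out <- NULL
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      v <- dmap[i, j]
      if (v < min_height || v <= 0) next
      nb <- c()
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
          nb <- c(nb, dmap[ii, jj])
      }
      if (all(v > nb)) out <- rbind(out, c(i, j))
    }
  }
  out
}

# binary mask of one or more discs on an H x W field
disc_mask <- function(H, W, centres, radius) {
  m <- matrix(FALSE, H, W)
  for (k in seq_len(nrow(centres))) {
    for (i in seq_len(H)) {
      for (j in seq_len(W)) {
        if ((i - centres[k, 1])^2 + (j - centres[k, 2])^2 <= radius^2)
          m[i, j] <- TRUE
      }
    }
  }
  m
}

# clean simulated field: well-separated nuclei, no debris
clean_sim_config <- function(seed, positive_fraction = 0.1, n_nuclei = 80) {
  simulation_config(n_nuclei = n_nuclei, positive_fraction = positive_fraction,
                    n_debris = 0, seed = seed)
}
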