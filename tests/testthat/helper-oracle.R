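# A random peak list over the standard window; intensities span several
# log-decades so some abundance coordinates fall outside [0, 1].
random_spectrum <- function(n, seed, sample_id = sprintf("rnd_%d", seed)) {
  set.seed(seed)
  spectrum(mz = runif(n, 150, 750),
           intensity = rlnorm(n, meanlog = 12, sdlog = 2),
           sample_id = sample_id)
}

# Brute-force featurization oracle: explicit per-peak loops over bin edges
# computed with seq(), and explicit triple loops for the normalisation and
# log transform. Kept deliberately independent of the package's vectorised
# code path.
featurize_oracle <- function(s, cfg = histogram_config()) {
  dims <- c(cfg$n_mz_bins, cfg$n_abund_bins, cfg$n_kmd_bins)
  counts <- array(0, dim = dims)
  p <- s$peaks
  locate <- function(v, edges) {
    nb <- length(edges) - 1
    for (b in seq_len(nb)) {
      top_ok <- if (b == nb) v <= edges[b + 1] else v < edges[b + 1]
      if (v >= edges[b] && top_ok) return(b)
    }
    NA_integer_
  }
  if (nrow(p)) {
    mean_log <- sum(log(p$intensity)) / nrow(p)
    e_mz <- seq(cfg$mz_range[1], cfg$mz_range[2], length.out = dims[1] + 1)
    e_y <- seq(0, 1, length.out = dims[2] + 1)
    e_k <- seq(cfg$kmd_range_mDa[1], cfg$kmd_range_mDa[2],
               length.out = dims[3] + 1)
    for (r in seq_len(nrow(p))) {
      km <- p$mz[r] * 14.00000 / 14.01565
      kmd <- (floor(km + 0.5) - km) * 1000
      y <- (log(p$intensity[r]) - mean_log + cfg$abund_offset) / cfg$abund_scale
      i <- locate(p$mz[r], e_mz)
      j <- locate(y, e_y)
      k <- locate(kmd, e_k)
      if (!is.na(i) && !is.na(j) && !is.na(k))
        counts[i, j, k] <- counts[i, j, k] + 1
    }
  }
  nrm <- array(0, dim = dims)
  for (j in seq_len(dims[2])) {
    for (k in seq_len(dims[3])) {
      tot <- 0
      for (i in seq_len(dims[1])) tot <- tot + counts[i, j, k]
      for (i in seq_len(dims[1]))
        nrm[i, j, k] <- counts[i, j, k] / (tot + cfg$eps)
    }
  }
  x <- cfg$log_gain * log(cfg$log_floor + nrm) + cfg$log_shift
  list(counts = counts, x = x)
}

# Four well-separated gaussian classes for classifier contract tests.
make_blobs <- function(n_per_class = 20, dim = 20, shift = 10, sd = 0.5,
                       seed = 1, classes = c("A", "B", "C", "D")) {
  set.seed(seed)
  rows <- list()
  labels <- character(0)
  for (ci in seq_along(classes)) {
    center <- rep(0, dim)
    center[ci] <- shift
    rows[[ci]] <- matrix(rnorm(n_per_class * dim, sd = sd), n_per_class, dim,
                         byrow = TRUE) + rep(center, each = n_per_class)
    labels <- c(labels, rep(classes[ci], n_per_class))
  }
  labeled_dataset(do.call(rbind, rows), labels)
}
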