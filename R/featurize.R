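#' Histogram configuration for feature images
#'
#' All binning ranges, bin counts and transform constants used to turn a
#' peak list into a mass x log-abundance x KMD histogram image. Defaults
#' give the standard 32 x 32 x 5 geometry: 32 mass bins of width 18.75 Da
#' over m/z 150-750, 32 abundance bins over the unit interval of
#' `y = (ln a - <ln a> + abund_offset) / abund_scale`, and 5 KMD bins of
#' width 200 mDa over (-500, 500]. The abundance constants (0.5, 9.2) place
#' both the strongest peaks and the instrument noise floor inside [0, 1];
#' subtracting the mean log intensity calibrates between samples. After
#' counting, each (abundance, KMD) column is normalised across the mass
#' bins, `N = n / (sum_i n + eps)`, and compressed by the truncated log
#' transform `X = log_gain * ln(log_floor + N) + log_shift`, which at the
#' default constants maps all values into approximately [0.0987, 1.2977].
#'
#' @param mz_range numeric length-2, mass axis range (Da).
#' @param n_mz_bins,n_abund_bins,n_kmd_bins bin counts per axis.
#' @param kmd_range_mDa numeric length-2, KMD axis range (mDa).
#' @param abund_offset,abund_scale abundance-coordinate constants.
#' @param eps stabiliser added to the per-column count total before dividing.
#' @param log_floor,log_gain,log_shift truncated-log-transform constants.
#' @param clip if `TRUE`, abundance coordinates outside [0, 1] are clipped
#'   to the range instead of dropped (sensitivity analysis; default drops).
#' @return An object of class `"histogram_config"`.
#' @export
histogram_config <- function(mz_range = c(150, 750),
                             n_mz_bins = 32L,
                             n_abund_bins = 32L,
                             kmd_range_mDa = c(-500, 500),
                             n_kmd_bins = 5L,
                             abund_offset = 0.5,
                             abund_scale = 9.2,
                             eps = 1e-8,
                             log_floor = 0.1,
                             log_gain = 0.5,
                             log_shift = 1.25,
                             clip = FALSE) {
  cfg <- list(mz_range = as.numeric(mz_range),
              n_mz_bins = as.integer(n_mz_bins),
              n_abund_bins = as.integer(n_abund_bins),
              kmd_range_mDa = as.numeric(kmd_range_mDa),
              n_kmd_bins = as.integer(n_kmd_bins),
              abund_offset = abund_offset, abund_scale = abund_scale,
              eps = eps, log_floor = log_floor, log_gain = log_gain,
              log_shift = log_shift, clip = isTRUE(clip))
  with(cfg, {
    stopifnot(n_mz_bins >= 1, n_abund_bins >= 1, n_kmd_bins >= 1,
              mz_range[1] < mz_range[2], kmd_range_mDa[1] < kmd_range_mDa[2],
              abund_scale > 0, log_floor > 0, eps >= 0)
  })
  structure(cfg, class = "histogram_config")
}

#' @export
print.histogram_config <- function(x, ...) {
  cat(sprintf("<histogram_config> %d x %d x %d (mass x abundance x KMD)\n",
              x$n_mz_bins, x$n_abund_bins, x$n_kmd_bins))
  cat(sprintf("  m/z [%g, %g] (bin width %g Da), KMD [%g, %g] mDa\n",
              x$mz_range[1], x$mz_range[2],
              diff(x$mz_range) / x$n_mz_bins,
              x$kmd_range_mDa[1], x$kmd_range_mDa[2]))
  invisible(x)
}

# Theoretical output range of the truncated log transform for N in [0, 1].
.x_range <- function(cfg) {
  cfg$log_gain * log(cfg$log_floor + c(0, 1)) + cfg$log_shift
}

#' Abundance coordinate of a peak intensity
#'
#' `y = (ln(intensity) - mean_log + abund_offset) / abund_scale`, natural
#' logarithm. Values in [0, 1] land on the abundance axis; others are
#' dropped (or clipped when the configuration says so).
#'
#' @param intensity positive peak intensity (or vector).
#' @param mean_log mean of natural-log intensities of the spectrum the peak
#'   belongs to.
#' @param cfg a [histogram_config()].
#' @return Numeric abundance coordinate(s).
#' @export
abundance_coordinate <- function(intensity, mean_log, cfg = histogram_config()) {
  if (any(intensity <= 0)) stop("intensity must be positive")
  (log(intensity) - mean_log + cfg$abund_offset) / cfg$abund_scale
}

# Half-open bin index on [lo, hi): floor((v-lo)/w) + 1, with the final bin
# closed at the top. Out-of-range values return NA.
.bin_index <- function(v, lo, hi, n) {
  w <- (hi - lo) / n
  idx <- floor((v - lo) / w) + 1
  idx[v == hi] <- n
  idx[idx < 1 | idx > n] <- NA_integer_
  as.integer(idx)
}

#' Raw 3D histogram counts for a spectrum
#'
#' Maps each peak of an already-filtered spectrum to a (mass bin, abundance
#' bin, KMD bin) cell and counts. The abundance reference `mean_log` is the
#' arithmetic mean of natural-log intensities over the peaks of `s` itself,
#' so each feature image is self-calibrated. Peaks whose abundance
#' coordinate falls outside [0, 1] are dropped (default) or clipped. All
#' bins are half-open `[lo, hi)` with the final bin closed.
#'
#' @param s a [spectrum()], already filtered to the m/z window.
#' @param cfg a [histogram_config()].
#' @return Integer array of dim `c(n_mz_bins, n_abund_bins, n_kmd_bins)`
#'   with attributes `n_used` (peaks counted) and `mean_log`.
#' @export
bin_counts <- function(s, cfg = histogram_config()) {
  stopifnot(inherits(s, "spectrum"), inherits(cfg, "histogram_config"))
  dims <- c(cfg$n_mz_bins, cfg$n_abund_bins, cfg$n_kmd_bins)
  counts <- array(0L, dim = dims)
  p <- s$peaks
  if (!nrow(p)) {
    attr(counts, "n_used") <- 0L
    attr(counts, "mean_log") <- NA_real_
    return(counts)
  }
  mean_log <- mean(log(p$intensity))
  y <- abundance_coordinate(p$intensity, mean_log, cfg)
  if (cfg$clip) y <- pmin(pmax(y, 0), 1)
  kmd <- compute_kendrick(p$mz)$kmd_mDa
  i <- .bin_index(p$mz, cfg$mz_range[1], cfg$mz_range[2], cfg$n_mz_bins)
  j <- .bin_index(y, 0, 1, cfg$n_abund_bins)
  k <- .bin_index(kmd, cfg$kmd_range_mDa[1], cfg$kmd_range_mDa[2], cfg$n_kmd_bins)
  ok <- !is.na(i) & !is.na(j) & !is.na(k)
  cell <- (k[ok] - 1L) * dims[1] * dims[2] + (j[ok] - 1L) * dims[1] + i[ok]
  tab <- tabulate(cell, nbins = prod(dims))
  counts[] <- as.integer(tab)
  attr(counts, "n_used") <- sum(ok)
  attr(counts, "mean_log") <- mean_log
  counts
}

#' Normalise histogram counts over the mass axis
#'
#' For each fixed (abundance, KMD) column, divides the counts by the column
#' total over the mass bins plus a small stabiliser:
#' `N_ijk = n_ijk / (sum_i n_ijk + eps)`. Empty columns stay zero.
#'
#' @param counts integer array from [bin_counts()].
#' @param cfg a [histogram_config()].
#' @return Real array of the same dimensions.
#' @export
normalize_counts <- function(counts, cfg = histogram_config()) {
  dims <- c(cfg$n_mz_bins, cfg$n_abund_bins, cfg$n_kmd_bins)
  if (!identical(dim(counts), as.integer(dims)))
    stop("counts dimensions do not match the configuration")
  totals <- apply(counts, c(2, 3), sum)
  denom <- aperm(array(totals + cfg$eps, dim = dims[c(2, 3, 1)]), c(3, 1, 2))
  out <- counts / denom
  attributes(out) <- list(dim = dim(out))
  out
}

#' Truncated log transform of normalised histogram values
#'
#' `X = log_gain * ln(log_floor + N) + log_shift` (natural logarithm),
#' mapping N in [0, 1] into approximately [0.0987, 1.2977] at the default
#' constants. Strictly increasing in N.
#'
#' @param n_norm normalised values in [0, 1] (array or vector).
#' @param cfg a [histogram_config()].
#' @return Transformed values, same shape.
#' @export
log_transform <- function(n_norm, cfg = histogram_config()) {
  if (any(n_norm < 0 | n_norm > 1)) stop("normalised values must lie in [0, 1]")
  cfg$log_gain * log(cfg$log_floor + n_norm) + cfg$log_shift
}

#' Featurize a spectrum into a histogram image
#'
#' Composes [bin_counts()], [normalize_counts()] and [log_transform()] into
#' the full feature image for one (sample, parity) data point. Deterministic
#' for a fixed input; an empty spectrum yields the constant floor image.
#' Multiplying all intensities by a constant leaves the image unchanged (the
#' mean-log subtraction cancels the shift).
#'
#' @param s a filtered [spectrum()] with parity assigned.
#' @param cfg a [histogram_config()].
#' @return An object of class `"feature_image"`: list with `sample_id`,
#'   `parity`, `counts` (integer array), `x` (transformed array),
#'   `n_peaks_used`, `mean_log` and `config`.
#' @export
featurize_spectrum <- function(s, cfg = histogram_config()) {
  counts <- bin_counts(s, cfg)
  x <- log_transform(normalize_counts(counts, cfg), cfg)
  structure(list(sample_id = s$sample_id,
                 parity = s$parity,
                 label = s$label,
                 counts = counts,
                 x = x,
                 n_peaks_used = attr(counts, "n_used"),
                 mean_log = attr(counts, "mean_log"),
                 config = cfg),
            class = "feature_image")
}

#' @export
print.feature_image <- function(x, ...) {
  cat(sprintf("<feature_image> %s (%s)  %d x %d x %d, %d peaks used\n",
              x$sample_id, x$parity, dim(x$x)[1], dim(x$x)[2], dim(x$x)[3],
              x$n_peaks_used))
  invisible(x)
}

#' Flatten a feature image to a vector
#'
#' Fixed axis order: mass-major, then abundance, then KMD — element
#' `((i-1) * n_abund + (j-1)) * n_kmd + k` of the output is cell
#' `(i, j, k)` of the tensor. The order is a coordinate permutation (it does
#' not affect PCA) but is kept stable for reproducibility.
#' [unflatten_image()] is its exact inverse.
#'
#' @param img a `"feature_image"` or a bare 3D array.
#' @return Numeric vector of length `n_mz * n_abund * n_kmd` (5120 at the
#'   default geometry).
#' @export
flatten_image <- function(img) {
  x <- if (inherits(img, "feature_image")) img$x else img
  stopifnot(length(dim(x)) == 3)
  as.vector(aperm(x, c(3, 2, 1)))
}

#' @rdname flatten_image
#' @param v numeric vector produced by [flatten_image()].
#' @param cfg the [histogram_config()] defining the tensor shape.
#' @export
unflatten_image <- function(v, cfg = histogram_config()) {
  dims <- c(cfg$n_mz_bins, cfg$n_abund_bins, cfg$n_kmd_bins)
  if (length(v) != prod(dims)) stop("length does not match configuration")
  aperm(array(v, dim = dims[c(3, 2, 1)]), c(3, 2, 1))
}

#' Featurize a set of labelled spectra into a dataset
#'
#' The full front end of the classifier: each spectrum is filtered to the
#' m/z window and S/N threshold, optionally split by nominal-mass parity
#' (giving two data points per sample), featurized and flattened. Rows are
#' stacked into a feature matrix with class labels and sample groupings.
#'
#' @param spectra list of labelled [spectrum()] objects.
#' @param cfg a [histogram_config()].
#' @param mz_min,mz_max,snr_min filter settings (see [filter_peaks()]).
#' @param split if `TRUE` (default), split each spectrum by parity.
#' @return An object of class `"labeled_dataset"`: list with `features`
#'   (matrix, rows = data points), `labels` (factor), `groups` (sample ids),
#'   `parity` (character) and `config`.
#' @export
featurize_dataset <- function(spectra, cfg = histogram_config(),
                              mz_min = 150, mz_max = 750, snr_min = 2,
                              split = TRUE) {
  imgs <- list()
  for (s in spectra) {
    fs <- filter_peaks(s, mz_min, mz_max, snr_min)
    parts <- if (split) split_parity(fs) else list(fs)
    for (p in parts) imgs[[length(imgs) + 1L]] <- featurize_spectrum(p, cfg)
  }
  features <- do.call(rbind, lapply(imgs, flatten_image))
  structure(list(features = features,
                 labels = factor(vapply(imgs, `[[`, "", "label")),
                 groups = vapply(imgs, `[[`, "", "sample_id"),
                 parity = vapply(imgs, `[[`, "", "parity"),
                 config = cfg),
            class = "labeled_dataset")
}

#' Assemble a labelled dataset from a feature matrix
#'
#' Constructor for the container [featurize_dataset()] produces, for use
#' with externally computed feature vectors. Each sample id may appear at
#' most twice (its even and odd parity points).
#'
#' @param features numeric matrix, rows = data points.
#' @param labels class labels (coerced to factor), one per row.
#' @param groups sample id per row; defaults to one group per row.
#' @param parity optional parity marker per row.
#' @param cfg the [histogram_config()] the features correspond to.
#' @return An object of class `"labeled_dataset"`.
#' @export
labeled_dataset <- function(features, labels, groups = NULL, parity = NULL,
                            cfg = histogram_config()) {
  features <- as.matrix(features)
  labels <- factor(labels)
  if (length(labels) != nrow(features))
    stop("labels must match the number of feature rows")
  if (is.null(groups)) groups <- sprintf("pt_%d", seq_len(nrow(features)))
  if (length(groups) != nrow(features)) stop("groups length mismatch")
  if (any(table(groups) > 2))
    stop("each sample id may appear at most twice (even + odd parity)")
  if (is.null(parity)) parity <- rep(NA_character_, nrow(features))
  structure(list(features = features, labels = labels,
                 groups = as.character(groups), parity = parity,
                 config = cfg),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d data points x %d features\n",
              nrow(x$features), ncol(x$features)))
  print(table(x$labels))
  invisible(x)
}
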