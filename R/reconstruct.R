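#' Reconstruct a model feature image from PCA scores
#'
#' Inverts the PCA projection at a chosen coordinate: the training-mean
#' image plus `score_1` times the first component and `score_2` times the
#' second, reshaped to the histogram-image tensor. Reconstructions are raw
#' linear combinations — values may leave the transform's output range and
#' are not clipped here; [render_rgb()] clips for display only. With a
#' `scores` vector of length m, the first m components are used instead,
#' so a full-rank score vector of a training point reproduces that point.
#'
#' @param model a `"feature_pca"` (or `"biogen_fit"`, whose projection is
#'   used) with at least 2 fitted components.
#' @param score_1,score_2 coordinates along the first two components.
#' @param scores alternative to `score_1`/`score_2`: numeric vector of
#'   scores for the leading `length(scores)` components.
#' @param cfg the [histogram_config()] defining the tensor shape.
#' @return Numeric array of dim `c(n_mz, n_abund, n_kmd)`.
#' @export
reconstruct_image <- function(model, score_1 = 0, score_2 = 0,
                              scores = NULL, cfg = histogram_config()) {
  if (inherits(model, "biogen_fit")) model <- model$pca
  stopifnot(inherits(model, "feature_pca"))
  if (is.null(scores)) {
    if (model$n_components < 2)
      stop("model must have at least 2 components")
    scores <- c(score_1, score_2)
  }
  m <- length(scores)
  if (m > model$n_components)
    stop("more scores than fitted components")
  v <- model$center +
    drop(model$rotation[, seq_len(m), drop = FALSE] %*% scores)
  unflatten_image(v, cfg)
}

#' Grid of model images over the first two component extremes
#'
#' Builds an `n x n` grid of reconstructed model images spanning the
#' observed extremes of the first two component scores independently
#' (per-component min to max), the map-of-spectral-space view.
#'
#' @param model a `"feature_pca"` or `"biogen_fit"`.
#' @param observed_scores matrix of scores of the training points (columns
#'   1 and 2 used).
#' @param n grid side length (default 8, i.e. 64 panels).
#' @param cfg the [histogram_config()].
#' @return List with `pc1`, `pc2` (the grid coordinates) and `images`
#'   (n x n list matrix of arrays; rows index pc2 from high to low so the
#'   grid prints like a plot).
#' @export
reconstruct_grid <- function(model, observed_scores, n = 8,
                             cfg = histogram_config()) {
  s1 <- seq(min(observed_scores[, 1]), max(observed_scores[, 1]), length.out = n)
  s2 <- seq(min(observed_scores[, 2]), max(observed_scores[, 2]), length.out = n)
  images <- matrix(list(), n, n)
  for (r in seq_len(n)) {
    for (c in seq_len(n)) {
      images[[r, c]] <- reconstruct_image(model, s1[c], rev(s2)[r], cfg = cfg)
    }
  }
  list(pc1 = s1, pc2 = s2, images = images)
}

#' Render KMD slices of a feature image as an RGB raster
#'
#' Three KMD slices of the image become the red, green and blue channels,
#' each linearly rescaled from the transform's theoretical output range to
#' [0, 1] (clipped). Cells where the three slices agree render gray/white;
#' a slice that dominates shows as its channel colour. The default slices
#' are the field's "bins 2, 3 and 4" counted from zero, i.e. R indices
#' 3, 4, 5.
#'
#' @param img a `"feature_image"` or bare 3D array.
#' @param kmd_bins integer vector of three 1-based KMD slice indices
#'   (default `c(3, 4, 5)`).
#' @param cfg a [histogram_config()] (used for the value range; taken from
#'   `img` when it is a feature image).
#' @return Numeric array `n_mz x n_abund x 3` with values in [0, 1].
#' @export
render_rgb <- function(img, kmd_bins = c(3, 4, 5), cfg = NULL) {
  if (inherits(img, "feature_image")) {
    if (is.null(cfg)) cfg <- img$config
    img <- img$x
  }
  if (is.null(cfg)) cfg <- histogram_config()
  if (length(kmd_bins) != 3 || any(kmd_bins < 1 | kmd_bins > dim(img)[3]))
    stop("kmd_bins must be three indices within 1..", dim(img)[3])
  rng <- .x_range(cfg)
  scaled <- (img[, , kmd_bins, drop = FALSE] - rng[1]) / diff(rng)
  pmin(pmax(scaled, 0), 1)
}

#' @export
#' @rdname render_rgb
#' @param x a `"feature_image"` (plot method).
#' @param ... passed to [graphics::plot()].
plot.feature_image <- function(x, kmd_bins = c(3, 4, 5), ...) {
  rgb_arr <- render_rgb(x, kmd_bins)
  # raster rows run top to bottom: flip abundance so bin 1 sits at the bottom
  ras <- grDevices::rgb(t(rgb_arr[, rev(seq_len(dim(rgb_arr)[2])), 1]),
                        t(rgb_arr[, rev(seq_len(dim(rgb_arr)[2])), 2]),
                        t(rgb_arr[, rev(seq_len(dim(rgb_arr)[2])), 3]))
  dim(ras) <- c(dim(rgb_arr)[2], dim(rgb_arr)[1])
  plot(NA, xlim = x$config$mz_range, ylim = c(0, 1), xlab = "m/z",
       ylab = "binned log relative abundance",
       main = sprintf("%s (%s)", x$sample_id, x$parity), ...)
  rasterImage(ras, x$config$mz_range[1], 0, x$config$mz_range[2], 1,
              interpolate = FALSE)
  invisible(x)
}

#' Parse an elemental composition string
#'
#' Parses formulas like `"C16H32O2"` into element counts. By default only
#' the CHNOS alphabet is accepted; other elements raise an error unless
#' `allow_other = TRUE`.
#'
#' @param formula character vector of composition strings.
#' @param allow_other admit elements outside CHNOS (counts still returned
#'   for CHNOS only).
#' @return Matrix with one row per formula and columns C, H, N, O, S.
#' @export
parse_formula <- function(formula, allow_other = FALSE) {
  out <- matrix(0L, nrow = length(formula), ncol = 5,
                dimnames = list(formula, c("C", "H", "N", "O", "S")))
  for (i in seq_along(formula)) {
    f <- formula[i]
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    toks <- regmatches(f, list(m))[[1]]
    if (!length(toks) || sum(attr(m, "match.length")) != nchar(f))
      stop("cannot parse formula: ", f)
    for (t in toks) {
      el <- gsub("[0-9]", "", t)
      n <- gsub("[^0-9]", "", t)
      n <- if (nzchar(n)) as.integer(n) else 1L
      if (el %in% colnames(out)) {
        out[i, el] <- out[i, el] + n
      } else if (!allow_other) {
        stop("element outside CHNOS alphabet in ", f, ": ", el)
      }
    }
  }
  out
}

#' van Krevelen coordinates of assigned formulas
#'
#' Computes the H/C versus O/C atomic-ratio coordinates used to visualise
#' compound-class and maturation trends of assigned elemental compositions.
#'
#' @param formula character vector of compositions (CHNOS), or a matrix of
#'   element counts as returned by [parse_formula()].
#' @param intensity optional intensities carried through for marker
#'   weighting.
#' @return Data frame with columns `formula`, `oc` (O/C), `hc` (H/C) and
#'   `intensity`.
#' @examples
#' van_krevelen("C16H32O2")  # palmitic acid: O/C 0.125, H/C 2
#' @export
van_krevelen <- function(formula, intensity = NULL) {
  counts <- if (is.matrix(formula)) formula else parse_formula(formula)
  if (any(counts[, "C"] < 1))
    stop("formulas must contain at least one carbon")
  data.frame(formula = rownames(counts),
             oc = counts[, "O"] / counts[, "C"],
             hc = counts[, "H"] / counts[, "C"],
             intensity = if (is.null(intensity)) NA_real_ else intensity,
             row.names = NULL)
}
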