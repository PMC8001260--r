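#' Construct a spectrum object from peak data
#'
#' A spectrum is one sample's resolved peak list plus metadata. Peaks are
#' stored sorted ascending by m/z; duplicate m/z values are kept as distinct
#' peaks, never merged.
#'
#' @param mz numeric vector of measured mass-to-charge values (Da, singly
#'   charged assumed); must be positive.
#' @param intensity numeric vector of detector magnitudes (arbitrary units);
#'   must be positive.
#' @param snr optional numeric vector of signal-to-noise ratios (>= 0).
#' @param formula optional character vector of assigned elemental
#'   compositions (CHNOS convention); `NA` where unassigned.
#' @param sample_id opaque sample identifier.
#' @param label class label, one of `"Biological"`, `"Meteorite"`,
#'   `"Petroleum"`, `"Synthetic"`, or `NA` for unlabelled data.
#' @param parity `"all"`, `"even"` or `"odd"`: which nominal-mass parity
#'   subset this spectrum represents.
#' @return An object of class `"spectrum"`: a list with elements
#'   `sample_id`, `label`, `parity` and `peaks` (a data frame sorted
#'   ascending by `mz`).
#' @examples
#' s <- spectrum(c(200.2, 150.1), c(5, 10), sample_id = "demo")
#' s$peaks$mz  # sorted: 150.1, 200.2
#' @export
spectrum <- function(mz, intensity, snr = NULL, formula = NULL,
                     sample_id = "sample", label = NA_character_,
                     parity = c("all", "even", "odd")) {
  parity <- match.arg(parity)
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length")
  if (length(mz) && (anyNA(mz) || any(mz <= 0)))
    stop("all mz values must be positive and non-missing")
  if (length(intensity) && (anyNA(intensity) || any(intensity <= 0)))
    stop("all intensity values must be positive and non-missing")
  peaks <- data.frame(mz = mz, intensity = intensity)
  if (!is.null(snr)) {
    snr <- as.numeric(snr)
    if (length(snr) != length(mz)) stop("snr length mismatch")
    if (any(!is.na(snr) & snr < 0)) stop("snr must be non-negative")
    peaks$snr <- snr
  }
  if (!is.null(formula)) {
    if (length(formula) != length(mz)) stop("formula length mismatch")
    peaks$formula <- as.character(formula)
  }
  ord <- order(peaks$mz)  # stable sort: ties keep input order
  peaks <- peaks[ord, , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(sample_id = as.character(sample_id),
                 label = as.character(label),
                 parity = parity,
                 peaks = peaks),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s  label: %s  parity: %s  peaks: %d\n",
              x$sample_id, x$label, x$parity, nrow(x$peaks)))
  if (nrow(x$peaks)) {
    cat(sprintf("  m/z range: %.5f - %.5f\n",
                min(x$peaks$mz), max(x$peaks$mz)))
  }
  invisible(x)
}

#' Number of peaks in a spectrum
#' @param s a [spectrum()] object.
#' @return integer count.
#' @export
n_peaks <- function(s) nrow(s$peaks)

.detect_sep <- function(line) {
  if (lengths(regmatches(line, gregexpr("\t", line))) > 0) "\t" else ","
}

.is_number <- function(x) {
  suppressWarnings(!is.na(as.numeric(x)))
}

#' Read a delimited peak list
#'
#' Reads one sample's peak list from delimited text (comma or tab,
#' auto-detected from the first non-empty line). A header row is
#' auto-detected: if the first two fields of the first line are not both
#' numeric it is treated as a header and columns are mapped by name
#' (`mz`/`m.z`/`mass`, `intensity`/`abundance`, `snr`/`s.n`, `formula`);
#' without a header, columns are taken positionally as mz, intensity, snr,
#' formula. Malformed rows raise an error naming the offending line numbers.
#'
#' @param path path to the file.
#' @param sample_id sample identifier; defaults to the file name without
#'   extension.
#' @param label optional class label.
#' @return A [spectrum()] with peaks sorted ascending by m/z.
#' @seealso [write_peaklist()]
#' @export
read_peaklist <- function(path, sample_id = NULL, label = NA_character_) {
  if (!file.exists(path)) stop("peak-list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty peak-list file: ", path)
  sep <- .detect_sep(lines[[1]])
  fields <- strsplit(lines, sep, fixed = TRUE)
  fields <- lapply(fields, trimws)
  if (any(lengths(fields) < 2))
    stop("rows with fewer than two columns at line(s): ",
         paste(line_no[lengths(fields) < 2], collapse = ", "))

  first <- fields[[1]]
  has_header <- !(.is_number(first[[1]]) && .is_number(first[[2]]))
  if (has_header) {
    header <- tolower(gsub("[^a-z/]", "", tolower(first)))
    fields <- fields[-1]
    line_no <- line_no[-1]
    if (!length(fields)) stop("peak-list file has a header but no data rows: ", path)
    pick <- function(aliases) {
      i <- which(header %in% aliases)
      if (length(i)) i[[1]] else NA_integer_
    }
    col <- c(mz = pick(c("mz", "m/z", "mass")),
             intensity = pick(c("intensity", "abundance", "int")),
             snr = pick(c("snr", "s/n", "sn")),
             formula = pick("formula"))
    if (is.na(col[["mz"]]) || is.na(col[["intensity"]]))
      stop("header found but no mz/intensity columns recognised in: ", path)
  } else {
    col <- c(mz = 1L, intensity = 2L, snr = NA_integer_, formula = NA_integer_)
    wid <- min(lengths(fields))
    if (wid >= 3) col[["snr"]] <- 3L
    if (wid >= 4) col[["formula"]] <- 4L
  }

  # trailing empty fields are dropped by strsplit; treat them as blank
  get_col <- function(i) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else "", character(1))
  }
  mz_raw <- get_col(col[["mz"]])
  int_raw <- get_col(col[["intensity"]])
  bad <- !.is_number(mz_raw) | !.is_number(int_raw)
  if (any(bad))
    stop("non-numeric mz/intensity at line(s): ",
         paste(line_no[bad], collapse = ", "))
  snr <- NULL
  if (!is.na(col[["snr"]])) {
    snr_raw <- get_col(col[["snr"]])
    snr <- suppressWarnings(as.numeric(snr_raw))
  }
  formula <- if (!is.na(col[["formula"]])) get_col(col[["formula"]]) else NULL
  if (!is.null(formula)) formula[!nzchar(formula)] <- NA_character_
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  spectrum(as.numeric(mz_raw), as.numeric(int_raw), snr = snr,
           formula = formula, sample_id = sample_id, label = label)
}

#' Write a peak list as delimited text
#'
#' Numeric values are written with six decimal places, so a read/write round
#' trip preserves them to 1e-6. A header row is always written.
#'
#' @param s a [spectrum()].
#' @param path output file path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(s, path, sep = ",") {
  stopifnot(inherits(s, "spectrum"))
  p <- s$peaks
  cols <- c("mz", "intensity", intersect(c("snr", "formula"), names(p)))
  fmt <- function(v) if (is.numeric(v)) sprintf("%.6f", v) else ifelse(is.na(v), "", v)
  body <- do.call(paste, c(lapply(p[cols], fmt), list(sep = sep)))
  writeLines(c(paste(cols, collapse = sep), body), path)
  invisible(path)
}

#' Kendrick mass quantities for measured masses
#'
#' The CH2-based Kendrick mass rescales measured m/z by 14.00000/14.01565 so
#' that CH2 homologues differ by exactly 14; the Kendrick mass defect (KMD)
#' is the nominal (nearest-integer) Kendrick mass minus the Kendrick exact
#' mass, reported in milli-Daltons. Members of one homologous series share a
#' KMD. Ties in the nearest-integer rounding go half away from zero, which
#' bounds the KMD to (-500, 500] mDa.
#'
#' @param mz numeric vector of measured m/z values (> 0).
#' @return A data frame with columns `mz`, `kendrick_mass`, `nominal_mass`
#'   and `kmd_mDa`.
#' @examples
#' compute_kendrick(140.15650)  # 10 x CH2: KMD = 0
#' @export
compute_kendrick <- function(mz) {
  mz <- as.numeric(mz)
  if (anyNA(mz) || any(mz <= 0)) stop("mz must be positive")
  km <- mz * .kendrick_factor
  nominal <- floor(km + 0.5)  # half away from zero for positive masses
  data.frame(mz = mz,
             kendrick_mass = km,
             nominal_mass = nominal,
             kmd_mDa = (nominal - km) * 1000)
}

#' Filter a spectrum by m/z window and signal-to-noise
#'
#' Retains peaks with `mz_min <= mz <= mz_max` (both endpoints inclusive)
#' and, when an S/N column is present, `snr > snr_min` (strictly greater,
#' the instrument-export convention). Spectra without an S/N column keep all
#' in-window peaks. Filtering is idempotent and order-preserving; an empty
#' result is allowed.
#'
#' @param s a [spectrum()].
#' @param mz_min,mz_max inclusive m/z window bounds (Da); default 150-750.
#' @param snr_min strict lower S/N threshold; default 2.
#' @return The filtered [spectrum()].
#' @export
filter_peaks <- function(s, mz_min = 150, mz_max = 750, snr_min = 2) {
  stopifnot(inherits(s, "spectrum"))
  if (mz_min >= mz_max) stop("mz_min must be < mz_max")
  p <- s$peaks
  keep <- p$mz >= mz_min & p$mz <= mz_max
  if ("snr" %in% names(p))
    keep <- keep & (is.na(p$snr) | p$snr > snr_min)
  s$peaks <- p[keep, , drop = FALSE]
  rownames(s$peaks) <- NULL
  s
}

#' Split a spectrum by nominal-mass parity
#'
#' Each peak is assigned even or odd by the parity of the nearest integer to
#' its measured m/z (ties rounded half away from zero). The two outputs
#' partition the input exactly. Parity from the nominal Kendrick mass is
#' available for sensitivity analysis via `basis = "kendrick"`.
#'
#' @param s a [spectrum()] with `parity == "all"`.
#' @param basis `"measured"` (default) or `"kendrick"`: which mass the
#'   nearest-integer parity is taken from.
#' @return A list with elements `even` and `odd`, both [spectrum()] objects
#'   with `parity` marked.
#' @export
split_parity <- function(s, basis = c("measured", "kendrick")) {
  stopifnot(inherits(s, "spectrum"))
  basis <- match.arg(basis)
  if (s$parity != "all")
    stop("spectrum already split: parity is ", s$parity)
  m <- if (basis == "measured") s$peaks$mz else s$peaks$mz * .kendrick_factor
  nominal <- floor(m + 0.5)
  is_even <- nominal %% 2 == 0
  take <- function(idx, parity) {
    out <- s
    out$peaks <- s$peaks[idx, , drop = FALSE]
    rownames(out$peaks) <- NULL
    out$parity <- parity
    out
  }
  list(even = take(is_even, "even"), odd = take(!is_even, "odd"))
}

#' Read / write a sample manifest
#'
#' A manifest is a CSV with columns `file`, `sample_id`, `label` mapping
#' peak-list files to samples. Paths are interpreted relative to the
#' manifest's directory.
#'
#' @param path manifest CSV path.
#' @return `read_manifest`: a data frame with columns `file`, `sample_id`,
#'   `label`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("file", "sample_id", "label")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  m[need]
}

#' @rdname read_manifest
#' @param manifest data frame with columns `file`, `sample_id`, `label`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load all spectra listed in a manifest
#'
#' @param path manifest CSV path (see [read_manifest()]).
#' @return A list of [spectrum()] objects, labelled per the manifest.
#' @export
read_dataset <- function(path) {
  m <- read_manifest(path)
  dir <- dirname(path)
  lapply(seq_len(nrow(m)), function(i) {
    f <- m$file[i]
    if (!file.exists(f)) f <- file.path(dir, m$file[i])
    read_peaklist(f, sample_id = m$sample_id[i], label = m$label[i])
  })
}
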