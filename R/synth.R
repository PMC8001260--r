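# Mass with a prescribed Kendrick mass defect: for integer nominal Kendrick
# mass M and target KMD t (mDa), m = (M - t/1000) / (14/14.01565). CH2 steps
# from such a base preserve the KMD exactly.
.mass_for_kmd <- function(nominal_km, kmd_mDa) {
  (nominal_km - kmd_mDa / 1000) / .kendrick_factor
}

#' Parameters for one synthetic spectrum
#'
#' Class presets emulate the qualitative structure the four sample classes
#' show in binned KMD space. Petroleum: many long CH2 homologous series in
#' a narrow KMD band, each followed by a lower-intensity "echo" at offset
#' KMD. Synthetic (iterative-reaction products): mass ladders on non-CH2
#' repeat units (HCN 27.01090, CH2O 30.01057 Da) whose KMD drifts along the
#' ladder. Biological: fewer discrete masses with high log-intensity
#' contrast plus short lipid-like CH2 series. Meteorite: very high peak
#' density with broad KMD spread. All classes share a common noise-floor
#' model (random low-intensity peaks) and sub-ppm seeded mass jitter
#' (0.2 ppm RMS, emulating FT-ICR accuracy without breaking 1 ppm biomarker
#' matching).
#'
#' The `structure` knob interpolates towards a class-independent random
#' model: structured peak counts scale by `structure` and a common random
#' background scales by `1 - structure`, so at `structure = 0` all classes
#' are draws from one model and classification accuracy falls to chance.
#'
#' @param class_name one of `"Biological"`, `"Meteorite"`, `"Petroleum"`,
#'   `"Synthetic"`.
#' @param seed integer seed; the same parameters and seed give an identical
#'   spectrum.
#' @param structure class-structure weight in [0, 1]; default 1 (full class
#'   structure).
#' @param ... preset overrides (any field of the returned list, e.g.
#'   `noise_n = 0`, `mass_jitter_ppm = 0`).
#' @return An object of class `"synth_params"`.
#' @export
synth_params <- function(class_name = c("Biological", "Meteorite",
                                        "Petroleum", "Synthetic"),
                         seed = 0, structure = 1, ...) {
  class_name <- match.arg(class_name)
  if (structure < 0 || structure > 1) stop("structure must be in [0, 1]")
  p <- list(class_name = class_name, seed = as.integer(seed),
            structure = structure,
            mz_window = c(150, 750),
            mass_jitter_ppm = 0.2,
            noise_n = 300, noise_meanlog = 9, noise_sdlog = 0.7,
            bg_n = 1200, bg_meanlog = 11.5, bg_sdlog = 1.2)
  preset <- switch(class_name,
    Petroleum = list(n_series = 25, series_len_mean = 25,
                     kmd_band = c(0, 90),
                     echo = list(kmd_offset = 150, factor = 0.15),
                     repeat_units = .ch2_mass,
                     series_meanlog = 12, series_meanlog_sd = 0.7,
                     member_sdlog = 0.4),
    Synthetic = list(n_series = 12, series_len_mean = 14,
                     repeat_units = c(HCN = 27.010899, CH2O = 30.010565),
                     ladder_decay = 0.15,
                     series_meanlog = 12, series_meanlog_sd = 0.7,
                     member_sdlog = 0.3),
    Biological = list(n_discrete = 70, discrete_meanlog = 13,
                      discrete_sdlog = 2.5,
                      n_series = 4, series_len_mean = 8,
                      repeat_units = .ch2_mass,
                      series_meanlog = 12, series_meanlog_sd = 0.5,
                      member_sdlog = 0.6),
    Meteorite = list(n_random = 4000, random_meanlog = 11,
                     random_sdlog = 1.0))
  p <- utils::modifyList(c(p, preset), list(...))
  structure(p, class = "synth_params")
}

# scale a structured count by the structure knob
.scaled <- function(n, structure) as.integer(round(n * structure))

#' Generate one synthetic spectrum
#'
#' Deterministic for fixed parameters and seed. See [synth_params()] for
#' what each class emulates. The generator is an explicit caricature for
#' testing the pipeline, not a chemical simulator.
#'
#' @param p a [synth_params()] object.
#' @param sample_id identifier for the resulting spectrum.
#' @return A labelled [spectrum()] with peaks in the m/z window, intensity
#'   and S/N columns (S/N referenced to the noise-floor median intensity).
#' @export
generate_spectrum <- function(p, sample_id = p$class_name) {
  stopifnot(inherits(p, "synth_params"))
  set.seed(p$seed)
  w <- p$mz_window
  mz <- numeric(0); intensity <- numeric(0)
  add <- function(m, a) {
    keep <- m >= w[1] & m <= w[2]
    mz <<- c(mz, m[keep]); intensity <<- c(intensity, a[keep])
  }

  ch2_series <- function(n_series, len_mean, kmd_band = NULL,
                         base_range = c(160, 420), echo = NULL,
                         meanlog, meanlog_sd, sdlog) {
    for (i in seq_len(n_series)) {
      len <- max(3L, stats::rpois(1, len_mean))
      base <- if (is.null(kmd_band)) {
        runif(1, base_range[1], base_range[2])
      } else {
        .mass_for_kmd(sample(seq(round(base_range[1]), round(base_range[2])), 1),
                      runif(1, kmd_band[1], kmd_band[2]))
      }
      m <- base + (seq_len(len) - 1) * .ch2_mass
      ml <- rnorm(1, meanlog, meanlog_sd)
      a <- rlnorm(length(m), ml, sdlog)
      add(m, a)
      if (!is.null(echo)) {
        add(m - echo$kmd_offset / 1000 / .kendrick_factor, a * echo$factor)
      }
    }
  }

  switch(p$class_name,
    Petroleum = ch2_series(.scaled(p$n_series, p$structure),
                           p$series_len_mean, kmd_band = p$kmd_band,
                           base_range = c(160, 360), echo = p$echo,
                           meanlog = p$series_meanlog,
                           meanlog_sd = p$series_meanlog_sd,
                           sdlog = p$member_sdlog),
    Synthetic = {
      for (i in seq_len(.scaled(p$n_series, p$structure))) {
        unit <- p$repeat_units[[sample(length(p$repeat_units), 1)]]
        len <- max(3L, stats::rpois(1, p$series_len_mean))
        base <- runif(1, w[1], 320)
        m <- base + (seq_len(len) - 1) * unit
        ml <- rnorm(1, p$series_meanlog, p$series_meanlog_sd)
        a <- rlnorm(length(m), ml - p$ladder_decay * (seq_len(len) - 1),
                    p$member_sdlog)
        add(m, a)
      }
    },
    Biological = {
      n_d <- .scaled(p$n_discrete, p$structure)
      add(runif(n_d, w[1], w[2]),
          rlnorm(n_d, p$discrete_meanlog, p$discrete_sdlog))
      ch2_series(.scaled(p$n_series, p$structure), p$series_len_mean,
                 base_range = c(200, 420),
                 meanlog = p$series_meanlog,
                 meanlog_sd = p$series_meanlog_sd,
                 sdlog = p$member_sdlog)
    },
    Meteorite = {
      n_r <- .scaled(p$n_random, p$structure)
      add(runif(n_r, w[1], w[2]),
          rlnorm(n_r, p$random_meanlog, p$random_sdlog))
    })

  # common noise floor
  if (p$noise_n > 0) {
    add(runif(p$noise_n, w[1], w[2]),
        rlnorm(p$noise_n, p$noise_meanlog, p$noise_sdlog))
  }
  # class-independent background, grows as structure is removed
  n_bg <- .scaled(p$bg_n, 1 - p$structure)
  if (n_bg > 0) {
    add(runif(n_bg, w[1], w[2]), rlnorm(n_bg, p$bg_meanlog, p$bg_sdlog))
  }
  if (!length(mz)) stop("parameters generated an empty spectrum")
  # seeded sub-ppm mass error
  if (p$mass_jitter_ppm > 0) {
    mz <- mz * (1 + rnorm(length(mz), 0, p$mass_jitter_ppm * 1e-6))
  }
  snr <- intensity / exp(p$noise_meanlog)
  spectrum(mz, intensity, snr = snr, sample_id = sample_id,
           label = p$class_name)
}

#' Generate a labelled synthetic dataset
#'
#' Draws `per_class` spectra per class with child seeds derived
#' deterministically from `master_seed`. Optionally writes the peak lists
#' and a manifest CSV in the package's peak-list dialect.
#'
#' @param per_class spectra per class (>= 1).
#' @param master_seed integer master seed.
#' @param classes character vector of class names (default all four).
#' @param structure class-structure weight passed to [synth_params()].
#' @param out_dir if non-`NULL`, write peak lists and `manifest.csv` there.
#' @param ... further preset overrides passed to [synth_params()].
#' @return List with `spectra` (list of labelled [spectrum()]s) and
#'   `manifest` (data frame `file`, `sample_id`, `label`).
#' @export
generate_dataset <- function(per_class = 40, master_seed = 0,
                             classes = c("Biological", "Meteorite",
                                         "Petroleum", "Synthetic"),
                             structure = 1, out_dir = NULL, ...) {
  if (per_class < 1) stop("per_class must be >= 1")
  spectra <- list()
  rows <- list()
  i <- 0L
  for (cl in classes) {
    for (j in seq_len(per_class)) {
      i <- i + 1L
      child <- (as.integer(master_seed) %% 100000L) * 10007L + i * 97L
      sid <- sprintf("%s_%03d", tolower(cl), j)
      p <- synth_params(cl, seed = child, structure = structure, ...)
      spectra[[i]] <- generate_spectrum(p, sample_id = sid)
      rows[[i]] <- data.frame(file = paste0(sid, ".csv"),
                              sample_id = sid, label = cl)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(spectra))
      write_peaklist(spectra[[i]], file.path(out_dir, manifest$file[i]))
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  }
  list(spectra = spectra, manifest = manifest)
}
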