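#' Component band specification
#'
#' Describes one analyte's UV absorption envelope as a sum of Gaussian bands.
#' `peak` is the peak molar-scale absorptivity in AU mL ug^-1 cm^-1 with the
#' 1 cm path length folded in, so a pure solution at concentration c (ug/mL)
#' absorbs `c * peak` AU at the band centre.
#'
#' @param name Component name.
#' @param bands Data frame (or tibble) with columns `center_nm`, `sigma_nm`,
#'   `peak`; at least one band, all sigmas and peaks > 0.
#' @return An object of class `component_spec`.
#' @export
component_spec <- function(name, bands) {
  bands <- tibble::as_tibble(bands)
  stopifnot(all(c("center_nm", "sigma_nm", "peak") %in% names(bands)))
  if (nrow(bands) < 1 || any(bands$sigma_nm <= 0) || any(bands$peak <= 0)) {
    stop("Component '", name, "' needs >= 1 band with sigma_nm > 0 and peak > 0.",
         call. = FALSE)
  }
  structure(list(name = name, bands = bands), class = "component_spec")
}

#' Default five-component band library
#'
#' Builds Gaussian band libraries for the five analytes of the eye-drop
#' assay: naphazoline HCl (NZ), pheniramine maleate (PN), NZ impurity B and
#' PN impurities A and B. The bands are a synthetic surrogate for the
#' measured pure spectra: every component carries a band centred inside the
#' 250--300 nm working window, neighbouring components overlap severely
#' there (pairwise cosine similarity of the pure spectra well above 0.5),
#' strong secondary bands sit below 250 nm where the instrument is noisy,
#' and all envelopes decay to under 5% of their maximum above 300 nm.
#' Peak absorptivities are scaled so design-level mixtures fall in roughly
#' 0.1--1.5 AU.
#'
#' @param seed Integer seed; applies a small reproducible jitter (band
#'   centres +/- 1 nm, widths +/- 3%, peaks +/- 5%) so replicate libraries
#'   differ slightly, as repeated standard preparations would.
#' @return Named list of five [component_spec()] objects, in the assay order
#'   `NZ, PN, NZ_impB, PN_impA, PN_impB`.
#' @examples
#' lib <- default_library(seed = 0)
#' names(lib)
#' @export
default_library <- function(seed = 0) {
  base <- list(
    NZ = data.frame(                       # naphthalene-like doublet
      center_nm = c(270, 281, 223), sigma_nm = c(6, 4.5, 11),
      peak = c(0.030, 0.020, 0.060)),
    PN = data.frame(                       # main band + short-wave shoulder
      center_nm = c(258, 265, 218), sigma_nm = c(7, 4, 10),
      peak = c(0.012, 0.006, 0.030)),
    NZ_impB = data.frame(                  # envelope over NZ + red satellite
      center_nm = c(277, 293, 228), sigma_nm = c(7, 4, 12),
      peak = c(0.040, 0.030, 0.090)),
    PN_impA = data.frame(                  # blue-shifted PN-like pair
      center_nm = c(254, 263, 221), sigma_nm = c(5, 9, 10),
      peak = c(0.020, 0.011, 0.045)),
    PN_impB = data.frame(                  # red-shifted band + shoulder
      center_nm = c(286, 265, 231), sigma_nm = c(6, 6, 12),
      peak = c(0.020, 0.010, 0.040))
  )
  withr::with_seed(as.integer(seed), {
    purrr::imap(base, function(b, nm) {
      n <- nrow(b)
      b$center_nm <- b$center_nm + stats::runif(n, -1, 1)
      b$sigma_nm <- b$sigma_nm * (1 + stats::runif(n, -0.03, 0.03))
      b$peak <- b$peak * (1 + stats::runif(n, -0.05, 0.05))
      component_spec(nm, b)
    })
  })
}

#' Pure-component spectrum at unit concentration
#'
#' Evaluates the Beer-Lambert kernel of one component on a grid:
#' \deqn{a(\lambda) = \sum_k p_k \exp\{-(\lambda - \mu_k)^2 / (2\sigma_k^2)\}.}
#'
#' @param spec A [component_spec()].
#' @param grid A [wl_grid()].
#' @return Numeric vector of absorbances (AU per unit ug/mL), one per grid
#'   point; non-negative.
#' @export
pure_spectrum <- function(spec, grid) {
  wl <- grid$wavelength_nm
  out <- numeric(length(wl))
  for (k in seq_len(nrow(spec$bands))) {
    b <- spec$bands[k, ]
    out <- out + b$peak * exp(-(wl - b$center_nm)^2 / (2 * b$sigma_nm^2))
  }
  out
}

#' Instrument noise model
#'
#' Homoscedastic Gaussian photometric noise within each wavelength regime:
#' `sigma_below_250` applies below 250 nm (the high-noise end of the scan)
#' and `sigma_base` elsewhere. An optional smooth sinusoidal baseline drift
#' with a random per-sample phase emulates slow lamp/baseline wander.
#'
#' @param sigma_base Photometric noise SD (AU) at and above 250 nm.
#' @param sigma_below_250 Noise SD (AU) below 250 nm; typically larger.
#' @param baseline_drift_amplitude Amplitude (AU) of the smooth drift; 0
#'   disables it.
#' @param seed Integer seed for reproducible simulation.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_base = 0.001, sigma_below_250 = 0.008,
                        baseline_drift_amplitude = 0, seed = 1) {
  if (sigma_base < 0 || sigma_below_250 < 0 || baseline_drift_amplitude < 0) {
    stop("Noise sigmas and drift amplitude must be >= 0.", call. = FALSE)
  }
  structure(
    list(sigma_base = sigma_base, sigma_below_250 = sigma_below_250,
         baseline_drift_amplitude = baseline_drift_amplitude,
         seed = as.integer(seed)),
    class = "noise_model"
  )
}

#' Simulate mixture spectra
#'
#' Generates absorbance spectra of mixtures by Beer-Lambert superposition of
#' the pure-component spectra plus instrument noise:
#' \deqn{A_i(\lambda) = \sum_j c_{ij}\, s_j(\lambda) + \epsilon_i(\lambda),}
#' with \eqn{\epsilon} Gaussian at the regime-dependent SD of the noise
#' model, plus the optional baseline drift. Fully reproducible under the
#' noise model's seed.
#'
#' @param conc Concentration table: data frame (an optional `run_id` column
#'   is ignored) or matrix, samples x components (ug/mL); column order must
#'   match `library`.
#' @param library Named list of [component_spec()] objects.
#' @param grid A [wl_grid()].
#' @param noise A [noise_model()], or `NULL` for noiseless spectra.
#' @param sample_ids Optional sample identifiers.
#' @return A [spectrum_set()].
#' @export
simulate_mixtures <- function(conc, library, grid, noise = noise_model(),
                              sample_ids = NULL) {
  C <- conc_to_matrix(conc, names(library))
  if (any(C < 0)) stop("Concentrations must be non-negative.", call. = FALSE)
  S <- t(vapply(library, pure_spectrum, numeric(grid$n_points), grid = grid))
  A <- C %*% S
  if (!is.null(noise)) {
    wl <- grid$wavelength_nm
    sd_wl <- ifelse(wl < 250, noise$sigma_below_250, noise$sigma_base)
    A <- withr::with_seed(noise$seed, {
      eps <- matrix(stats::rnorm(length(A)), nrow = nrow(A)) *
        matrix(sd_wl, nrow = nrow(A), ncol = length(wl), byrow = TRUE)
      drift <- 0
      if (noise$baseline_drift_amplitude > 0) {
        phase <- stats::runif(nrow(A), 0, 2 * pi)
        drift <- noise$baseline_drift_amplitude *
          sin(outer(phase, 2 * pi * (wl - wl[1]) / 150, `+`))
      }
      A + eps + drift
    })
  }
  spectrum_set(A, grid, sample_ids)
}

#' Normalize spectra to unit maximum
#'
#' Divides each spectrum by its own maximum so every row peaks at 1. Used
#' for spectral characterization and overlay plots only; calibration always
#' operates on raw absorbances.
#'
#' @param s A [spectrum_set()].
#' @return A [spectrum_set()] with each row's maximum equal to 1.
#' @export
normalize_spectra <- function(s) {
  mx <- apply(s$absorbance, 1, max)
  if (any(mx <= 0)) {
    stop("Cannot normalize: sample(s) ",
         paste(s$sample_ids[mx <= 0], collapse = ", "),
         " have non-positive maximum absorbance.", call. = FALSE)
  }
  spectrum_set(s$absorbance / mx, s$grid, s$sample_ids)
}

# coerce a concentration table (tibble with optional run_id, or matrix)
# to a samples x components matrix in library order
conc_to_matrix <- function(conc, component_names = NULL) {
  if (is.data.frame(conc)) {
    conc <- conc[setdiff(names(conc), "run_id")]
    if (!is.null(component_names)) {
      missing <- setdiff(component_names, names(conc))
      if (length(missing) > 0) {
        stop("Concentration table lacks component(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
      conc <- conc[component_names]
    }
    as.matrix(conc)
  } else {
    M <- as.matrix(conc)
    if (!is.null(component_names) && ncol(M) != length(component_names)) {
      stop("Concentration matrix must have one column per component.",
           call. = FALSE)
    }
    M
  }
}
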