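#' Evenly spaced wavelength grid
#'
#' Defines the wavelength axis of a scan with inclusive endpoints. The
#' default matches a 200.0--400.0 nm scan at 0.2 nm intervals (1001 points);
#' the 250.0--300.0 nm working window at the same step has 251 points.
#'
#' @param start_nm,stop_nm Scan limits in nm, `start_nm < stop_nm`.
#' @param step_nm Sampling interval in nm, > 0. `(stop - start)` must be an
#'   integer multiple of the step (within floating tolerance).
#' @return An object of class `wl_grid` with elements `start_nm`, `stop_nm`,
#'   `step_nm`, `n_points` and the wavelength vector `wavelength_nm`.
#' @examples
#' wl_grid(200, 400, 0.2)$n_points
#' @export
wl_grid <- function(start_nm = 200, stop_nm = 400, step_nm = 0.2) {
  if (!(start_nm < stop_nm) || step_nm <= 0) {
    stop("Need start_nm < stop_nm and step_nm > 0.", call. = FALSE)
  }
  n_steps <- (stop_nm - start_nm) / step_nm
  if (abs(n_steps - round(n_steps)) > 1e-6) {
    stop("(stop_nm - start_nm) must be a multiple of step_nm.", call. = FALSE)
  }
  n_points <- as.integer(round(n_steps)) + 1L
  structure(
    list(
      start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm,
      n_points = n_points,
      wavelength_nm = start_nm + step_nm * (seq_len(n_points) - 1)
    ),
    class = "wl_grid"
  )
}

#' @export
print.wl_grid <- function(x, ...) {
  cat(sprintf("<wl_grid> %.1f-%.1f nm @ %.1f nm (%d points)\n",
              x$start_nm, x$stop_nm, x$step_nm, x$n_points))
  invisible(x)
}

#' Set of absorbance spectra on a common grid
#'
#' Bundles an `n_samples x n_points` absorbance matrix (AU) with its
#' wavelength grid and sample identifiers.
#'
#' @param absorbance Numeric matrix, one row per sample, one column per grid
#'   point; all entries finite.
#' @param grid A [wl_grid()].
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to `S1..Sn`.
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(absorbance, grid, sample_ids = NULL) {
  absorbance <- as.matrix(absorbance)
  if (ncol(absorbance) != grid$n_points) {
    stop("Absorbance matrix has ", ncol(absorbance),
         " columns but the grid has ", grid$n_points, " points.", call. = FALSE)
  }
  if (!all(is.finite(absorbance))) {
    stop("Absorbance matrix contains non-finite entries.", call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(absorbance)))
  if (length(sample_ids) != nrow(absorbance) || anyDuplicated(sample_ids)) {
    stop("`sample_ids` must be unique, one per spectrum.", call. = FALSE)
  }
  dimnames(absorbance) <- NULL
  structure(
    list(grid = grid, absorbance = absorbance,
         sample_ids = as.character(sample_ids)),
    class = "spectrum_set"
  )
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra, %.1f-%.1f nm @ %.1f nm (%d points)\n",
              nrow(x$absorbance), x$grid$start_nm, x$grid$stop_nm,
              x$grid$step_nm, x$grid$n_points))
  invisible(x)
}

#' Tidy a spectrum set to long form
#'
#' @param x A `spectrum_set`.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `wavelength_nm`, `absorbance`.
#' @method tidy spectrum_set
#' @export
tidy.spectrum_set <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(x$sample_ids, each = x$grid$n_points),
    wavelength_nm = rep(x$grid$wavelength_nm, times = length(x$sample_ids)),
    absorbance = as.vector(t(x$absorbance))
  )
}

#' @method as_tibble spectrum_set
#' @export
as_tibble.spectrum_set <- function(x, ...) tidy.spectrum_set(x, ...)

#' Plot a spectrum set
#'
#' Overlaid absorbance traces, one line per sample.
#'
#' @param object A `spectrum_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spectrum_set
#' @export
autoplot.spectrum_set <- function(object, ...) {
  df <- tidy.spectrum_set(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength_nm, .data$absorbance,
                                   group = .data$sample_id,
                                   colour = .data$sample_id)) +
    ggplot2::geom_line(linewidth = 0.3, show.legend = length(object$sample_ids) <= 8) +
    ggplot2::labs(x = "Wavelength (nm)", y = "Absorbance (AU)") +
    ggplot2::theme_minimal()
}
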