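#' Select a wavelength window
#'
#' Restricts a spectrum set to an inclusive wavelength window by slicing
#' existing grid points; no interpolation is performed. The informative
#' window for the five-analyte assay is 250.0--300.0 nm: below 250 nm the
#' instrument is noisy and above 300 nm absorption is essentially zero. On a
#' 0.2 nm grid that window holds exactly 251 points.
#'
#' @param s A [spectrum_set()].
#' @param low_nm,high_nm Window bounds in nm, inclusive; must lie within the
#'   grid (matched to grid points with 1e-9 nm tolerance).
#' @return A [spectrum_set()] on the sliced grid.
#' @examples
#' g <- wl_grid(200, 400, 0.2)
#' s <- spectrum_set(matrix(1, 1, g$n_points), g)
#' select_window(s, 250, 300)$grid$n_points
#' @export
select_window <- function(s, low_nm = 250, high_nm = 300) {
  g <- s$grid
  tol <- 1e-9
  if (low_nm < g$start_nm - tol || high_nm > g$stop_nm + tol || low_nm > high_nm) {
    stop(sprintf("Window [%g, %g] nm must lie within the grid [%g, %g] nm.",
                 low_nm, high_nm, g$start_nm, g$stop_nm), call. = FALSE)
  }
  keep <- which(g$wavelength_nm >= low_nm - tol & g$wavelength_nm <= high_nm + tol)
  wl <- g$wavelength_nm[keep]
  # slice, never re-derive: keeps the original grid points bit-exactly
  sub <- structure(list(start_nm = wl[1], stop_nm = wl[length(wl)],
                        step_nm = g$step_nm, n_points = length(wl),
                        wavelength_nm = wl),
                   class = "wl_grid")
  spectrum_set(s$absorbance[, keep, drop = FALSE], sub, s$sample_ids)
}

#' Fit a mean-centering transform
#'
#' Stores the column means of the calibration spectra `X` and concentrations
#' `Y`. Both blocks are centered before regression and the concentration
#' means are added back after prediction; validation data are always centered
#' with the calibration means (no information leakage).
#'
#' @param X Calibration absorbance matrix (samples x wavelengths).
#' @param Y Calibration concentration matrix (samples x components).
#' @return An object of class `centering_transform` with `x_means`,
#'   `y_means` and the fitted dimensions.
#' @export
fit_centering <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) < 2 || nrow(Y) < 2) {
    stop("Centering needs at least 2 rows.", call. = FALSE)
  }
  if (nrow(X) != nrow(Y)) stop("X and Y must have equal row counts.", call. = FALSE)
  structure(
    list(x_means = colMeans(X), y_means = colMeans(Y),
         n_x = ncol(X), n_y = ncol(Y)),
    class = "centering_transform"
  )
}

#' Apply or invert a centering transform
#'
#' `apply_centering()` subtracts the stored calibration means;
#' `invert_centering()` adds them back, so `invert(apply(M)) == M` exactly.
#'
#' @param transform A [fit_centering()] result.
#' @param M Matrix to (un)center.
#' @param block `"x"` (spectra) or `"y"` (concentrations); selects which
#'   stored mean vector applies.
#' @return Matrix of the same shape as `M`.
#' @export
apply_centering <- function(transform, M, block = c("x", "y")) {
  block <- match.arg(block)
  mu <- centering_means(transform, M, block)
  sweep(as.matrix(M), 2, mu, `-`)
}

#' @rdname apply_centering
#' @export
invert_centering <- function(transform, M, block = c("x", "y")) {
  block <- match.arg(block)
  mu <- centering_means(transform, M, block)
  sweep(as.matrix(M), 2, mu, `+`)
}

centering_means <- function(transform, M, block) {
  mu <- if (block == "x") transform$x_means else transform$y_means
  if (ncol(as.matrix(M)) != length(mu)) {
    stop("Matrix has ", ncol(as.matrix(M)), " columns; transform was fitted on ",
         length(mu), " (block '", block, "').", call. = FALSE)
  }
  mu
}
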