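#' Write and read spectra CSV
#'
#' Spectra are stored with a `wavelength_nm` first column and one column per
#' sample (header = sample id), absorbances rounded to 6 decimal places so a
#' write/read cycle round-trips bit-exactly at that precision.
#'
#' @param s A [spectrum_set()].
#' @param path Output file path.
#' @return `write_spectra_csv()` returns `path` invisibly;
#'   `read_spectra_csv()` returns a [spectrum_set()].
#' @export
write_spectra_csv <- function(s, path) {
  df <- data.frame(wavelength_nm = round(s$grid$wavelength_nm, 6))
  A <- t(s$absorbance)
  colnames(A) <- s$sample_ids
  df <- cbind(df, round(A, 6))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  check_rectangular_csv(path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "wavelength_nm") {
    stop("First column must be `wavelength_nm`.", call. = FALSE)
  }
  if (anyDuplicated(names(df)[-1])) {
    stop("Duplicated sample id(s): ",
         paste(unique(names(df)[-1][duplicated(names(df)[-1])]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(vapply(df, is.numeric, logical(1)))) {
    stop("Non-numeric cells found in ", path, ".", call. = FALSE)
  }
  wl <- df$wavelength_nm
  if (any(diff(wl) <= 0)) {
    stop("`wavelength_nm` must be strictly increasing.", call. = FALSE)
  }
  step <- stats::median(diff(wl))
  grid <- structure(
    list(start_nm = wl[1], stop_nm = wl[length(wl)], step_nm = step,
         n_points = length(wl), wavelength_nm = wl),
    class = "wl_grid"
  )
  spectrum_set(t(as.matrix(df[-1])), grid, sample_ids = names(df)[-1])
}

#' Write and read concentration CSV
#'
#' Concentration tables are stored as `run_id` plus one column per component
#' (ug/mL).
#'
#' @param conc Tibble with `run_id` and component columns.
#' @param path File path.
#' @return `write_conc_csv()` returns `path` invisibly; `read_conc_csv()`
#'   returns a tibble.
#' @export
write_conc_csv <- function(conc, path) {
  utils::write.csv(conc, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_conc_csv
#' @export
read_conc_csv <- function(path) {
  check_rectangular_csv(path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(vapply(df, is.numeric, logical(1)))) {
    stop("Non-numeric cells found in ", path, ".", call. = FALSE)
  }
  tibble::as_tibble(df)
}

# raggedness check with a row-numbered error, before delegating to read.csv
check_rectangular_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  nf <- lengths(strsplit(lines, ",", fixed = TRUE))
  bad <- which(nf != nf[1])
  if (length(bad) > 0) {
    stop("Ragged CSV ", path, ": row ", bad[1], " has ", nf[bad[1]],
         " fields, expected ", nf[1], ".", call. = FALSE)
  }
  invisible(TRUE)
}

#' Serialize a fitted model to JSON
#'
#' Writes a `pls_model` or `ann_model` (weights, centering/scaling, and
#' configuration) to a single versioned JSON document, readable back with
#' [load_model()]. Matrices are stored at full double precision.
#'
#' @param model A `pls_model` or `ann_model`.
#' @param path Output path.
#' @param provenance Optional named list (seeds, window, etc.) embedded in
#'   the document.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, provenance = list()) {
  type <- if (inherits(model, "pls_model")) "pls" else
    if (inherits(model, "ann_model")) "ann" else
      stop("Unsupported model class.", call. = FALSE)
  m <- unclass(model)
  if (!is.null(m$centering)) m$centering <- unclass(m$centering)
  doc <- list(
    schema_version = "1.0",
    model_type = type,
    package_version = as.character(utils::packageVersion("specal")),
    provenance = provenance,
    model = m
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- doc$model
  if (doc$model_type == "pls") {
    m$centering <- structure(m$centering, class = "centering_transform")
    for (f in c("W", "P", "Q", "T", "B")) m[[f]] <- as.matrix(m[[f]])
    structure(m, class = "pls_model")
  } else {
    m$W1 <- as.matrix(m$W1); m$W2 <- as.matrix(m$W2)
    m$b1 <- as.numeric(m$b1); m$b2 <- as.numeric(m$b2)
    structure(m, class = "ann_model")
  }
}
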