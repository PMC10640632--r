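#' Five-level multilevel calibration design
#'
#' Generates the 25-run, five-level calibration design used to prepare
#' multicomponent mixtures for multivariate calibration. Every factor takes
#' the coded levels \eqn{-2, -1, 0, +1, +2}, each exactly five times, and
#' every ordered pair of distinct factors enumerates all 25 level
#' combinations exactly once, so concentration profiles are mutually
#' orthogonal and no pair of analytes is confounded.
#'
#' Runs are indexed over the 25 cells of a 5 x 5 grid \eqn{(a, b)} and the
#' k-th factor is assigned level \eqn{(a + c_k b) \bmod 5} with distinct
#' multipliers \eqn{c_k}; this finite-field construction yields up to six
#' mutually orthogonal five-level columns and is deterministic.
#'
#' @param n_factors Number of factors (analytes), between 2 and 6.
#' @param factor_names Optional character vector of factor names. Defaults to
#'   the five-analyte naming `NZ, PN, NZ_impB, PN_impA, PN_impB` when
#'   `n_factors == 5`, otherwise `F1..Fk`.
#'
#' @return A tibble of class `design_table` with a `run_id` column and one
#'   integer column of coded levels per factor.
#' @examples
#' d <- generate_design(5)
#' table(d$NZ)
#' @export
generate_design <- function(n_factors = 5, factor_names = NULL) {
  if (!is.numeric(n_factors) || length(n_factors) != 1L ||
      n_factors != round(n_factors) || n_factors < 2 || n_factors > 6) {
    stop("`n_factors` must be a single integer between 2 and 6.", call. = FALSE)
  }
  n_factors <- as.integer(n_factors)
  if (is.null(factor_names)) {
    factor_names <- if (n_factors == 5L) {
      c("NZ", "PN", "NZ_impB", "PN_impA", "PN_impB")
    } else {
      paste0("F", seq_len(n_factors))
    }
  }
  if (length(factor_names) != n_factors || anyDuplicated(factor_names)) {
    stop("`factor_names` must give one distinct name per factor.", call. = FALSE)
  }

  run <- 0:24
  a <- run %/% 5L
  b <- run %% 5L
  # columns a, b, a+b, a+2b, a+3b, a+4b (mod 5) are mutually orthogonal
  multipliers <- list(NULL, NULL, 1L, 2L, 3L, 4L)
  cols <- lapply(seq_len(n_factors), function(k) {
    lev <- if (k == 1L) a else if (k == 2L) b else (a + multipliers[[k]] * b) %% 5L
    as.integer(lev - 2L)
  })
  names(cols) <- factor_names
  out <- tibble::tibble(run_id = run + 1L, !!!cols)
  class(out) <- c("design_table", class(out))
  out
}

#' Map coded design levels to concentrations
#'
#' Converts the coded levels of a [generate_design()] table to working
#' concentrations. Level \eqn{-2} maps to `c_min`, level \eqn{+2} to `c_max`,
#' with the five levels equally spaced:
#' \deqn{c = c_{min} + (level + 2)\,(c_{max} - c_{min})/4.}
#'
#' @param design A `design_table` from [generate_design()].
#' @param ranges Named list (or data frame with `factor`, `c_min`, `c_max`
#'   columns); each element a numeric `c(c_min, c_max)` in ug/mL. Must cover
#'   every factor of the design.
#'
#' @return A tibble with `run_id` and one concentration column (ug/mL) per
#'   factor.
#' @examples
#' d <- generate_design(5)
#' conc <- realize_concentrations(d, assay_ranges())
#' sort(unique(conc$NZ))
#' @export
realize_concentrations <- function(design, ranges) {
  fac <- design_factors(design)
  ranges <- as_range_list(ranges)
  missing <- setdiff(fac, names(ranges))
  if (length(missing) > 0) {
    stop("`ranges` is missing factor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- design["run_id"]
  for (f in fac) {
    r <- ranges[[f]]
    if (length(r) != 2 || !all(is.finite(r)) || r[1] <= 0 || r[2] <= r[1]) {
      stop("Range for ", f, " must be c(c_min, c_max) with 0 < c_min < c_max.",
           call. = FALSE)
    }
    out[[f]] <- r[1] + (design[[f]] + 2) * (r[2] - r[1]) / 4
  }
  tibble::as_tibble(out)
}

#' Concentration ranges of the five-analyte eye-drop assay
#'
#' Default working ranges (ug/mL) for the two drugs and three impurities:
#' naphazoline HCl 5--13, pheniramine maleate 10--60, NZ impurity B 1--5 and
#' PN impurities A and B 2--14.
#'
#' @return Named list of `c(c_min, c_max)` pairs.
#' @export
assay_ranges <- function() {
  list(
    NZ      = c(5, 13),
    PN      = c(10, 60),
    NZ_impB = c(1, 5),
    PN_impA = c(2, 14),
    PN_impB = c(2, 14)
  )
}

#' Split design runs into calibration and validation sets
#'
#' Randomly assigns `n_validation` runs to the validation set and the rest to
#' calibration, redrawing until every level of every factor is represented at
#' least once in the calibration subset (so models never extrapolate in the
#' coded-level space).
#'
#' @param design A `design_table`.
#' @param n_validation Number of validation runs (default 10, leaving 15 for
#'   calibration).
#' @param seed Integer seed; the split is reproducible for a fixed seed.
#' @param max_draws Redraw budget for the coverage constraint.
#'
#' @return A tibble of class `calibration_split` with columns `run_id` and
#'   `role` (`"calibration"` or `"validation"`).
#' @examples
#' sp <- split_runs(generate_design(5), n_validation = 10, seed = 1)
#' table(sp$role)
#' @export
split_runs <- function(design, n_validation = 10, seed = 1, max_draws = 1000) {
  n <- nrow(design)
  if (!is.numeric(n_validation) || n_validation <= 0 || n_validation >= n) {
    stop("`n_validation` must be strictly between 0 and ", n, ".", call. = FALSE)
  }
  n_validation <- as.integer(n_validation)
  fac <- design_factors(design)
  levels_all <- lapply(design[fac], function(x) sort(unique(x)))

  withr::with_seed(as.integer(seed), {
    for (draw in seq_len(max_draws)) {
      val <- sort(sample.int(n, n_validation))
      cal <- setdiff(seq_len(n), val)
      covered <- all(vapply(fac, function(f) {
        all(levels_all[[f]] %in% design[[f]][cal])
      }, logical(1)))
      if (covered) {
        role <- rep("calibration", n)
        role[val] <- "validation"
        out <- tibble::tibble(run_id = design$run_id, role = role)
        class(out) <- c("calibration_split", class(out))
        return(out)
      }
    }
    stop("Could not satisfy level coverage in ", max_draws,
         " draws; reduce `n_validation`.", call. = FALSE)
  })
}

#' Row indices of a split role
#'
#' @param split A `calibration_split`.
#' @param role `"calibration"` or `"validation"`.
#' @return Integer vector of row positions.
#' @export
split_indices <- function(split, role = c("calibration", "validation")) {
  role <- match.arg(role)
  which(split$role == role)
}

design_factors <- function(design) {
  setdiff(names(design), "run_id")
}

as_range_list <- function(ranges) {
  if (is.data.frame(ranges)) {
    stats::setNames(
      purrr::map2(ranges$c_min, ranges$c_max, c),
      ranges$factor
    )
  } else {
    ranges
  }
}
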