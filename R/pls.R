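#' Fit a PLS2 calibration model by NIPALS
#'
#' From-scratch NIPALS partial least squares regression of a concentration
#' block on a spectral block. Both blocks are mean-centered internally using
#' the calibration data (the centering transform is stored in the model and
#' re-used at prediction time). Latent variables are extracted one at a time
#' by the classical alternating NIPALS iteration with deflation of both
#' blocks.
#'
#' Determinism: the Y-score is initialized from the Y column of maximal
#' variance; the inner loop stops when the relative change of the weight
#' vector falls below 1e-12 (at most 500 iterations); and each weight
#' vector's largest-magnitude element is forced positive, which removes the
#' sign indeterminacy of the factorization.
#'
#' @param X Calibration spectra, samples x wavelengths (raw absorbances).
#' @param Y Calibration concentrations, samples x components (ug/mL).
#' @param n_lv Number of latent variables A, `1 <= A <= min(n - 1, p)`.
#' @param center Logical; mean-center both blocks (the default and the
#'   standard treatment for this assay).
#' @return An object of class `pls_model` with the centering transform,
#'   weights `W` (p x A), X-loadings `P`, Y-loadings `Q`, scores `T`,
#'   regression coefficients `B` (p x m, for centered data) and `n_lv`.
#' @examples
#' X <- matrix(rnorm(40), 8, 5); Y <- X %*% matrix(rnorm(10), 5, 2)
#' m <- fit_pls(X, Y, n_lv = 2)
#' predict(m, X)[1:2, ]
#' @export
fit_pls <- function(X, Y, n_lv, center = TRUE) {
  X <- as.matrix(X)
  Y <- conc_to_matrix(Y)
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  if (nrow(Y) != n) stop("X and Y must have equal row counts.", call. = FALSE)
  a_max <- min(n - 1, p)
  if (!is.numeric(n_lv) || n_lv < 1 || n_lv > a_max) {
    stop("`n_lv` must be between 1 and min(n - 1, p) = ", a_max, ".",
         call. = FALSE)
  }
  n_lv <- as.integer(n_lv)

  centering <- fit_centering(X, Y)
  Xc <- if (center) apply_centering(centering, X, "x") else X
  Yc <- if (center) apply_centering(centering, Y, "y") else Y
  if (!center) centering <- fit_centering(0 * X, 0 * Y)  # identity means

  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Q <- matrix(0, m, n_lv); Tm <- matrix(0, n, n_lv)
  x_scale <- sum(Xc^2)
  Xa <- Xc; Ya <- Yc
  for (a in seq_len(n_lv)) {
    if (sum(Xa^2) <= 1e-12 * max(x_scale, 1)) {
      stop("X block is rank deficient: at most ", a - 1L,
           " latent variable(s) can be extracted.", call. = FALSE)
    }
    u <- Ya[, which.max(apply(Ya, 2, stats::var)), drop = TRUE]
    if (sum(u^2) == 0) u <- Ya[, 1]
    w_old <- rep(0, p)
    for (it in seq_len(500)) {
      w <- crossprod(Xa, u)[, 1] / sum(u^2)
      w <- w / sqrt(sum(w^2))
      tt <- Xa %*% w
      q <- crossprod(Ya, tt)[, 1] / sum(tt^2)
      if (sum(q^2) > 0) u <- (Ya %*% q)[, 1] / sum(q^2)
      if (sqrt(sum((w - w_old)^2)) < 1e-12) break
      w_old <- w
    }
    # fixed sign convention for reproducible serialization
    if (w[which.max(abs(w))] < 0) {
      w <- -w; tt <- -tt; q <- -q
    }
    pp <- crossprod(Xa, tt)[, 1] / sum(tt^2)
    W[, a] <- w; P[, a] <- pp; Q[, a] <- q; Tm[, a] <- tt
    Xa <- Xa - tcrossprod(tt, pp)
    Ya <- Ya - tcrossprod(tt, q)
  }
  B <- W %*% solve(crossprod(P, W), t(Q))
  structure(
    list(centering = centering, W = W, P = P, Q = Q, T = Tm, B = B,
         n_lv = n_lv, component_names = colnames(Y),
         ss_x_total = x_scale, ss_x_residual = sum(Xa^2)),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variables, %d wavelengths -> %d components\n",
              x$n_lv, nrow(x$B), ncol(x$B)))
  invisible(x)
}

#' Predict concentrations from a PLS model
#'
#' Applies the stored calibration centering to new spectra, multiplies by
#' the regression coefficient matrix and adds back the concentration means.
#'
#' @param object A `pls_model`.
#' @param newdata Raw absorbance matrix or [spectrum_set()] with the fitted
#'   wavelength dimension.
#' @param n_lv Optional smaller number of latent variables to use (via the
#'   score recursion); default uses the full fitted model.
#' @param ... Unused.
#' @return Matrix of predicted concentrations (samples x components, ug/mL).
#' @export
predict.pls_model <- function(object, newdata, n_lv = NULL, ...) {
  X <- if (inherits(newdata, "spectrum_set")) newdata$absorbance else
    as.matrix(newdata)
  Xc <- apply_centering(object$centering, X, "x")
  if (is.null(n_lv) || n_lv == object$n_lv) {
    Yc <- Xc %*% object$B
  } else {
    if (n_lv < 1 || n_lv > object$n_lv) {
      stop("`n_lv` must be between 1 and the fitted ", object$n_lv, ".",
           call. = FALSE)
    }
    Tn <- pls_scores(object, Xc)
    Yc <- Tn[, seq_len(n_lv), drop = FALSE] %*%
      t(object$Q[, seq_len(n_lv), drop = FALSE])
  }
  out <- invert_centering(object$centering, Yc, "y")
  colnames(out) <- object$component_names
  out
}

# scores of new (already centered) spectra via the weight/loading recursion
pls_scores <- function(model, Xc) {
  n <- nrow(Xc)
  Tn <- matrix(0, n, model$n_lv)
  E <- Xc
  for (a in seq_len(model$n_lv)) {
    tt <- E %*% model$W[, a, drop = FALSE]
    Tn[, a] <- tt
    E <- E - tt %*% t(model$P[, a, drop = FALSE])
  }
  Tn
}

#' Leave-one-out cross-validation curve
#'
#' For each candidate latent-variable count `A = 1..a_max`, each calibration
#' sample is predicted by a model fitted on the remaining samples; the root
#' mean squared error of cross-validation (RMSECV) is aggregated on the
#' original concentration scale, pooled over all components and also per
#' component. One NIPALS fit at `a_max` is performed per fold; predictions
#' for smaller A come from truncating the score/loading expansion, which is
#' exactly the nested NIPALS model sequence.
#'
#' @param X Calibration spectra (samples x wavelengths).
#' @param Y Calibration concentrations (samples x components).
#' @param a_max Largest latent-variable count; must satisfy
#'   `a_max <= min(n - 2, p)` so every fold can be fitted.
#' @return A tibble of class `cv_curve` with columns `n_lv`, `component`
#'   (each component plus `"overall"` for the pooled curve) and `rmsecv`.
#' @export
loo_curve <- function(X, Y, a_max) {
  X <- as.matrix(X); Y <- conc_to_matrix(Y)
  n <- nrow(X)
  comp <- colnames(Y) %||% paste0("C", seq_len(ncol(Y)))
  if (a_max < 1 || a_max > min(n - 2, ncol(X))) {
    stop("`a_max` must be between 1 and min(n - 2, p) = ",
         min(n - 2, ncol(X)), ".", call. = FALSE)
  }
  pred <- array(NA_real_, dim = c(n, ncol(Y), a_max))
  for (i in seq_len(n)) {
    fit <- fit_pls(X[-i, , drop = FALSE], Y[-i, , drop = FALSE], n_lv = a_max)
    for (a in seq_len(a_max)) {
      pred[i, , a] <- predict(fit, X[i, , drop = FALSE], n_lv = a)
    }
  }
  per_a <- purrr::map_dfr(seq_len(a_max), function(a) {
    E <- pred[, , a, drop = TRUE] - Y
    E <- matrix(E, nrow = n)
    tibble::tibble(
      n_lv = a,
      component = c(comp, "overall"),
      rmsecv = c(sqrt(colMeans(E^2)), sqrt(mean(E^2)))
    )
  })
  class(per_a) <- c("cv_curve", class(per_a))
  per_a
}

#' Choose the latent-variable count from a CV curve
#'
#' Parsimony rule: the smallest A whose pooled RMSECV is within
#' `threshold_ratio` of the curve minimum, i.e. the first A with
#' `rmsecv <= (1 + threshold_ratio) * min(rmsecv)`.
#'
#' @param curve A [loo_curve()] result (the `"overall"` component is used),
#'   or a bare numeric vector of errors indexed by A.
#' @param threshold_ratio Relative tolerance above the minimum; default 0.02.
#' @return The selected integer A.
#' @examples
#' select_n_lv(c(5, 1, 0.5, 0.49, 0.489), threshold_ratio = 0.05)
#' @export
select_n_lv <- function(curve, threshold_ratio = 0.02) {
  if (inherits(curve, "cv_curve") || is.data.frame(curve)) {
    cv <- curve[curve$component == "overall", ]
    cv <- cv[order(cv$n_lv), ]
    err <- cv$rmsecv
    a_vals <- cv$n_lv
  } else {
    err <- as.numeric(curve)
    a_vals <- seq_along(err)
  }
  if (length(err) == 0) stop("Empty cross-validation curve.", call. = FALSE)
  a_vals[which(err <= (1 + threshold_ratio) * min(err))[1]]
}

#' Calibration-set RMSEC per latent-variable count
#'
#' Root mean squared error of calibration (fitted values against the
#' calibration concentrations) for each A up to `a_max`, pooled across
#' components. Complements [loo_curve()]; both decrease with A, but only
#' the cross-validated curve flattens when components start fitting noise.
#'
#' @inheritParams loo_curve
#' @return Tibble with columns `n_lv` and `rmsec`.
#' @export
rmsec_curve <- function(X, Y, a_max) {
  X <- as.matrix(X); Y <- conc_to_matrix(Y)
  fit <- fit_pls(X, Y, n_lv = a_max)
  purrr::map_dfr(seq_len(a_max), function(a) {
    E <- predict(fit, X, n_lv = a) - Y
    tibble::tibble(n_lv = a, rmsec = sqrt(mean(E^2)))
  })
}

#' Tidy a PLS model's coefficients
#'
#' @param x A `pls_model`.
#' @param ... Unused.
#' @return Long tibble with `wavelength_index`, `component`, `coefficient`
#'   (coefficients apply to centered absorbances).
#' @method tidy pls_model
#' @export
tidy.pls_model <- function(x, ...) {
  comp <- x$component_names %||% paste0("C", seq_len(ncol(x$B)))
  tibble::tibble(
    wavelength_index = rep(seq_len(nrow(x$B)), times = ncol(x$B)),
    component = rep(comp, each = nrow(x$B)),
    coefficient = as.vector(x$B)
  )
}

#' One-row summary of a PLS model
#'
#' @param x A `pls_model`.
#' @param ... Unused.
#' @return Tibble with `n_lv`, `n_wavelengths`, `n_components` and the
#'   fraction of (centered) X variance explained by the scores.
#' @method glance pls_model
#' @export
glance.pls_model <- function(x, ...) {
  tibble::tibble(
    n_lv = x$n_lv,
    n_wavelengths = nrow(x$B),
    n_components = ncol(x$B),
    x_variance_explained = 1 - x$ss_x_residual / x$ss_x_total
  )
}

#' Plot a cross-validation curve
#'
#' @param object A `cv_curve` from [loo_curve()].
#' @param ... Unused.
#' @return A ggplot of RMSECV against latent variables, one line per
#'   component plus the pooled curve.
#' @method autoplot cv_curve
#' @export
autoplot.cv_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$n_lv, .data$rmsecv,
                                       colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Latent variables", y = "RMSECV (µg/mL)") +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
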