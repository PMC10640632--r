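# Shared fixtures, built in code at test time.

# small random linear calibration problem (X full rank, linear Y)
linear_fixture <- function(n = 12, p = 16, m = 3, noise = 0.01, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    B <- matrix(stats::rnorm(p * m), p, m)
    Y <- X %*% B + matrix(stats::rnorm(n * m, 0, noise), n, m)
    colnames(X) <- paste0("w", seq_len(p))
    colnames(Y) <- paste0("c", seq_len(m))
    list(X = X, Y = Y)
  })
}

# the full synthetic study: 25-run design, simulated spectra, 15/10 split
design_data <- function(noise = noise_model(seed = 7), library_seed = 0,
                        split_seed = 1) {
  d <- generate_design(5)
  conc <- realize_concentrations(d, assay_ranges())
  g <- wl_grid(200, 400, 0.2)
  s <- simulate_mixtures(conc, default_library(library_seed), g, noise)
  sw <- select_window(s, 250, 300)
  sp <- split_runs(d, 10, seed = split_seed)
  fac <- setdiff(names(d), "run_id")
  list(design = d, conc = conc, grid = g, spectra = sw,
       X = sw$absorbance, Y = as.matrix(conc[fac]),
       cal = split_indices(sp, "calibration"),
       val = split_indices(sp, "validation"))
}

# Moore-Penrose pseudoinverse via SVD (independent least-squares oracle)
pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
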