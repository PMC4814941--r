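# Shared fixtures: small, fast cohort specifications built in code.

# clean conditions: no jitter, no noise, no wander, no between-subject
# variation — the generator output is exactly the rendered template train
clean_spec <- function(..., jitter_sd_s = 0, seed = 42) {
  cohort_spec(jitter_sd_s = jitter_sd_s, wander_amp = 0, noise_sd = 0,
              subject_amp_sdlog = 0, subject_shape_sd = 0,
              subject_harm_sdlog = 0, subject_harm_phase_sd = 0,
              seed = seed, ...)
}

# a tiny two-group spec with no planted effects (null cohort)
null_spec <- function(n = 8, seed = 42, ...) {
  cohort_spec(n_healthy = n, n_fld = n, effects = list(), seed = seed, ...)
}

# fundamental-frequency amplitude of a tone estimated by discrete Fourier
# analysis (the independent spectral oracle used against the DCT filter)
fft_amplitude <- function(x, fs, freq) {
  n <- length(x)
  sp <- stats::fft(x)
  k <- round(freq * n / fs)
  2 * Mod(sp[k + 1L]) / n
}

# Exhaustive KKT oracle for the lasso: enumerate all sign patterns on <= 5
# features, solve the stationarity system for each, and keep the solution
# whose signs and subgradients are consistent.  Independent of coordinate
# descent.
lasso_kkt_oracle <- function(Z, Y, lambda, tol = 1e-9) {
  p <- ncol(Z)
  stopifnot(p <= 5)
  G <- crossprod(Z)
  g <- drop(crossprod(Z, Y))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), p)))
  for (i in seq_len(nrow(signs))) {
    s <- signs[i, ]
    A <- which(s != 0)
    beta <- numeric(p)
    if (length(A)) {
      sol <- tryCatch(solve(G[A, A, drop = FALSE], g[A] - lambda * s[A]),
                      error = function(e) NULL)
      if (is.null(sol)) next
      if (any(sign(sol) != s[A])) next
      beta[A] <- sol
    }
    grad <- g - drop(G %*% beta)
    if (all(abs(grad[setdiff(seq_len(p), A)]) <= lambda + tol))
      return(beta)
  }
  stop("no KKT-consistent sign pattern found")
}
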