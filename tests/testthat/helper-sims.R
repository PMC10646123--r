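# Shared simulation cache: several test files interrogate the same reference
# runs; each is computed once per test session.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache, inherits = FALSE)) {
    assign(key, expr, envir = .sim_cache)
  }
  get(key, envir = .sim_cache, inherits = FALSE)
}

# Reference 1D run: combined mode, Table-style defaults, 400 cells, 2000 d.
default_run <- function() {
  cached("default", fr_run(fr_config(fr_params())))
}

# Same run with fungal self-inhibition disabled (disk control).
disk_run <- function() {
  cached("disk", fr_run(fr_config(fr_params(s_I = 0, s_F = 0)),
                        keep_snapshots = FALSE))
}

# Brute-force biometrics oracle: plain loops over the arrays, no shared code
# with fr_biometrics().
brute_biometrics <- function(x, F, P, p_inf, eps) {
  n <- length(x)
  mids <- (x[-1] + x[-n]) / 2
  wl <- c(mids, x[n]) - c(x[1], mids)
  FB <- -Inf; iF <- NA
  for (i in seq_len(n)) if (F[i] >= FB) { FB <- F[i]; iF <- i }
  PS <- 0; PI <- 0; BZ <- 0
  for (i in seq_len(n)) {
    if (P[i] - p_inf > PS) PS <- P[i] - p_inf
    if (p_inf - P[i] > PI) PI <- p_inf - P[i]
    if (P[i] < p_inf * (1 - eps)) BZ <- BZ + wl[i]
  }
  iP <- NA
  for (i in seq_len(n)) {
    if (P[i] - p_inf > eps * p_inf && P[i] - p_inf == PS) iP <- i
  }
  RW <- if (is.na(iP)) NA_real_ else abs(x[iF] - x[iP])
  list(FB = FB, PS = PS, PI = PI, BZ = BZ, RW = RW)
}

# Builds a synthetic transect with a fungal pulse and prescribed plant bands.
synthetic_transect <- function(n = 100, f_peak_at = 70, f_amp = 0.5) {
  x <- seq_len(n) - 1
  F <- f_amp * exp(-(x - f_peak_at)^2 / 8)
  F[F < 1e-9] <- 0
  data.frame(x = x, F = F, P = rep(1, n))
}
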