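#' Simulation configuration
#'
#' Bundles the model parameters with the numerical setup: domain geometry,
#' timestep, run length, initial conditions and snapshot frequency. The
#' reference setup is a 400 x 400 lattice (dx = 1 dm, i.e. 0.1 m resolution),
#' dt = 1 d, 2000 days, a fungal inoculum of 0.01 g/dm^2 at the central cell
#' and plants at 1 g/dm^2 everywhere; the 1D transect default (400 cells,
#' inoculum at the first cell) is the fast workhorse for sweeps.
#'
#' The explicit scheme requires the diffusion number
#' `max(D_F, D_P) * dt / dx^2 <= 0.25`; configurations violating it are
#' refused.
#'
#' @param params an [fr_params] object.
#' @param geometry integer vector: length 1 for a 1D transect (number of
#'   cells) or length 2 for a 2D lattice (rows, columns).
#' @param dx grid spacing (dm).
#' @param dt timestep (d).
#' @param n_steps number of timesteps.
#' @param inoculum_amount initial fungal biomass at the inoculum cell
#'   (g/dm^2).
#' @param inoculum_site cell index (1D) or `c(row, col)` (2D); default the
#'   first cell in 1D (front travels inward) and the central cell in 2D.
#' @param initial_plant initial plant biomass everywhere (g/dm^2).
#' @param snapshot_stride record a snapshot every this many steps.
#' @param hypothesis_mode optional; if given, [fr_hypothesis()] is applied to
#'   `params`.
#' @return An object of class `fr_config`.
#' @examples
#' cfg <- fr_config(fr_params(), geometry = 400)
#' @export
fr_config <- function(params = fr_params(),
                      geometry = 400L,
                      dx = 1,
                      dt = 1,
                      n_steps = 2000L,
                      inoculum_amount = 0.01,
                      inoculum_site = NULL,
                      initial_plant = 1,
                      snapshot_stride = 10L,
                      hypothesis_mode = NULL) {
  stopifnot(inherits(params, "fr_params"),
            length(geometry) %in% 1:2, all(geometry >= 3),
            dx > 0, dt > 0, n_steps >= 1,
            inoculum_amount >= 0, initial_plant >= 0, snapshot_stride >= 1)
  if (!is.null(hypothesis_mode)) params <- fr_hypothesis(params, hypothesis_mode)
  geometry <- as.integer(geometry)
  if (is.null(inoculum_site)) {
    inoculum_site <- if (length(geometry) == 1L) 1L else (geometry + 1L) %/% 2L
  }
  inoculum_site <- as.integer(inoculum_site)
  if (length(inoculum_site) != length(geometry) ||
      any(inoculum_site < 1L | inoculum_site > geometry)) {
    stop("'inoculum_site' outside the grid", call. = FALSE)
  }
  mu <- max(params$D_F, params$D_P) * dt / dx^2
  if (mu > 0.25) {
    stop(sprintf(
      "diffusion number D*dt/dx^2 = %.3g exceeds 0.25; reduce dt or coarsen dx",
      mu), call. = FALSE)
  }
  structure(list(params = params, geometry = geometry, dx = dx, dt = dt,
                 n_steps = as.integer(n_steps),
                 inoculum_amount = inoculum_amount,
                 inoculum_site = inoculum_site,
                 initial_plant = initial_plant,
                 snapshot_stride = as.integer(snapshot_stride)),
            class = "fr_config")
}

#' @export
print.fr_config <- function(x, ...) {
  cat("Fairy-ring simulation configuration\n")
  cat("  domain : ", paste(x$geometry, collapse = " x "),
      " cells, dx = ", x$dx, " dm\n", sep = "")
  cat("  time   : dt = ", x$dt, " d, ", x$n_steps, " steps (",
      x$dt * x$n_steps, " d)\n", sep = "")
  cat("  init   : F = ", x$inoculum_amount, " at cell (",
      paste(x$inoculum_site, collapse = ", "), "), P = ",
      x$initial_plant, " everywhere\n", sep = "")
  cat("  params : a = ", x$params$a, ", s_T = ", x$params$s_T,
      ", W = ", x$params$W, ", g_F = ", x$params$g_F, "\n", sep = "")
  invisible(x)
}

#' Initial state of a simulation
#'
#' All fields are zero except the fungal inoculum (a single cell) and the
#' plant cover (uniform).
#'
#' @param config an [fr_config] object.
#' @return A named list of six fields `F, I, T, S, P, N`, each a vector (1D)
#'   or matrix (2D).
#' @export
fr_initialize <- function(config) {
  stopifnot(inherits(config, "fr_config"))
  g <- config$geometry
  zero <- if (length(g) == 1L) numeric(g) else matrix(0, g[1L], g[2L])
  F <- zero
  if (length(g) == 1L) {
    F[config$inoculum_site] <- config$inoculum_amount
  } else {
    F[config$inoculum_site[1L], config$inoculum_site[2L]] <-
      config$inoculum_amount
  }
  P <- zero + config$initial_plant
  list(F = F, I = zero, T = zero, S = zero, P = P, N = zero)
}

#' One forward-Euler step of the full model
#'
#' Available water is evaluated once from the fungal field at the start of the
#' step; all six reactions are then computed from the same snapshot
#' (frozen-coefficient scheme), fungus and plants additionally diffuse, and
#' the updated fields are clipped at zero (explicit Euler can overshoot
#' mortality terms near zero).
#'
#' @param state named list of the six fields (see [fr_initialize()]).
#' @param params an [fr_params] object.
#' @param dt timestep (d).
#' @param dx grid spacing (dm).
#' @return The updated state list.
#' @export
fr_step <- function(state, params, dt = 1, dx = 1) {
  F <- state$F; I <- state$I; T <- state$T
  S <- state$S; P <- state$P; N <- state$N
  W_bar <- available_water(F, params)
  F2 <- F + dt * (fungus_reaction(F, I, params) +
                    params$D_F * laplacian(F, dx))
  I2 <- I + dt * inhibitor_reaction(F, I, W_bar, params)
  T2 <- T + dt * toxin_reaction(F, T, W_bar, params)
  S2 <- S + dt * stimulant_reaction(F, S, params)
  P2 <- P + dt * (plant_reaction(P, W_bar, S, N, T, params) +
                    params$D_P * laplacian(P, dx))
  N2 <- N + dt * nutrient_reaction(P, N, T, W_bar, params)
  if (!all(is.finite(F2)) || !all(is.finite(P2))) {
    stop("non-finite values encountered: the explicit scheme blew up",
         call. = FALSE)
  }
  list(F = pmax(F2, 0), I = pmax(I2, 0), T = pmax(T2, 0),
       S = pmax(S2, 0), P = pmax(P2, 0), N = pmax(N2, 0))
}

#' Outermost position of the fungal front
#'
#' The front position is the largest distance from the inoculum at which
#' fungal biomass still reaches `threshold` (default 1e-3 g/dm^2, 10% of the
#' standard inoculum). Returns 0 if the fungus is nowhere above threshold.
#'
#' @param F fungal field (vector or matrix).
#' @param site inoculum cell (index or `c(row, col)`).
#' @param dx grid spacing (dm).
#' @param threshold detection threshold (g/dm^2).
#' @return Distance (dm) from the inoculum cell to the outermost detected cell.
#' @export
front_position <- function(F, site, dx = 1, threshold = 1e-3) {
  if (is.matrix(F)) {
    idx <- which(F >= threshold, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(0)
    max(sqrt((idx[, 1L] - site[1L])^2 + (idx[, 2L] - site[2L])^2)) * dx
  } else {
    idx <- which(F >= threshold)
    if (length(idx) == 0L) return(0)
    max(abs(idx - site[1L])) * dx
  }
}

#' Run a fairy-ring simulation
#'
#' Integrates the six-equation model from [fr_initialize()] with forward
#' Euler, recording snapshots and the fungal front position.
#'
#' @param config an [fr_config] object.
#' @param keep_snapshots logical; if `FALSE` only the final state, times and
#'   front positions are kept (lighter for sweeps).
#' @param front_threshold fungal biomass threshold (g/dm^2) used for front
#'   tracking.
#' @return An object of class `fr_sim`: a list with elements `config`,
#'   `times` (d), `front_positions` (dm), `snapshots` (list of state lists, or
#'   `NULL`), and `final` (the final state list).
#' @examples
#' \donttest{
#' cfg <- fr_config(fr_params(), geometry = 400, n_steps = 2000)
#' sim <- fr_run(cfg)
#' summary(sim)
#' }
#' @export
fr_run <- function(config, keep_snapshots = TRUE, front_threshold = 1e-3) {
  stopifnot(inherits(config, "fr_config"))
  p <- config$params
  dt <- config$dt; dx <- config$dx
  state <- fr_initialize(config)
  stride <- config$snapshot_stride
  rec_steps <- seq(0L, config$n_steps, by = stride)
  if (rec_steps[length(rec_steps)] != config$n_steps) {
    rec_steps <- c(rec_steps, config$n_steps)
  }
  times <- rec_steps * dt
  fronts <- numeric(length(rec_steps))
  snaps <- if (keep_snapshots) vector("list", length(rec_steps)) else NULL
  ri <- 1L
  record <- function(i) {
    fronts[ri] <<- front_position(state$F, config$inoculum_site, dx,
                                  front_threshold)
    if (keep_snapshots) snaps[[ri]] <<- state
    ri <<- ri + 1L
  }
  record(0L)
  for (i in seq_len(config$n_steps)) {
    state <- fr_step(state, p, dt, dx)
    if (ri <= length(rec_steps) && i == rec_steps[ri]) record(i)
  }
  structure(list(config = config, times = times, front_positions = fronts,
                 snapshots = snaps, final = state,
                 front_threshold = front_threshold),
            class = "fr_sim")
}

#' @export
print.fr_sim <- function(x, ...) {
  g <- x$config$geometry
  cat("Fairy-ring simulation: ", paste(g, collapse = " x "), " cells, ",
      max(x$times), " d\n", sep = "")
  cat("  final front position: ",
      format(x$front_positions[length(x$front_positions)]), " dm\n", sep = "")
  cat("  final fungal peak   : ", format(max(x$final$F), digits = 4),
      " g/dm^2\n", sep = "")
  invisible(x)
}

#' @export
summary.fr_sim <- function(object, ...) {
  fin <- object$final
  out <- list(
    days = max(object$times),
    geometry = object$config$geometry,
    front_position = object$front_positions[length(object$front_positions)],
    front_speed = tryCatch(front_speed(object)$speed, error = function(e) NA_real_),
    peaks = vapply(fin, max, numeric(1)),
    totals = vapply(fin, sum, numeric(1)) * object$config$dx^
      length(object$config$geometry)
  )
  class(out) <- "summary.fr_sim"
  out
}

#' @export
print.summary.fr_sim <- function(x, ...) {
  cat("Fairy-ring simulation after", x$days, "d on a",
      paste(x$geometry, collapse = " x "), "grid\n")
  cat(sprintf("  front position: %.1f dm  (speed %.4f dm/d)\n",
              x$front_position, x$front_speed))
  cat("  field maxima (g/dm^2):\n")
  print(round(x$peaks, 4))
  invisible(x)
}

#' @export
plot.fr_sim <- function(x, which = c("transect", "front"), ...) {
  which <- match.arg(which)
  if (which == "front") {
    graphics::plot(x$times, x$front_positions, type = "l",
                   xlab = "time (d)", ylab = "front position (dm)", ...)
    return(invisible(x))
  }
  tr <- final_transect(x)
  graphics::plot(tr$x, tr$P, type = "l", col = "forestgreen", lwd = 2,
                 xlab = "distance from inoculum (dm)",
                 ylab = expression(biomass ~ (g ~ dm^-2)),
                 ylim = range(0, tr$P, tr$F), ...)
  graphics::lines(tr$x, tr$F, col = "firebrick", lwd = 2, lty = 2)
  graphics::legend("topright", c("plants P", "fungus F"),
                   col = c("forestgreen", "firebrick"), lty = c(1, 2),
                   lwd = 2, bty = "n")
  invisible(x)
}

#' Extract the final biomass transect from a simulation
#'
#' For a 1D run, the domain itself; for a 2D run, the axis-aligned ray from
#' the inoculum cell to the right-hand domain edge.
#'
#' @param sim an `fr_sim` object.
#' @return A data frame with columns `x` (dm from the inoculum), `F`, `P`,
#'   and attributes `time` (d) and `params`.
#' @export
final_transect <- function(sim) {
  stopifnot(inherits(sim, "fr_sim"))
  g <- sim$config$geometry
  st <- sim$final
  if (length(g) == 1L) {
    s <- sim$config$inoculum_site[1L]
    idx <- s:g
    F <- st$F[idx]; P <- st$P[idx]
  } else {
    r <- sim$config$inoculum_site[1L]; cc <- sim$config$inoculum_site[2L]
    idx <- cc:g[2L]
    F <- st$F[r, idx]; P <- st$P[r, idx]
  }
  tr <- data.frame(x = (seq_along(idx) - 1) * sim$config$dx, F = F, P = P)
  attr(tr, "time") <- max(sim$times)
  attr(tr, "params") <- sim$config$params
  tr
}

#' Shape drift of the fungal front in the co-moving frame
#'
#' After the initial transient the fungal front travels with constant shape.
#' This is assessed by comparing the first snapshot in `window` against every
#' later snapshot, shifted by an integer number of cells: because the pulse is
#' only a few cells wide, grid sampling aliases profiles displaced by a
#' fractional number of cells, so the comparison is made at the
#' near-commensurate displacement (the pair/shift with the smallest sup-norm
#' difference). For a true travelling wave this minimum is small; a front that
#' grows, decays or changes shape cannot score low for any displacement.
#'
#' @param sim a 1D `fr_sim` run with snapshots.
#' @param window time window (d); default the last half of the run.
#' @param min_shift smallest displacement (cells) considered, so that the
#'   trivial zero-shift comparison is excluded.
#' @return A list with `drift` (sup-norm difference divided by the front
#'   amplitude), `times` (the snapshot pair used) and `shift` (cells).
#' @export
front_profile_drift <- function(sim, window = NULL, min_shift = 5L) {
  stopifnot(inherits(sim, "fr_sim"), length(sim$config$geometry) == 1L)
  if (is.null(sim$snapshots)) {
    stop("run with keep_snapshots = TRUE to assess profile drift",
         call. = FALSE)
  }
  if (is.null(window)) window <- c(max(sim$times) / 2, max(sim$times))
  idx <- which(sim$times >= window[1L] & sim$times <= window[2L])
  if (length(idx) < 2L) stop("need >= 2 snapshots in the window", call. = FALSE)
  f1 <- sim$snapshots[[idx[1L]]]$F
  amp <- max(f1)
  if (amp <= 0) stop("no fungal front in the window", call. = FALSE)
  n <- length(f1)
  best <- Inf; best_pair <- c(NA_real_, NA_real_); best_shift <- NA_integer_
  for (j in idx[-1L]) {
    f2 <- sim$snapshots[[j]]$F
    s0 <- which.max(f2) - which.max(f1)
    for (s in unique(pmax(min_shift, s0 + (-1:1)))) {
      if (s >= n - 2L) next
      d <- max(abs(f2[(s + 1L):n] - f1[1:(n - s)])) / amp
      if (d < best) {
        best <- d
        best_pair <- c(sim$times[idx[1L]], sim$times[j])
        best_shift <- s
      }
    }
  }
  if (!is.finite(best)) {
    stop("front displacement never reached 'min_shift' cells in the window",
         call. = FALSE)
  }
  list(drift = best, times = best_pair, shift = best_shift)
}

#' Front speed from a trajectory
#'
#' Least-squares slope of the recorded front position against time over a
#' window. After the initial transient the fungal front is a travelling wave,
#' so the fit should be nearly perfect (the R-squared is returned so the
#' constancy of the speed can be checked).
#'
#' @param sim an `fr_sim` object.
#' @param window numeric length-2: time window (d); default the last half of
#'   the run.
#' @return A list with `speed` (dm/d), `r_squared`, and `n` (snapshots used).
#' @export
front_speed <- function(sim, window = NULL) {
  stopifnot(inherits(sim, "fr_sim"))
  if (is.null(window)) window <- c(max(sim$times) / 2, max(sim$times))
  keep <- sim$times >= window[1L] & sim$times <= window[2L]
  if (sum(keep) < 3L) stop("need >= 3 snapshots in the window", call. = FALSE)
  t <- sim$times[keep]; y <- sim$front_positions[keep]
  g <- sim$config$geometry
  max_extent <- if (length(g) == 1L) {
    (g - sim$config$inoculum_site[1L]) * sim$config$dx
  } else {
    (min(g - sim$config$inoculum_site) ) * sim$config$dx
  }
  if (max(y) >= max_extent - sim$config$dx) {
    stop("front reached the domain boundary inside the window; speed would be contaminated",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ t)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(speed = unname(stats::coef(fit)[2L]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       n = sum(keep))
}
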