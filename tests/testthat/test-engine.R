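test_that("configuration enforces the explicit-scheme stability bound", {
  expect_error(fr_config(fr_params(D_F = 0.3), dt = 1, dx = 1),
               "exceeds 0.25")
  expect_error(fr_config(fr_params(), dx = 0.1), "exceeds 0.25")
  expect_silent(fr_config(fr_params(), dx = 0.5, n_steps = 10))
  expect_error(fr_config(fr_params(), geometry = 400L, inoculum_site = 401L),
               "outside the grid")
})

test_that("initial conditions place the inoculum and uniform sward", {
  st <- fr_initialize(fr_config(fr_params(), geometry = c(9L, 9L)))
  expect_equal(sum(st$F), 0.01)
  expect_equal(st$F[5, 5], 0.01)
  expect_equal(range(st$P), c(1, 1))
  expect_true(all(st$I == 0) && all(st$T == 0) && all(st$S == 0) &&
                all(st$N == 0))
  st1 <- fr_initialize(fr_config(fr_params(), geometry = 50L))
  expect_equal(st1$F[1], 0.01)     # transect mode: front travels inward
  expect_equal(sum(st1$F), 0.01)
})

test_that("the all-zero state is a fixed point and zero inoculum stays fungus-free", {
  p <- fr_params()
  z <- lapply(stats::setNames(nm = c("F", "I", "T", "S", "P", "N")),
              function(nm) rep(0, 10))
  expect_equal(fr_step(z, p), z)
  sim <- fr_run(fr_config(fr_params(), geometry = 30L, n_steps = 50L,
                          inoculum_amount = 0), keep_snapshots = FALSE)
  expect_equal(sum(sim$final$F), 0)
})

test_that("one step from a heterogeneous state matches a symbol-by-symbol oracle", {
  p <- fr_params()
  F <- c(0.02, 0.45, 0.10, 0.00, 0.30, 0.05)
  I <- c(0.30, 0.05, 0.00, 0.02, 0.10, 0.00)
  T <- c(0.40, 0.20, 0.05, 0.00, 0.10, 0.01)
  S <- c(0.10, 0.30, 0.02, 0.00, 0.05, 0.00)
  P <- c(0.05, 0.20, 0.90, 1.10, 0.70, 1.00)
  N <- c(0.25, 0.10, 0.05, 0.20, 0.00, 0.15)
  got <- fr_step(list(F = F, I = I, T = T, S = S, P = P, N = N), p,
                 dt = 1, dx = 1)
  # independent recomputation: explicit formulas, mirrored ghost cells
  n <- length(F)
  for (i in c(1L, 3L, 6L)) {
    il <- max(i - 1L, 1L); ir <- min(i + 1L, n)
    wb <- if (p$a * F[i] < p$W) 1 - p$b^(p$a * F[i] - p$W) else 0
    dF <- p$g_F * F[i] * (1 - p$s_I * I[i]) * p$W / (p$W + p$k_W) -
      p$d_F * F[i]^2 - p$s_F * F[i] * I[i] +
      p$D_F * (F[il] + F[ir] - 2 * F[i])
    dI <- p$c_I * (p$d_F * F[i]^2 + p$s_F * F[i] * I[i]) -
      p$k_I * I[i] - p$l_I * I[i] * wb
    dT <- p$c_T * F[i] - p$k_T * T[i] - p$l_T * T[i] * wb
    dS <- p$c_S * F[i] - p$k_S * S[i]
    dP <- p$g_P * P[i] * (wb * (p$q_P + S[i] + N[i]) - P[i]) -
      p$s_T * T[i] * P[i] + p$D_P * (P[il] + P[ir] - 2 * P[i])
    dN <- p$g_N * (p$g_P * P[i]^2 + p$s_T * P[i] * T[i]) * wb -
      p$u_N * p$g_P * wb * P[i] * N[i] - p$l_N * N[i] * wb
    expect_equal(got$F[i], max(F[i] + dF, 0))
    expect_equal(got$I[i], max(I[i] + dI, 0))
    expect_equal(got$T[i], max(T[i] + dT, 0))
    expect_equal(got$S[i], max(S[i] + dS, 0))
    expect_equal(got$P[i], max(P[i] + dP, 0))
    expect_equal(got$N[i], max(N[i] + dN, 0))
  }
})

test_that("fungus and plants diffuse conservatively, chemicals do not move", {
  p <- fr_params()
  st <- list(F = c(0, 0, 0.4, 0, 0), I = c(0, 0, 0.2, 0, 0),
             T = c(0, 0, 0.2, 0, 0), S = c(0, 0, 0.2, 0, 0),
             P = c(0, 0, 0.5, 0, 0), N = c(0, 0, 0.2, 0, 0))
  st2 <- fr_step(st, p)
  expect_gt(st2$F[2], 0)  # fungus spreads
  expect_gt(st2$P[2], 0)  # plants spread
  expect_equal(st2$I[2], 0)
  expect_equal(st2$T[2], 0)
  expect_equal(st2$S[2], 0)
  expect_equal(st2$N[2], 0)
})

test_that("a fungus-free sward relaxes to the closed-form baseline", {
  cfg <- fr_config(fr_params(), geometry = 40L, n_steps = 2000L,
                   inoculum_amount = 0)
  sim <- fr_run(cfg, keep_snapshots = FALSE)
  pb <- plant_baseline(fr_params())
  expect_lt(max(abs(sim$final$P - pb)), 1e-6)
  expect_lt(diff(range(sim$final$P)), 1e-12)  # stays uniform
  # approach is monotone in the sup distance to the fixed point
  sim2 <- fr_run(fr_config(fr_params(), geometry = 20L, n_steps = 300L,
                           inoculum_amount = 0, snapshot_stride = 50L))
  d <- vapply(sim2$snapshots, function(s) max(abs(s$P - pb)), numeric(1))
  expect_true(all(diff(d) <= 1e-12))
})

test_that("identical configurations give bit-identical trajectories", {
  cfg <- fr_config(fr_params(), geometry = 60L, n_steps = 300L)
  s1 <- fr_run(cfg)
  s2 <- fr_run(cfg)
  expect_identical(s1$final, s2$final)
  expect_identical(s1$front_positions, s2$front_positions)
})

test_that("blow-up is reported rather than silently propagated", {
  st <- list(F = c(0, 1e200, 0), I = rep(0, 3), T = rep(0, 3),
             S = rep(0, 3), P = rep(1, 3), N = rep(0, 3))
  expect_error(fr_step(st, fr_params()), "non-finite")
})

test_that("front position and speed recover a synthetic linear trajectory", {
  times <- seq(0, 1000, by = 10)
  sim <- structure(list(
    config = fr_config(fr_params(), geometry = 400L),
    times = times,
    front_positions = 0.4 * times,
    snapshots = NULL, final = NULL, front_threshold = 1e-3
  ), class = "fr_sim")
  fs <- front_speed(sim, window = c(0, 900))
  expect_equal(fs$speed, 0.4)
  expect_equal(fs$r_squared, 1)
  # window touching the boundary is refused
  expect_error(front_speed(sim, window = c(0, 1000)),
               "reached the domain boundary")
  expect_error(front_speed(sim, window = c(0, 15)), ">= 3 snapshots")
  # front_position itself
  F <- rep(0, 50); F[c(3, 20)] <- c(0.5, 0.002)
  expect_equal(front_position(F, site = 1L, dx = 1), 19)
  expect_equal(front_position(F, site = 1L, dx = 1, threshold = 0.1), 2)
  expect_equal(front_position(rep(0, 50), site = 1L), 0)
})

test_that("front speed increases with the fungal growth rate", {
  s_slow <- cached("run_gF_0.02",
                   fr_run(fr_config(fr_params(g_F = 0.02)),
                          keep_snapshots = FALSE))
  s_fast <- cached("run_gF_0.04",
                   fr_run(fr_config(fr_params(g_F = 0.04)),
                          keep_snapshots = FALSE))
  v1 <- front_speed(s_slow, c(1000, 1800))$speed
  v2 <- front_speed(s_fast, c(1000, 1800))$speed
  expect_gt(v2, v1)
})

test_that("refinement: smooth dynamics agree exactly, the front speed is stable", {
  # fungus-free sward: dt-halving is invisible at the fixed point
  u1 <- fr_run(fr_config(fr_params(), geometry = 20L, n_steps = 2000L,
                         inoculum_amount = 0, dt = 1), keep_snapshots = FALSE)
  u2 <- fr_run(fr_config(fr_params(), geometry = 20L, n_steps = 4000L,
                         inoculum_amount = 0, dt = 0.5), keep_snapshots = FALSE)
  expect_lt(max(abs(u1$final$P - u2$final$P)), 1e-9)
  # travelling front: speed within 5% under dt-halving, 10% under dx-halving
  v_ref <- front_speed(default_run(), c(1000, 1800))$speed
  s_dt <- cached("run_dt_half",
                 fr_run(fr_config(fr_params(), dt = 0.5, n_steps = 4000L),
                        keep_snapshots = FALSE))
  v_dt <- front_speed(s_dt, c(1000, 1800))$speed
  expect_lt(abs(v_dt - v_ref) / v_ref, 0.05)
  s_dx <- cached("run_dx_half",
                 fr_run(fr_config(fr_params(), geometry = 200L, dx = 0.5,
                                  n_steps = 2000L), keep_snapshots = FALSE))
  v_dx <- front_speed(s_dx, c(800, 1600))$speed
  expect_lt(abs(v_dx - v_ref) / v_ref, 0.10)
})

test_that("2D fields with a central inoculum stay four-fold symmetric", {
  cfg <- fr_config(fr_params(), geometry = c(61L, 61L), n_steps = 600L)
  sim <- fr_run(cfg, keep_snapshots = FALSE)
  rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
  for (f in c("F", "P", "I", "N")) {
    m <- sim$final[[f]]
    expect_lt(max(abs(m - rot90(m))), 1e-12 * max(1, max(abs(m))))
  }
  expect_gt(max(sim$final$F), 0.01)  # the colony actually grew
})

test_that("the 1D transect reproduces the 2D radial band ordering", {
  sim2d <- cached("run_2d_101",
                  fr_run(fr_config(fr_params(), geometry = c(101L, 101L),
                                   n_steps = 1000L), keep_snapshots = FALSE))
  sim1d <- cached("run_1d_1000",
                  fr_run(fr_config(fr_params(), n_steps = 1000L),
                         keep_snapshots = FALSE))
  for (tr in list(final_transect(sim2d), final_transect(sim1d))) {
    iF <- which.max(tr$F)
    expect_gt(iF, 2)                        # ring: peak away from the centre
    expect_lt(tr$F[1], 0.5 * max(tr$F))     # interior die-back
    iTrough <- which.min(tr$P)
    expect_lt(abs(iTrough - iF), 6)         # plant trough rides the front
    expect_gt(tr$P[length(tr$P)], tr$P[iTrough])  # far field intact
  }
})

test_that("co-moving front profile drift is small for the reference run", {
  d <- front_profile_drift(default_run(), window = c(1000, 1800))
  expect_lt(d$drift, 0.02)
  expect_gte(d$shift, 5L)
})
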