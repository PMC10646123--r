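#' Experiment presets
#'
#' Named, reproducible experiment grids mirroring the published analyses:
#' \describe{
#'   \item{fig4_hydrophobicity}{hydrophobicity-only panel: `s_T = 0`,
#'     `W` over \[0.1, 2\] (6 levels) x `g_F` over \[0.01, 0.05\] (5 levels)}
#'   \item{fig5_phytotoxicity}{phytotoxicity-only panel: `a = 0`,
#'     `s_T` over \[0.9, 1.3\] (3 levels) x `g_F` (5 levels)}
#'   \item{fig6_combined}{combined panel: `a = 2`, `s_T` over \[0.1, 0.5\]
#'     (3 levels) x `W` (6 levels) x `g_F` (5 levels)}
#'   \item{type13_demo}{the strong-stimulant parameterization
#'     (`c_S = 0.8, k_S = 1, g_N = 0.2, W = 2, g_F = 0.05`, combined mode)
#'     that produces the rare type 1.3 ring}
#'   \item{ring_vs_disk}{two runs contrasting the default (self-inhibited)
#'     fungus, which grows as a ring, with `s_I = s_F = 0`, which grows as a
#'     disk}
#'   \item{heatmap}{the full one-at-a-time sensitivity analysis over every
#'     model parameter}
#' }
#'
#' @param name preset name (see above).
#' @param geometry passed to [fr_config()]; default 1D, 400 cells.
#' @param n_steps simulation length (d).
#' @param eps classification tolerance.
#' @param verbose print a line per run.
#' @return For the panel presets: an object of class `fr_panel`, a data frame
#'   with one row per grid cell (`s_T`, `W`, `g_F`, the five biometrics and
#'   the `type` label). For `type13_demo`: an `fr_sim` with the biometrics
#'   and label attached as attributes. For `ring_vs_disk`: a list of two
#'   `fr_sim` objects (`ring`, `disk`). For `heatmap`: an [fr_sensitivity]
#'   object.
#' @examples
#' \donttest{
#' pan <- fr_preset("fig5_phytotoxicity")
#' table(pan$type)
#' }
#' @export
fr_preset <- function(name = c("fig4_hydrophobicity", "fig5_phytotoxicity",
                               "fig6_combined", "type13_demo", "ring_vs_disk",
                               "heatmap"),
                      geometry = 400L, n_steps = 2000L, eps = 0.02,
                      verbose = FALSE) {
  name <- match.arg(name)
  Ws <- seq(0.1, 2, length.out = 6)
  gFs <- seq(0.01, 0.05, length.out = 5)
  switch(name,
    fig4_hydrophobicity = fr_panel(
      expand.grid(s_T = 0, W = Ws, g_F = gFs), a = 2,
      geometry = geometry, n_steps = n_steps, eps = eps, verbose = verbose),
    fig5_phytotoxicity = fr_panel(
      expand.grid(s_T = seq(0.9, 1.3, length.out = 5), W = 1, g_F = gFs),
      a = 0,
      geometry = geometry, n_steps = n_steps, eps = eps, verbose = verbose),
    fig6_combined = fr_panel(
      expand.grid(s_T = c(0.1, 0.3, 0.5), W = Ws, g_F = gFs), a = 2,
      geometry = geometry, n_steps = n_steps, eps = eps, verbose = verbose),
    type13_demo = {
      cfg <- fr_config(fr_params(c_S = 0.8, k_S = 1, g_N = 0.2, W = 2,
                                 g_F = 0.05),
                       geometry = geometry, n_steps = n_steps)
      sim <- fr_run(cfg, keep_snapshots = FALSE)
      b <- fr_biometrics(final_transect(sim), eps = eps)
      attr(sim, "biometrics") <- b
      attr(sim, "type") <- fr_classify(b)
      sim
    },
    ring_vs_disk = {
      ring <- fr_run(fr_config(fr_params(), geometry = geometry,
                               n_steps = n_steps), keep_snapshots = FALSE)
      disk <- fr_run(fr_config(fr_params(s_I = 0, s_F = 0),
                               geometry = geometry, n_steps = n_steps),
                     keep_snapshots = FALSE)
      list(ring = ring, disk = disk)
    },
    heatmap = fr_sensitivity(config = fr_config(fr_params(),
                                                geometry = geometry,
                                                n_steps = n_steps),
                             eps = eps, verbose = verbose)
  )
}

#' Run a classification panel over a parameter grid
#'
#' One 1D (or 2D) simulation per row of `grid`, classified at the final time.
#'
#' @param grid data frame of parameter columns (any [fr_params()] names);
#'   each row is one run.
#' @param ... fixed parameter overrides applied to every run (e.g. `a = 2`).
#' @param geometry,n_steps passed to [fr_config()].
#' @param eps classification tolerance.
#' @param verbose print one line per run.
#' @return An `fr_panel` data frame: the grid columns plus `FB`, `PS`, `PI`,
#'   `BZ`, `RW` and `type` (`NA` with a message in `note` if a run failed).
#' @export
fr_panel <- function(grid, ..., geometry = 400L, n_steps = 2000L,
                     eps = 0.02, verbose = FALSE) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L)
  fixed <- list(...)
  out <- grid
  out$FB <- out$PS <- out$PI <- out$BZ <- out$RW <- NA_real_
  out$type <- NA_character_
  out$note <- ""
  for (i in seq_len(nrow(grid))) {
    overrides <- c(as.list(grid[i, , drop = FALSE]), fixed)
    res <- tryCatch({
      cfg <- fr_config(do.call(fr_params, overrides), geometry = geometry,
                       n_steps = n_steps)
      sim <- fr_run(cfg, keep_snapshots = FALSE)
      b <- fr_biometrics(final_transect(sim), eps = eps)
      list(b = b, lab = as.character(fr_classify(b)))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$note[i] <- conditionMessage(res)
    } else {
      out[i, c("FB", "PS", "PI", "BZ", "RW")] <-
        res$b[c("FB", "PS", "PI", "BZ", "RW")]
      out$type[i] <- res$lab
    }
    if (verbose) {
      message(sprintf("[%d/%d] %s -> %s", i, nrow(grid),
                      paste(names(grid), unlist(grid[i, ]), sep = "=",
                            collapse = " "),
                      if (is.na(out$type[i])) out$note[i] else out$type[i]))
    }
  }
  class(out) <- c("fr_panel", "data.frame")
  out
}

#' @export
print.fr_panel <- function(x, ...) {
  cat("Fairy-ring classification panel (", nrow(x), " runs)\n", sep = "")
  cat("type counts:\n")
  print(table(x$type, useNA = "ifany"))
  NextMethod()
  invisible(x)
}
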