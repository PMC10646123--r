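#' Closed-form fungus-free plant steady state
#'
#' With no fungus the available water is `W_bar = 1 - b^(-W)` and plants and
#' nutrients settle on the coupled fixed point
#' `P* = W_bar * (q_P + N*)` with
#' `N* = g_N * g_P * P*^2 / (u_N * g_P * P* + l_N)`:
#' logistic plant turnover keeps releasing nutrients even without fungal
#' mortality, so the baseline sits above the water-limited capacity
#' `W_bar * q_P` whenever `g_N > 0` (and equals it when `g_N = 0`).
#'
#' @param params an [fr_params] object.
#' @return The baseline plant biomass `P*` (g/dm^2).
#' @examples
#' plant_baseline(fr_params(g_N = 0)) # (1 - b^-W) * q_P
#' @export
plant_baseline <- function(params) {
  wb <- 1 - params$b^(-params$W)
  if (wb <= 0) return(0)
  nstar <- function(P) {
    params$g_N * params$g_P * P^2 / (params$u_N * params$g_P * P + params$l_N)
  }
  P <- wb * params$q_P
  if (params$g_N == 0) return(P)
  for (i in 1:500) {
    P_new <- wb * (params$q_P + nstar(P))
    if (abs(P_new - P) < 1e-14) return(P_new)
    P <- P_new
  }
  warning("plant_baseline: fixed-point iteration did not fully converge")
  P
}

#' Empirical plant baseline of a transect
#'
#' Mean plant biomass over the fungus-free far field: the cells beyond the
#' fungal front (plus a small buffer) where `F` is below the detection
#' threshold. This is the "near unstimulated vegetation" against which
#' stimulation and inhibition are measured.
#'
#' @param transect data frame with columns `x` (dm, strictly increasing),
#'   `F`, `P` (g/dm^2), e.g. from [final_transect()].
#' @param front_threshold fungal detection threshold (g/dm^2).
#' @param buffer number of cells skipped just beyond the front before the
#'   far-field average starts (plant diffusion smears the pattern slightly
#'   past the fungal front).
#' @return The far-field mean of `P` (g/dm^2).
#' @export
fr_baseline <- function(transect, front_threshold = 1e-3, buffer = 10L) {
  check_transect(transect)
  n <- nrow(transect)
  det <- which(transect$F >= front_threshold)
  first_far <- if (length(det)) max(det) + 1L + buffer else 1L
  if (n - first_far + 1L < ceiling(0.1 * n)) {
    stop("fungal front too close to the far boundary: no fungus-free far field (need >= 10% of the domain)",
         call. = FALSE)
  }
  mean(transect$P[first_far:n])
}

check_transect <- function(transect) {
  if (!is.data.frame(transect) || !all(c("x", "F", "P") %in% names(transect))) {
    stop("'transect' must be a data frame with columns x, F, P", call. = FALSE)
  }
  if (nrow(transect) < 3L || any(diff(transect$x) <= 0)) {
    stop("'x' must be strictly increasing with >= 3 points", call. = FALSE)
  }
  invisible(transect)
}

#' Biometric indicators of a fairy-ring transect
#'
#' Computes the five field-measurable indicators from a plant/fungus biomass
#' transect:
#' \describe{
#'   \item{FB}{fungal biomass: the peak of `F` (g/dm^2)}
#'   \item{PS}{plant stimulation: maximum of `P - P_inf` over the transect
#'     (0 if plants never exceed the baseline)}
#'   \item{PI}{plant inhibition: maximum of `P_inf - P` (0 if plants never
#'     drop below the baseline)}
#'   \item{BZ}{bare-zone width: total width (dm) where
#'     `P < P_inf * (1 - eps)`}
#'   \item{RW}{ring width: distance (dm) between the fungal and plant biomass
#'     peaks; `NA` when no stimulated band exists (no plant peak to measure
#'     to)}
#' }
#' plus the baseline `P_inf` and the band structure: the maximal runs where
#' `P` deviates from the baseline by more than `eps * P_inf`, each tagged
#' `stimulated`/`inhibited` and `ahead`/`behind` relative to the fungal peak
#' (ahead = larger `x`, the direction of front propagation).
#'
#' Ties among identical global maxima are broken toward the front (largest
#' `x`).
#'
#' @param transect data frame with columns `x`, `F`, `P`.
#' @param eps significance tolerance as a fraction of the baseline (default
#'   0.02); deviations smaller than `eps * P_inf` are ignored.
#' @param baseline optional pre-computed baseline; defaults to
#'   [fr_baseline()] of the transect.
#' @param front_threshold fungal detection threshold passed to
#'   [fr_baseline()].
#' @return An object of class `fr_biometrics`: a list with elements `FB`,
#'   `PS`, `PI`, `BZ`, `RW`, `P_inf`, `eps` and `bands` (a data frame with
#'   columns `kind`, `side`, `extreme`, `extent`, `x_from`, `x_to`).
#' @examples
#' tr <- data.frame(x = 0:99, F = dnorm(0:99, 50, 3),
#'                  P = 1 - 0.4 * dnorm(0:99, 50, 2) / dnorm(0, 0, 2))
#' fr_biometrics(tr, baseline = 1)
#' @export
fr_biometrics <- function(transect, eps = 0.02, baseline = NULL,
                          front_threshold = 1e-3) {
  check_transect(transect)
  if (!(eps > 0 && eps < 0.2)) stop("'eps' must be in (0, 0.2)", call. = FALSE)
  x <- transect$x; F <- transect$F; P <- transect$P
  p_inf <- if (is.null(baseline)) {
    fr_baseline(transect, front_threshold = front_threshold)
  } else baseline
  # cell widths from midpoints between neighbours (uniform grids give dx)
  mids <- (x[-1] + x[-length(x)]) / 2
  wl <- c(mids, x[length(x)]) - c(x[1], mids)

  i_F <- which(F == max(F)); i_F <- i_F[length(i_F)]  # tie -> nearest front
  FB <- F[i_F]
  dev <- P - p_inf
  PS <- max(c(dev, 0))
  PI <- max(c(-dev, 0))
  BZ <- sum(wl[P < p_inf * (1 - eps)])

  tol <- eps * p_inf
  lab <- integer(length(P))
  lab[dev > tol] <- 1L
  lab[dev < -tol] <- -1L
  bands <- band_runs(lab, x, wl, dev, i_F)

  RW <- NA_real_
  if (any(bands$kind == "stimulated")) {
    i_P <- which(dev == PS & dev > tol)
    if (length(i_P)) {
      i_P <- i_P[length(i_P)]
      RW <- abs(x[i_F] - x[i_P])
    }
  }
  structure(list(FB = FB, PS = PS, PI = PI, BZ = BZ, RW = RW,
                 P_inf = p_inf, eps = eps, bands = bands),
            class = "fr_biometrics")
}

band_runs <- function(lab, x, wl, dev, i_F) {
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  out <- data.frame(kind = character(0), side = character(0),
                    extreme = numeric(0), extent = numeric(0),
                    x_from = numeric(0), x_to = numeric(0),
                    stringsAsFactors = FALSE)
  for (k in which(keep)) {
    idx <- starts[k]:ends[k]
    d <- dev[idx]
    i_ext <- idx[which.max(abs(d))]
    out <- rbind(out, data.frame(
      kind = if (r$values[k] > 0L) "stimulated" else "inhibited",
      side = if (i_ext > i_F) "ahead" else "behind",
      extreme = dev[i_ext],
      extent = sum(wl[idx]),
      x_from = x[idx[1L]], x_to = x[idx[length(idx)]],
      stringsAsFactors = FALSE))
  }
  out[order(out$x_from), , drop = FALSE]
}

#' @export
print.fr_biometrics <- function(x, ...) {
  cat("Fairy-ring biometrics (baseline P_inf =",
      format(x$P_inf, digits = 5), ", eps =", x$eps, ")\n")
  cat(sprintf("  FB = %.4g  PS = %.4g  PI = %.4g  BZ = %.4g dm  RW = %s dm\n",
              x$FB, x$PS, x$PI, x$BZ,
              if (is.na(x$RW)) "NA" else format(x$RW, digits = 4)))
  if (nrow(x$bands)) {
    cat("  bands:\n")
    print(x$bands, row.names = FALSE, digits = 4)
  } else cat("  no significant vegetation bands\n")
  invisible(x)
}

#' Classify a fairy-ring type from its biometrics
#'
#' Decision tree over the significant vegetation bands of an
#' [fr_biometrics()] record, following the classical field typology:
#' \describe{
#'   \item{3}{no significant bands -- no visible effect on vegetation}
#'   \item{2}{stimulated band(s) only -- luxuriant belt, no die-back}
#'   \item{1.2}{inhibited band(s) only -- dead belt, no flourishing belt}
#'   \item{1}{inhibition plus stimulation behind the fungal peak only --
#'     dead belt followed (inside) by a flourishing belt}
#'   \item{1.1}{inhibition plus stimulation on both sides, the belt ahead no
#'     stronger than the one behind}
#'   \item{1.3}{inhibition plus stimulation with the belt ahead of the front
#'     stronger than the one behind (including ahead-only stimulation)}
#' }
#'
#' @param record an `fr_biometrics` object.
#' @return An object of class `fr_type`: a character scalar in
#'   `"1"`, `"1.1"`, `"1.2"`, `"1.3"`, `"2"`, `"3"`.
#' @examples
#' tr <- data.frame(x = 0:199, F = 0 * (0:199), P = rep(1, 200))
#' fr_classify(fr_biometrics(tr, baseline = 1)) # "3"
#' @export
fr_classify <- function(record) {
  stopifnot(inherits(record, "fr_biometrics"))
  b <- record$bands
  stim <- b[b$kind == "stimulated", , drop = FALSE]
  inhib <- b[b$kind == "inhibited", , drop = FALSE]
  label <-
    if (nrow(stim) == 0L && nrow(inhib) == 0L) "3"
    else if (nrow(inhib) == 0L) "2"
    else if (nrow(stim) == 0L) "1.2"
    else {
      ahead  <- max(c(stim$extreme[stim$side == "ahead"], 0))
      behind <- max(c(stim$extreme[stim$side == "behind"], 0))
      if (ahead == 0) "1" else if (ahead > behind) "1.3" else "1.1"
    }
  structure(label, class = "fr_type")
}

#' @export
print.fr_type <- function(x, ...) {
  cat("Fairy-ring type:", unclass(x), "\n")
  invisible(x)
}

#' Read / write biomass transects as delimited text
#'
#' Plain-text interchange for the biometrics subsystem: a headered
#' tab-separated table with columns `x`, `F`, `P`.
#'
#' @param path file path.
#' @param transect data frame with columns `x`, `F`, `P`.
#' @return `read_transect` returns the transect data frame;
#'   `write_transect` returns `path` invisibly.
#' @export
read_transect <- function(path) {
  tr <- utils::read.delim(path, check.names = FALSE)
  check_transect(tr)
  tr
}

#' @rdname read_transect
#' @export
write_transect <- function(transect, path) {
  check_transect(transect)
  utils::write.table(transect[c("x", "F", "P")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
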