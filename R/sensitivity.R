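#' Fold change of a metric across sweep levels
#'
#' `fc = (max(x) - min(x)) / min(x)`, always non-negative. If the minimum is
#' zero the fold change is undefined and `NA` is returned (flagged rather
#' than infinite); `NA` inputs (e.g. an undefined ring width at some level)
#' also yield `NA`.
#'
#' @param values numeric vector of metric values, one per sweep level.
#' @return A non-negative scalar, or `NA` when undefined.
#' @examples
#' fold_change(c(0.5, 1, 1.5)) # 2
#' @export
fold_change <- function(values) {
  if (!length(values)) stop("'values' must be non-empty", call. = FALSE)
  if (anyNA(values)) return(NA_real_)
  if (any(values < 0)) {
    stop("metric values must be non-negative", call. = FALSE)
  }
  lo <- min(values)
  if (lo == 0) return(NA_real_)
  (max(values) - lo) / lo
}

#' Sign of the Pearson correlation between sweep levels and a metric
#'
#' Returns +1/-1 for a clear monotone association and 0 when the metric does
#' not respond: zero variance, any undefined value, or `|r| < dead_zone`
#' (weak correlations are not called, to avoid asserting signs from
#' numerical noise on insensitive parameters).
#'
#' @param levels numeric vector of parameter values (>= 3).
#' @param values numeric vector of metric values, same length.
#' @param dead_zone correlations with `|r|` below this are reported as 0.
#' @return -1, 0 or +1.
#' @examples
#' correlation_sign(1:5, c(2, 3, 5, 8, 9)) # +1
#' @export
correlation_sign <- function(levels, values, dead_zone = 0.1) {
  stopifnot(length(levels) == length(values), length(levels) >= 3L)
  ok <- !is.na(levels) & !is.na(values)
  if (sum(ok) < 3L) return(0)
  levels <- levels[ok]; values <- values[ok]
  if (stats::sd(values) == 0 || stats::sd(levels) == 0) return(0)
  r <- stats::cor(levels, values)
  if (abs(r) < dead_zone) 0 else sign(r)
}

#' One-at-a-time parameter sweep with biometric read-out
#'
#' Runs one full simulation per level of a single parameter (all other
#' parameters held at the base configuration), extracts the final transect
#' and returns the five biometric indicators per level. The default levels
#' span +/- 50% of the base value in 5 steps
#' (0.5, 0.75, 1, 1.25, 1.5 x default).
#'
#' @param parameter name of the parameter to vary (a Table-style symbol, see
#'   [fr_params()]).
#' @param config base [fr_config]; sweeps default to the 1D transect setup.
#' @param multipliers strictly increasing multipliers of the base value
#'   (>= 3).
#' @param eps band-significance tolerance passed to [fr_biometrics()].
#' @return A data frame with one row per level: `parameter`, `multiplier`,
#'   `level` (the parameter value), `FB`, `PS`, `PI`, `BZ`, `RW`, `type`, and
#'   `ok` (`FALSE` rows record a failed run instead of silently dropping the
#'   level).
#' @export
fr_sweep <- function(parameter, config = fr_config(),
                     multipliers = c(0.5, 0.75, 1, 1.25, 1.5),
                     eps = 0.02) {
  stopifnot(inherits(config, "fr_config"),
            length(multipliers) >= 3L, all(diff(multipliers) > 0))
  base <- config$params
  if (!parameter %in% names(base)) {
    stop("unknown parameter '", parameter, "'; valid names: ",
         paste(names(base), collapse = ", "), call. = FALSE)
  }
  levels <- base[[parameter]] * multipliers
  rows <- lapply(seq_along(levels), function(i) {
    out <- data.frame(parameter = parameter, multiplier = multipliers[i],
                      level = levels[i], FB = NA_real_, PS = NA_real_,
                      PI = NA_real_, BZ = NA_real_, RW = NA_real_,
                      type = NA_character_, ok = FALSE,
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      cfg_i <- config
      cfg_i$params[[parameter]] <- levels[i]
      validate_fr_params(cfg_i$params)
      sim <- fr_run(cfg_i, keep_snapshots = FALSE)
      b <- fr_biometrics(final_transect(sim), eps = eps)
      list(b = b, lab = fr_classify(b))
    }, error = function(e) e)
    if (!inherits(res, "error")) {
      out[c("FB", "PS", "PI", "BZ", "RW")] <-
        res$b[c("FB", "PS", "PI", "BZ", "RW")]
      out$type <- as.character(res$lab)
      out$ok <- TRUE
    } else {
      attr(out, "error") <- conditionMessage(res)
    }
    out
  })
  do.call(rbind, rows)
}

#' Full sensitivity analysis: signs and fold changes per parameter
#'
#' Sweeps each parameter +/- 50% around the base configuration (one at a
#' time), computes the Pearson correlation sign and the fold change of each
#' biometric indicator, and assembles the column-normalized heatmap matrix
#' (each metric column divided by its maximum fold change, so intensities are
#' comparable within a column only).
#'
#' @param parameters character vector of parameter names to sweep; defaults
#'   to every model parameter.
#' @param config base [fr_config].
#' @param multipliers sweep levels as multipliers of the default.
#' @param eps band-significance tolerance.
#' @param dead_zone `|r|` threshold below which a sign is reported as 0.
#' @param verbose print one line per completed sweep.
#' @return An object of class `fr_sensitivity`: a list with `table` (long
#'   data frame: metric, parameter, sign, fc, fc_norm and the per-level raw
#'   values), `fc` and `sign` (parameters x metrics matrices), `fc_norm`
#'   (column-normalized `fc`), and `sweeps` (the raw per-level data).
#' @export
fr_sensitivity <- function(parameters = NULL, config = fr_config(),
                           multipliers = c(0.5, 0.75, 1, 1.25, 1.5),
                           eps = 0.02, dead_zone = 0.1, verbose = FALSE) {
  if (is.null(parameters)) parameters <- names(config$params)
  metrics <- c("FB", "PS", "PI", "BZ", "RW")
  sweeps <- list()
  fc <- sg <- matrix(NA_real_, length(parameters), length(metrics),
                     dimnames = list(parameters, metrics))
  for (pn in parameters) {
    sw <- fr_sweep(pn, config, multipliers, eps)
    sweeps[[pn]] <- sw
    for (m in metrics) {
      vals <- sw[[m]]
      vals[!sw$ok] <- NA
      fc[pn, m] <- tryCatch(fold_change(vals), error = function(e) NA_real_)
      sg[pn, m] <- correlation_sign(sw$level, vals, dead_zone)
    }
    if (verbose) {
      message(sprintf("swept %-4s: sign(FB,PS,PI,BZ,RW) = %s", pn,
                      paste(sg[pn, ], collapse = " ")))
    }
  }
  col_max <- apply(fc, 2L, function(z) {
    if (all(is.na(z))) NA_real_ else max(z, na.rm = TRUE)
  })
  if (anyNA(col_max)) {
    warning("metric column(s) with no defined fold change: ",
            paste(metrics[is.na(col_max)], collapse = ", "))
  }
  fc_norm <- sweep(fc, 2L, ifelse(col_max > 0, col_max, 1), "/")
  long <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(metric = m, parameter = parameters, sign = sg[, m],
               fc = fc[, m], fc_norm = fc_norm[, m],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(table = long, fc = fc, sign = sg, fc_norm = fc_norm,
                 sweeps = sweeps, multipliers = multipliers),
            class = "fr_sensitivity")
}

#' @export
print.fr_sensitivity <- function(x, ...) {
  cat("Parameter sensitivity (", nrow(x$fc), " parameters x ",
      ncol(x$fc), " biometrics; ", length(x$multipliers),
      " levels in [", min(x$multipliers), ", ", max(x$multipliers),
      "] x default)\n", sep = "")
  cat("correlation signs:\n")
  print(x$sign)
  cat("fold changes:\n")
  print(round(x$fc, 3))
  invisible(x)
}

#' @export
plot.fr_sensitivity <- function(x, ...) {
  m <- x$sign * x$fc_norm
  m[is.na(m)] <- 0
  np <- nrow(m); nm <- ncol(m)
  pal <- grDevices::colorRampPalette(c("firebrick", "white", "navy"))(101)
  graphics::image(seq_len(nm), seq_len(np), t(m[np:1, , drop = FALSE]),
                  col = pal, zlim = c(-1, 1), axes = FALSE,
                  xlab = "", ylab = "", ...)
  graphics::axis(1, at = seq_len(nm), labels = colnames(m), las = 1)
  graphics::axis(2, at = seq_len(np), labels = rev(rownames(m)), las = 2,
                 cex.axis = 0.7)
  graphics::box()
  invisible(x)
}

#' Export a sensitivity table as delimited text
#'
#' @param x an `fr_sensitivity` object.
#' @param path output file path (tab-separated, headered).
#' @return `path`, invisibly.
#' @export
write_sensitivity <- function(x, path) {
  stopifnot(inherits(x, "fr_sensitivity"))
  long <- x$table
  wide <- long
  for (i in seq_along(x$multipliers)) {
    wide[[paste0("value_x", x$multipliers[i])]] <- vapply(
      seq_len(nrow(long)), function(r) {
        sw <- x$sweeps[[long$parameter[r]]]
        sw[[long$metric[r]]][i]
      }, numeric(1))
  }
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
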