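#' Read a simulation configuration from a YAML file
#'
#' The file is a flat key-value mapping. All model parameter symbols are
#' accepted verbatim (`g_F`, `s_I`, `k_W`, `d_F`, `s_F`, `c_I`, `k_I`, `l_I`,
#' `c_T`, `k_T`, `l_T`, `a`, `b`, `g_P`, `q_P`, `s_T`, `c_S`, `k_S`, `g_N`,
#' `u_N`, `l_N`, `W`, `D_F`, `D_P`), alongside the numerical settings of
#' [fr_config()] (`geometry`, `dx`, `dt`, `n_steps`, `inoculum_amount`,
#' `inoculum_site`, `initial_plant`, `snapshot_stride`, `hypothesis_mode`).
#' Unknown keys are an error.
#'
#' @param path path to a YAML file.
#' @param overrides optional named list applied on top of the file (e.g. from
#'   command-line `--set key=value` flags).
#' @return An [fr_config] object.
#' @export
fr_read_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (length(overrides)) raw[names(overrides)] <- overrides
  param_names <- names(fr_params())
  config_names <- c("geometry", "dx", "dt", "n_steps", "inoculum_amount",
                    "inoculum_site", "initial_plant", "snapshot_stride",
                    "hypothesis_mode")
  bad <- setdiff(names(raw), c(param_names, config_names))
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         "\nvalid keys: ", paste(c(param_names, config_names), collapse = ", "),
         call. = FALSE)
  }
  params <- do.call(fr_params, raw[intersect(names(raw), param_names)])
  cfg_args <- raw[intersect(names(raw), config_names)]
  cfg_args$params <- params
  do.call(fr_config, cfg_args)
}

#' Write a configuration to YAML
#'
#' @param config an [fr_config] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
fr_write_config <- function(config, path) {
  stopifnot(inherits(config, "fr_config"))
  flat <- c(unclass(config$params),
            config[c("geometry", "dx", "dt", "n_steps", "inoculum_amount",
                     "inoculum_site", "initial_plant", "snapshot_stride")])
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Export / import trajectories
#'
#' Two lossless interchange formats for [fr_run()] results:
#' a long delimited table (`format = "tsv"`: one row per cell per snapshot
#' with columns `time, x[, y], F, I, T, S, P, N, W_bar`; text, diff-friendly)
#' and a compact gridded binary (`format = "rds"`, R serialization of the
#' full `fr_sim` object). The TSV reader reconstructs an `fr_sim`-like object
#' with the same snapshots.
#'
#' @param sim an `fr_sim` object (run with `keep_snapshots = TRUE` for a full
#'   export).
#' @param path output file.
#' @param format `"tsv"` or `"rds"`.
#' @return `fr_write_trajectory` returns `path` invisibly;
#'   `fr_read_trajectory` returns an `fr_sim` object.
#' @export
fr_write_trajectory <- function(sim, path, format = c("tsv", "rds")) {
  stopifnot(inherits(sim, "fr_sim"))
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(sim, path)
    return(invisible(path))
  }
  if (is.null(sim$snapshots)) {
    stop("run with keep_snapshots = TRUE to export a full trajectory",
         call. = FALSE)
  }
  g <- sim$config$geometry
  dx <- sim$config$dx
  two_d <- length(g) == 2L
  coords <- if (two_d) {
    data.frame(x = rep((seq_len(g[2L]) - 1) * dx, each = g[1L]),
               y = rep((seq_len(g[1L]) - 1) * dx, times = g[2L]))
  } else {
    data.frame(x = (seq_len(g) - 1) * dx)
  }
  blocks <- lapply(seq_along(sim$times), function(i) {
    st <- sim$snapshots[[i]]
    cbind(data.frame(time = sim$times[i]), coords,
          data.frame(F = as.vector(st$F), I = as.vector(st$I),
                     T = as.vector(st$T), S = as.vector(st$S),
                     P = as.vector(st$P), N = as.vector(st$N),
                     W_bar = as.vector(available_water(st$F,
                                                       sim$config$params))))
  })
  tab <- do.call(rbind, blocks)
  header <- paste0("# fairyringr trajectory; geometry=",
                   paste(g, collapse = "x"), "; dx=", dx,
                   "; dt=", sim$config$dt,
                   "; front_threshold=", sim$front_threshold)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(format(tab, digits = 17, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname fr_write_trajectory
#' @export
fr_read_trajectory <- function(path, format = c("tsv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") return(readRDS(path))
  header <- readLines(path, n = 1L)
  meta <- regmatches(header, gregexpr("[a-z_]+=[0-9x.eE+-]+", header))[[1L]]
  kv <- strsplit(meta, "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  g <- as.integer(strsplit(meta[["geometry"]], "x", fixed = TRUE)[[1L]])
  tab <- utils::read.delim(path, skip = 1L, check.names = FALSE)
  times <- unique(tab$time)
  reshape_field <- function(v) {
    if (length(g) == 2L) matrix(v, g[1L], g[2L]) else v
  }
  snaps <- lapply(times, function(tm) {
    blk <- tab[tab$time == tm, , drop = FALSE]
    lapply(stats::setNames(nm = c("F", "I", "T", "S", "P", "N")),
           function(f) reshape_field(blk[[f]]))
  })
  structure(list(config = list(geometry = g, dx = as.numeric(meta[["dx"]]),
                               dt = as.numeric(meta[["dt"]])),
                 times = times,
                 front_positions = NULL,
                 snapshots = snaps,
                 final = snaps[[length(snaps)]],
                 front_threshold = as.numeric(meta[["front_threshold"]])),
            class = "fr_sim")
}
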