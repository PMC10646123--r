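#' Model parameters for the fairy-ring simulator
#'
#' Builds the full parameter vector of the six-equation plant--fungus model.
#' Defaults are the published reference values; the three ranged parameters
#' take documented defaults: `g_F = 0.03` (midpoint of \[0.01, 0.05\]),
#' `W = 1` (the reference demonstration value within \[0.1, 2\]) and
#' `s_T = 0.3` (midpoint of the combined-hypothesis range \[0.1, 0.5\]).
#' `a = 2` and `s_T = 0.3` correspond to the combined
#' hydrophobicity + phytotoxicity configuration; use [fr_hypothesis()] to
#' switch hypothesis modes.
#'
#' @param ... named parameter overrides. Valid names are the Table-style
#'   symbols: `g_F`, `s_I`, `k_W`, `d_F`, `s_F`, `c_I`, `k_I`, `l_I`, `c_T`,
#'   `k_T`, `l_T`, `a`, `b`, `g_P`, `q_P`, `s_T`, `c_S`, `k_S`, `g_N`, `u_N`,
#'   `l_N`, `W`, `D_F`, `D_P`.
#'
#' @return An object of class `fr_params`: a named list of scalar parameters.
#'
#' @details Parameter meanings (units):
#' \describe{
#'   \item{g_F}{fungal growth rate (1/d), range 0.01--0.05}
#'   \item{s_I}{sensitivity of fungal growth to the self-inhibitor (dm^2/g)}
#'   \item{k_W}{Michaelis--Menten constant for soil water (dimensionless)}
#'   \item{d_F}{fungal death rate (dm^2/(d g))}
#'   \item{s_F}{sensitivity of fungal death to the self-inhibitor (dm^2/(d g))}
#'   \item{c_I}{self-inhibitor release per unit fungal mortality (dimensionless)}
#'   \item{k_I, l_I}{self-inhibitor degradation and leaching rates (1/d)}
#'   \item{c_T, k_T, l_T}{phytotoxin production, degradation, leaching (1/d)}
#'   \item{a}{hydrophobicity strength (dm^2/g); 0 disables the hydrophobicity
#'     pathway, 2 enables it}
#'   \item{b}{base of the water-infiltration power law (dimensionless, > 1)}
#'   \item{g_P}{plant growth rate (dm^2/(d g))}
#'   \item{q_P}{baseline plant carrying capacity (g/dm^2)}
#'   \item{s_T}{plant sensitivity to phytotoxins (dm^2/(d g)); 0 disables the
#'     phytotoxicity pathway}
#'   \item{c_S, k_S}{phytostimulant production and degradation rates (1/d)}
#'   \item{g_N}{nutrient release per unit plant mortality (dimensionless)}
#'   \item{u_N}{plant nutrient uptake coefficient (dimensionless)}
#'   \item{l_N}{nutrient leaching rate (1/d)}
#'   \item{W}{soil-water input (dimensionless), range 0.1--2}
#'   \item{D_F, D_P}{fungal and plant diffusion coefficients (dm^2/d)}
#' }
#'
#' @examples
#' p <- fr_params(g_F = 0.05, W = 2)
#' p$W
#' @export
fr_params <- function(...) {
  p <- list(
    g_F = 0.03, s_I = 1, k_W = 0.3, d_F = 0.005, s_F = 2,
    c_I = 0.05, k_I = 0.001, l_I = 0.001,
    c_T = 0.07, k_T = 0.07, l_T = 0.01,
    a = 2, b = 9,
    g_P = 0.9, q_P = 1, s_T = 0.3,
    c_S = 0.07, k_S = 0.07,
    g_N = 0.08, u_N = 0.3, l_N = 0.1,
    W = 1, D_F = 0.01, D_P = 0.01
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over))) {
    over <- over[[1L]]
  }
  if (length(over)) {
    nm <- names(over)
    if (is.null(nm) || any(nm == "")) {
      stop("all parameter overrides must be named", call. = FALSE)
    }
    bad <- setdiff(nm, names(p))
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "),
           "\nvalid names: ", paste(names(p), collapse = ", "),
           call. = FALSE)
    }
    p[nm] <- lapply(over, as.numeric)
  }
  validate_fr_params(p)
  structure(p, class = "fr_params")
}

validate_fr_params <- function(p) {
  vals <- unlist(p, use.names = TRUE)
  if (any(!is.finite(vals))) {
    stop("non-finite parameter value(s): ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "), call. = FALSE)
  }
  if (any(vals < 0)) {
    stop("parameters must be non-negative; offending: ",
         paste(names(vals)[vals < 0], collapse = ", "), call. = FALSE)
  }
  if (p$b <= 1) {
    stop("'b' must be > 1 so that available water stays in [0, 1)",
         call. = FALSE)
  }
  invisible(p)
}

#' Apply a hypothesis mode to a parameter set
#'
#' The model's two suppression pathways are toggled through `a`
#' (hydrophobicity) and `s_T` (phytotoxicity): `"hydrophobicity"` sets
#' `a = 2, s_T = 0`; `"phytotoxicity"` sets `a = 0` and, unless `s_T` is in
#' the phytotoxicity range already, `s_T = 1.1` (midpoint of \[0.9, 1.3\]);
#' `"combined"` sets `a = 2` and `s_T = 0.3` (midpoint of \[0.1, 0.5\]).
#'
#' @param params an [fr_params] object.
#' @param mode one of `"hydrophobicity"`, `"phytotoxicity"`, `"combined"`.
#' @param s_T optional hypothesis-specific override of the plant toxin
#'   sensitivity (ignored in hydrophobicity mode, where `s_T` is 0).
#' @return The modified `fr_params` object.
#' @examples
#' fr_hypothesis(fr_params(), "hydrophobicity")$s_T
#' @export
fr_hypothesis <- function(params, mode = c("combined", "hydrophobicity",
                                           "phytotoxicity"),
                          s_T = NULL) {
  stopifnot(inherits(params, "fr_params"))
  mode <- match.arg(mode)
  params[c("a", "s_T")] <- switch(mode,
    hydrophobicity = list(a = 2, s_T = 0),
    phytotoxicity  = list(a = 0, s_T = if (is.null(s_T)) 1.1 else s_T),
    combined       = list(a = 2, s_T = if (is.null(s_T)) 0.3 else s_T)
  )
  validate_fr_params(params)
  attr(params, "hypothesis") <- mode
  params
}

#' @export
print.fr_params <- function(x, ...) {
  cat("Fairy-ring model parameters")
  h <- attr(x, "hypothesis")
  if (!is.null(h)) cat(" (", h, " mode)", sep = "")
  cat(":\n")
  v <- unlist(x)
  print(noquote(formatC(v, format = "g", digits = 4)))
  invisible(x)
}
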