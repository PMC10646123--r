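#' Water available to plants under fungal hydrophobicity
#'
#' The dense mycelial mat makes the topsoil hydrophobic, so only part of the
#' soil-water input reaches the plant rooting zone (and the leaching
#' processes). Available water is
#' `W_bar = 1 - b^(a*F - W)` where `a*F < W`, and 0 where `a*F >= W`,
#' which lies in `[0, 1)` whenever `b > 1`.
#'
#' @param F fungal biomass field (g/dm^2), any shape.
#' @param params an [fr_params] object (uses `a`, `b`, `W`).
#' @return A field of the same shape as `F`, values in `[0, 1)`.
#' @examples
#' available_water(0, fr_params(a = 2, b = 9, W = 1)) # 1 - 1/9
#' @export
available_water <- function(F, params) {
  if (params$b <= 1) {
    stop("'b' must be > 1 so that available water stays in [0, 1)",
         call. = FALSE)
  }
  e <- params$a * F - params$W
  w <- 1 - params$b^e
  w[e >= 0] <- 0
  w
}

#' Local reaction terms of the six-equation fairy-ring model
#'
#' The non-spatial right-hand sides, one function per state variable.
#' Fungal growth is limited by the self-inhibitor `I` and by total soil water
#' `W` (Michaelis--Menten); the self-inhibitor is released in proportion to
#' fungal mortality; phytotoxins and phytostimulants are produced in
#' proportion to fungal biomass; plants grow logistically toward a carrying
#' capacity set by available water, phytostimulants and nutrients, and are
#' killed by phytotoxins; nutrients are released by plant mortality and lost
#' to uptake and leaching, all gated by available water `W_bar`.
#'
#' All functions are elementwise over fields of a common shape and return the
#' instantaneous rate (g/(dm^2 d)). Negative rates are legitimate (local
#' decline); the time-stepper is responsible for keeping states non-negative.
#'
#' @param F,I,T,S,P,N state fields (g/dm^2).
#' @param W_bar available-water field from [available_water()].
#' @param params an [fr_params] object.
#' @return A rate field of the same shape as the inputs.
#' @name fr_reactions
NULL

#' @rdname fr_reactions
#' @export
fungus_reaction <- function(F, I, params) {
  params$g_F * F * (1 - params$s_I * I) * (params$W / (params$W + params$k_W)) -
    params$d_F * F^2 - params$s_F * F * I
}

#' @rdname fr_reactions
#' @export
inhibitor_reaction <- function(F, I, W_bar, params) {
  params$c_I * (params$d_F * F^2 + params$s_F * F * I) -
    params$k_I * I - params$l_I * I * W_bar
}

#' @rdname fr_reactions
#' @export
toxin_reaction <- function(F, T, W_bar, params) {
  params$c_T * F - params$k_T * T - params$l_T * T * W_bar
}

#' @rdname fr_reactions
#' @export
stimulant_reaction <- function(F, S, params) {
  params$c_S * F - params$k_S * S
}

#' @rdname fr_reactions
#' @export
plant_reaction <- function(P, W_bar, S, N, T, params) {
  params$g_P * P * (W_bar * (params$q_P + S + N) - P) - params$s_T * T * P
}

#' @rdname fr_reactions
#' @export
nutrient_reaction <- function(P, N, T, W_bar, params) {
  params$g_N * (params$g_P * P^2 + params$s_T * P * T) * W_bar -
    params$u_N * (params$g_P * W_bar * P * N) -
    params$l_N * N * W_bar
}

#' Discrete Laplacian with zero-flux (Neumann) boundaries
#'
#' Central 3-point (1D vector) or 5-point (2D matrix) stencil divided by
#' `dx^2`. Boundaries are handled by ghost-cell mirroring, so no material
#' crosses the domain edge and the operator conserves mass: the domain sum of
#' the result is zero to round-off.
#'
#' @param field numeric vector (1D) or matrix (2D), at least 3 cells per
#'   dimension.
#' @param dx grid spacing (dm), > 0.
#' @return A field of the same shape: the discrete `del^2` of `field`.
#' @examples
#' laplacian(c(0, 1, 0), dx = 1) # c(1, -2, 1)
#' @export
laplacian <- function(field, dx = 1) {
  stopifnot(is.numeric(field), dx > 0)
  if (is.matrix(field)) {
    nr <- nrow(field); nc <- ncol(field)
    if (nr < 3L || nc < 3L) stop("grid must have >= 3 cells per dimension",
                                 call. = FALSE)
    up    <- field[c(1L, seq_len(nr - 1L)), , drop = FALSE]
    down  <- field[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
    left  <- field[, c(1L, seq_len(nc - 1L)), drop = FALSE]
    right <- field[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
    (up + down + left + right - 4 * field) / dx^2
  } else {
    n <- length(field)
    if (n < 3L) stop("grid must have >= 3 cells per dimension", call. = FALSE)
    left  <- field[c(1L, seq_len(n - 1L))]
    right <- field[c(seq_len(n - 1L) + 1L, n)]
    (left + right - 2 * field) / dx^2
  }
}
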