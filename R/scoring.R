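#' SHAPE reactivity comparison score
#'
#' The pairwise scoring function at the heart of reactivity-driven
#' alignment: `max(m * |ri - rj| + b, m + b)`, a line of negative slope `m`
#' through intercept `b`, clipped at the value reached at a difference of one
#' SHAPE unit. With the published parameters (`m = -2, b = 2`) identical
#' reactivities score `2`, and differences of one SHAPE unit or more score
#' `0`. A missing reactivity on either side contributes the neutral score 0,
#' so alignment through unprobed positions is neither rewarded nor penalized.
#'
#' @param ri,rj Reactivities (numeric scalars or vectors; `NA` = missing).
#' @param params An [alignment_params()] object.
#' @return Numeric score(s).
#' @examples
#' p <- alignment_params()
#' shape_score(0.5, 0.5, p)  # 2: intercept at zero difference
#' shape_score(0.2, 0.7, p)  # 1: linear branch
#' shape_score(0.0, 3.0, p)  # 0: clipped floor
#' shape_score(NA, 1.4, p)   # 0: missing is neutral
#' @export
shape_score <- function(ri, rj, params) {
  validate_params(params)
  if (any(!is.na(ri) & !is.finite(ri)) || any(!is.na(rj) & !is.finite(rj)))
    stop("non-finite reactivity value", call. = FALSE)
  s <- pmax(params$m * abs(ri - rj) + params$b, params$m + params$b)
  s[is.na(ri) | is.na(rj)] <- 0
  s
}

#' Base-identity score
#'
#' `MATCH` for identical bases, `MISMATCH` otherwise. The ambiguity code `N`
#' scores `MISMATCH` against everything (including another `N`).
#'
#' @param xi,yj Single bases (character) in the normalized RNA alphabet.
#' @param params An [alignment_params()] object.
#' @return Numeric score(s).
#' @export
base_score <- function(xi, yj, params) {
  ifelse(xi == yj & xi != "N", params$match, params$mismatch)
}

#' Total score of one alignment column
#'
#' The per-column term of the dynamic program: the SHAPE comparison score in
#' `shape_only` mode, plus the base-identity term in `combined` mode.
#'
#' @param i,j Positions (1-based) in `px` and `py`.
#' @param px,py [reactivity_profile()]s.
#' @param params An [alignment_params()] object.
#' @return Numeric score.
#' @export
column_score <- function(i, j, px, py, params) {
  if (any(i < 1L) || any(i > length(px)) || any(j < 1L) || any(j > length(py)))
    stop("position out of profile range", call. = FALSE)
  s <- shape_score(px$reactivities[i], py$reactivities[j], params)
  if (params$mode == "combined")
    s <- s + base_score(profile_bases(px)[i], profile_bases(py)[j], params)
  s
}
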