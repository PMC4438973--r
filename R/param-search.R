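#' Candidate grid for scoring-parameter optimization
#'
#' Cartesian product of per-parameter candidate lists. Defaults bracket the
#' published optima; any parameter can be frozen by giving a single value.
#' In combined mode the scoring-line parameters `m` and `b` are conventionally
#' frozen at the SHAPE-only optimum and only the gap and base-identity terms
#' are searched (see [grid_search()]).
#'
#' @param m,b,gop,gep,match,mismatch Numeric candidate vectors.
#' @param mode `"shape_only"` or `"combined"` (controls whether
#'   `match`/`mismatch` are part of the grid).
#' @return A data.frame of class `param_grid`, one row per grid point.
#' @export
param_grid <- function(m = seq(-4, -0.5, by = 0.5),
                       b = seq(0.5, 4, by = 0.5),
                       gop = seq(-10, -1, by = 1),
                       gep = c(-2, -1.5, -1, -0.5, -0.25, -0.1),
                       match = 2, mismatch = -2,
                       mode = c("shape_only", "combined")) {
  mode <- match.arg(mode)
  grid <- if (mode == "combined")
    expand.grid(m = m, b = b, gop = gop, gep = gep,
                match = match, mismatch = mismatch,
                KEEP.OUT.ATTRS = FALSE)
  else
    expand.grid(m = m, b = b, gop = gop, gep = gep, KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0L) stop("empty parameter grid", call. = FALSE)
  attr(grid, "mode") <- mode
  class(grid) <- c("param_grid", "data.frame")
  grid
}

#' Exhaustive grid search for alignment parameters
#'
#' Evaluates every grid point by aligning every training pair with those
#' parameters and averaging [alignment_sensitivity()] against the pairs'
#' reference alignments. Returns the argmax (ties broken by grid order) and
#' the full result table. Deterministic: no randomness is involved.
#'
#' @param training A list of training cases, each a list with elements
#'   `px`, `py` ([reactivity_profile()]s) and `reference` (an
#'   [aligned_pairs()] set).
#' @param grid A [param_grid()].
#' @return A list with `best` (the winning [alignment_params()]), `best_mean`
#'   (its mean sensitivity) and `table` (one row per grid point: parameters,
#'   per-pair sensitivities, mean).
#' @export
grid_search <- function(training, grid = param_grid()) {
  if (!length(training)) stop("empty training set", call. = FALSE)
  stopifnot(inherits(grid, "param_grid"))
  mode <- attr(grid, "mode")
  sens <- matrix(NA_real_, nrow(grid), length(training))
  colnames(sens) <- paste0("sens_", seq_along(training))
  for (g in seq_len(nrow(grid))) {
    prm <- alignment_params(mode = mode,
                            m = grid$m[g], b = grid$b[g],
                            gop = grid$gop[g], gep = grid$gep[g],
                            match = if (mode == "combined") grid$match[g] else 2,
                            mismatch = if (mode == "combined") grid$mismatch[g] else -2)
    for (k in seq_along(training)) {
      tr <- training[[k]]
      aln <- gotoh_align(tr$px, tr$py, prm)
      sens[g, k] <- alignment_sensitivity(alignment_pairs(aln), tr$reference)
    }
  }
  tab <- cbind(as.data.frame(grid), sens,
               mean_sensitivity = rowMeans(sens))
  best_row <- which.max(tab$mean_sensitivity)
  best <- alignment_params(mode = mode,
                           m = grid$m[best_row], b = grid$b[best_row],
                           gop = grid$gop[best_row], gep = grid$gep[best_row],
                           match = if (mode == "combined") grid$match[best_row] else 2,
                           mismatch = if (mode == "combined") grid$mismatch[best_row] else -2)
  list(best = best, best_mean = tab$mean_sensitivity[best_row], table = tab)
}
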