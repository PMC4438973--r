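BASE_CODES <- c(A = 0L, C = 1L, G = 2L, U = 3L, N = 4L)

encode_bases <- function(p) unname(BASE_CODES[profile_bases(p)])

new_pairwise_alignment <- function(columns, score, params,
                                   free_endgaps = FALSE) {
  structure(list(columns = columns, score = score, params = params,
                 free_endgaps = free_endgaps),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  n <- nrow(x$columns)
  gaps <- sum(is.na(x$columns))
  cat(sprintf("Pairwise alignment: %d columns (%d gapped), score %.4f [%s]\n",
              n, gaps, x$score, x$params$mode))
  invisible(x)
}

#' Global affine-gap alignment of two reactivity profiles
#'
#' Gotoh dynamic programming over SHAPE reactivity profiles. Three matrices
#' are filled: `D` (best score for the aligned prefixes), `P` (best score
#' ending with a profile-x nucleotide against a gap) and `Q` (ditto for
#' profile y), with `D[0,0] = 0`, border cells `GOP + k * GEP`, and the gap
#' matrices' borders held at a large negative sentinel. Each column
#' contributes [column_score()]; a gap run of length L costs `GOP + L * GEP`.
#' Traceback follows pointers recorded at fill time (tie order: diagonal,
#' then gap in y, then gap in x; gap extension preferred over re-opening),
#' so results are deterministic.
#'
#' @param px,py [reactivity_profile()]s to align.
#' @param params An [alignment_params()] object; its `mode` selects
#'   SHAPE-only or combined scoring.
#' @param free_endgaps If `TRUE`, terminal gaps are not penalized
#'   (semi-global alignment). Default `FALSE`: terminal gaps cost the same
#'   as internal ones, per the border initialization.
#' @return A `pairwise_alignment`: `columns` (two-column integer matrix of
#'   positions, `NA` for gaps), `score`, and the parameter snapshot.
#' @examples
#' p <- alignment_params()
#' x <- reactivity_profile("x", "ACGU", c(0.1, 0.9, 0.4, 0.2))
#' y <- reactivity_profile("y", "ACGU", c(0.1, 0.9, 0.4, 0.2))
#' gotoh_align(x, y, p)$score  # 4 identical columns: 4 * b = 8
#' @export
gotoh_align <- function(px, py, params = alignment_params(),
                        free_endgaps = FALSE) {
  stopifnot(inherits(px, "reactivity_profile"),
            inherits(py, "reactivity_profile"))
  validate_params(params)
  res <- .gotoh_core(px$reactivities, py$reactivities,
                     encode_bases(px), encode_bases(py),
                     params$m, params$b, params$gop, params$gep,
                     params$match, params$mismatch,
                     params$mode == "combined", free_endgaps)
  cols <- cbind(x = res$x, y = res$y)
  new_pairwise_alignment(cols, res$score, params, free_endgaps)
}

#' Exhaustive small-instance alignment oracle
#'
#' Enumerates every global alignment of the two profiles (every monotone
#' column sequence), scores each by direct summation of column scores and
#' affine gap costs, and returns the maximum score together with all optimal
#' alignments. Intended as an independent correctness oracle for
#' [gotoh_align()]; refuses instances with more than 16 nucleotides in
#' total.
#'
#' @param px,py [reactivity_profile()]s with `length(px) + length(py) <= 16`.
#' @param params An [alignment_params()] object.
#' @param tol Scores within `tol` of the maximum count as co-optimal.
#' @return A list with `score` (best total) and `alignments` (list of
#'   two-column position matrices, `NA` for gaps).
#' @export
exhaustive_align <- function(px, py, params = alignment_params(),
                             tol = 1e-9) {
  stopifnot(inherits(px, "reactivity_profile"),
            inherits(py, "reactivity_profile"))
  validate_params(params)
  nx <- length(px); ny <- length(py)
  if (nx + ny > 16L)
    stop("exhaustive enumeration refused for length(x) + length(y) > 16",
         call. = FALSE)
  cs <- if (nx && ny)
    outer(seq_len(nx), seq_len(ny),
          function(i, j) column_score(i, j, px, py, params))
  else matrix(0, nx, ny)

  best <- -Inf
  opt <- list()
  rec <- function(i, j, score, last, cols) {
    if (i == nx && j == ny) {
      if (score > best + tol) {
        best <<- score
        opt <<- list(cols)
      } else if (score >= best - tol) {
        opt[[length(opt) + 1L]] <<- cols
      }
      return(invisible())
    }
    if (i < nx && j < ny)
      rec(i + 1L, j + 1L, score + cs[i + 1L, j + 1L], "d",
          rbind(cols, c(i + 1L, j + 1L)))
    if (i < nx)
      rec(i + 1L, j,
          score + params$gep + if (last != "u") params$gop else 0,
          "u", rbind(cols, c(i + 1L, NA)))
    if (j < ny)
      rec(i, j + 1L,
          score + params$gep + if (last != "l") params$gop else 0,
          "l", rbind(cols, c(NA, j + 1L)))
  }
  rec(0L, 0L, 0, "-", matrix(integer(0), 0, 2))
  if (nx == 0L && ny == 0L) { best <- 0; opt <- list(matrix(integer(0), 0, 2)) }
  list(score = best, alignments = opt)
}

#' Independently re-score an alignment
#'
#' Recomputes an alignment's total score by direct summation over its column
#' list — column scores for aligned columns, plus `GOP` once per maximal gap
#' run and `GEP` per gapped column — without consulting the dynamic-program
#' matrices. Used to verify DP scores.
#'
#' @param alignment A `pairwise_alignment` (or a bare two-column position
#'   matrix).
#' @param px,py The aligned [reactivity_profile()]s.
#' @param params An [alignment_params()] object.
#' @param free_endgaps If `TRUE`, terminal gap runs cost nothing.
#' @return The total score (numeric scalar).
#' @export
score_alignment <- function(alignment, px, py, params,
                            free_endgaps = FALSE) {
  cols <- if (inherits(alignment, "pairwise_alignment")) {
    free_endgaps <- alignment$free_endgaps
    if (missing(params)) params <- alignment$params
    alignment$columns
  } else alignment
  validate_params(params)
  xs <- as.integer(cols[, 1L]); ys <- as.integer(cols[, 2L])
  if (any(is.na(xs) & is.na(ys)))
    stop("inconsistent alignment: all-gap column", call. = FALSE)
  if (!identical(xs[!is.na(xs)], seq_len(length(px))) ||
      !identical(ys[!is.na(ys)], seq_len(length(py))))
    stop("inconsistent alignment: positions must cover each profile once, in order",
         call. = FALSE)
  paired <- !is.na(xs) & !is.na(ys)
  total <- if (any(paired))
    sum(column_score(xs[paired], ys[paired], px, py, params)) else 0
  # gap runs: maximal stretches of gap-in-x or gap-in-y columns
  gapside <- ifelse(is.na(xs), "x", ifelse(is.na(ys), "y", "."))
  r <- rle(gapside)
  isgap <- r$values != "."
  if (free_endgaps && length(r$values)) {
    # leading/trailing gap runs are free
    keep <- rep(TRUE, length(r$values))
    if (r$values[1L] != ".") keep[1L] <- FALSE
    if (r$values[length(r$values)] != ".") keep[length(keep)] <- FALSE
    total <- total + sum((params$gop + r$lengths * params$gep)[isgap & keep])
  } else {
    total <- total + sum((params$gop + r$lengths * params$gep)[isgap])
  }
  total
}
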