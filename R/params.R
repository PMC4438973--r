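#' Alignment scoring and gap parameters
#'
#' Bundles the parameters of the SHAPE comparison scoring function (slope `m`,
#' intercept `b`), the affine gap model (opening penalty `GOP`, extension
#' penalty `GEP`) and, in combined mode, the base-identity terms (`MATCH`,
#' `MISMATCH`). Defaults per mode are the published optima from exhaustive
#' search over rRNA training alignments: SHAPE-only `m = -2, b = 2, GOP = -5,
#' GEP = -0.25`; combined `m = -2, b = 2, GOP = -6, GEP = -1, MATCH = 2,
#' MISMATCH = -2`.
#'
#' The SHAPE comparison score of two reactivities with absolute difference
#' `d` is `max(m * d + b, m + b)`: a line of (negative) slope `m` through the
#' intercept `b` at `d = 0`, clipped at the value it attains at `d = 1` (zero
#' for the published parameters). Small reactivity differences thus score
#' high; differences of one SHAPE unit or more score at the floor.
#'
#' @param mode `"shape_only"` (reactivities alone) or `"combined"`
#'   (reactivities plus base identity).
#' @param m Slope of the SHAPE scoring line, score units per SHAPE unit;
#'   must be negative.
#' @param b Intercept of the SHAPE scoring line (score at zero difference);
#'   must be positive.
#' @param gop Gap opening penalty, `<= 0`. Default depends on `mode`.
#' @param gep Gap extension penalty, `<= 0`, charged per gapped column
#'   (a gap of length L costs `gop + L * gep`). Default depends on `mode`.
#' @param match Base-identity bonus (combined mode), `>= 0`.
#' @param mismatch Base-identity penalty (combined mode), `<= 0`.
#' @return An object of class `shape_alignment_params`.
#' @examples
#' alignment_params()                      # published SHAPE-only set
#' alignment_params("combined")            # published combined set
#' alignment_params(gop = -8, gep = -0.5)  # custom gaps
#' @export
alignment_params <- function(mode = c("shape_only", "combined"),
                             m = -2, b = 2,
                             gop = NULL, gep = NULL,
                             match = 2, mismatch = -2) {
  mode <- match.arg(mode)
  if (is.null(gop)) gop <- if (mode == "combined") -6 else -5
  if (is.null(gep)) gep <- if (mode == "combined") -1 else -0.25
  p <- structure(
    list(mode = mode, m = as.numeric(m), b = as.numeric(b),
         gop = as.numeric(gop), gep = as.numeric(gep),
         match = as.numeric(match), mismatch = as.numeric(mismatch)),
    class = "shape_alignment_params"
  )
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "shape_alignment_params"))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!all(vapply(p[c("m", "b", "gop", "gep", "match", "mismatch")],
                  num1, logical(1))))
    stop("alignment parameters must be finite scalars", call. = FALSE)
  if (p$m >= 0) stop("slope m must be negative", call. = FALSE)
  if (p$b <= 0) stop("intercept b must be positive", call. = FALSE)
  if (p$gop > 0 || p$gep > 0)
    stop("gap penalties GOP and GEP must be <= 0", call. = FALSE)
  if (p$mode == "combined" && (p$match < 0 || p$mismatch > 0))
    stop("combined mode requires MATCH >= 0 and MISMATCH <= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.shape_alignment_params <- function(x, ...) {
  cat("Alignment parameters [", x$mode, "]\n", sep = "")
  cat(sprintf("  m = %g, b = %g, GOP = %g, GEP = %g", x$m, x$b, x$gop, x$gep))
  if (x$mode == "combined")
    cat(sprintf(", MATCH = %g, MISMATCH = %g", x$match, x$mismatch))
  cat("\n")
  invisible(x)
}

#' Read alignment parameters from a key=value file
#'
#' Accepts lines of the form `key = value` (case-insensitive keys `mode, m, b,
#' gop, gep, match, mismatch`); blank lines and `#` comments are ignored.
#' Unspecified keys take the mode's published defaults.
#'
#' @param path Path to the parameter file.
#' @return A `shape_alignment_params` object.
#' @export
read_alignment_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2L)
  if (length(bad))
    stop("malformed parameter line: '", lines[bad[1]], "'", call. = FALSE)
  keys <- tolower(trimws(vapply(kv, `[`, "", 1L)))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  known <- c("mode", "m", "b", "gop", "gep", "match", "mismatch")
  if (length(unknown <- setdiff(keys, known)))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  args <- list()
  for (i in seq_along(keys)) {
    if (keys[i] == "mode") {
      args$mode <- gsub("-", "_", vals[i])
    } else {
      v <- suppressWarnings(as.numeric(vals[i]))
      if (is.na(v)) stop("non-numeric value for '", keys[i], "'", call. = FALSE)
      args[[keys[i]]] <- v
    }
  }
  do.call(alignment_params, args)
}
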