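#' RNA secondary structure as a set of base pairs
#'
#' Stores base pairs `(x, y)` with `x < y` (1-based) plus two per-pair flags:
#' `canonical` (Watson-Crick or G-U wobble, judged against `sequence` when one
#' is supplied, otherwise assumed `TRUE`) and `pseudoknot` (pair crosses the
#' nested backbone of the structure). Each position may pair at most once.
#'
#' @param length Sequence length (number of nucleotides).
#' @param x,y Integer vectors of paired positions, `x[k] < y[k]`.
#' @param sequence Optional RNA sequence used to evaluate the canonical flag.
#' @param pseudoknot Optional logical vector; when `NULL`, crossing pairs are
#'   detected greedily (pairs are scanned 5' to 3'; a pair crossing an
#'   already-kept pair is flagged).
#' @return An object of class `secondary_structure`.
#' @export
secondary_structure <- function(length, x, y, sequence = NULL,
                                pseudoknot = NULL) {
  x <- as.integer(x); y <- as.integer(y)
  stopifnot(length(x) == length(y))
  if (length(x)) {
    swap <- x > y
    tmp <- x[swap]; x[swap] <- y[swap]; y[swap] <- tmp
    if (any(x == y)) stop("a position cannot pair with itself", call. = FALSE)
    if (any(x < 1L) || any(y > length))
      stop("pair position outside sequence of length ", length, call. = FALSE)
    if (anyDuplicated(c(x, y)))
      stop("a position participates in more than one pair", call. = FALSE)
    o <- order(x)
    x <- x[o]; y <- y[o]
    if (!is.null(pseudoknot)) pseudoknot <- pseudoknot[o]
  }
  if (is.null(pseudoknot)) pseudoknot <- flag_crossing(x, y)
  canonical <- if (is.null(sequence)) rep(TRUE, length(x)) else {
    b <- strsplit(normalize_rna(sequence), "", fixed = TRUE)[[1]]
    if (length(b) != length)
      stop("sequence length does not match structure length", call. = FALSE)
    paste0(b[x], b[y]) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  structure(list(length = as.integer(length),
                 pairs = cbind(x = x, y = y),
                 canonical = canonical, pseudoknot = pseudoknot,
                 sequence = if (is.null(sequence)) NULL
                            else normalize_rna(sequence)),
            class = "secondary_structure")
}

# greedy 5'->3' scan: a pair crossing an already-accepted pair is a pseudoknot
flag_crossing <- function(x, y) {
  n <- length(x)
  pk <- logical(n)
  if (n < 2L) return(pk)
  kx <- integer(0); ky <- integer(0)
  for (k in seq_len(n)) {
    crosses <- (kx < x[k] & x[k] < ky & ky < y[k]) |
               (x[k] < kx & kx < y[k] & y[k] < ky)
    if (any(crosses)) pk[k] <- TRUE
    else { kx <- c(kx, x[k]); ky <- c(ky, y[k]) }
  }
  pk
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("Secondary structure: %d nt, %d pairs (%d pseudoknotted, %d non-canonical)\n",
              x$length, nrow(x$pairs), sum(x$pseudoknot), sum(!x$canonical)))
  invisible(x)
}

#' Read a secondary structure from CT or dot-bracket
#'
#' CT files are 1-based six-column connectivity tables; the pairing table
#' must be symmetric (`x` pairs `y` implies `y` pairs `x`). Dot-bracket input
#' may be a bare structure line or a FASTA-like block (`>name`, sequence,
#' structure); the primary tier is `()`, and `[]`, `{}`, `<>` tiers are
#' flagged as pseudoknots.
#'
#' @param path Path to the structure file.
#' @param dialect `"auto"` (detected from content), `"ct"` or `"dotbracket"`.
#' @return A [secondary_structure()].
#' @export
read_structure <- function(path, dialect = c("auto", "ct", "dotbracket")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "auto") {
    dialect <- if (any(grepl("[][(){}<>.]", lines) &
                      !grepl("[0-9]", lines))) "dotbracket" else "ct"
    if (grepl("^\\s*[0-9]+", lines[1])) dialect <- "ct"
  }
  if (dialect == "ct") read_ct(lines) else read_dotbracket(lines)
}

read_ct <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  n <- suppressWarnings(as.integer(header[1]))
  if (is.na(n)) stop("CT format error: bad header", call. = FALSE)
  rows <- strsplit(trimws(lines[-1]), "[[:space:]]+")
  if (length(rows) < n)
    stop("CT format error: fewer rows than header declares", call. = FALSE)
  rows <- rows[seq_len(n)]
  if (any(lengths(rows) < 5L))
    stop("CT format error: row with fewer than 5 columns", call. = FALSE)
  idx <- as.integer(vapply(rows, `[`, "", 1L))
  base <- vapply(rows, `[`, "", 2L)
  partner <- as.integer(vapply(rows, function(r) r[[length(r) - 1L]], ""))
  if (anyNA(idx) || anyNA(partner) || !identical(idx, seq_len(n)))
    stop("CT format error: malformed index or pairing column", call. = FALSE)
  # symmetry of the pairing table
  paired <- which(partner > 0L)
  bad <- paired[partner[partner[paired]] != paired]
  if (length(bad))
    stop("CT format error: inconsistent pairing table at position ", bad[1],
         " (", bad[1], " pairs ", partner[bad[1]], " but ", partner[bad[1]],
         " pairs ", partner[partner[bad[1]]], ")", call. = FALSE)
  keep <- paired[paired < partner[paired]]
  secondary_structure(n, keep, partner[keep],
                      sequence = paste(base, collapse = ""))
}

read_dotbracket <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  lines <- lines[!grepl("^>", lines)]
  lines <- sub("\\s.*$", "", lines)  # strip trailing free-energy annotations
  is_struct <- grepl("^[][(){}<>.-]+$", lines) & grepl("[][(){}<>]|^\\.+$", lines)
  seq_line <- lines[grepl("^[ACGUTNacgutn]+$", lines)]
  struct <- lines[is_struct]
  if (!length(struct))
    stop("dot-bracket format error: no structure line found", call. = FALSE)
  db <- struct[1]
  chars <- strsplit(db, "", fixed = TRUE)[[1]]
  tiers <- list(c("(", ")"), c("[", "]"), c("{", "}"), c("<", ">"))
  x <- integer(0); y <- integer(0); pk <- logical(0)
  for (t in seq_along(tiers)) {
    open <- tiers[[t]][1]; close <- tiers[[t]][2]
    stack <- integer(0)
    for (k in seq_along(chars)) {
      if (chars[k] == open) stack <- c(stack, k)
      else if (chars[k] == close) {
        if (!length(stack))
          stop("dot-bracket format error: unbalanced '", close,
               "' at position ", k, call. = FALSE)
        x <- c(x, stack[length(stack)]); y <- c(y, k)
        pk <- c(pk, t > 1L)
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack))
      stop("dot-bracket format error: unbalanced '", open, "' at position ",
           stack[1], call. = FALSE)
  }
  seqn <- if (length(seq_line)) seq_line[1] else NULL
  if (!is.null(seqn) && nchar(seqn) != length(chars)) seqn <- NULL
  # within one bracket tier crossings are impossible, so the tier flag is the
  # complete pseudoknot annotation
  secondary_structure(length(chars), x, y, sequence = seqn, pseudoknot = pk)
}

#' Render base pairs as a dot-bracket string
#'
#' Non-pseudoknotted pairs use `()`; pseudoknotted pairs use `[]`.
#'
#' @param structure A [secondary_structure()].
#' @return A dot-bracket string of length `structure$length`.
#' @export
as_dotbracket <- function(structure) {
  stopifnot(inherits(structure, "secondary_structure"))
  chars <- rep(".", structure$length)
  p <- structure$pairs
  pk <- structure$pseudoknot
  chars[p[!pk, "x"]] <- "("; chars[p[!pk, "y"]] <- ")"
  chars[p[pk, "x"]] <- "["; chars[p[pk, "y"]] <- "]"
  paste(chars, collapse = "")
}
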