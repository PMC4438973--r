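#' Set of matched positions between two sequences
#'
#' The unit of alignment benchmarking: the set of `(i, j)` nucleotide pairs
#' (1-based, `i` in sequence 1, `j` in sequence 2) matched by an alignment.
#' Pairs must form a colinear partial matching: each position used at most
#' once per side, and `j` strictly increasing with `i`.
#'
#' @param i,j Integer vectors of equal length, 1-based positions.
#' @param source Label, e.g. `"reference"` or `"predicted"`.
#' @return An object of class `aligned_pair_set`: a two-column integer
#'   matrix (`i`, `j`) sorted by `i`, with a `source` attribute.
#' @export
aligned_pairs <- function(i, j, source = "predicted") {
  i <- as.integer(i); j <- as.integer(j)
  stopifnot(length(i) == length(j))
  if (length(i)) {
    if (any(i < 1L) || any(j < 1L)) stop("positions must be >= 1", call. = FALSE)
    o <- order(i)
    i <- i[o]; j <- j[o]
    if (anyDuplicated(i) || anyDuplicated(j))
      stop("each position may appear in at most one pair", call. = FALSE)
    if (is.unsorted(j, strictly = TRUE))
      stop("pairs must be colinear (no crossing pairs)", call. = FALSE)
  }
  structure(cbind(i = i, j = j), class = "aligned_pair_set", source = source)
}

#' @export
print.aligned_pair_set <- function(x, ...) {
  cat(sprintf("Aligned pair set (%s): %d pairs\n",
              attr(x, "source") %||% "?", nrow(x)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pair_keys <- function(pairs) {
  if (nrow(pairs) == 0L) character(0)
  else paste(pairs[, 1L], pairs[, 2L], sep = ":")
}

#' Read a reference pairwise alignment (aligned FASTA or Clustal)
#'
#' Extracts, for two rows of a gap-containing alignment, the set of matched
#' nucleotide positions: one `(i, j)` pair per column in which both rows hold
#' a nucleotide. Columns with a gap (`-` or `.`) in either row contribute no
#' pair. Ungapped (sequence) coordinates are recovered per row.
#'
#' @param path Aligned FASTA (gapped rows) or Clustal file.
#' @param rows Indices of the two rows to compare (default first two).
#' @return A list with `sequences` (named gapped rows, RNA-normalized) and
#'   `pairs` (an [aligned_pairs()] set, `source = "reference"`).
#' @export
read_reference_alignment <- function(path, rows = c(1L, 2L)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  gapped <- if (grepl("^CLUSTAL", first, ignore.case = TRUE))
    read_clustal(path) else read_gapped_fasta(path)
  if (length(gapped) < 2L)
    stop("alignment format error: fewer than 2 rows in ", path, call. = FALSE)
  if (length(unique(nchar(gapped))) != 1L)
    stop("alignment format error: rows have unequal aligned lengths",
         call. = FALSE)
  stopifnot(length(rows) == 2L, all(rows >= 1L), all(rows <= length(gapped)))
  list(sequences = gapped,
       pairs = gapped_rows_to_pairs(gapped[[rows[1L]]], gapped[[rows[2L]]]))
}

read_gapped_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr))
    stop("alignment format error: not FASTA or Clustal", call. = FALSE)
  rec <- cumsum(hdr)
  if (any(nzchar(trimws(lines)) & !hdr & rec == 0))
    stop("alignment format error: data before first header", call. = FALSE)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]),
                 function(x) gsub("[[:space:]]", "", paste(x, collapse = "")),
                 "")
  names(seqs) <- sub("^>\\s*", "", sub("\\s.*", "", lines[hdr]))
  normalize_gapped(seqs)
}

read_clustal <- function(path) {
  lines <- readLines(path, warn = FALSE)[-1L]
  lines <- lines[nzchar(trimws(lines))]
  # conservation lines hold only *:. and spaces; sequence lines start with a name
  keep <- grepl("^\\S+\\s+\\S+", lines) & !grepl("^[*:. ]+$", lines)
  lines <- lines[keep]
  if (!length(lines))
    stop("alignment format error: no sequence rows in Clustal file",
         call. = FALSE)
  name <- sub("\\s.*", "", lines)
  seqpart <- gsub("[[:space:]0-9]", "", sub("^\\S+\\s+", "", lines))
  seqs <- vapply(split(seqpart, factor(name, levels = unique(name))),
                 paste, "", collapse = "")
  normalize_gapped(seqs)
}

normalize_gapped <- function(seqs) {
  s <- chartr("T.", "U-", toupper(seqs))
  bad <- grepl("[^ACGUN-]", s)
  if (any(bad))
    stop("alignment format error: row '", names(s)[bad][1],
         "' contains non-IUPAC characters", call. = FALSE)
  as.list(s)
}

gapped_rows_to_pairs <- function(row1, row2) {
  if (nchar(row1) != nchar(row2))
    stop("alignment format error: rows have unequal aligned lengths",
         call. = FALSE)
  c1 <- strsplit(row1, "", fixed = TRUE)[[1]] != "-"
  c2 <- strsplit(row2, "", fixed = TRUE)[[1]] != "-"
  both <- c1 & c2
  aligned_pairs(cumsum(c1)[both], cumsum(c2)[both], source = "reference")
}

#' Matched pairs of a pairwise alignment
#'
#' Extracts the [aligned_pairs()] set (non-gap columns) from a
#' [gotoh_align()] result.
#'
#' @param alignment A `pairwise_alignment`.
#' @return An `aligned_pair_set` with `source = "predicted"`.
#' @export
alignment_pairs <- function(alignment) {
  stopifnot(inherits(alignment, "pairwise_alignment"))
  cols <- alignment$columns
  keep <- !is.na(cols[, 1L]) & !is.na(cols[, 2L])
  aligned_pairs(cols[keep, 1L], cols[keep, 2L], source = "predicted")
}

gapped_alignment_rows <- function(alignment, px, py) {
  cols <- alignment$columns
  bx <- profile_bases(px); by <- profile_bases(py)
  r1 <- ifelse(is.na(cols[, 1L]), "-", bx[cols[, 1L]])
  r2 <- ifelse(is.na(cols[, 2L]), "-", by[cols[, 2L]])
  stats::setNames(c(paste(r1, collapse = ""), paste(r2, collapse = "")),
                  c(px$name, py$name))
}

#' Write a pairwise alignment to disk
#'
#' `aligned-fasta` emits the two gapped rows as a FASTA alignment (readable
#' back by [read_reference_alignment()], and usable as input to
#' consistency-based MSA tools). `tsv` emits one line per alignment column
#' with positions (1-based, `-` for gaps), bases and reactivities of both
#' profiles — the reactivity-aligned report format.
#'
#' @param alignment A `pairwise_alignment` from [gotoh_align()].
#' @param px,py The two [reactivity_profile()]s that were aligned.
#' @param path Output path.
#' @param format `"aligned-fasta"` or `"tsv"`.
#' @export
write_pairwise_alignment <- function(alignment, px, py, path,
                                     format = c("aligned-fasta", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(alignment, "pairwise_alignment"),
            inherits(px, "reactivity_profile"),
            inherits(py, "reactivity_profile"))
  cols <- alignment$columns
  xi <- cols[, 1L]; yj <- cols[, 2L]
  if (any(xi[!is.na(xi)] > length(px)) || any(yj[!is.na(yj)] > length(py)))
    stop("alignment refers to positions outside the profiles", call. = FALSE)
  if (format == "aligned-fasta") {
    rows <- gapped_alignment_rows(alignment, px, py)
    writeLines(paste0(">", names(rows), "\n", rows), path)
  } else {
    bx <- profile_bases(px); by <- profile_bases(py)
    fmt_pos <- function(p) ifelse(is.na(p), "-", as.character(p))
    fmt_val <- function(v) ifelse(is.na(v), "-", sprintf("%.4f", v))
    rx <- ifelse(is.na(xi), NA_real_, px$reactivities[ifelse(is.na(xi), 1L, xi)])
    ry <- ifelse(is.na(yj), NA_real_, py$reactivities[ifelse(is.na(yj), 1L, yj)])
    lines <- c(
      "column\tx_pos\tx_base\tx_reactivity\ty_pos\ty_base\ty_reactivity",
      sprintf("%d\t%s\t%s\t%s\t%s\t%s\t%s",
              seq_len(nrow(cols)),
              fmt_pos(xi), ifelse(is.na(xi), "-", bx[ifelse(is.na(xi), 1L, xi)]),
              fmt_val(rx),
              fmt_pos(yj), ifelse(is.na(yj), "-", by[ifelse(is.na(yj), 1L, yj)]),
              fmt_val(ry)))
    writeLines(lines, path)
  }
  invisible(path)
}
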