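#' Per-nucleotide SHAPE reactivity profile
#'
#' A named RNA sequence together with one SHAPE reactivity per nucleotide.
#' Missing measurements (unprobed or sentinel `-999` positions on disk) are
#' stored as `NA`. Reactivities are in arbitrary normalized SHAPE units;
#' small negative values are legitimate (SHAPE-MaP normalization subtracts a
#' background) and are kept as-is.
#'
#' @param name Identifier string.
#' @param sequence RNA sequence over `A,C,G,U,N` (input `T` is normalized to
#'   `U`, case to upper).
#' @param reactivities Numeric vector, one value per nucleotide, `NA` for
#'   missing. Defaults to all-missing.
#' @return An object of class `reactivity_profile`.
#' @examples
#' reactivity_profile("hp", "GGGAAACCC", c(0.1, 0.2, 0.1, 1.5, 2, 1.2, 0.1, NA, 0.2))
#' @export
reactivity_profile <- function(name, sequence,
                               reactivities = rep(NA_real_, nchar(sequence))) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- normalize_rna(sequence)
  reactivities <- as.numeric(reactivities)
  if (nchar(sequence) != length(reactivities))
    stop("sequence length (", nchar(sequence), ") != number of reactivities (",
         length(reactivities), ")", call. = FALSE)
  if (any(!is.na(reactivities) & !is.finite(reactivities)))
    stop("non-finite reactivity value", call. = FALSE)
  structure(list(name = name, sequence = sequence, reactivities = reactivities),
            class = "reactivity_profile")
}

normalize_rna <- function(sequence) {
  s <- chartr("T", "U", toupper(sequence))
  if (grepl("[^ACGUN]", s))
    stop("sequence contains non-IUPAC characters (allowed: A,C,G,U/T,N)",
         call. = FALSE)
  s
}

#' @export
print.reactivity_profile <- function(x, ...) {
  n <- nchar(x$sequence)
  cat(sprintf("Reactivity profile '%s': %d nt, %d probed\n",
              x$name, n, sum(!is.na(x$reactivities))))
  invisible(x)
}

#' @export
length.reactivity_profile <- function(x) nchar(x$sequence)

profile_bases <- function(p) strsplit(p$sequence, "", fixed = TRUE)[[1]]

#' Read sequences from a FASTA file
#'
#' Sequences are upper-cased and DNA `T` is normalized to RNA `U`; record
#' names keep their case. Malformed input (text before the first header, an
#' empty record, or non-IUPAC characters) raises an error naming the
#' offending line.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  body <- nzchar(trimws(lines)) & !hdr
  if (any(body & cumsum(hdr) == 0))
    stop("FASTA format error at line ", which(body & cumsum(hdr) == 0)[1],
         ": sequence data before first '>' header", call. = FALSE)
  if (!any(hdr)) stop("FASTA format error: no records in ", path, call. = FALSE)
  rec <- cumsum(hdr)
  empty <- setdiff(seq_len(sum(hdr)), unique(rec[body]))
  if (length(empty)) {
    line <- which(hdr)[empty[1]]
    stop("FASTA format error at line ", line, ": empty record '",
         sub("^>\\s*", "", lines[line]), "'", call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*", "", names(set))
  bad <- grepl("[^ACGTUNacgtun]", seqs)
  if (any(bad))
    stop("FASTA format error: record '", names(seqs)[bad][1],
         "' contains non-IUPAC characters", call. = FALSE)
  vapply(seqs, normalize_rna, "")
}

#' Read a two-column SHAPE reactivity file
#'
#' The file holds one whitespace-delimited `position reactivity` pair per
#' line, positions 1-based; `-999` is the conventional sentinel for missing
#' data. Positions absent from the file are also treated as missing.
#'
#' @param path Path to the reactivity file.
#' @param sequence RNA sequence the profile belongs to.
#' @param name Profile name; defaults to the file's base name.
#' @return A [reactivity_profile()].
#' @export
read_shape_reactivities <- function(path, sequence,
                                    name = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sequence <- normalize_rna(sequence)
  n <- nchar(sequence)
  react <- rep(NA_real_, n)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (length(lines)) {
    fields <- strsplit(lines, "[[:space:]]+")
    if (any(lengths(fields) < 2L))
      stop("reactivity format error: line '",
           lines[which(lengths(fields) < 2L)[1]],
           "' has fewer than two columns", call. = FALSE)
    pos <- suppressWarnings(as.integer(vapply(fields, `[`, "", 1L)))
    val <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
    if (anyNA(pos))
      stop("reactivity format error: non-integer position", call. = FALSE)
    if (anyNA(val))
      stop("reactivity format error: non-numeric reactivity", call. = FALSE)
    if (any(pos < 1L | pos > n))
      stop("reactivity position ", pos[which(pos < 1L | pos > n)[1]],
           " outside sequence of length ", n, call. = FALSE)
    val[val == -999] <- NA_real_
    react[pos] <- val
  }
  reactivity_profile(name, sequence, react)
}

#' Write a profile's reactivities in the two-column dialect
#'
#' Inverse of [read_shape_reactivities()]: one `position reactivity` line per
#' nucleotide, `-999` for missing.
#'
#' @param profile A [reactivity_profile()].
#' @param path Output path.
#' @export
write_shape_reactivities <- function(profile, path) {
  stopifnot(inherits(profile, "reactivity_profile"))
  r <- profile$reactivities
  r[is.na(r)] <- -999
  writeLines(sprintf("%d %.6f", seq_along(r), r), path)
  invisible(path)
}

#' Read a FASTA + .shape file pair into a profile
#'
#' Convenience wrapper: the FASTA file's first record supplies name and
#' sequence, the reactivity file the SHAPE values.
#'
#' @param fasta_path FASTA file (first record used).
#' @param shape_path Two-column reactivity file.
#' @return A [reactivity_profile()].
#' @export
read_profile <- function(fasta_path, shape_path) {
  seqs <- read_fasta(fasta_path)
  p <- read_shape_reactivities(shape_path, seqs[[1L]], name = names(seqs)[1L])
  p
}
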