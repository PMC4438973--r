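#' Specification of a consensus folding job
#'
#' Bundles the inputs of the first pipeline step: a multiple (or pairwise)
#' sequence alignment, optional per-sequence SHAPE profiles, and the engine
#' options used throughout this workflow — ribosum covariation scoring, a
#' maximum base-pairing distance of 600 nt, and Deigan-style SHAPE
#' pseudo-free energies.
#'
#' @param alignment Named list/vector of gapped rows of equal length
#'   (`-` gaps), as returned in `read_reference_alignment()$sequences`.
#' @param profiles Optional list of [reactivity_profile()]s, one per row, in
#'   row order; each must match its row's ungapped length. Reactivities are
#'   passed to the engine as pseudo-free energy restraints.
#' @param max_pair_distance Maximum base-pair span in nucleotides
#'   (default 600).
#' @param ribosum Use ribosum covariation scoring (default `TRUE`).
#' @param shape_method Engine SHAPE-to-energy conversion string (default
#'   `"D"`, the Deigan conversion with engine-default slope/intercept).
#' @return A list of class `fold_job`.
#' @export
fold_job <- function(alignment, profiles = NULL,
                     max_pair_distance = 600L, ribosum = TRUE,
                     shape_method = "D") {
  alignment <- as.list(alignment)
  if (length(alignment) < 2L)
    stop("consensus folding needs an alignment of >= 2 rows", call. = FALSE)
  if (length(unique(nchar(unlist(alignment)))) != 1L)
    stop("alignment rows have unequal lengths", call. = FALSE)
  if (max_pair_distance <= 0)
    stop("max pair distance must be positive", call. = FALSE)
  if (!is.null(profiles)) {
    if (length(profiles) != length(alignment))
      stop("need one SHAPE profile per alignment row", call. = FALSE)
    ungapped <- nchar(gsub("-", "", unlist(alignment), fixed = TRUE))
    plen <- vapply(profiles, length, integer(1))
    if (!all(plen == ungapped))
      stop("profile lengths do not match ungapped row lengths", call. = FALSE)
  }
  structure(list(alignment = alignment, profiles = profiles,
                 max_pair_distance = as.integer(max_pair_distance),
                 ribosum = ribosum, shape_method = shape_method),
            class = "fold_job")
}

engine_path <- function(exe) {
  path <- Sys.which(exe)
  if (!nzchar(path))
    stop("folding engine not found: '", exe,
         "' must be on the PATH (ViennaRNA package)", call. = FALSE)
  path
}

engine_version <- function(exe) {
  out <- tryCatch(system2(engine_path(exe), "--version", stdout = TRUE,
                          stderr = TRUE),
                  error = function(e) "unknown")
  paste(out, collapse = " ")
}

run_engine <- function(exe, args, dir, label) {
  stdout_f <- file.path(dir, paste0(label, ".out"))
  stderr_f <- file.path(dir, paste0(label, ".err"))
  status <- system2(engine_path(exe), args, stdout = stdout_f,
                    stderr = stderr_f)
  if (!identical(status, 0L)) {
    err <- paste(readLines(stderr_f, warn = FALSE), collapse = "\n")
    stop(exe, " exited with status ", status, ":\n", err, call. = FALSE)
  }
  readLines(stdout_f, warn = FALSE)
}

write_clustal <- function(alignment, path) {
  nm <- names(alignment)
  if (is.null(nm)) nm <- paste0("seq", seq_along(alignment))
  nm <- gsub("[^A-Za-z0-9_.-]", "_", nm)
  width <- max(nchar(nm)) + 2L
  lines <- c("CLUSTAL W (shapealign)", "",
             sprintf(paste0("%-", width, "s%s"), nm, unlist(alignment)))
  writeLines(lines, path)
  invisible(path)
}

#' Consensus folding of an alignment with SHAPE restraints
#'
#' Invokes the alignment-folding engine (`RNAalifold`) with partition
#' function on, ribosum scoring, the job's maximum pairing distance, and
#' per-sequence SHAPE reactivity files as pseudo-free energy terms. The
#' engine's pair-probability output is parsed into base-pair probabilities
#' on alignment columns. Command line, engine version and working files are
#' recorded in the result for provenance.
#'
#' @param job A [fold_job()].
#' @param dir Working directory for engine files (default: fresh tempdir).
#' @return A list of class `consensus_fold`: `consensus_structure` (the
#'   engine's consensus dot-bracket as a [secondary_structure()] on
#'   alignment columns), `probabilities` (data.frame `i`, `j`, `prob`),
#'   `engine_version`, `command`.
#' @export
run_consensus_fold <- function(job, dir = tempfile("alifold")) {
  stopifnot(inherits(job, "fold_job"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  owd <- setwd(dir); on.exit(setwd(owd), add = TRUE)
  write_clustal(job$alignment, "input.aln")
  args <- c("-p", "--noPS", paste0("--maxBPspan=", job$max_pair_distance))
  if (job$ribosum) args <- c(args, "-r")
  if (!is.null(job$profiles)) {
    shape_files <- character(length(job$profiles))
    for (k in seq_along(job$profiles)) {
      shape_files[k] <- sprintf("seq%d.shape", k)
      write_shape_reactivities(job$profiles[[k]], shape_files[k])
    }
    args <- c(args, paste0("--shape=", paste(shape_files, collapse = ",")),
              paste0("--shapeMethod=", job$shape_method))
  }
  args <- c(args, "input.aln")
  out <- run_engine("RNAalifold", args, ".", "alifold_stdout")
  probs <- parse_alifold_out("alifold.out")
  db <- grep("^[().]+", out, value = TRUE)
  if (!length(db))
    stop("could not parse consensus structure from RNAalifold output",
         call. = FALSE)
  db <- sub("\\s.*$", "", db[1])
  st <- read_dotbracket_string(db)
  structure(list(consensus_structure = st, probabilities = probs,
                 engine_version = engine_version("RNAalifold"),
                 command = paste("RNAalifold", paste(args, collapse = " ")),
                 dir = dir),
            class = "consensus_fold")
}

read_dotbracket_string <- function(db, sequence = NULL) {
  tf <- tempfile(fileext = ".db")
  on.exit(unlink(tf))
  writeLines(c(if (!is.null(sequence)) sequence, db), tf)
  read_structure(tf, dialect = "dotbracket")
}

# alifold.out rows: "   i    j  <x> p% <entropy> <pairing types>"
parse_alifold_out <- function(path) {
  if (!file.exists(path))
    stop("engine produced no pair-probability output (", path, ")",
         call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rows <- grep("^\\s*[0-9]+\\s+[0-9]+\\s", lines, value = TRUE)
  if (!length(rows))
    return(data.frame(i = integer(0), j = integer(0), prob = numeric(0)))
  fields <- strsplit(trimws(rows), "[[:space:]]+")
  i <- as.integer(vapply(fields, `[`, "", 1L))
  j <- as.integer(vapply(fields, `[`, "", 2L))
  pcol <- vapply(fields, function(f) grep("%$", f, value = TRUE)[1], "")
  prob <- as.numeric(sub("%$", "", pcol)) / 100
  ok <- !is.na(i) & !is.na(j) & !is.na(prob)
  df <- data.frame(i = i[ok], j = j[ok], prob = prob[ok])
  df[order(-df$prob, df$i), ]
}

#' Extract high-probability consensus pairs
#'
#' Retains alignment-column pairs whose pairing probability is strictly
#' greater than the threshold (a pair at exactly the threshold is dropped).
#'
#' @param probabilities Data.frame `i`, `j`, `prob` (from
#'   [run_consensus_fold()]), probabilities in `[0, 1]`.
#' @param threshold Probability cutoff in `[0, 1)`; default 0.95.
#' @return A data.frame of class `consensus_pairs` (`i`, `j`, `prob`) with
#'   the threshold as attribute.
#' @export
extract_consensus_pairs <- function(probabilities, threshold = 0.95) {
  if (threshold < 0 || threshold >= 1)
    stop("threshold must lie in [0, 1)", call. = FALSE)
  if (nrow(probabilities) &&
      (any(probabilities$prob < 0) || any(probabilities$prob > 1)))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  keep <- probabilities[probabilities$prob > threshold, , drop = FALSE]
  keep <- keep[order(keep$i), , drop = FALSE]
  rownames(keep) <- NULL
  attr(keep, "threshold") <- threshold
  class(keep) <- c("consensus_pairs", "data.frame")
  keep
}

#' Map consensus column pairs onto one sequence's coordinates
#'
#' Converts alignment-column pairs to ungapped positions of a single row. A
#' pair is dropped for this sequence if either column is a gap in the row,
#' or if the mapped bases cannot form a canonical (Watson-Crick or G-U)
#' pair — constraints the individual folding engine would reject.
#'
#' @param pairs A `consensus_pairs` data.frame (columns `i`, `j` on
#'   alignment columns).
#' @param alignment_row The row's gapped sequence (string).
#' @return A data.frame `i`, `j` of 1-based sequence positions.
#' @export
map_consensus_to_sequence <- function(pairs, alignment_row) {
  chars <- strsplit(alignment_row, "", fixed = TRUE)[[1]]
  if (nrow(pairs) && max(pairs$i, pairs$j) > length(chars))
    stop("consensus pair column outside alignment width", call. = FALSE)
  nongap <- chars != "-"
  colmap <- ifelse(nongap, cumsum(nongap), NA_integer_)
  out <- data.frame(i = integer(0), j = integer(0))
  if (!nrow(pairs)) return(out)
  si <- colmap[pairs$i]; sj <- colmap[pairs$j]
  ok <- !is.na(si) & !is.na(sj)
  bases <- chartr("T", "U", toupper(chars))
  canonical <- paste0(bases[pairs$i], bases[pairs$j]) %in%
    c("AU", "UA", "GC", "CG", "GU", "UG")
  ok <- ok & canonical
  data.frame(i = si[ok], j = sj[ok])
}

#' Individually refold a sequence under hard pair constraints
#'
#' Invokes the single-sequence engine (`RNAfold`) with the consensus pairs
#' forced (`F i j 1` command constraints), SHAPE reactivities as
#' pseudo-free energies, and the maximum pairing distance. The minimum
#' free-energy structure is parsed back and checked to contain every
#' constraint pair.
#'
#' @param sequence RNA sequence (string) or a [reactivity_profile()].
#' @param shape Optional [reactivity_profile()] supplying SHAPE restraints
#'   (taken from `sequence` when it is a profile).
#' @param constraints Data.frame `i`, `j` of forced pairs (1-based), e.g.
#'   from [map_consensus_to_sequence()]. May be empty.
#' @param max_pair_distance Maximum base-pair span (default 600).
#' @param shape_method Engine SHAPE conversion string (default `"D"`).
#' @param dir Working directory for engine files (default: fresh tempdir).
#' @return A [secondary_structure()] (with `engine_version` and `command`
#'   attributes).
#' @export
constrained_individual_fold <- function(sequence, shape = NULL,
                                        constraints = NULL,
                                        max_pair_distance = 600L,
                                        shape_method = "D",
                                        dir = tempfile("rnafold")) {
  if (inherits(sequence, "reactivity_profile")) {
    if (is.null(shape) && any(!is.na(sequence$reactivities))) shape <- sequence
    sequence <- sequence$sequence
  }
  sequence <- normalize_rna(sequence)
  n <- nchar(sequence)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  owd <- setwd(dir); on.exit(setwd(owd), add = TRUE)
  writeLines(c(">seq", sequence), "input.fa")
  args <- c("--noPS", paste0("--maxBPspan=", max_pair_distance))
  has_constraints <- !is.null(constraints) && nrow(constraints) > 0L
  if (has_constraints) {
    if (any(constraints$i < 1L | constraints$j > n))
      stop("constraint pair outside sequence", call. = FALSE)
    writeLines(sprintf("F %d %d 1", constraints$i, constraints$j),
               "constraints.txt")
    args <- c(args, "--commands=constraints.txt")
  }
  if (!is.null(shape)) {
    write_shape_reactivities(shape, "shape.dat")
    args <- c(args, "--shape=shape.dat",
              paste0("--shapeMethod=", shape_method))
  }
  args <- c(args, "input.fa")
  out <- run_engine("RNAfold", args, ".", "rnafold_stdout")
  db <- grep("^[().]", out, value = TRUE)
  if (!length(db))
    stop("could not parse MFE structure from RNAfold output", call. = FALSE)
  db <- sub("\\s.*$", "", db[1])
  st <- read_dotbracket_string(db, sequence = sequence)
  if (has_constraints) {
    have <- paste(st$pairs[, 1L], st$pairs[, 2L])
    want <- paste(constraints$i, constraints$j)
    missing_pairs <- setdiff(want, have)
    if (length(missing_pairs))
      stop("engine did not honor constraint pair(s): ",
           paste(missing_pairs, collapse = ", "), call. = FALSE)
  }
  attr(st, "engine_version") <- engine_version("RNAfold")
  attr(st, "command") <- paste("RNAfold", paste(args, collapse = " "))
  st
}

#' Two-step consensus structure pipeline
#'
#' The full SHAPE-directed workflow: (1) consensus folding of the alignment
#' with covariation + SHAPE pseudo-energies; (2) extraction of pairs with
#' pairing probability above the threshold; (3) per-sequence mapping of
#' those pairs to ungapped coordinates; (4) constrained SHAPE-directed
#' individual refolding of each sequence.
#'
#' @param job A [fold_job()].
#' @param threshold Consensus pair probability cutoff (default 0.95).
#' @return A list of class `structure_pipeline_result`: `consensus` (the
#'   [run_consensus_fold()] result), `consensus_pairs`, and `individual` —
#'   a named list per row with `constraints` and `structure`.
#' @export
consensus_structure_pipeline <- function(job, threshold = 0.95) {
  stopifnot(inherits(job, "fold_job"))
  cons <- run_consensus_fold(job)
  cpairs <- extract_consensus_pairs(cons$probabilities, threshold)
  nm <- names(job$alignment)
  if (is.null(nm)) nm <- paste0("seq", seq_along(job$alignment))
  individual <- vector("list", length(job$alignment))
  names(individual) <- nm
  for (k in seq_along(job$alignment)) {
    row <- job$alignment[[k]]
    constr <- map_consensus_to_sequence(cpairs, row)
    seqk <- gsub("-", "", row, fixed = TRUE)
    shape <- if (!is.null(job$profiles)) job$profiles[[k]] else NULL
    st <- constrained_individual_fold(seqk, shape = shape,
                                      constraints = constr,
                                      max_pair_distance = job$max_pair_distance,
                                      shape_method = job$shape_method)
    individual[[k]] <- list(constraints = constr, structure = st)
  }
  structure(list(consensus = cons, consensus_pairs = cpairs,
                 individual = individual, threshold = threshold),
            class = "structure_pipeline_result")
}
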