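#' Alignment sensitivity against a reference
#'
#' Percentage of the reference's matched nucleotide pairs that are recovered
#' by a test alignment: `100 * |test intersect reference| / |reference|`.
#' Pair identity is exact (no positional allowance).
#'
#' @param test,reference [aligned_pairs()] sets.
#' @return Sensitivity as a percentage in `[0, 100]`.
#' @export
alignment_sensitivity <- function(test, reference) {
  stopifnot(inherits(test, "aligned_pair_set"),
            inherits(reference, "aligned_pair_set"))
  if (nrow(reference) == 0L)
    stop("sensitivity is undefined for an empty reference", call. = FALSE)
  100 * sum(pair_keys(test) %in% pair_keys(reference)) / nrow(reference)
}

#' Compare a predicted secondary structure with a reference
#'
#' Pseudoknotted and non-canonical pairs (anything other than Watson-Crick
#' or G-U) are removed from both structures first. A reference pair `(x, y)`
#' is then matched by any predicted pair `(x', y')` satisfying the local
#' refolding criterion
#' `(x == x' and |y - y'| <= allowance) or (y == y' and |x - x'| <= allowance)`:
#' one helix end must coincide exactly, the other may shift by up to
#' `allowance` nucleotides. Sensitivity is the percentage of (filtered)
#' reference pairs matched; PPV the percentage of (filtered) predicted pairs
#' matched.
#'
#' @param predicted,reference [secondary_structure()]s over the same
#'   sequence length.
#' @param allowance Maximum register shift (nucleotides); `0` reduces to
#'   exact pair matching. Default 5.
#' @return A list of class `structure_comparison`: `sens`, `ppv`
#'   (percentages), `allowance`, counts, and the matched/unmatched reference
#'   and predicted pair matrices.
#' @export
structure_compare <- function(predicted, reference, allowance = 5L) {
  stopifnot(inherits(predicted, "secondary_structure"),
            inherits(reference, "secondary_structure"))
  if (predicted$length != reference$length)
    stop("structures refer to different sequence lengths", call. = FALSE)
  if (allowance < 0) stop("allowance must be >= 0", call. = FALSE)
  keep <- function(s) s$pairs[s$canonical & !s$pseudoknot, , drop = FALSE]
  ref <- keep(reference); prd <- keep(predicted)
  match_one <- function(x, y, other) {
    if (nrow(other) == 0L) return(FALSE)
    any((other[, 1L] == x & abs(other[, 2L] - y) <= allowance) |
        (other[, 2L] == y & abs(other[, 1L] - x) <= allowance))
  }
  ref_hit <- vapply(seq_len(nrow(ref)),
                    function(k) match_one(ref[k, 1L], ref[k, 2L], prd),
                    logical(1))
  prd_hit <- vapply(seq_len(nrow(prd)),
                    function(k) match_one(prd[k, 1L], prd[k, 2L], ref),
                    logical(1))
  structure(list(
    sens = if (nrow(ref)) 100 * sum(ref_hit) / nrow(ref) else NA_real_,
    ppv = if (nrow(prd)) 100 * sum(prd_hit) / nrow(prd) else NA_real_,
    allowance = as.integer(allowance),
    n_reference = nrow(ref), n_predicted = nrow(prd),
    matched_reference = ref[ref_hit, , drop = FALSE],
    unmatched_reference = ref[!ref_hit, , drop = FALSE],
    matched_predicted = prd[prd_hit, , drop = FALSE],
    unmatched_predicted = prd[!prd_hit, , drop = FALSE]),
    class = "structure_comparison")
}

#' @export
print.structure_comparison <- function(x, ...) {
  cat(sprintf("Structure comparison (allowance %d nt): sens %.1f%% (%d ref pairs), ppv %.1f%% (%d predicted pairs)\n",
              x$allowance, x$sens, x$n_reference, x$ppv, x$n_predicted))
  invisible(x)
}

#' Distribution of reactivity differences over matched pairs
#'
#' For every matched pair `(i, j)` with both reactivities measured, computes
#' `|r_x(i) - r_y(j)|` and bins the values into a fixed-width histogram.
#' Pairs with a missing reactivity on either side are excluded.
#'
#' @param pairs An [aligned_pairs()] set.
#' @param px,py [reactivity_profile()]s.
#' @param bin_width Histogram bin width in SHAPE units (default 0.1).
#' @return A list of class `diff_distribution`: `bin_edges`, `counts`,
#'   `n_pairs`, and the raw `deltas`.
#' @export
reactivity_difference_distribution <- function(pairs, px, py,
                                               bin_width = 0.1) {
  stopifnot(inherits(pairs, "aligned_pair_set"))
  if (bin_width <= 0) stop("bin width must be positive", call. = FALSE)
  if (nrow(pairs) && (max(pairs[, 1L]) > length(px) ||
                      max(pairs[, 2L]) > length(py)))
    stop("pairs reference positions outside the profiles", call. = FALSE)
  rx <- px$reactivities[pairs[, 1L]]
  ry <- py$reactivities[pairs[, 2L]]
  ok <- !is.na(rx) & !is.na(ry)
  deltas <- abs(rx[ok] - ry[ok])
  edges <- seq(0, bin_width * (ceiling(max(deltas, bin_width) / bin_width) + 1L),
               by = bin_width)
  counts <- if (length(deltas))
    tabulate(findInterval(deltas, edges, rightmost.closed = TRUE),
             nbins = length(edges) - 1L)
  else integer(length(edges) - 1L)
  structure(list(bin_edges = edges, counts = counts,
                 n_pairs = length(deltas), deltas = deltas),
            class = "diff_distribution")
}

#' Randomized control for the reactivity-difference distribution
#'
#' The null model for "do related nucleotides have similar reactivities?":
#' in each trial the y-side reactivities are permuted uniformly at random
#' across the matched positions (conserving their multiset), and the
#' difference distribution is recomputed. Returns per-bin mean and standard
#' deviation over trials, and a two-sample Welch t-test comparing the
#' related `|delta|` sample against the pooled randomized `|delta|` sample.
#'
#' @param pairs An [aligned_pairs()] set.
#' @param px,py [reactivity_profile()]s.
#' @param n_trials Number of randomization trials (default 8).
#' @param seed Integer seed; required for reproducibility.
#' @param bin_width Histogram bin width (default 0.1).
#' @return A list of class `randomized_control`: `related`
#'   (the observed `diff_distribution`), `mean_counts`, `sd_counts`
#'   (per bin, across trials), `t_test` (the `htest`), `p_value`,
#'   `related_mean`, `randomized_mean`.
#' @export
randomized_control <- function(pairs, px, py, n_trials = 8L, seed,
                               bin_width = 0.1) {
  if (n_trials < 2L) stop("need at least 2 randomization trials", call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  related <- reactivity_difference_distribution(pairs, px, py, bin_width)
  if (related$n_pairs < 2L)
    stop("fewer than 2 pairs with reactivities on both sides", call. = FALSE)
  rx <- px$reactivities[pairs[, 1L]]
  ry <- py$reactivities[pairs[, 2L]]
  ok <- !is.na(rx) & !is.na(ry)
  rx <- rx[ok]; ry <- ry[ok]
  edges <- related$bin_edges
  nb <- length(edges) - 1L
  counts <- matrix(0L, n_trials, nb)
  rand_deltas <- vector("list", n_trials)
  set.seed(as.integer(seed))
  for (t in seq_len(n_trials)) {
    d <- abs(rx - sample(ry))
    rand_deltas[[t]] <- d
    # clamp into the related histogram range so every draw lands in a bin
    dc <- pmin(d, edges[length(edges)])
    counts[t, ] <- tabulate(findInterval(dc, edges, rightmost.closed = TRUE),
                            nbins = nb)
  }
  pooled <- unlist(rand_deltas)
  tt <- welch_or_degenerate(related$deltas, pooled)
  structure(list(related = related,
                 mean_counts = colMeans(counts),
                 sd_counts = apply(counts, 2L, stats::sd),
                 t_test = tt$htest, p_value = tt$p,
                 related_mean = mean(related$deltas),
                 randomized_mean = mean(pooled),
                 n_trials = n_trials),
            class = "randomized_control")
}

# Welch t-test that tolerates zero-variance samples (t.test errors or yields
# NaN on essentially-constant data): equal means then give p = 1, unequal 0.
welch_or_degenerate <- function(a, b) {
  ht <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
  if (!is.null(ht) && is.finite(ht$p.value))
    return(list(htest = ht, p = ht$p.value))
  list(htest = ht,
       p = if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
}

#' Write a difference-distribution report as TSV
#'
#' One row per histogram bin: `bin_low`, `bin_high`, `count`, and (when a
#' [randomized_control()] is given) `randomized_mean`, `randomized_sd`.
#'
#' @param dist A `diff_distribution`, or a `randomized_control` (whose
#'   related distribution and per-bin randomized statistics are both
#'   written).
#' @param path Output path.
#' @export
write_histogram_tsv <- function(dist, path) {
  ctrl <- NULL
  if (inherits(dist, "randomized_control")) { ctrl <- dist; dist <- dist$related }
  stopifnot(inherits(dist, "diff_distribution"))
  nb <- length(dist$bin_edges) - 1L
  df <- data.frame(bin_low = dist$bin_edges[-(nb + 1L)],
                   bin_high = dist$bin_edges[-1L],
                   count = dist$counts)
  if (!is.null(ctrl)) {
    df$randomized_mean <- ctrl$mean_counts
    df$randomized_sd <- ctrl$sd_counts
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an alignment-sensitivity table as TSV
#'
#' One row per benchmarked pair: the two profile names, one column of
#' sensitivity per alignment mode. Layout mirrors a standard pairwise
#' benchmark table.
#'
#' @param rows A data.frame with columns `sequence1`, `sequence2` and one or
#'   more numeric sensitivity columns.
#' @param path Output path.
#' @export
write_sensitivity_tsv <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write structure-comparison results as TSV
#'
#' One row per RNA: name, number of reference and predicted pairs after
#' filtering, sensitivity and PPV.
#'
#' @param comparisons Named list of `structure_comparison` objects.
#' @param path Output path.
#' @export
write_structure_tsv <- function(comparisons, path) {
  df <- do.call(rbind, lapply(names(comparisons), function(nm) {
    cc <- comparisons[[nm]]
    data.frame(rna = nm, n_reference = cc$n_reference,
               n_predicted = cc$n_predicted,
               sens = round(cc$sens, 1), ppv = round(cc$ppv, 1),
               allowance = cc$allowance)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
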