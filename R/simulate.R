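#' Configuration for the synthetic homolog simulator
#'
#' Defines the study conditions emulated by the generator: an ancestral RNA
#' with a two-component reactivity model (paired positions lowly reactive,
#' unpaired positions highly reactive) evolves into a descendant by
#' substitutions and geometric-length indels, while homologous positions
#' receive reactivity perturbations whose magnitudes are exponentially
#' distributed — reproducing the exponential decay of reactivity differences
#' observed between related nucleotides in curated rRNA alignments.
#'
#' @param length Ancestor length in nucleotides (default 1500, rRNA-scale).
#' @param substitution_rate Per-site base substitution probability
#'   (default 0.25, matching the divergence of the rRNA training pairs).
#' @param indel_rate Per-site probability of opening an indel (default 0.02).
#' @param mean_indel_length Mean indel length, geometric (default 3 nt).
#' @param related_delta_rate Rate `lambda` of the exponential reactivity
#'   perturbation between homologous positions, SHAPE units^-1 (default 4;
#'   mean related difference 0.25 SHAPE units).
#' @param missing_rate Fraction of positions with missing reactivity
#'   (default 0.05).
#' @param paired_fraction Fraction of base-paired (low-reactivity) positions
#'   (default 0.55, rRNA-like).
#' @param paired_mean,unpaired_mean Means of the exponential reactivity
#'   components for paired and unpaired positions (defaults 0.1 and 1.0
#'   SHAPE units).
#' @param seed Integer seed carried by the config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(length = 1500L, substitution_rate = 0.25,
                       indel_rate = 0.02, mean_indel_length = 3,
                       related_delta_rate = 4, missing_rate = 0.05,
                       paired_fraction = 0.55,
                       paired_mean = 0.1, unpaired_mean = 1.0,
                       seed = 101L) {
  cfg <- list(length = as.integer(length),
              substitution_rate = substitution_rate,
              indel_rate = indel_rate,
              mean_indel_length = mean_indel_length,
              related_delta_rate = related_delta_rate,
              missing_rate = missing_rate,
              paired_fraction = paired_fraction,
              paired_mean = paired_mean, unpaired_mean = unpaired_mean,
              seed = as.integer(seed))
  rates <- c(cfg$substitution_rate, cfg$indel_rate, cfg$missing_rate,
             cfg$paired_fraction)
  if (any(rates < 0 | rates > 1))
    stop("rates must lie in [0, 1]", call. = FALSE)
  if (cfg$length < 1L) stop("length must be >= 1", call. = FALSE)
  if (cfg$related_delta_rate <= 0) stop("lambda must be > 0", call. = FALSE)
  if (cfg$mean_indel_length < 1) stop("mean indel length must be >= 1",
                                      call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

draw_reactivity <- function(n, paired, config) {
  means <- ifelse(paired, config$paired_mean, config$unpaired_mean)
  stats::rexp(n, rate = 1 / means)
}

#' Simulate a reactivity profile over a pairing mask
#'
#' Paired positions draw from a low-reactivity exponential component (mean
#' `paired_mean`), unpaired positions from a high one (mean
#' `unpaired_mean`); values are non-negative by construction. Missing data
#' are injected at `missing_rate`. Deterministic under `seed`.
#'
#' @param structure_mask Logical vector, `TRUE` for paired positions; its
#'   length must equal `config$length`.
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param name Profile name.
#' @return A [reactivity_profile()] with a random sequence and the `mask`
#'   stored as an attribute.
#' @export
simulate_reactivity_profile <- function(structure_mask, config = sim_config(),
                                        seed = config$seed,
                                        name = "synthetic") {
  if (length(structure_mask) != config$length)
    stop("mask length must equal config$length", call. = FALSE)
  set.seed(as.integer(seed))
  n <- config$length
  bases <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
  react <- draw_reactivity(n, structure_mask, config)
  react[stats::runif(n) < config$missing_rate] <- NA_real_
  p <- reactivity_profile(name, paste(bases, collapse = ""), react)
  attr(p, "mask") <- structure_mask
  p
}

#' Evolve a homologous descendant with a known true alignment
#'
#' Walks the ancestor applying per-site substitutions and geometric-length
#' indels (insertions and deletions equally likely). Homologous positions
#' keep the ancestor's reactivity plus a sign-symmetric exponential
#' perturbation of rate `related_delta_rate`, clipped at zero, so the
#' absolute reactivity difference between truly related positions follows
#' the exponential-decay distribution the aligner's scoring function is
#' built for. Inserted positions draw fresh reactivities from the marginal
#' model. The exact ancestor-to-descendant position matching is returned.
#'
#' @param ancestor A [reactivity_profile()] (typically from
#'   [simulate_reactivity_profile()]).
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed + 1` so that an
#'   ancestor and its descendant use distinct streams).
#' @return A list with `descendant` (a [reactivity_profile()]) and
#'   `true_pairs` (an [aligned_pairs()] set, `source = "reference"`).
#' @export
evolve_homolog <- function(ancestor, config = sim_config(),
                           seed = config$seed + 1L) {
  stopifnot(inherits(ancestor, "reactivity_profile"))
  set.seed(as.integer(seed))
  anc_bases <- profile_bases(ancestor)
  anc_react <- ancestor$reactivities
  mask <- attr(ancestor, "mask") %||% rep(FALSE, length(ancestor))
  n <- length(ancestor)
  alphabet <- c("A", "C", "G", "U")

  out_bases <- character(0)
  out_react <- numeric(0)
  out_mask <- logical(0)
  ti <- integer(0); tj <- integer(0)

  i <- 1L
  while (i <= n) {
    if (stats::runif(1) < config$indel_rate) {
      len <- 1L + stats::rgeom(1, 1 / config$mean_indel_length)
      if (stats::runif(1) < 0.5) {           # deletion: skip ancestor sites
        i <- i + len
        next
      } else {                               # insertion: novel descendant sites
        ins_mask <- stats::runif(len) < config$paired_fraction
        ins_react <- draw_reactivity(len, ins_mask, config)
        ins_react[stats::runif(len) < config$missing_rate] <- NA_real_
        out_bases <- c(out_bases, sample(alphabet, len, replace = TRUE))
        out_react <- c(out_react, ins_react)
        out_mask <- c(out_mask, ins_mask)
      }
    }
    # homologous site
    base <- anc_bases[i]
    if (stats::runif(1) < config$substitution_rate)
      base <- sample(setdiff(alphabet, base), 1L)
    r <- anc_react[i]
    if (!is.na(r)) {
      # sign-symmetric exponential perturbation; a step that would cross zero
      # is reflected upward so |delta| stays exactly Exp(lambda) and
      # reactivities stay non-negative
      delta <- stats::rexp(1, config$related_delta_rate)
      s <- sample(c(-1, 1), 1L)
      if (s < 0 && r - delta < 0) s <- 1
      r <- r + s * delta
    }
    if (stats::runif(1) < config$missing_rate) r <- NA_real_
    out_bases <- c(out_bases, base)
    out_react <- c(out_react, r)
    out_mask <- c(out_mask, mask[i])
    ti <- c(ti, i); tj <- c(tj, length(out_bases))
    i <- i + 1L
  }
  if (!length(out_bases)) {  # pathological all-deleted case
    out_bases <- sample(alphabet, 1L)
    out_react <- draw_reactivity(1L, FALSE, config)
    out_mask <- FALSE
  }
  d <- reactivity_profile(paste0(ancestor$name, "_descendant"),
                          paste(out_bases, collapse = ""), out_react)
  attr(d, "mask") <- out_mask
  list(descendant = d,
       true_pairs = aligned_pairs(ti, tj, source = "reference"))
}

#' Simulate a homologous profile pair
#'
#' Convenience wrapper: draws a pairing mask, simulates the ancestor, and
#' evolves one descendant.
#'
#' @param config A [sim_config()].
#' @return A list with `px` (ancestor), `py` (descendant) and `true_pairs`.
#' @export
simulate_homolog_pair <- function(config = sim_config()) {
  set.seed(config$seed)
  mask <- stats::runif(config$length) < config$paired_fraction
  px <- simulate_reactivity_profile(mask, config, seed = config$seed,
                                    name = "ancestor")
  ev <- evolve_homolog(px, config)
  list(px = px, py = ev$descendant, true_pairs = ev$true_pairs)
}
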