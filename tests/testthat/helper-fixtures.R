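# shared fixture builders; everything is generated in code

make_profile <- function(seq, react, name = "p") {
  reactivity_profile(name, seq, react)
}

random_profile <- function(n, name = "p", missing_rate = 0.15) {
  seq <- paste(sample(c("A", "C", "G", "U", "N"), max(n, 0), replace = TRUE),
               collapse = "")
  r <- round(runif(n, -0.2, 3), 3)
  r[runif(n) < missing_rate] <- NA
  reactivity_profile(name, seq, r)
}

random_valid_params <- function(mode = sample(c("shape_only", "combined"), 1)) {
  alignment_params(mode,
                   m = -runif(1, 0.5, 4), b = runif(1, 0.5, 4),
                   gop = -runif(1, 0, 8), gep = -runif(1, 0, 2),
                   match = runif(1, 0, 3), mismatch = -runif(1, 0, 3))
}

alignment_key <- function(cols) paste(cols[, 1], cols[, 2], collapse = ";")

# unambiguous 18-nt hairpin: 6 GC-stem pairs, hexaloop, with compensating
# substitutions across rows so covariation supports the stem
hairpin_alignment <- function() {
  list(s1 = "GGGGGGAAAAAACCCCCC",
       s2 = "GGGGGGAACAAACCCCCC",
       s3 = "GGGCGGAAAAAACCGCCC",
       s4 = "GGGGCGAAAAAACGCCCC")
}

hairpin_profiles <- function(aln = hairpin_alignment()) {
  shape <- c(rep(0.1, 6), rep(1.6, 6), rep(0.1, 6))
  lapply(names(aln), function(n) reactivity_profile(n, aln[[n]], shape))
}

hairpin_stem_pairs <- function() cbind(x = 1:6, y = 18:13)

engine_available <- function() {
  nzchar(Sys.which("RNAalifold")) && nzchar(Sys.which("RNAfold"))
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
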