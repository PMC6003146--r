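# Independent oracles for the aligner tests: exhaustive recursion over all
# monotone alignment paths (no banding, no traceback machinery shared with
# the implementation).  Only usable for tiny strings.

oracle_sub <- function(a, b, scoring) {
  if (a == b && a %in% c("A", "C", "G", "T")) scoring$match
  else scoring$mismatch
}

# best global score of h[j+1..], v[i+1..] by plain recursion
oracle_global <- function(h, v, scoring = scoring_scheme()) {
  hs <- strsplit(h, "")[[1]]
  vs <- strsplit(v, "")[[1]]
  rec <- function(j, i) {
    if (j > length(hs) && i > length(vs)) return(0L)
    best <- -.Machine$integer.max
    if (j <= length(hs) && i <= length(vs))
      best <- max(best, oracle_sub(hs[j], vs[i], scoring) + rec(j + 1, i + 1))
    if (j <= length(hs)) best <- max(best, scoring$gap + rec(j + 1, i))
    if (i <= length(vs)) best <- max(best, scoring$gap + rec(j, i + 1))
    best
  }
  rec(1L, 1L)
}

# best overlap (semi-global) score: global score of a core h[j0+1..j1] vs
# v[i0+1..i1] where the start lies on row 0 or column 0 of the lattice and
# the end on the last row or column; enumerated exhaustively.
oracle_semiglobal <- function(h, v, scoring = scoring_scheme()) {
  l1 <- nchar(h); l2 <- nchar(v)
  best <- 0L  # empty core (pure end-gap alignment) scores 0
  for (i0 in 0:l2) for (j0 in 0:l1) {
    if (i0 > 0 && j0 > 0) next
    for (i1 in i0:l2) for (j1 in j0:l1) {
      if (i1 < l2 && j1 < l1) next
      best <- max(best, oracle_global(substr(h, j0 + 1, j1),
                                      substr(v, i0 + 1, i1), scoring))
    }
  }
  best
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# fabricate a minimal band_alignment for certification unit tests
fake_alignment <- function(n_match, touched_edge, extra = 0L) {
  s <- paste(rep("A", n_match + extra), collapse = "")
  structure(list(score = 3L * n_match, cigar = paste0(n_match, "M"),
                 start = c(i = 0L, j = 0L),
                 end = c(i = n_match, j = n_match),
                 n_match = n_match, n_mismatch = 0L, n_gap = 0L,
                 touched_edge = touched_edge, band = NULL,
                 mode = "semiglobal", swapped = FALSE,
                 seq_h = s, seq_v = s), class = "band_alignment")
}
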