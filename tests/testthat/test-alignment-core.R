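test_that("full DP reproduces hand-checked global and overlap alignments", {
  a <- full_dp_align("ACGT", "ACGT")
  expect_equal(a$score, 12L)
  expect_equal(a$cigar, "4M")
  expect_equal(a$n_match, 4L)

  b <- full_dp_align("ACGT", "AGT")
  expect_equal(b$score, 7L)
  expect_equal(b$cigar, "1M1D2M")
  expect_equal(b$n_match, 3L)

  s <- full_dp_align("GGGACGTGGG", "ACGT", mode = "semiglobal")
  expect_equal(s$score, 12L)
  expect_equal(s$cigar, "4M")
  # both GGG flanks are free end gaps: aligned core covers h[4..7] only
  expect_equal(unname(s$start), c(0L, 3L))
  expect_equal(unname(s$end), c(4L, 7L))

  expect_error(full_dp_align("", "ACGT"), "non-empty")
  expect_error(full_dp_align("ACGT", ""), "non-empty")
})

test_that("full DP agrees with exhaustive path enumeration on tiny pairs", {
  set.seed(101)
  for (k in 1:30) {
    h <- random_dna(sample(2:7, 1))
    v <- random_dna(sample(2:7, 1))
    expect_equal(full_dp_align(h, v)$score, oracle_global(h, v),
                 info = paste(h, v, "global"))
    expect_equal(full_dp_align(h, v, mode = "semiglobal")$score,
                 oracle_semiglobal(h, v), info = paste(h, v, "semiglobal"))
  }
})

test_that("full DP scores match the Biostrings aligner on random pairs", {
  set.seed(202)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 3, mismatch = -1,
                                                  baseOnly = TRUE)
  for (k in 1:15) {
    h <- random_dna(sample(50:150, 1))
    v <- random_dna(sample(50:150, 1))
    pg <- Biostrings::pairwiseAlignment(v, h, substitutionMatrix = mat,
                                        gapOpening = 0, gapExtension = 2,
                                        type = "global", scoreOnly = TRUE)
    po <- Biostrings::pairwiseAlignment(v, h, substitutionMatrix = mat,
                                        gapOpening = 0, gapExtension = 2,
                                        type = "overlap", scoreOnly = TRUE)
    expect_equal(full_dp_align(h, v)$score, pg)
    expect_equal(full_dp_align(h, v, mode = "semiglobal")$score, po)
  }
})

test_that("non-ACGT letters never match, even against themselves", {
  a <- full_dp_align("NNNN", "NNNN")
  expect_equal(a$score, -4L)     # 4 mismatches beat any gapped layout
  expect_equal(a$n_match, 0L)
  expect_equal(count_matches(a), 0L)
})

test_that("banded DP with a full-width band equals full DP", {
  set.seed(303)
  for (k in 1:200) {
    h <- random_dna(sample(20:300, 1))
    v <- random_dna(sample(20:300, 1))
    mode <- if (k %% 2) "global" else "semiglobal"
    f <- full_dp_align(h, v, mode = mode)
    b <- banded_dp_align(h, v, mode = mode, band = max(nchar(h), nchar(v)))
    expect_identical(b$score, f$score)
    expect_identical(b$cigar, f$cigar)
  }
})

test_that("banded score never exceeds full score and grows with w", {
  set.seed(404)
  for (k in 1:50) {
    h <- random_dna(sample(100:200, 1))
    v <- random_dna(sample(100:200, 1))
    f <- full_dp_align(h, v, mode = "semiglobal")
    prev <- -Inf
    for (w in c(2L, 5L, 10L, 40L, 300L)) {
      b <- banded_dp_align(h, v, mode = "semiglobal", band = w)
      expect_lte(b$score, f$score)
      expect_gte(b$score, prev)
      prev <- b$score
    }
  }
})

test_that("zero-width band aligns identical sequences along the diagonal", {
  b <- banded_dp_align("ACGT", "ACGT", band = 0)
  expect_equal(b$score, 12L)
  expect_equal(b$cigar, "4M")
  expect_error(dp_band(-1, 4, 4), ">= 0")
})

test_that("banded DP handles long sequences a full matrix could not", {
  # 100 kb identical reads in a w = 2 band: ~0.5M stored cells versus
  # 1e10 for the full matrix
  s <- random_sequence(100000, seed = 99)
  b <- banded_dp_align(s, s, band = 2)
  expect_equal(b$score, 300000L)
  expect_equal(b$cigar, "100000M")
})

test_that("scores re-derive exactly from CIGAR and sequences", {
  set.seed(505)
  sc <- scoring_scheme(2, -3, -4)
  for (k in 1:40) {
    h <- random_dna(sample(30:120, 1))
    v <- random_dna(sample(30:120, 1))
    mode <- if (k %% 2) "global" else "semiglobal"
    r <- if (k %% 3) full_dp_align(h, v, sc, mode)
         else banded_dp_align(h, v, sc, mode, band = 8L)
    expect_identical(rescore_alignment(r, sc), r$score)
    expect_identical(count_matches(r), r$n_match)
  }
})

test_that("global CIGARs consume both sequences exactly", {
  set.seed(606)
  for (k in 1:30) {
    h <- random_dna(sample(10:80, 1))
    v <- random_dna(sample(10:80, 1))
    r <- full_dp_align(h, v)
    ops <- banddp:::parse_cigar(r$cigar)
    expect_equal(sum(ops != "I"), nchar(h))  # M + D columns
    expect_equal(sum(ops != "D"), nchar(v))  # M + I columns
  }
})

test_that("path deviation is the signed maximal diagonal excursion", {
  d0 <- path_deviation_stat(full_dp_align("ACGTACGT", "ACGTACGT"))
  expect_identical(d0, 0L)

  # 3 consecutive D columns (gaps in the vertical sequence) push j ahead
  # of i: excursion -3; 3 I columns give +3
  r <- full_dp_align("ACGGGGCT", "ACCT")
  expect_equal(r$cigar, "2M4D2M")
  expect_identical(path_deviation_stat(r), -4L)
  r2 <- full_dp_align("ACCT", "ACGGGGCT")
  expect_equal(r2$cigar, "2M4I2M")
  expect_identical(path_deviation_stat(r2), 4L)

  # swapping the two roles negates the excursion
  set.seed(707)
  for (k in 1:10) {
    h <- random_dna(60); v <- random_dna(50)
    expect_identical(path_deviation_stat(full_dp_align(h, v)),
                     -path_deviation_stat(full_dp_align(v, h)))
  }
})

test_that("touched_edge reflects the traceback path, not filled cells", {
  # identical reads in a wide band: path is the diagonal, far from edges
  b <- banded_dp_align("ACGTACGTAC", "ACGTACGTAC", band = 3)
  expect_false(b$touched_edge)
  # in a zero-width band every path cell sits on the boundary offset
  b0 <- banded_dp_align("ACGTACGTAC", "ACGTACGTAC", band = 0)
  expect_true(b0$touched_edge)
  # a 2-base insertion burst in a w = 2 symmetric band: the optimal path
  # moves onto the band edge, follows it, and still matches the full DP
  flank <- strrep("ACGT", 5)
  h2 <- paste0(flank, "GG", flank)
  v2 <- paste0(flank, flank)
  b2 <- banded_dp_align(h2, v2, mode = "semiglobal",
                        band = dp_band(2, nchar(h2), nchar(v2),
                                       extend = FALSE))
  expect_true(b2$touched_edge)
  expect_equal(b2$score, full_dp_align(h2, v2, mode = "semiglobal")$score)
  # a burst much wider than the band: the constrained path is suboptimal
  # yet may stay off the edge (diagonal mismatches), the hard case the
  # match-count criterion exists for
  h8 <- paste0(flank, strrep("G", 8), flank)
  b8 <- banded_dp_align(h8, v2, mode = "semiglobal",
                        band = dp_band(2, nchar(h8), nchar(v2),
                                       extend = FALSE))
  expect_lt(b8$score, full_dp_align(h8, v2, mode = "semiglobal")$score)
})

test_that("orientation swap is transparent to the caller", {
  h <- random_dna(40); v <- random_dna(60)  # seq_h shorter after swap
  b <- banded_dp_align(h, v, mode = "global", band = 60)
  f <- full_dp_align(h, v, mode = "global")
  expect_identical(b$score, f$score)
  expect_identical(b$cigar, f$cigar)
  expect_identical(rescore_alignment(b), b$score)
})
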