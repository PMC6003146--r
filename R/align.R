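#' Diagonal band geometry
#'
#' A band over the alignment lattice of a horizontal sequence of length `l1`
#' (columns) and a vertical sequence of length `l2 <= l1` (rows).  With
#' `extend = TRUE` (the default, the *corridor* band) a cell `(i, j)` is
#' in-band iff `-w - (l1 - l2) <= i - j <= +w`: the band of half-width `w`
#' hugs the corridor between the main diagonal and the end-to-end diagonal,
#' so a global path can always reach the corner cell and, when `w >= l2`,
#' the band covers the whole matrix.  With `extend = FALSE` the band is
#' symmetric about the main diagonal, `|i - j| <= w`, and does not widen
#' with the length difference -- the geometry under which restart rates
#' follow the random-walk model directly.
#'
#' @param w Non-negative integer half-width.
#' @param l1 Length of the longer (horizontal) sequence.
#' @param l2 Length of the shorter (vertical) sequence.
#' @param extend Extend the lower side by `l1 - l2` (corridor band)?
#' @return An object of class `dp_band` with fields `w`, `l1`, `l2`,
#'   `extend`, and the resolved boundary offsets `w_hi` (= `w`) and `w_lo`.
#' @export
dp_band <- function(w, l1, l2, extend = TRUE) {
  w <- as.integer(w); l1 <- as.integer(l1); l2 <- as.integer(l2)
  if (is.na(w) || w < 0L) stop("band half-width `w` must be >= 0")
  if (is.na(l1) || is.na(l2) || l1 < 1L || l2 < 1L) stop("invalid lengths")
  if (l1 < l2) stop("`l1` must be >= `l2`")
  structure(list(w = w, l1 = l1, l2 = l2, extend = isTRUE(extend),
                 w_hi = w,
                 w_lo = w + if (isTRUE(extend)) l1 - l2 else 0L),
            class = "dp_band")
}

#' @rdname dp_band
#' @param band A `dp_band`.
#' @param i,j Lattice coordinates (0-based rows/columns).
#' @return `in_band()`: logical, whether each `(i, j)` lies inside the band.
#' @export
in_band <- function(band, i, j) {
  s <- i - j
  s >= -band$w_lo & s <= band$w_hi
}

#' @export
print.dp_band <- function(x, ...) {
  cat(sprintf("band: w = %d (%s) over %d x %d lattice (width %d)\n",
              x$w, if (x$extend) "corridor" else "symmetric",
              x$l2, x$l1, x$w_hi + x$w_lo + 1L))
  invisible(x)
}

check_sequence <- function(s, arg) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || nchar(s) == 0L)
    stop("`", arg, "` must be a single non-empty string")
  toupper(s)
}

new_alignment <- function(raw, seq_h, seq_v, mode, band, swapped) {
  if (swapped) {
    # the DP ran on the transposed problem: swap I<->D and (i,j) coords
    raw$cigar <- chartr("ID", "DI", raw$cigar)
    tmp <- raw$i0; raw$i0 <- raw$j0; raw$j0 <- tmp
    tmp <- raw$i1; raw$i1 <- raw$j1; raw$j1 <- tmp
  }
  structure(list(
    score = raw$score,
    cigar = raw$cigar,
    start = c(i = raw$i0, j = raw$j0),
    end = c(i = raw$i1, j = raw$j1),
    n_match = raw$n_match,
    n_mismatch = raw$n_mismatch,
    n_gap = raw$n_gap,
    touched_edge = raw$touched_edge,
    band = band,
    mode = mode,
    swapped = swapped,
    seq_h = seq_h,
    seq_v = seq_v), class = "band_alignment")
}

#' Full-matrix dynamic-programming alignment
#'
#' Needleman-Wunsch alignment over the complete `(l2+1) x (l1+1)` score
#' matrix, in global mode (path anchored at both corner cells) or
#' semi-global / overlap mode (leading and trailing gaps in either sequence
#' are free: first row and column start at 0 and the score is maximised
#' over the last row and column).  Only `A`, `C`, `G`, `T` can match; any
#' other letter mismatches even against itself.  Traceback ties prefer a
#' match/mismatch column, then a gap in the vertical sequence, then a gap
#' in the horizontal one, so output is deterministic.
#'
#' CIGAR convention: `M` = aligned pair, `I` = base of the vertical
#' (second) sequence opposite a gap in the horizontal one, `D` = base of
#' the horizontal (first) sequence opposite a gap in the vertical one.
#' Hence `#M + #D = l1` and `#M + #I = l2` in global mode; in semi-global
#' mode the CIGAR covers only the aligned core between `start` and `end`.
#'
#' @param seq_h Horizontal (first) sequence, a nucleotide string.
#' @param seq_v Vertical (second) sequence.
#' @param scoring A [scoring_scheme()].
#' @param mode `"global"` or `"semiglobal"`.
#'
#' @return An object of class `band_alignment` with elements `score`,
#'   `cigar`, `start`/`end` (0-based lattice nodes of the traceback path),
#'   `n_match`, `n_mismatch`, `n_gap`, `touched_edge` (`NA` for the full
#'   matrix), `band` (`NULL` here), and `mode`.
#' @examples
#' full_dp_align("ACGT", "ACGT")           # score 12, "4M"
#' full_dp_align("ACGT", "AGT")            # score 7, "1M1D2M"
#' full_dp_align("GGGACGTGGG", "ACGT", mode = "semiglobal")
#' @export
full_dp_align <- function(seq_h, seq_v, scoring = scoring_scheme(),
                          mode = c("global", "semiglobal")) {
  mode <- match.arg(mode)
  seq_h <- check_sequence(seq_h, "seq_h")
  seq_v <- check_sequence(seq_v, "seq_v")
  raw <- cpp_full_dp(seq_h, seq_v, scoring$match, scoring$mismatch,
                     scoring$gap, mode == "semiglobal")
  raw$touched_edge <- NA
  new_alignment(raw, seq_h, seq_v, mode, band = NULL, swapped = FALSE)
}

#' Banded dynamic-programming alignment
#'
#' Same alignment problem as [full_dp_align()] but the path is confined to
#' a diagonal band ([dp_band()]): only in-band cells are filled, boundary
#' cells use in-band predecessors only, and storage and time are
#' proportional to `(w_hi + w_lo + 1) * l2` rather than `l1 * l2`.  If
#' the first sequence is the shorter one the pair is transposed internally
#' and the reported alignment is mapped back, so the band geometry always
#' sees `l1 >= l2`.  `touched_edge` is `TRUE` iff some cell of the
#' traceback path lies on a band boundary offset (`i - j` equal to `+w` or
#' `-w_lo`), the first optimality-certification criterion for semi-global
#' alignments.  Global mode errors if the band cannot reach the corner
#' cell (only possible for a symmetric band narrower than `l1 - l2`).
#'
#' @inheritParams full_dp_align
#' @param band A [dp_band()], or a single non-negative integer taken as the
#'   half-width `w` (lengths are then derived from the sequences).
#' @return A `band_alignment`; see [full_dp_align()].  `band` holds the
#'   `dp_band` used (in internal orientation, `l1 >= l2`).
#' @examples
#' a <- banded_dp_align("ACGT", "ACGT", band = 0)   # diagonal band, score 12
#' a$score
#' @export
banded_dp_align <- function(seq_h, seq_v, scoring = scoring_scheme(),
                            mode = c("global", "semiglobal"), band) {
  mode <- match.arg(mode)
  seq_h <- check_sequence(seq_h, "seq_h")
  seq_v <- check_sequence(seq_v, "seq_v")
  swapped <- nchar(seq_h) < nchar(seq_v)
  h <- if (swapped) seq_v else seq_h
  v <- if (swapped) seq_h else seq_v
  if (is.numeric(band)) band <- dp_band(band, nchar(h), nchar(v))
  if (!inherits(band, "dp_band")) stop("`band` must be a dp_band or a half-width")
  if (band$l1 != nchar(h) || band$l2 != nchar(v))
    stop("band lengths (", band$l1, ", ", band$l2,
         ") do not match the sequences (", nchar(h), ", ", nchar(v), ")")
  raw <- cpp_banded_dp(h, v, scoring$match, scoring$mismatch, scoring$gap,
                       mode == "semiglobal", band$w_hi, band$w_lo,
                       prefer_up = swapped)
  new_alignment(raw, seq_h, seq_v, mode, band = band, swapped = swapped)
}

parse_cigar <- function(cigar) {
  if (nchar(cigar) == 0L)
    return(character(0))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MID]", cigar))[[1]]
  if (length(lens) != length(ops)) stop("malformed CIGAR: ", cigar)
  rep(ops, lens)
}

#' Lattice path of an alignment
#'
#' Reconstructs the ordered list of matrix nodes visited by the traceback
#' path, from `start` to `end`, as a two-column integer matrix of 0-based
#' `(i, j)` lattice coordinates (`i` indexes the vertical sequence, `j` the
#' horizontal one).
#'
#' @param result A `band_alignment`.
#' @return Integer matrix with columns `i` and `j`.
#' @export
alignment_path <- function(result) {
  ops <- parse_cigar(result$cigar)
  di <- unname(c(M = 1L, I = 1L, D = 0L)[ops])
  dj <- unname(c(M = 1L, I = 0L, D = 1L)[ops])
  cbind(i = result$start[["i"]] + c(0L, cumsum(di)),
        j = result$start[["j"]] + c(0L, cumsum(dj)))
}

#' Maximal signed diagonal excursion of an alignment path
#'
#' The travelled distance `d` of the band model: over the path nodes
#' `(i_k, j_k)` it is the signed offset `s_k = i_k - j_k` at the index
#' maximising `|s_k|` (earliest such index on ties).  Under symmetric
#' simulations its mean is ~0 and its standard deviation is what the
#' random-walk model estimates as `sigma_d`; swapping the roles of the two
#' sequences negates it.
#'
#' @param result A `band_alignment`.
#' @return A single integer, the signed excursion.
#' @export
path_deviation_stat <- function(result) {
  p <- alignment_path(result)
  s <- p[, "i"] - p[, "j"]
  s[which.max(abs(s))]
}

#' Number of identical aligned pairs
#'
#' Recomputes the match count of an alignment from its CIGAR and the two
#' sequences (rather than trusting the stored `n_match`).  Only A/C/G/T
#' letters can match.
#'
#' @param result A `band_alignment`.
#' @return Integer count of `M` columns whose two characters are identical.
#' @export
count_matches <- function(result) {
  ops <- parse_cigar(result$cigar)
  if (length(ops) == 0L) return(0L)
  hpos <- result$start[["j"]] + cumsum(ops != "I")
  vpos <- result$start[["i"]] + cumsum(ops != "D")
  m <- ops == "M"
  if (!any(m)) return(0L)
  hb <- substring(result$seq_h, hpos[m], hpos[m])
  vb <- substring(result$seq_v, vpos[m], vpos[m])
  sum(hb == vb & hb %in% c("A", "C", "G", "T"))
}

#' Re-score an alignment from its CIGAR
#'
#' Independently recomputes the alignment score by summing per-column
#' scores (match/mismatch for `M` columns, the gap score for `I`/`D`
#' columns); free end gaps of semi-global alignments are outside the CIGAR
#' and cost nothing.  Used by the test-suite invariant that `score` always
#' equals the re-scored path.
#'
#' @param result A `band_alignment`.
#' @param scoring The [scoring_scheme()] the alignment was computed with.
#' @return Integer score.
#' @export
rescore_alignment <- function(result, scoring = scoring_scheme()) {
  ops <- parse_cigar(result$cigar)
  if (length(ops) == 0L) return(0L)
  n_m <- count_matches(result)
  n_cols <- sum(ops == "M")
  n_gaps <- sum(ops != "M")
  n_m * scoring$match + (n_cols - n_m) * scoring$mismatch +
    n_gaps * scoring$gap
}

#' Aligned-row text rendering of a pairwise alignment
#'
#' @param result A `band_alignment`.
#' @return Character vector of three strings: the horizontal sequence row,
#'   a midline (`|` match, space otherwise), and the vertical sequence row.
#' @export
alignment_strings <- function(result) {
  ops <- parse_cigar(result$cigar)
  if (length(ops) == 0L) return(c("", "", ""))
  hpos <- result$start[["j"]] + cumsum(ops != "I")
  vpos <- result$start[["i"]] + cumsum(ops != "D")
  hch <- ifelse(ops == "I", "-", substring(result$seq_h, hpos, hpos))
  vch <- ifelse(ops == "D", "-", substring(result$seq_v, vpos, vpos))
  mid <- ifelse(ops == "M" & hch == vch & hch %in% c("A", "C", "G", "T"),
                "|", " ")
  c(paste(hch, collapse = ""), paste(mid, collapse = ""),
    paste(vch, collapse = ""))
}

#' @export
print.band_alignment <- function(x, width = 60L, max_blocks = 5L, ...) {
  cat(sprintf("%s %salignment: score %d, %d match / %d mismatch / %d gap\n",
              x$mode, if (is.null(x$band)) "full-matrix " else
                sprintf("banded (w = %d) ", x$band$w),
              x$score, x$n_match, x$n_mismatch, x$n_gap))
  cat(sprintf("  h[%d..%d] vs v[%d..%d]  cigar %s\n",
              x$start[["j"]] + 1L, x$end[["j"]], x$start[["i"]] + 1L,
              x$end[["i"]],
              if (nchar(x$cigar) > 40L)
                paste0(substr(x$cigar, 1L, 40L), "...") else x$cigar))
  if (!is.null(x$band))
    cat(sprintf("  path %s the band edge\n",
                if (isTRUE(x$touched_edge)) "touches" else "stays off"))
  rows <- alignment_strings(x)
  n <- nchar(rows[1])
  starts <- seq(1L, n, by = width)
  for (b in starts[seq_len(min(length(starts), max_blocks))]) {
    e <- min(b + width - 1L, n)
    cat("  ", substr(rows[1], b, e), "\n  ", substr(rows[2], b, e),
        "\n  ", substr(rows[3], b, e), "\n", sep = "")
  }
  if (length(starts) > max_blocks) cat("  ...\n")
  invisible(x)
}

#' One-row tabular record of an alignment
#'
#' @param result A `band_alignment`.
#' @param query_id,target_id Identifiers for the vertical and horizontal
#'   sequences.
#' @param decision Optional `band_certification` to include.
#' @return A one-row `data.frame` suitable for a TSV alignment report.
#' @export
alignment_record <- function(result, query_id = "query",
                             target_id = "target", decision = NULL) {
  rec <- data.frame(
    query = query_id,
    target = target_id,
    mode = result$mode,
    w = if (is.null(result$band)) NA_integer_ else result$band$w,
    score = result$score,
    cigar = result$cigar,
    n_match = result$n_match,
    touched_edge = result$touched_edge,
    stringsAsFactors = FALSE)
  if (!is.null(decision)) {
    rec$accepted <- decision$accepted
    rec$reason <- decision$reason
    rec$threshold <- decision$threshold_used
  }
  rec
}
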