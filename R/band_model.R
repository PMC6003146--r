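#' Effective step probability of the indel random walk
#'
#' The diagonal deviation of an alignment path between two reads is modeled
#' as a symmetric 1-D random walk: each insertion or deletion in either
#' read moves the path one step off the diagonal.  The per-column
#' probability of a step in a given direction is
#' `p = 2 (p_d + p_i - p_d^2 - p_i^2)`; the factor 2 counts indels arising
#' in both reads of the pair, and the quadratic terms remove indels that
#' cancel at the same position.  Higher-order cancellation terms (an
#' insertion in one read absorbed by a nearby deletion in the other) are
#' deliberately dropped, so `p` slightly overestimates the effective step
#' rate -- a conservative choice for band sizing.
#'
#' @param profile An [error_profile()].
#' @return The step probability, a number in `[0, 1]`.
#' @examples
#' step_probability(error_set(1))  # 0.2247
#' @export
step_probability <- function(profile) {
  stopifnot(inherits(profile, "error_profile"))
  2 * (profile$p_d + profile$p_i - profile$p_d^2 - profile$p_i^2)
}

#' Standard deviation of the diagonal deviation
#'
#' For a symmetric walk of length `N` with step probability `p`, the net
#' travelled distance `d` has variance `2 N p`, hence
#' `sigma_d = sqrt(2 N p)`.  A band of half-width `3 sigma_d` contains the
#' alignment path with probability > 99.7%.
#'
#' @param profile An [error_profile()].
#' @param N Walk length in bases (use the longer read length).
#' @return `sigma_d`, a non-negative number.
#' @examples
#' sigma_d(error_set(1), 2000)              # 30.0
#' sigma_d(error_profile_pacbio(), 30000)   # ~111
#' @export
sigma_d <- function(profile, N) {
  stopifnot(is.numeric(N), N >= 1)
  sqrt(2 * N * step_probability(profile))
}

#' Variance of the travelled distance of an asymmetric walk
#'
#' Internal cross-check of the band model: for a walk of `N` steps taking a
#' right step with probability `p_r`, a left step with probability `p_l`
#' and staying put otherwise, the net displacement `d = r - l` has variance
#' `N p_r (1 - p_r) + N p_l (1 - p_l) + 2 N p_r p_l` (from the multinomial
#' moments of `(r, l)`).  With `p_r = p_l = p` this reduces to `2 N p`, the
#' symmetric form used by [sigma_d()].
#'
#' @param p_r,p_l Step probabilities (`p_r + p_l <= 1`).
#' @param N Walk length.
#' @return The variance of `d`.
#' @export
walk_displacement_variance <- function(p_r, p_l, N) {
  stopifnot(p_r >= 0, p_l >= 0, p_r + p_l <= 1, N >= 1)
  N * p_r * (1 - p_r) + N * p_l * (1 - p_l) + 2 * N * p_r * p_l
}

#' Staged band-widening schedule
#'
#' Half-widths to try in order: `ceiling(sigma)`, `ceiling(2 sigma)`,
#' `ceiling(3 sigma)`, then doubling until the band covers the whole
#' matrix; every value is capped at `l2` (at which point the band is the
#' full matrix) and the schedule is strictly increasing.  Starting at
#' `w = sigma` and restarting on failure costs about `3.52 sigma N`
#' expected column-evaluations, roughly half the `6 sigma N` of going
#' straight to `w = 3 sigma`.
#'
#' @param sigma `sigma_d` for the pair (must be > 0).
#' @param l1,l2 Sequence lengths, `l1 >= l2`.
#' @return Increasing integer vector of half-widths, the last one `>= l2`
#'   capped to `l2`.
#' @examples
#' band_schedule(26.2, 2000, 2000)
#' band_schedule(10, 30, 25)
#' @export
band_schedule <- function(sigma, l1, l2) {
  stopifnot(is.numeric(sigma), sigma > 0, l1 >= l2, l2 >= 1)
  ws <- ceiling(sigma * (1:3))
  while (ws[length(ws)] < l2) ws <- c(ws, 2 * ws[length(ws)])
  ws <- pmin(as.integer(ws), as.integer(l2))
  ws <- unique(ws)
  ws[seq_len(which.max(ws >= l2))]
}

#' Expected cost coefficient of the staged schedule
#'
#' A banded pass at half-width `k * sigma` evaluates about
#' `2 k sigma N` cells, so a run that succeeds at stage `k` has cost
#' `(2 + 4 + ... + 2k) sigma N`.  Given the fraction of pairs resolved at
#' each stage, this returns the expected coefficient of `sigma_d * N`.
#' With stage fractions (0.68, 0.28, 0.04) -- the normal-model
#' probabilities of the path fitting within 1, 2 and 3 sigma -- the
#' coefficient is 3.52, versus 6 for a single pass at `w = 3 sigma`.
#'
#' @param stage_fractions Probabilities of first success at each stage;
#'   must sum to 1.
#' @param stage_multipliers Band multipliers per stage (default `1, 2, ...,
#'   k`, i.e. the `sigma, 2 sigma, 3 sigma` schedule).
#' @return The expected cost coefficient.
#' @examples
#' expected_cost_coefficient(c(0.68, 0.28, 0.04))  # 3.52
#' @export
expected_cost_coefficient <- function(stage_fractions,
                                      stage_multipliers =
                                        seq_along(stage_fractions)) {
  stage_fractions <- as.numeric(stage_fractions)
  stage_multipliers <- as.numeric(stage_multipliers)
  stopifnot(length(stage_fractions) == length(stage_multipliers),
            all(stage_fractions >= 0))
  if (abs(sum(stage_fractions) - 1) > 1e-9)
    stop("stage fractions must sum to 1")
  sum(stage_fractions * cumsum(2 * stage_multipliers))
}

#' Upper bound on the score of any path leaving the band
#'
#' A global path that exits a band of half-width `w` must spend at least
#' `w + 1` gap columns on each side of the corridor; counting its gaps and
#' assuming every remaining column is a match gives the bound
#' `best_out = [2 (w + 1) - (l1 - l2)] g + [l2 - (w + 1)] m` with `g` the
#' gap score and `m` the match score.  If the banded score reaches this
#' bound, no out-of-band path can beat it.
#'
#' @param w Band half-width.
#' @param l1,l2 Sequence lengths, `l1 >= l2`.
#' @param scoring A [scoring_scheme()].
#' @return The bound, or `NA` when `w + 1 > l2` (no path can leave the
#'   band).
#' @examples
#' best_out_score(3, 20, 12)  # 24 with default +3/-1/-2 scores
#' @export
best_out_score <- function(w, l1, l2, scoring = scoring_scheme()) {
  stopifnot(w >= 0, l1 >= l2, l2 >= 1)
  if (w + 1 > l2) return(NA_real_)
  (2 * (w + 1) - (l1 - l2)) * scoring$gap + (l2 - (w + 1)) * scoring$match
}

new_certification <- function(accepted, reason, threshold) {
  stopifnot(reason %in% c("in_band_certified", "edge_touched",
                          "match_count_low", "global_bound_certified",
                          "global_bound_failed"))
  structure(list(accepted = accepted, reason = reason,
                 threshold_used = threshold), class = "band_certification")
}

#' @export
print.band_certification <- function(x, ...) {
  cat(sprintf("certification: %s (%s, threshold %s)\n",
              if (x$accepted) "accepted" else "rejected", x$reason,
              format(x$threshold_used)), sep = "")
  invisible(x)
}

#' Certify a banded global alignment score
#'
#' A banded global score is provably optimal when it is at least
#' [best_out_score()], the upper bound on any path that exits the band.
#'
#' @param s_band Score returned by a global banded alignment.
#' @param w,l1,l2 Band geometry used.
#' @param scoring The [scoring_scheme()] used.
#' @return A `band_certification` with `accepted`, `reason`
#'   (`global_bound_certified` / `global_bound_failed`) and
#'   `threshold_used` (the bound).
#' @export
certify_global <- function(s_band, w, l1, l2, scoring = scoring_scheme()) {
  bound <- best_out_score(w, l1, l2, scoring)
  ok <- is.na(bound) || s_band >= bound
  new_certification(ok, if (ok) "global_bound_certified" else
    "global_bound_failed", bound)
}

#' Expected match count and its confidence threshold
#'
#' The number of matches `N_m` in an alignment of reads with per-base
#' unchanged-probability `p_u` is approximately binomial:
#' `E(N_m) = N p_u`, `Var(N_m) = N p_u (1 - p_u)`.  The lower half of the
#' 99% confidence interval, `E(N_m) - 3 sd`, is the second certification
#' criterion: a banded alignment with fewer matches is suspected of having
#' been squeezed by the band.
#'
#' @param profile An [error_profile()].
#' @param N Read length (use the longer of the pair).
#' @return Named numeric vector `mean`, `sd`, `lower_threshold`.
#' @examples
#' match_count_bounds(error_set(3), 2000)  # mean 1780, threshold ~1738
#' @export
match_count_bounds <- function(profile, N) {
  stopifnot(inherits(profile, "error_profile"), N >= 1)
  m <- N * profile$p_u
  s <- sqrt(N * profile$p_u * (1 - profile$p_u))
  c(mean = m, sd = s, lower_threshold = m - 3 * s)
}

#' Certify a banded semi-global alignment
#'
#' Two-criteria procedure for semi-global alignments, where the global
#' score bound does not apply because the path ends are free: (i) reject if
#' the traceback path touches the band edge; (ii) otherwise reject if the
#' match count falls below the [match_count_bounds()] lower threshold;
#' else accept.  Criterion (i) has priority.
#'
#' @param result A semi-global `band_alignment` from [banded_dp_align()].
#' @param profile The [error_profile()] of the reads.
#' @param N Read length for the match-count model (defaults to the longer
#'   input sequence).
#' @return A `band_certification` with reason `edge_touched`,
#'   `match_count_low`, or `in_band_certified`; `threshold_used` is the
#'   match-count threshold.
#' @export
certify_semiglobal <- function(result, profile,
                               N = max(nchar(result$seq_h),
                                       nchar(result$seq_v))) {
  thr <- match_count_bounds(profile, N)[["lower_threshold"]]
  if (isTRUE(result$touched_edge))
    return(new_certification(FALSE, "edge_touched", thr))
  if (count_matches(result) < thr)
    return(new_certification(FALSE, "match_count_low", thr))
  new_certification(TRUE, "in_band_certified", thr)
}

#' Adaptive banded alignment with staged widening
#'
#' Runs [banded_dp_align()] over the [band_schedule()] half-widths,
#' certifying each stage ([certify_global()] in global mode,
#' [certify_semiglobal()] in semi-global mode) and returning the first
#' accepted result.  The final schedule stage has `w = l2`, i.e. the band
#' covers the whole matrix, so an exhausted schedule still yields the exact
#' full-matrix optimum (the certification decision of that last stage is
#' reported as computed; with a full-matrix band the score is optimal by
#' construction).
#'
#' @inheritParams full_dp_align
#' @param profile An [error_profile()] describing the reads; sets
#'   `sigma_d` (with `N` = longer read length) and the match-count
#'   threshold.
#' @return A list of class `adaptive_alignment`: `result` (the
#'   `band_alignment`), `decision` (the `band_certification` of the
#'   accepted/last stage), and `stages_used` (every half-width tried).
#' @examples
#' p <- make_pair(500, error_set(3), seed = 7)
#' a <- align_adaptive(p$seq_a, p$seq_b, error_set(3))
#' a$stages_used
#' @export
align_adaptive <- function(seq_h, seq_v, profile,
                           scoring = scoring_scheme(),
                           mode = c("semiglobal", "global")) {
  mode <- match.arg(mode)
  seq_h <- check_sequence(seq_h, "seq_h")
  seq_v <- check_sequence(seq_v, "seq_v")
  l1 <- max(nchar(seq_h), nchar(seq_v))
  l2 <- min(nchar(seq_h), nchar(seq_v))
  N <- l1
  sigma <- sigma_d(profile, N)
  schedule <- if (sigma > 0) band_schedule(sigma, l1, l2) else l2
  stages <- integer(0)
  for (w in schedule) {
    res <- banded_dp_align(seq_h, seq_v, scoring, mode, w)
    dec <- if (mode == "global") {
      certify_global(res$score, w, l1, l2, scoring)
    } else {
      certify_semiglobal(res, profile, N)
    }
    stages <- c(stages, w)
    if (dec$accepted || w >= l2) break
  }
  structure(list(result = res, decision = dec, stages_used = stages),
            class = "adaptive_alignment")
}

#' @export
print.adaptive_alignment <- function(x, ...) {
  cat(sprintf("adaptive alignment: %d stage(s), w tried: %s\n",
              length(x$stages_used),
              paste(x$stages_used, collapse = ", ")))
  print(x$decision)
  print(x$result)
  invisible(x)
}
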