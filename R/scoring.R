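#' Linear scoring scheme
#'
#' Per-column scores used by every aligner in the package: a positive match
#' score, a non-positive mismatch score, and a non-positive linear gap score
#' (no affine opening cost).
#'
#' @param match Integer score for an identical aligned pair (> 0).
#' @param mismatch Integer score for a non-identical aligned pair (<= 0).
#' @param gap Integer score per gap symbol (<= 0).
#'
#' @return An object of class `scoring_scheme`.
#' @examples
#' scoring_scheme()           # defaults +3 / -1 / -2
#' scoring_scheme(1, 0, -1)   # unit-cost edit-distance-like scheme
#' @export
scoring_scheme <- function(match = 3L, mismatch = -1L, gap = -2L) {
  match <- as.integer(match)
  mismatch <- as.integer(mismatch)
  gap <- as.integer(gap)
  if (is.na(match) || match <= 0L) stop("`match` must be a positive integer")
  if (is.na(mismatch) || mismatch > 0L) stop("`mismatch` must be <= 0")
  if (is.na(gap) || gap > 0L) stop("`gap` must be <= 0")
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("scoring: match %+d, mismatch %+d, gap %+d\n",
              x$match, x$mismatch, x$gap))
  invisible(x)
}

#' Per-base sequencing error profile
#'
#' Probabilities that a nucleotide of a read is unchanged (`p_u`),
#' substituted (`p_m`), followed by an inserted base (`p_i`), or deleted
#' (`p_d`).  The four probabilities must sum to one.  The profile drives
#' both the read simulator and the band model.
#'
#' @param p_u Probability of no modification.
#' @param p_m Mismatch (substitution) probability.
#' @param p_i Insertion probability.
#' @param p_d Deletion probability.
#'
#' @return An object of class `error_profile`.
#' @seealso [error_set()], [error_profile_pacbio()]
#' @export
error_profile <- function(p_u, p_m, p_i, p_d) {
  p <- c(p_u = p_u, p_m = p_m, p_i = p_i, p_d = p_d)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("all probabilities must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-9)
    stop("p_u + p_m + p_i + p_d must equal 1 (tolerance 1e-9), got ",
         format(sum(p), digits = 12))
  structure(as.list(p), class = "error_profile")
}

#' @export
print.error_profile <- function(x, ...) {
  cat(sprintf("error profile: p_u %.4g, p_m %.4g, p_i %.4g, p_d %.4g\n",
              x$p_u, x$p_m, x$p_i, x$p_d))
  invisible(x)
}

#' Benchmark error-rate sets
#'
#' Three error-rate sets used throughout the validation experiments:
#' set 1 = (0.85, 0.03, 0.075, 0.045), set 2 = (0.93, 0.01, 0.04, 0.02),
#' set 3 = (0.89, 0.02, 0.06, 0.03), each given as
#' (`p_u`, `p_m`, `p_i`, `p_d`).
#'
#' @param k Set number, 1, 2 or 3.
#' @return An [error_profile()].
#' @export
error_set <- function(k) {
  sets <- list(
    error_profile(0.85, 0.03, 0.075, 0.045),
    error_profile(0.93, 0.01, 0.04, 0.02),
    error_profile(0.89, 0.02, 0.06, 0.03))
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 3L) stop("`k` must be 1, 2 or 3")
  sets[[k]]
}

#' Typical PacBio long-read error profile
#'
#' Indicative third-generation (PacBio) error rates: 3% mismatches,
#' 7% insertions, 4% deletions.
#'
#' @return An [error_profile()].
#' @export
error_profile_pacbio <- function() {
  error_profile(0.86, 0.03, 0.07, 0.04)
}
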