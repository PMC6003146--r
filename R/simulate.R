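DNA_BASES <- c("A", "C", "G", "T")

#' Random nucleotide sequence
#'
#' I.i.d. uniform A/C/G/T.  With `seed = NULL` the current RNG stream is
#' used (so callers can run several draws under one seed); otherwise the
#' seed is set first and the draw is fully deterministic.
#'
#' @param N Length in bases (>= 1).
#' @param seed Optional integer seed.
#' @return A nucleotide string of length `N`.
#' @export
random_sequence <- function(N, seed = NULL) {
  N <- as.integer(N)
  if (is.na(N) || N < 1L) stop("`N` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  paste(sample(DNA_BASES, N, replace = TRUE), collapse = "")
}

#' Mutate a sequence under a per-base error profile
#'
#' Each ancestor base independently draws one event from
#' (`p_u`, `p_m`, `p_i`, `p_d`): *keep* emits the base unchanged,
#' *substitute* emits a uniformly chosen different base, *insert* emits the
#' kept base followed by one uniform random base (after-position
#' convention), *delete* emits nothing.  Indels are single-base events --
#' the model is strictly per-nucleotide, with no indel length
#' distribution.  The RNG is consumed in a fixed order (events, then
#' substitution bases, then inserted bases) so output is reproducible.
#'
#' @param seq Ancestor nucleotide string.
#' @param profile An [error_profile()].
#' @param seed Optional integer seed (`NULL` = use current RNG stream).
#' @return A list with `seq` (the mutated string) and `log`, a
#'   `mutation_log`: `events` (data frame of ancestor position, event,
#'   emitted base(s)) plus totals `n_sub`, `n_ins`, `n_del`.  Replaying the
#'   log with [replay_mutations()] reproduces `seq` exactly.
#' @export
mutate <- function(seq, profile, seed = NULL) {
  stopifnot(inherits(profile, "error_profile"))
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  N <- length(chars)
  if (N == 0L) stop("cannot mutate an empty sequence")
  events <- sample(c("keep", "substitute", "insert", "delete"), N,
                   replace = TRUE,
                   prob = c(profile$p_u, profile$p_m, profile$p_i,
                            profile$p_d))
  emitted <- chars
  is_sub <- events == "substitute"
  if (any(is_sub)) {
    # pick one of the three bases differing from the original; a non-ACGT
    # ancestor letter substitutes to any of the four
    u <- sample.int(3L, sum(is_sub), replace = TRUE)
    orig <- match(chars[is_sub], DNA_BASES)
    alt <- ((orig - 1L + u) %% 4L) + 1L
    sub_base <- DNA_BASES[alt]
    if (anyNA(orig))
      sub_base[is.na(orig)] <- sample(DNA_BASES, sum(is.na(orig)),
                                      replace = TRUE)
    emitted[is_sub] <- sub_base
  }
  is_ins <- events == "insert"
  if (any(is_ins))
    emitted[is_ins] <- paste0(chars[is_ins],
                              sample(DNA_BASES, sum(is_ins),
                                     replace = TRUE))
  is_del <- events == "delete"
  emitted[is_del] <- ""
  log <- structure(list(
    events = data.frame(pos = seq_len(N), event = events,
                        emitted = emitted, stringsAsFactors = FALSE),
    n_sub = sum(is_sub), n_ins = sum(is_ins), n_del = sum(is_del)),
    class = "mutation_log")
  list(seq = paste(emitted, collapse = ""), log = log)
}

#' Replay a mutation log on its ancestor
#'
#' Concatenates the emitted bases of a [mutate()] log, reproducing the
#' derived sequence exactly; errors if the log does not cover the ancestor.
#'
#' @param ancestor The ancestor string the log was produced from.
#' @param log A `mutation_log`.
#' @return The derived sequence.
#' @export
replay_mutations <- function(ancestor, log) {
  stopifnot(inherits(log, "mutation_log"))
  if (nrow(log$events) != nchar(ancestor))
    stop("log covers ", nrow(log$events), " positions but ancestor has ",
         nchar(ancestor))
  keep <- log$events$event == "keep"
  anc <- strsplit(toupper(ancestor), "", fixed = TRUE)[[1]]
  if (!all(log$events$emitted[keep] == anc[keep]))
    stop("log does not match this ancestor")
  paste(log$events$emitted, collapse = "")
}

#' @export
print.mutation_log <- function(x, ...) {
  cat(sprintf("mutation log: %d positions, %d sub / %d ins / %d del\n",
              nrow(x$events), x$n_sub, x$n_ins, x$n_del))
  invisible(x)
}

#' Simulate a pair of error-prone reads
#'
#' Draws a uniform random ancestor of length `N` and derives the pair from
#' it.  With `pairing = "both_mutated"` (the default) both reads are
#' independent [mutate()] draws from the ancestor, so indels accumulate in
#' both -- the situation the factor 2 in [step_probability()] accounts
#' for.  With `"one_mutated"` the first read is the ancestor itself and
#' only the second is mutated.
#'
#' @param N Ancestor length in bases.
#' @param profile An [error_profile()].
#' @param seed Optional integer seed for the whole pair.
#' @param pairing `"both_mutated"` or `"one_mutated"`.
#' @return A list of class `simulated_pair`: `seq_a`, `seq_b`, `ancestor`,
#'   `log_a` (`NULL` under `one_mutated`), `log_b`, `profile`, `seed`,
#'   `pairing`.
#' @examples
#' p <- make_pair(1000, error_set(2), seed = 42)
#' nchar(p$seq_a); nchar(p$seq_b)
#' @export
make_pair <- function(N, profile, seed = NULL,
                      pairing = c("both_mutated", "one_mutated")) {
  pairing <- match.arg(pairing)
  if (!is.null(seed)) set.seed(seed)
  ancestor <- random_sequence(N)
  if (pairing == "both_mutated") {
    a <- mutate(ancestor, profile)
    b <- mutate(ancestor, profile)
    out <- list(seq_a = a$seq, seq_b = b$seq, ancestor = ancestor,
                log_a = a$log, log_b = b$log)
  } else {
    b <- mutate(ancestor, profile)
    out <- list(seq_a = ancestor, seq_b = b$seq, ancestor = ancestor,
                log_a = NULL, log_b = b$log)
  }
  structure(c(out, list(profile = profile, seed = seed, pairing = pairing)),
            class = "simulated_pair")
}

#' @export
print.simulated_pair <- function(x, ...) {
  cat(sprintf("simulated pair (%s): ancestor %d bp -> %d / %d bp\n",
              x$pairing, nchar(x$ancestor), nchar(x$seq_a),
              nchar(x$seq_b)))
  invisible(x)
}

# One reproducible sub-seed per pair, derived from the master seed so
# experiment cells can be generated independently.
pair_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(2147483646L, n)
}
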