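#' Read a multi-record FASTA file
#'
#' Parses FASTA via Biostrings, concatenating wrapped lines, uppercasing,
#' and preserving record order.  Records with empty sequences are rejected
#' by name.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id` and `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("malformed FASTA header in ", path)
  seqs <- toupper(as.character(set))
  empty <- nchar(seqs) == 0L
  if (any(empty))
    stop("empty sequence for record '", ids[which(empty)[1]], "' in ", path)
  data.frame(id = ids, seq = unname(seqs), stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param seqs Character vector of sequences.
#' @param ids Record identifiers (defaults to `names(seqs)` or `seq_1`,
#'   `seq_2`, ...).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, ids = NULL, path, width = 70L) {
  if (is.null(ids)) ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq_", seq_along(seqs))
  stopifnot(length(ids) == length(seqs), all(nchar(seqs) > 0L))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(seqs)) {
    writeLines(paste0(">", ids[k]), con)
    s <- seqs[k]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

#' Write a tab-separated report
#'
#' @param df A data frame (alignment records, experiment tables).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Flat key/value record of the parameters of a run, sufficient to
#' reproduce it (seed included).
#'
#' @param params Named list of parameters (scalars or short vectors).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(params, path) {
  stopifnot(!is.null(names(params)), all(nzchar(names(params))))
  flat <- vapply(params, function(v) {
    if (inherits(v, "error_profile") || inherits(v, "scoring_scheme"))
      v <- unlist(unclass(v))
    paste(format(v, trim = TRUE), collapse = ",")
  }, character(1))
  writeLines(paste0(names(flat), "=", flat), path)
  invisible(path)
}

#' Read a key=value configuration file
#'
#' Plain `key=value` lines (comments start with `#`); values holding
#' commas are split into vectors.  Used by the command-line interface.
#'
#' @param path Path to the config file.
#' @return Named list of character vectors.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1]])
  vals <- lapply(kv, function(m) strsplit(m[3], ",", fixed = TRUE)[[1]])
  names(vals) <- vapply(kv, function(m) trimws(m[2]), character(1))
  vals
}
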