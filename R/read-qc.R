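# Read quality control: 3' adaptor clipping, 3' quality trimming, and
# full-length rRNA contamination screening with bounded mismatches.

#' Trim adaptors and low-quality 3' regions from reads
#'
#' Adaptor occurrences are located by an exact-match seed (the first
#' `seed_len` bases of the adaptor) and extended to the read end allowing 10%
#' mismatches; the leftmost qualifying occurrence and everything 3' of it is
#' removed. Remaining 3' bases with phred quality below `quality_min` are
#' then trimmed, and reads shorter than `min_len` are discarded.
#'
#' @param reads Tibble with columns `read_id`, `sequence`, `quality`
#'   (phred+33); extra columns are carried through.
#' @param quality_min Phred threshold for the 3' quality scan.
#' @param adaptor Adaptor sequence, or `NULL`/`""` to skip adaptor clipping.
#' @param min_len Minimum surviving read length (bp).
#' @param seed_len Exact-match seed length for adaptor location.
#' @return The trimmed reads tibble, with attributes `n_adaptor_trimmed`,
#'   `n_quality_trimmed`, `n_discarded`.
#' @export
trim_reads <- function(reads, quality_min = 20L, adaptor = "AGATCGGAAGAGC",
                       min_len = 30L, seed_len = 10L) {
  stopifnot(quality_min >= 0, min_len >= 1)
  bad <- nchar(reads$sequence) != nchar(reads$quality)
  if (any(bad)) {
    stop("malformed record(s): sequence/quality length mismatch for ",
         paste(utils::head(reads$read_id[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  seqs <- reads$sequence
  quals <- reads$quality
  n <- length(seqs)
  cut <- nchar(seqs) + 1L  # first removed position per read

  if (!is.null(adaptor) && nzchar(adaptor)) {
    assert_dna(adaptor, "adaptor", iupac = TRUE)
    seed <- substring(adaptor, 1L, min(seed_len, nchar(adaptor)))
    occ <- gregexpr(seed, seqs, fixed = TRUE)
    for (i in seq_len(n)) {
      pos <- occ[[i]]
      if (pos[1] == -1L) next
      L <- nchar(seqs[i])
      for (p in pos) {
        span <- min(L - p + 1L, nchar(adaptor))
        mm <- hamming_chr(substring(seqs[i], p, p + span - 1L),
                          substring(adaptor, 1L, span))
        if (mm <= floor(0.1 * span)) { cut[i] <- p; break }
      }
    }
  }
  n_adaptor <- sum(cut <= nchar(seqs))
  seqs <- substring(seqs, 1L, cut - 1L)
  quals <- substring(quals, 1L, cut - 1L)

  # 3' quality scan: drop trailing bases below threshold
  pre_q <- nchar(seqs)
  keep_len <- vapply(seq_len(n), function(i) {
    q <- utf8ToInt(quals[i]) - 33L
    L <- length(q)
    while (L > 0L && q[L] < quality_min) L <- L - 1L
    L
  }, integer(1))
  seqs <- substring(seqs, 1L, keep_len)
  quals <- substring(quals, 1L, keep_len)
  n_qual <- sum(keep_len < pre_q)

  out <- reads
  out$sequence <- seqs
  out$quality <- quals
  drop <- nchar(out$sequence) < min_len
  out <- out[!drop, , drop = FALSE]
  attr(out, "n_adaptor_trimmed") <- n_adaptor
  attr(out, "n_quality_trimmed") <- n_qual
  attr(out, "n_discarded") <- sum(drop)
  out
}

#' Screen reads against rRNA references
#'
#' A read is removed iff its full length matches some window of some rRNA
#' record, on either strand, with at most `max_mismatch` substitutions
#' (`N` counts as a mismatch). Matching uses k-mer pigeonhole seeding with
#' direct verification, the same contract as an ungapped short-read aligner
#' run with an end-to-end mismatch budget.
#'
#' @param reads Reads tibble (`read_id`, `sequence`, ...).
#' @param rrna Named character vector of rRNA reference sequences.
#' @param max_mismatch Maximum substitutions for a full-length match.
#' @return A list: `kept` and `removed` (tibbles partitioning the input) and
#'   `report` (tibble: `read_id`, `contaminant`, `mismatches` for removed
#'   reads, best placement).
#' @export
screen_rrna <- function(reads, rrna, max_mismatch = 2L) {
  stopifnot(max_mismatch >= 0)
  if (length(rrna) == 0L) {
    warning("empty rRNA reference: all reads kept")
    return(list(kept = reads, removed = reads[0, , drop = FALSE],
                report = tibble::tibble(read_id = character(),
                                        contaminant = character(),
                                        mismatches = integer())))
  }
  q <- stats::setNames(reads$sequence, reads$read_id)
  hits <- match_hamming(q, rrna, max_mismatch)
  best <- best_hits(hits)
  removed_ids <- best$query
  is_removed <- reads$read_id %in% removed_ids
  report <- tibble::tibble(read_id = best$query, contaminant = best$subject,
                           mismatches = best$mismatches)
  list(kept = reads[!is_removed, , drop = FALSE],
       removed = reads[is_removed, , drop = FALSE],
       report = report)
}
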