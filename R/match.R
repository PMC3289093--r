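# Full-length bounded-mismatch matching of short queries against a set of
# subject sequences, by k-mer pigeonhole seeding: a query with at most k
# substitutions relative to some subject window must contain at least one of
# k+1 non-overlapping seed segments exactly; every exact seed hit is then
# verified by direct Hamming comparison. Both strands are searched; minus
# strand hits report the start of the window on the forward subject.

# queries, subjects: named character vectors. Returns a data.table with
# columns query, subject, start (1-based), strand, mismatches, holding every
# placement with mismatches <= max_mismatch.
match_hamming <- function(queries, subjects, max_mismatch = 2L) {
  empty <- data.table::data.table(query = character(), subject = character(),
                                  start = integer(), strand = character(),
                                  mismatches = integer())
  if (length(queries) == 0L || length(subjects) == 0L) return(empty)
  stopifnot(!is.null(names(queries)), !is.null(names(subjects)))
  k <- as.integer(max_mismatch)
  stopifnot(k >= 0L)

  slen <- nchar(subjects)
  out <- list()
  qlen <- nchar(queries)
  for (L in sort(unique(qlen))) {
    qs <- queries[qlen == L]
    w <- L %/% (k + 1L)
    if (w < 1L) next  # query shorter than the seed budget: no placement possible
    # subject index of all w-mers (forward strand only; strand handled on query)
    idx <- data.table::rbindlist(lapply(names(subjects), function(sj) {
      km <- kmers_of(subjects[[sj]], w)
      if (!length(km)) return(NULL)
      data.table::data.table(kmer = km, subject = sj, pos = seq_along(km))
    }))
    if (is.null(idx) || nrow(idx) == 0L) next
    data.table::setkey(idx, kmer)

    cand <- list()
    for (strand in c("+", "-")) {
      oriented <- if (strand == "+") qs else {
        rc <- revcomp_chr(qs); names(rc) <- names(qs); rc
      }
      for (i in 0:k) {
        off <- i * w
        seeds <- data.table::data.table(
          kmer = substring(oriented, off + 1L, off + w),
          query = names(qs))
        hit <- idx[seeds, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
        if (nrow(hit) == 0L) next
        hit[, start := pos - off]
        hit[, strand := strand]
        cand[[length(cand) + 1L]] <- hit[, list(query, subject, start, strand)]
      }
    }
    if (!length(cand)) next
    cand <- unique(data.table::rbindlist(cand))
    cand <- cand[start >= 1L & start + L - 1L <= slen[subject]]
    if (nrow(cand) == 0L) next

    # verify every candidate placement by direct recomputation
    win <- substring(subjects[cand$subject], cand$start, cand$start + L - 1L)
    qdict <- qs
    qrc <- revcomp_chr(qs); names(qrc) <- names(qs)
    qseq <- ifelse(cand$strand == "+", qdict[cand$query], qrc[cand$query])
    mm <- mapply(hamming_chr, qseq, win, USE.NAMES = FALSE)
    cand[, mismatches := as.integer(mm)]
    out[[length(out) + 1L]] <- cand[mismatches <= k]
  }
  if (!length(out)) return(empty)
  res <- data.table::rbindlist(out)
  data.table::setkeyv(res, c("query", "subject", "start", "strand"))
  unique(res)
}

# Best placement(s) per query: fewest mismatches, ties counted. With
# keep_ties = FALSE a single deterministic representative is kept per query
# (lexicographic by subject, start, strand); otherwise all tied best rows.
# Returns data.table(query, subject, start, strand, mismatches, n_best).
best_hits <- function(hits, keep_ties = FALSE) {
  if (nrow(hits) == 0L) {
    return(data.table::data.table(query = character(), subject = character(),
                                  start = integer(), strand = character(),
                                  mismatches = integer(), n_best = integer()))
  }
  h <- data.table::copy(hits)
  h[, best := min(mismatches), by = query]
  h <- h[mismatches == best]
  h[, n_best := .N, by = query]
  data.table::setorderv(h, c("query", "subject", "start", "strand"))
  if (keep_ties) {
    h[, best := NULL]
    return(h[])
  }
  h[, utils::head(.SD, 1L), by = query,
    .SDcols = c("subject", "start", "strand", "mismatches", "n_best")]
}
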