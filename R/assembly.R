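# Hybrid unigene assembly: EST screening, greedy overlap-layout-consensus
# assembly of ESTs, bounded-mismatch read alignment to unigenes, de Bruijn
# assembly of unaligned reads, and meta-assembly of the two unigene sets.

# ---------------------------------------------------------------------------
# Greedy overlap-layout-consensus engine
#
# Iteratively merges the pair of active sequences with the highest-scoring
# suffix-prefix overlap (>= min_overlap bases, >= min_identity, either
# strand) until none remains; containments are absorbed. Overlap candidates
# are located by an exact seed k-mer at the junction and verified by direct
# comparison; the consensus of each contig is the per-column majority vote
# over its laid-out member fragments. Ties in overlap score are broken
# lexicographically so results are deterministic.
# ---------------------------------------------------------------------------

# frag_seqs: named character vector of input fragments.
# Returns list of contigs: each list(consensus, members = data.table
# (frag_id, orient, offset)) with offset 0-based on the contig.
greedy_assemble <- function(frag_seqs, min_overlap = 40L, min_identity = 0.97) {
  stopifnot(min_overlap >= 10L, min_identity >= 0.9, min_identity <= 1)
  n0 <- length(frag_seqs)
  if (n0 == 0L) return(list())
  sw <- as.integer(min(16L, min_overlap))

  # node state: forward + reverse-complement consensus, member layout
  nodes <- new.env(parent = emptyenv())
  frag_rc <- revcomp_chr(unname(frag_seqs))
  for (i in seq_len(n0)) {
    id <- sprintf("f%06d", i)
    assign(id, list(seq = unname(frag_seqs[[i]]), rc = frag_rc[[i]],
                    members = data.table::data.table(
                      frag_id = names(frag_seqs)[i], orient = "+", offset = 0L)),
           envir = nodes)
  }
  active <- sort(ls(nodes))

  node_seq <- function(id, orient) {
    nd <- get(id, envir = nodes)
    if (orient == "+") nd$seq else nd$rc
  }

  max_mm <- function(olen) floor((1 - min_identity) * olen)

  index_rows <- function(ids) {
    data.table::rbindlist(lapply(ids, function(id) {
      data.table::rbindlist(lapply(c("+", "-"), function(o) {
        km <- kmers_of(node_seq(id, o), sw)
        if (!length(km)) return(NULL)
        data.table::data.table(kmer = km, id = id, orient = o,
                               pos = seq_along(km))
      }))
    }))
  }
  idx <- index_rows(active)
  if (is.null(idx) || nrow(idx) == 0L) {
    return(lapply(active, function(id) {
      nd <- get(id, envir = nodes)
      list(consensus = nd$seq, members = tibble::as_tibble(nd$members))
    }))
  }
  data.table::setkey(idx, kmer)

  # Terminal seed k-mers (prefix and suffix, both orientations) per node.
  node_seeds <- function(ids) {
    data.table::rbindlist(lapply(ids, function(q) {
      data.table::rbindlist(lapply(c("+", "-"), function(oq) {
        sq <- node_seq(q, oq)
        lq <- nchar(sq)
        if (lq < sw) return(NULL)
        data.table::data.table(q = q, oq = oq, end = c("pre", "suf"),
                               kmer = c(substring(sq, 1L, sw),
                                        substring(sq, lq - sw + 1L, lq)),
                               lq = lq)
      }))
    }))
  }

  # Verified junction/containment candidates: query terminal seeds joined
  # against the positional index in one batch, then verified per candidate.
  find_edges <- function(seeds, idx) {
    if (is.null(seeds) || nrow(seeds) == 0L ||
        is.null(idx) || nrow(idx) == 0L) return(NULL)
    res <- list()
    add_edge <- function(x, ox, y, oy, type, olen, off, score, mm) {
      res[[length(res) + 1L]] <<- data.table::data.table(
        x = x, ox = ox, y = y, oy = oy, type = type,
        olen = as.integer(olen), off = as.integer(off),
        score = as.integer(score), mm = as.integer(mm))
    }
    consider <- function(x, ox, y, oy, p) {
      # prefix of oriented y placed at position p of oriented x
      sx <- node_seq(x, ox); sy <- node_seq(y, oy)
      lx <- nchar(sx); ly <- nchar(sy)
      if (p + ly - 1L <= lx) {         # containment: y inside x
        mm <- hamming_chr(substring(sx, p, p + ly - 1L), sy)
        if (mm <= max_mm(ly)) add_edge(x, ox, y, oy, "contain", ly, p - 1L,
                                       2L * ly - mm, mm)
      } else {                          # suffix(x) / prefix(y) overlap
        olen <- lx - p + 1L
        if (olen >= min_overlap && olen < ly) {
          mm <- hamming_chr(substring(sx, p, lx), substring(sy, 1L, olen))
          if (mm <= max_mm(olen)) add_edge(x, ox, y, oy, "overlap", olen, NA_integer_,
                                           olen - mm, mm)
        }
      }
    }
    hit <- idx[seeds, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    hit <- hit[id != q]
    for (r in seq_len(nrow(hit))) {
      if (hit$end[r] == "pre") {
        # q as the right-hand/contained sequence: its prefix seed in others
        consider(hit$id[r], hit$orient[r], hit$q[r], hit$oq[r], hit$pos[r])
      } else {
        # q as the left-hand sequence: its suffix seed inside others.
        # The seed occupies [pos, pos+sw-1] of the oriented other, so in the
        # junction (q left, other right) the overlap spans the first
        # pos+sw-1 bases of the other and the last pos+sw-1 bases of q.
        q <- hit$q[r]; oq <- hit$oq[r]; lq <- hit$lq[r]
        o2 <- hit$id[r]; oo2 <- hit$orient[r]
        olen <- hit$pos[r] + sw - 1L
        p <- lq - olen + 1L
        if (p < 1L) next
        sy <- node_seq(o2, oo2)
        ly <- nchar(sy)
        if (olen > ly) next
        sq <- node_seq(q, oq)
        if (olen == ly) {
          # all of o2 sits inside (or flush with) q
          if (p + ly - 1L <= lq) {
            mm <- hamming_chr(substring(sq, p, p + ly - 1L), sy)
            if (mm <= max_mm(ly)) {
              add_edge(q, oq, o2, oo2, "contain", ly, p - 1L,
                       2L * ly - mm, mm)
            }
          }
        } else if (olen >= min_overlap) {
          mm <- hamming_chr(substring(sq, p, lq), substring(sy, 1L, olen))
          if (mm <= max_mm(olen)) {
            add_edge(q, oq, o2, oo2, "overlap", olen, NA_integer_,
                     olen - mm, mm)
          }
        }
      }
    }
    if (!length(res)) return(NULL)
    ed <- data.table::rbindlist(res)
    # canonical form: a junction (x,ox)->(y,oy) equals (y,flip oy)->(x,flip ox)
    flip <- function(o) ifelse(o == "+", "-", "+")
    swap <- ed$type == "overlap" &
      (ed$y < ed$x | (ed$y == ed$x & flip(ed$oy) < ed$ox))
    if (any(swap)) {
      tmp <- ed[swap]
      ed[swap, `:=`(x = tmp$y, ox = flip(tmp$oy), y = tmp$x, oy = flip(tmp$ox))]
    }
    unique(ed)
  }

  transform_members <- function(mem, orient, len, shift) {
    m <- data.table::copy(mem)
    if (orient == "-") {
      # member lengths derive from their fragment sequences
      flen <- nchar(frag_seqs[m$frag_id])
      m[, offset := len - (offset + flen)]
      m[, orient := ifelse(orient == "+", "-", "+")]
    }
    m[, offset := offset + shift]
    m
  }

  consensus_of <- function(members, contig_len) {
    counts <- matrix(0L, nrow = 4L, ncol = contig_len,
                     dimnames = list(DNA_BASES, NULL))
    for (r in seq_len(nrow(members))) {
      s <- frag_seqs[[members$frag_id[r]]]
      if (members$orient[r] == "-") s <- revcomp_chr(s)
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      posn <- members$offset[r] + seq_along(ch)
      ok <- ch %in% DNA_BASES & posn >= 1L & posn <= contig_len
      if (any(ok)) {
        ii <- cbind(match(ch[ok], DNA_BASES), posn[ok])
        counts[ii] <- counts[ii] + 1L
      }
    }
    top <- apply(counts, 2L, which.max)  # ties: first (alphabetical) base
    covered <- colSums(counts) > 0L
    out <- DNA_BASES[top]
    out[!covered] <- "N"
    paste(out, collapse = "")
  }

  seeds_tbl <- node_seeds(active)
  edges <- find_edges(seeds_tbl, idx)
  merge_i <- 0L
  while (!is.null(edges) && nrow(edges) > 0L) {
    data.table::setorderv(edges, c("score", "x", "y", "ox", "oy", "olen"),
                          order = c(-1L, 1L, 1L, 1L, 1L, 1L))
    e <- edges[1]
    nx <- get(e$x, envir = nodes); ny <- get(e$y, envir = nodes)
    lx <- nchar(nx$seq); ly <- nchar(ny$seq)
    if (e$type == "contain") {
      new_len <- lx
      memx <- transform_members(nx$members, e$ox, lx, 0L)
      memy <- transform_members(ny$members, e$oy, ly, e$off)
    } else {
      new_len <- lx + ly - e$olen
      memx <- transform_members(nx$members, e$ox, lx, 0L)
      memy <- transform_members(ny$members, e$oy, ly, lx - e$olen)
    }
    mem <- data.table::rbindlist(list(memx, memy))
    merge_i <- merge_i + 1L
    new_id <- sprintf("m%06d", merge_i)
    new_seq <- consensus_of(mem, new_len)
    assign(new_id, list(seq = new_seq, rc = revcomp_chr(new_seq),
                        members = mem), envir = nodes)
    rm(list = c(e$x, e$y), envir = nodes)
    active <- sort(c(setdiff(active, c(e$x, e$y)), new_id))
    # incremental index and seed-table update
    new_rows <- index_rows(new_id)
    idx <- data.table::rbindlist(list(idx[!(id %in% c(e$x, e$y))], new_rows))
    seeds_new <- node_seeds(new_id)
    seeds_tbl <- data.table::rbindlist(
      list(seeds_tbl[!(q %in% c(e$x, e$y))], seeds_new))
    edges <- edges[x != e$x & x != e$y & y != e$x & y != e$y]
    # junctions involving the new contig: its terminal seeds against the
    # rest, plus the rest's terminal seeds against the new contig alone
    # (catches fragments newly contained within the merged consensus)
    new_edges <- data.table::rbindlist(list(
      find_edges(seeds_new, idx),
      find_edges(seeds_tbl[q != new_id], new_rows)),
      use.names = TRUE, fill = TRUE)
    if (!is.null(new_edges) && nrow(new_edges)) {
      new_edges <- new_edges[(x == new_id | y == new_id)]
      edges <- unique(data.table::rbindlist(list(edges, new_edges)))
    }
    if (nrow(edges) == 0L) edges <- NULL
  }

  lapply(active, function(id) {
    nd <- get(id, envir = nodes)
    list(consensus = nd$seq, members = tibble::as_tibble(nd$members))
  })
}

unigene_tibble <- function(contigs, provenance) {
  if (!length(contigs)) {
    return(tibble::tibble(unigene_id = character(), sequence = character(),
                          length = integer(), provenance = character(),
                          members = list()))
  }
  seqs <- vapply(contigs, `[[`, character(1), "consensus")
  mem <- lapply(contigs, `[[`, "members")
  prov <- if (length(provenance) == 1L) rep(provenance, length(seqs)) else provenance
  tb <- tibble::tibble(sequence = seqs, length = nchar(seqs),
                       provenance = prov, members = mem)
  renumber_unigenes(tb)
}

# Assign PP-prefixed six-digit ids in decreasing length order (ties broken
# by sequence so numbering is a pure function of the input set).
renumber_unigenes <- function(tb) {
  ord <- order(-tb$length, tb$sequence)
  tb <- tb[ord, , drop = FALSE]
  tb <- tibble::add_column(tb, unigene_id = sprintf("PP%06d", seq_len(nrow(tb))),
                           .before = 1L)
  tb
}

# ---------------------------------------------------------------------------

#' Screen ESTs against vector, bacterial and rRNA references
#'
#' Terminal segments matching a cloning-vector record exactly (at least
#' `vector_min` bases, either strand of the vector) are clipped; ESTs whose
#' best local alignment to a bacterial or rRNA record covers at least 80% of
#' their length at >= 90% identity are discarded; survivors shorter than
#' `min_clean_len` are discarded.
#'
#' @param ests EST tibble (`est_id`, `sequence`, ...).
#' @param vector,bacterial,rrna Named character vectors of reference records
#'   (any may be empty).
#' @param min_clean_len Minimum surviving EST length (bp).
#' @param vector_min Minimum terminal vector match to clip (bp).
#' @return The screened EST tibble with attributes `n_clipped`,
#'   `n_discarded_contaminant`, `n_discarded_short`.
#' @export
screen_ests <- function(ests, vector = character(0), bacterial = character(0),
                        rrna = character(0), min_clean_len = 100L,
                        vector_min = 20L) {
  stopifnot(min_clean_len >= 1)
  seqs <- ests$sequence
  n <- length(seqs)
  n_clipped <- 0L

  if (length(vector) > 0L && n > 0L) {
    vec_all <- c(vector, revcomp_chr(vector))
    # longest terminal segment that is an exact substring of some vector record
    terminal_match <- function(s, from_start) {
      L <- nchar(s)
      probe <- function(len) {
        seg <- if (from_start) substring(s, 1L, len) else substring(s, L - len + 1L, L)
        any(grepl(seg, vec_all, fixed = TRUE))
      }
      if (L < vector_min || !probe(vector_min)) return(0L)
      lo <- vector_min; hi <- L
      while (lo < hi) {            # binary search for the longest match
        mid <- (lo + hi + 1L) %/% 2L
        if (probe(mid)) lo <- mid else hi <- mid - 1L
      }
      lo
    }
    for (i in seq_len(n)) {
      pre <- terminal_match(seqs[i], TRUE)
      if (pre > 0L) seqs[i] <- substring(seqs[i], pre + 1L)
      suf <- if (nchar(seqs[i]) > 0L) terminal_match(seqs[i], FALSE) else 0L
      if (suf > 0L) seqs[i] <- substring(seqs[i], 1L, nchar(seqs[i]) - suf)
      if (pre > 0L || suf > 0L) n_clipped <- n_clipped + 1L
    }
  }

  contaminated <- rep(FALSE, n)
  contam <- c(bacterial, rrna)
  if (length(contam) > 0L && n > 0L) {
    refs <- Biostrings::DNAStringSet(contam)
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                    baseOnly = TRUE)
    # k-mer prescreen: an EST that shares no 16-mer with any contaminant
    # (either strand) cannot reach 80% coverage at 90% identity
    kpre <- 16L
    ckm <- new.env(parent = emptyenv())
    for (s in c(contam, revcomp_chr(contam))) {
      for (w in kmers_of(s, kpre)) assign(w, TRUE, envir = ckm)
    }
    shares_kmer <- function(s) {
      any(vapply(kmers_of(s, kpre), exists, logical(1),
                 envir = ckm, inherits = FALSE))
    }
    for (i in seq_len(n)) {
      if (nchar(seqs[i]) == 0L) next
      if (!shares_kmer(seqs[i])) next
      for (qseq in c(seqs[i], revcomp_chr(seqs[i]))) {
        aln <- Biostrings::pairwiseAlignment(
          rep(Biostrings::DNAStringSet(qseq), length(refs)), refs,
          type = "local", substitutionMatrix = mat,
          gapOpening = 5, gapExtension = 2)
        j <- which.max(Biostrings::score(aln))
        a <- aln[j]
        span <- Biostrings::nchar(Biostrings::pattern(a))
        ident <- Biostrings::pid(a) / 100
        if (span >= 0.8 * nchar(seqs[i]) && ident >= 0.9) {
          contaminated[i] <- TRUE
          break
        }
      }
    }
  }

  out <- ests
  out$sequence <- seqs
  keep <- !contaminated & nchar(seqs) >= min_clean_len
  n_short <- sum(!contaminated & nchar(seqs) < min_clean_len)
  out <- out[keep, , drop = FALSE]
  attr(out, "n_clipped") <- n_clipped
  attr(out, "n_discarded_contaminant") <- sum(contaminated)
  attr(out, "n_discarded_short") <- n_short
  out
}

#' Assemble ESTs into unigenes by greedy overlap-layout-consensus
#'
#' Repeatedly merges the pair of sequences with the best suffix-prefix
#' overlap of at least `min_overlap` bases at `min_identity` or better,
#' on either strand, absorbing contained sequences, until no qualifying
#' overlap remains. Consensus bases are per-column majority votes over the
#' member layout. Singletons become single-member unigenes.
#'
#' @param ests EST tibble (`est_id`, `sequence`, ...).
#' @param min_overlap Minimum overlap (bp), at least 10.
#' @param min_identity Minimum overlap identity, in `[0.9, 1]`.
#' @return A unigene tibble (`unigene_id`, `sequence`, `length`,
#'   `provenance = "est"`, `members` list-column).
#' @export
assemble_ests <- function(ests, min_overlap = 40L, min_identity = 0.97) {
  frag <- stats::setNames(ests$sequence, ests$est_id)
  contigs <- greedy_assemble(frag, min_overlap, min_identity)
  unigene_tibble(contigs, "est")
}

#' Align reads to unigenes with a bounded mismatch budget
#'
#' Reports, per read, its best full-length placement (fewest substitutions,
#' at most `max_mismatch`) across all unigenes and both strands; reads with
#' no qualifying placement are routed to `unaligned`. Equally-best placements
#' are counted (`n_best`) for the downstream multi-mapping policy.
#'
#' @param reads Reads tibble (`read_id`, `sequence`, optional `library`).
#' @param unigenes Unigene tibble or named character vector.
#' @param max_mismatch Maximum substitutions for a full-length match.
#' @param keep_ties If `TRUE`, report every equally-best placement per read
#'   (needed for the random-tie-break counting policy); otherwise one
#'   deterministic representative per read.
#' @return A list: `hits` (tibble `read_id`, `unigene_id`, `start` (0-based
#'   on the forward unigene), `strand`, `mismatches`, `n_best`, plus
#'   `library` when present in `reads`) and `unaligned` (reads tibble).
#' @export
align_reads <- function(reads, unigenes, max_mismatch = 2L, keep_ties = FALSE) {
  stopifnot(max_mismatch >= 0)
  subj <- if (is.data.frame(unigenes)) {
    stats::setNames(unigenes$sequence, unigenes$unigene_id)
  } else unigenes
  if (length(subj) == 0L) {
    warning("empty unigene set: all reads unaligned")
    hits <- tibble::tibble(read_id = character(), unigene_id = character(),
                           start = integer(), strand = character(),
                           mismatches = integer(), n_best = integer())
    return(list(hits = hits, unaligned = reads))
  }
  q <- stats::setNames(reads$sequence, reads$read_id)
  best <- best_hits(match_hamming(q, subj, max_mismatch), keep_ties = keep_ties)
  hits <- tibble::tibble(read_id = best$query, unigene_id = best$subject,
                         start = best$start - 1L, strand = best$strand,
                         mismatches = best$mismatches, n_best = best$n_best)
  if ("library" %in% names(reads)) {
    hits <- dplyr::left_join(hits,
                             tibble::tibble(read_id = reads$read_id,
                                            library = reads$library),
                             by = "read_id")
  }
  list(hits = hits,
       unaligned = reads[!(reads$read_id %in% hits$read_id), , drop = FALSE])
}

#' De novo assembly of unaligned reads (de Bruijn graph)
#'
#' Builds a de Bruijn graph over canonical k-mers of the reads, removes
#' k-mers below the coverage cutoff and short dead-end tips (< 2k bases),
#' and emits maximal unbranched paths as contigs.
#'
#' @param reads Reads tibble (`read_id`, `sequence`).
#' @param k K-mer size, `15 <= k < read length`.
#' @param min_contig_len Minimum emitted contig length (bp).
#' @param cov_cutoff Minimum k-mer multiplicity retained, or `NULL` for the
#'   default rule: singleton k-mers are dropped when mean k-mer coverage is
#'   at least 10, otherwise all are kept.
#' @return A unigene tibble with `provenance = "denovo"` (no member layout).
#' @export
denovo_assemble <- function(reads, k = 31L, min_contig_len = 100L,
                            cov_cutoff = NULL) {
  k <- as.integer(k)
  stopifnot(k >= 15L)
  empty <- unigene_tibble(list(), "denovo")
  if (nrow(reads) == 0L) return(empty)
  if (any(nchar(reads$sequence) <= k)) {
    if (all(nchar(reads$sequence) <= k)) {
      stop("k must be smaller than the read length", call. = FALSE)
    }
  }
  seqs <- reads$sequence[nchar(reads$sequence) > k]
  if (!length(seqs)) return(empty)

  km <- unlist(lapply(seqs, kmers_of, w = k), use.names = FALSE)
  km <- km[grepl("^[ACGT]+$", km)]
  if (!length(km)) return(empty)
  rc <- revcomp_chr(km)
  canon <- pmin(km, rc)
  cov <- table(canon)
  if (is.null(cov_cutoff)) {
    cov_cutoff <- if (mean(cov) >= 10) 2L else 1L
  }
  keep <- names(cov)[cov >= cov_cutoff]
  if (!length(keep)) return(empty)

  build_contigs <- function(keep) {
    rckeep <- revcomp_chr(keep)
    oriented_all <- c(keep, rckeep)
    rc_all <- c(rckeep, keep)
    # hash of both orientations plus a reverse-complement lookup, so walking
    # never recomputes a reverse complement per k-mer
    S <- new.env(parent = emptyenv(), size = length(oriented_all) * 2L)
    RC <- new.env(parent = emptyenv(), size = length(oriented_all) * 2L)
    for (i in seq_along(oriented_all)) {
      assign(oriented_all[i], TRUE, envir = S)
      assign(oriented_all[i], rc_all[i], envir = RC)
    }
    present <- function(u) exists(u, envir = S, inherits = FALSE)
    succs <- function(u) {
      cand <- paste0(substring(u, 2L, k), DNA_BASES)
      cand[vapply(cand, present, logical(1))]
    }
    preds <- function(u) {
      cand <- paste0(DNA_BASES, substring(u, 1L, k - 1L))
      cand[vapply(cand, present, logical(1))]
    }
    visited <- new.env(parent = emptyenv(), size = length(oriented_all) * 2L)
    seen <- function(u) exists(u, envir = visited, inherits = FALSE)
    mark <- function(u) {
      assign(u, TRUE, envir = visited)
      assign(get(u, envir = RC, inherits = FALSE), TRUE, envir = visited)
    }

    walk <- function(start) {
      path_last <- character(0)
      u <- start
      mark(u)
      repeat {
        nx <- succs(u)
        if (length(nx) != 1L) break
        v <- nx[[1]]
        if (length(preds(v)) != 1L) break
        if (seen(v)) break
        mark(v)
        path_last <- c(path_last, substring(v, k, k))
        u <- v
      }
      paste0(start, paste(path_last, collapse = ""))
    }

    oriented <- oriented_all
    is_start <- vapply(oriented, function(u) {
      p <- preds(u)
      length(p) != 1L || length(succs(p[[1]])) > 1L
    }, logical(1))
    contigs <- character(0)
    for (u in oriented[is_start]) {
      if (!seen(u)) contigs <- c(contigs, walk(u))
    }
    for (u in keep) {           # leftovers: pure cycles
      if (!seen(u)) contigs <- c(contigs, walk(u))
    }
    contigs
  }

  contigs <- build_contigs(keep)
  # one round of tip clipping: short dead-end paths attached to a branch
  tip_len <- 2L * k
  is_tip <- nchar(contigs) < tip_len
  if (any(is_tip) && any(!is_tip)) {
    tip_kmers <- unlist(lapply(contigs[is_tip], kmers_of, w = k),
                        use.names = FALSE)
    tip_canon <- pmin(tip_kmers, revcomp_chr(tip_kmers))
    keep2 <- setdiff(keep, tip_canon)
    if (length(keep2)) contigs <- build_contigs(keep2)
  }
  contigs <- contigs[nchar(contigs) >= min_contig_len]
  # canonical orientation for determinism
  contigs <- unique(pmin(contigs, revcomp_chr(contigs)))
  unigene_tibble(lapply(contigs, function(s) {
    list(consensus = s, members = tibble::tibble(frag_id = character(0),
                                                 orient = character(0),
                                                 offset = integer(0)))
  }), "denovo")
}

#' Merge EST-derived and de novo unigene sets
#'
#' Runs the same greedy overlap merge over the union of the two unigene
#' sets; final unigenes are renumbered `PP000001...` in decreasing length
#' order and a total id map from every input id to its final id is returned.
#'
#' @param est_unigenes,denovo_unigenes Unigene tibbles.
#' @param min_overlap,min_identity As in [assemble_ests()].
#' @return A list: `unigenes` (merged, renumbered tibble; provenance is
#'   `"merged"` where members of both sets fused, otherwise inherited) and
#'   `id_map` (tibble `old_id`, `source`, `new_id`).
#' @export
merge_assemblies <- function(est_unigenes, denovo_unigenes,
                             min_overlap = 40L, min_identity = 0.97) {
  src <- c(rep("est", nrow(est_unigenes)), rep("denovo", nrow(denovo_unigenes)))
  old_ids <- c(est_unigenes$unigene_id, denovo_unigenes$unigene_id)
  tagged <- paste(src, old_ids, sep = ":")
  frag <- stats::setNames(c(est_unigenes$sequence, denovo_unigenes$sequence),
                          tagged)
  if (!length(frag)) {
    return(list(unigenes = unigene_tibble(list(), "merged"),
                id_map = tibble::tibble(old_id = character(),
                                        source = character(),
                                        new_id = character())))
  }
  contigs <- greedy_assemble(frag, min_overlap, min_identity)
  prov <- vapply(contigs, function(ct) {
    s <- unique(sub(":.*$", "", ct$members$frag_id))
    if (length(s) > 1L) "merged" else s
  }, character(1))
  out <- unigene_tibble(contigs, prov)
  id_map <- data.table::rbindlist(lapply(seq_len(nrow(out)), function(i) {
    m <- out$members[[i]]
    data.table::data.table(tag = unique(m$frag_id), new_id = out$unigene_id[i])
  }))
  id_map <- tibble::tibble(old_id = sub("^[^:]*:", "", id_map$tag),
                           source = sub(":.*$", "", id_map$tag),
                           new_id = id_map$new_id)
  # strip the tags from the stored member tables
  out$members <- lapply(out$members, function(m) {
    m$frag_id <- sub("^[^:]*:", "", m$frag_id)
    m
  })
  list(unigenes = out, id_map = id_map)
}
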