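# Regulator target-set overlap accounting: best-hit homolog mapping of
# unigenes to a reference organism's genes, intersection of DE unigene sets
# with a transcription-factor target catalogue (HY5-style light/dark
# labels), and functional-category tallies.

#' Map unigenes to reference genes by best local alignment
#'
#' Candidate reference genes are screened by shared k-mer counts (both
#' strands), then scored by banded local alignment
#' ([Biostrings::pairwiseAlignment], match +1, mismatch -2, gap open 5,
#' extend 2); the best-scoring hit is kept if it reaches `min_score` and an
#' e-value-like quantity `K * m * n * exp(-lambda * S)` (Karlin-Altschul
#' scaling with generic ungapped constants `K = 0.46`, `lambda = 1.28`;
#' approximate, only the thresholds matter) is at most `max_eval`. Ties are
#' broken by lexicographic reference id.
#'
#' @param unigenes Unigene tibble or named character vector.
#' @param reference Named character vector of reference gene sequences.
#' @param min_score Minimum alignment score.
#' @param max_eval Maximum e-value-like score.
#' @param k Seed k-mer size for candidate screening.
#' @param n_candidates Alignments computed per unigene (top candidates by
#'   shared k-mers).
#' @return A tibble (`unigene_id`, `reference_id`, `score`, `evalue_like`),
#'   at most one row (best hit) per unigene.
#' @export
map_homologs <- function(unigenes, reference, min_score = 40,
                         max_eval = 1e-6, k = 12L, n_candidates = 5L) {
  stopifnot(min_score > 0, max_eval > 0)
  q <- if (is.data.frame(unigenes)) {
    stats::setNames(unigenes$sequence, unigenes$unigene_id)
  } else unigenes
  empty <- tibble::tibble(unigene_id = character(), reference_id = character(),
                          score = numeric(), evalue_like = numeric())
  if (length(q) == 0L) return(empty)
  if (length(reference) == 0L) {
    warning("empty reference set: no homologs mapped")
    return(empty)
  }
  # k-mer index of the reference (forward strand)
  idx <- data.table::rbindlist(lapply(names(reference), function(rid) {
    km <- unique(kmers_of(reference[[rid]], k))
    if (!length(km)) return(NULL)
    data.table::data.table(kmer = km, ref = rid)
  }))
  data.table::setkey(idx, kmer)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  refs_dss <- Biostrings::DNAStringSet(reference)
  K <- 0.46; lambda <- 1.28
  total_n <- sum(nchar(reference))

  rows <- lapply(names(q), function(uid) {
    s <- q[[uid]]
    if (nchar(s) < k) return(NULL)
    best <- NULL
    for (qs in c(s, revcomp_chr(s))) {
      km <- unique(kmers_of(qs, k))
      hit <- idx[data.table::data.table(kmer = km), on = "kmer", nomatch = NULL]
      if (nrow(hit) == 0L) next
      tab <- sort(table(hit$ref), decreasing = TRUE)
      cand <- names(tab)[seq_len(min(n_candidates, length(tab)))]
      aln <- Biostrings::pairwiseAlignment(
        rep(Biostrings::DNAStringSet(qs), length(cand)), refs_dss[cand],
        type = "local", substitutionMatrix = mat,
        gapOpening = 5, gapExtension = 2)
      sc <- Biostrings::score(aln)
      ord <- order(-sc, cand)  # ties by lexicographic reference id
      j <- ord[1]
      if (is.null(best) || sc[j] > best$score ||
          (sc[j] == best$score && cand[j] < best$ref)) {
        best <- list(ref = cand[j], score = sc[j])
      }
    }
    if (is.null(best)) return(NULL)
    ev <- K * nchar(s) * total_n * exp(-lambda * best$score)
    if (best$score < min_score || ev > max_eval) return(NULL)
    tibble::tibble(unigene_id = uid, reference_id = best$ref,
                   score = best$score, evalue_like = ev)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) empty else out
}

#' Overlap of DE unigene sets with a regulator target catalogue
#'
#' Membership is via the homolog map: a DE unigene overlaps the target set
#' when its best-hit reference gene is a catalogued target. Reports the up-
#' and down-regulated overlaps, their total, and the decomposition over the
#' catalogue's light/dark condition labels (genes labelled `both` count in
#' both the light and dark intersections).
#'
#' @param de_up,de_down Disjoint character vectors of DE unigene ids.
#' @param homologs Tibble from [map_homologs()].
#' @param targets Tibble (`reference_id`, `condition`), condition one of
#'   `light`, `dark`, `both`, `unlabeled`.
#' @param universe Optional character vector of all assembled unigene ids;
#'   if supplied, DE ids outside it raise an error.
#' @return A list of counts: `n_up_target`, `n_down_target`, `n_total`,
#'   `n_up_light`, `n_up_dark`, `n_down_light`, `n_down_dark`, plus the
#'   member id sets in `members`.
#' @export
venn_counts <- function(de_up, de_down, homologs, targets, universe = NULL) {
  de_up <- unique(de_up); de_down <- unique(de_down)
  if (length(intersect(de_up, de_down)) > 0L) {
    stop("de_up and de_down must be disjoint", call. = FALSE)
  }
  if (!is.null(universe)) {
    missing <- setdiff(c(de_up, de_down), universe)
    if (length(missing)) {
      stop("DE unigene(s) absent from the assembly: ",
           paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
    }
  }
  stopifnot(all(c("reference_id", "condition") %in% names(targets)))
  if (anyDuplicated(targets$reference_id)) {
    stop("target catalogue ids must be unique", call. = FALSE)
  }
  cond <- stats::setNames(targets$condition, targets$reference_id)
  hmap <- stats::setNames(homologs$reference_id, homologs$unigene_id)

  members_of <- function(ids) {
    ref <- hmap[ids]
    ids[!is.na(ref) & ref %in% targets$reference_id]
  }
  label_of <- function(ids) cond[hmap[ids]]
  up_t <- members_of(de_up)
  down_t <- members_of(de_down)
  lab_up <- label_of(up_t)
  lab_down <- label_of(down_t)
  list(n_up_target = length(up_t),
       n_down_target = length(down_t),
       n_total = length(up_t) + length(down_t),
       n_up_light = sum(lab_up %in% c("light", "both")),
       n_up_dark = sum(lab_up %in% c("dark", "both")),
       n_down_light = sum(lab_down %in% c("light", "both")),
       n_down_dark = sum(lab_down %in% c("dark", "both")),
       members = list(up = up_t, down = down_t))
}

#' Tally functional categories over a gene set
#'
#' A gene may belong to several categories and then counts once in each;
#' genes with no annotation are tallied as `unclassified`. Input ids are
#' deduplicated first, so the tally is permutation-invariant and idempotent.
#'
#' @param genes Character vector of unigene ids.
#' @param annotation Tibble (`unigene_id`, `category`), possibly with
#'   multiple rows per unigene.
#' @return A tibble (`category`, `n`) sorted by decreasing count then
#'   category name.
#' @export
categorize <- function(genes, annotation) {
  genes <- unique(genes)
  if (length(genes) == 0L) {
    return(tibble::tibble(category = character(), n = integer()))
  }
  stopifnot(all(c("unigene_id", "category") %in% names(annotation)))
  ann <- unique(annotation[annotation$unigene_id %in% genes,
                           c("unigene_id", "category")])
  tally <- table(ann$category)
  n_unclassified <- sum(!(genes %in% ann$unigene_id))
  out <- tibble::tibble(category = names(tally), n = as.integer(tally))
  if (n_unclassified > 0L) {
    out <- dplyr::bind_rows(out, tibble::tibble(category = "unclassified",
                                                n = n_unclassified))
  }
  dplyr::arrange(out, dplyr::desc(n), category)
}
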