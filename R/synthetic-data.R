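# Synthetic-data generator: transcriptomes, contaminants, Sanger-style ESTs
# and two-condition Illumina-style read libraries with per-read ground truth,
# so every downstream stage can be validated against known answers.

#' Generate a synthetic transcript population
#'
#' Draws `n_genes` random transcript sequences with lengths uniform on
#' `[len_min, len_max]` and a target GC fraction, standing in for the
#' transcript population of a non-model crop (cauliflower curds) for which
#' no reference genome exists.
#'
#' @param n_genes Number of transcripts to generate.
#' @param len_min,len_max Inclusive transcript length bounds (bp).
#' @param gc Target GC fraction in `[0, 1]`.
#' @param seed Integer seed; generation is deterministic for a fixed seed.
#' @return A named character vector of DNA sequences (names are gene ids,
#'   `g000001` style) with attribute `gc_target`.
#' @examples
#' tx <- generate_transcriptome(5, 300, 600, gc = 0.4, seed = 1)
#' nchar(tx)
#' @export
generate_transcriptome <- function(n_genes, len_min = 300L, len_max = 2000L,
                                   gc = 0.42, seed = 1L) {
  stopifnot(n_genes >= 0)
  if (!(len_min > 0 && len_min <= len_max)) {
    stop("invalid length bounds: need 0 < len_min <= len_max", call. = FALSE)
  }
  stopifnot(gc >= 0, gc <= 1)
  if (n_genes == 0L) {
    out <- character(0)
    attr(out, "gc_target") <- gc
    return(out)
  }
  set.seed(as.integer(seed))
  span <- seq.int(len_min, len_max)
  lens <- span[sample.int(length(span), n_genes, replace = TRUE)]
  seqs <- random_dna(n_genes, lens, gc = gc)
  names(seqs) <- sprintf("g%06d", seq_len(n_genes))
  attr(seqs, "gc_target") <- gc
  seqs
}

#' Generate contaminant reference sequences
#'
#' Random rRNA, cloning-vector and bacterial sequences used to plant and then
#' screen contamination (the field workflow screens ESTs against UniVec, the
#' E. coli genome and the organism's rRNA, and reads against rRNA).
#'
#' @param n_rrna,n_vector,n_bacterial Record counts per class.
#' @param length Record length (bp), shared by all classes.
#' @param seed Integer seed.
#' @return A list with elements `rrna`, `vector`, `bacterial`, each a named
#'   character vector of DNA sequences; identifiers are disjoint from gene ids.
#' @export
generate_contaminants <- function(n_rrna = 2L, n_vector = 2L, n_bacterial = 2L,
                                  length = 1500L, seed = 1L) {
  stopifnot(n_rrna >= 0, n_vector >= 0, n_bacterial >= 0, length > 0)
  set.seed(as.integer(seed))
  mk <- function(n, prefix, gc) {
    if (n == 0L) return(stats::setNames(character(0), character(0)))
    s <- random_dna(n, rep(length, n), gc = gc)
    names(s) <- sprintf("%s_%03d", prefix, seq_len(n))
    s
  }
  list(rrna = mk(n_rrna, "rRNA", 0.55),
       vector = mk(n_vector, "vector", 0.50),
       bacterial = mk(n_bacterial, "bact", 0.51))
}

#' Simulate Sanger-style ESTs from a transcript set
#'
#' Each EST is a subsequence of one transcript (reverse-complemented with
#' probability 1/2) with substitution errors at `error_rate` per base.
#' Origin coordinates are retained so assembly can be checked exactly.
#'
#' @param transcripts Named character vector of transcripts.
#' @param n_ests Number of ESTs.
#' @param len_mean Mean EST length (bp); lengths are normal with sd
#'   `0.1 * len_mean`, clamped to `[0.5 * len_mean, transcript length]`.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return A tibble with columns `est_id`, `sequence`, `origin`, `start`
#'   (1-based on the forward transcript), `strand`, `n_errors`.
#' @export
simulate_ests <- function(transcripts, n_ests, len_mean = 500L,
                          error_rate = 0, seed = 1L) {
  stopifnot(n_ests >= 0, error_rate >= 0, error_rate < 1)
  if (n_ests == 0L) {
    return(tibble::tibble(est_id = character(), sequence = character(),
                          origin = character(), start = integer(),
                          strand = character(), n_errors = integer()))
  }
  if (length(transcripts) == 0L) {
    stop("cannot simulate ESTs from an empty transcript set", call. = FALSE)
  }
  set.seed(as.integer(seed))
  origin <- sample(names(transcripts), n_ests, replace = TRUE)
  tlen <- nchar(transcripts)[origin]
  len <- pmin(tlen, pmax(as.integer(len_mean / 2),
                         round(stats::rnorm(n_ests, len_mean, 0.1 * len_mean))))
  start <- vapply(seq_len(n_ests),
                  function(i) sample.int(tlen[i] - len[i] + 1L, 1L), integer(1))
  strand <- sample(c("+", "-"), n_ests, replace = TRUE)
  seqs <- substring(transcripts[origin], start, start + len - 1L)
  flip <- strand == "-"
  seqs[flip] <- revcomp_chr(seqs[flip])
  mut <- mutate_seqs(seqs, error_rate)
  tibble::tibble(est_id = sprintf("est%06d", seq_len(n_ests)),
                 sequence = unname(mut$seq), origin = unname(origin),
                 start = as.integer(start), strand = strand,
                 n_errors = mut$n_errors)
}

#' Define a two-condition differential-expression design
#'
#' Assigns per-gene baseline expression weights and plants up- and
#' down-regulated genes at a fixed true fold change. The default fold of 3
#' matches the calling threshold of the downstream test; acceptance-style
#' recovery experiments plant stronger effects (e.g. fold 10).
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param fraction_up,fraction_down Fractions of genes planted up/down
#'   (condition 2 relative to condition 1); must sum to at most 1.
#' @param fold True fold change for planted genes (>= 1).
#' @param base_mean Either a single positive number used for every gene or a
#'   vector of per-gene baseline means (arbitrary units: expression weights).
#'   The default draws log-normal weights (meanlog `log(20)`, sdlog 1).
#' @param seed Integer seed.
#' @return A tibble (`gene_id`, `mean_expr_1`, `mean_expr_2`, `true_fold`,
#'   `de_flag`) — the gene-level half of the truth ledger. `de_flag` is
#'   `"up"` iff `true_fold >= 3`, `"down"` iff `true_fold <= 1/3`, else
#'   `"null"`.
#' @export
de_design <- function(gene_ids, fraction_up = 0, fraction_down = 0,
                      fold = 3, base_mean = NULL, seed = 1L) {
  stopifnot(fraction_up >= 0, fraction_down >= 0,
            fraction_up + fraction_down <= 1, fold >= 1)
  n <- length(gene_ids)
  set.seed(as.integer(seed))
  if (is.null(base_mean)) {
    base_mean <- stats::rlnorm(n, meanlog = log(20), sdlog = 1)
  } else if (length(base_mean) == 1L) {
    base_mean <- rep(as.numeric(base_mean), n)
  }
  stopifnot(length(base_mean) == n, all(base_mean >= 0))
  n_up <- round(fraction_up * n)
  n_down <- round(fraction_down * n)
  flag <- rep("null", n)
  if (n_up + n_down > 0) {
    planted <- sample.int(n, n_up + n_down)
    flag[planted[seq_len(n_up)]] <- "up"
    if (n_down > 0) flag[planted[n_up + seq_len(n_down)]] <- "down"
  }
  m2 <- base_mean
  m2[flag == "up"] <- base_mean[flag == "up"] * fold
  m2[flag == "down"] <- base_mean[flag == "down"] / fold
  truef <- ifelse(base_mean > 0, m2 / base_mean, NA_real_)
  flag <- ifelse(!is.na(truef) & truef >= 3, "up",
                 ifelse(!is.na(truef) & truef <= 1 / 3, "down", "null"))
  tibble::tibble(gene_id = gene_ids, mean_expr_1 = base_mean,
                 mean_expr_2 = m2, true_fold = truef, de_flag = flag)
}

#' Simulate a per-gene count matrix under the Poisson model
#'
#' Per-library read totals are fixed at `depth` and allocated multinomially
#' with probabilities proportional to the design means, so marginal per-gene
#' counts are (conditioned) Poisson with mean proportional to
#' `mean_expr * depth` — the count model the digital-expression R statistic
#' assumes.
#'
#' @param design Tibble from [de_design()].
#' @param depth Integer vector of per-library read totals (length 2, or a
#'   scalar recycled).
#' @param seed Integer seed.
#' @return Integer matrix (genes x 2 libraries) with dimnames, plus attribute
#'   `library_sizes`.
#' @export
simulate_counts <- function(design, depth, seed = 1L) {
  stopifnot(all(depth >= 0))
  depth <- as.integer(rep(depth, length.out = 2L))
  set.seed(as.integer(seed))
  draw <- function(w, d) {
    if (d == 0L || sum(w) == 0) return(integer(length(w)))
    as.integer(stats::rmultinom(1L, d, prob = w / sum(w)))
  }
  m <- cbind(lib1 = draw(design$mean_expr_1, depth[1]),
             lib2 = draw(design$mean_expr_2, depth[2]))
  rownames(m) <- design$gene_id
  attr(m, "library_sizes") <- stats::setNames(colSums(m), colnames(m))
  m
}

#' Simulate two-condition Illumina-style read libraries
#'
#' Emits two libraries of fixed-length reads. Reads are allocated across
#' transcripts (multinomial on the design means, i.e. conditioned Poisson)
#' and across rRNA contaminant records (an `rrna_fraction` share of each
#' library); positions are uniform over valid starts, strand 50/50
#' (unstranded protocol). A fraction `adaptor_rate` of reads carries 3'
#' adaptor read-through; substitutions occur at `error_rate` per base.
#' Qualities are constant high (phred `q_high`) except a low-quality 3' tail
#' of `lowq_tail` bases at phred `q_low`, so quality trimming is exercised.
#'
#' @param transcripts Named character vector; every transcript must be at
#'   least `read_len` bp.
#' @param design Tibble from [de_design()] over `names(transcripts)`.
#' @param depth Reads per library (scalar or length-2).
#' @param read_len Read length (bp); default 86 mirrors an Illumina GAII lane.
#' @param error_rate Per-base substitution probability.
#' @param rrna Named character vector of rRNA records (may be empty).
#' @param rrna_fraction Expected fraction of reads of rRNA origin.
#' @param adaptor Adaptor sequence (IUPAC); used for 3' read-through.
#' @param adaptor_rate Fraction of reads carrying adaptor read-through.
#' @param lowq_tail,q_high,q_low Quality-string profile (see Details).
#' @param seed Integer seed; the two libraries use derived child seeds.
#' @return A list with `reads` (tibble: `read_id`, `library`, `sequence`,
#'   `quality`) and `truth` — a truth ledger list with `genes` (the design,
#'   per-library true means) and `reads` (tibble: `read_id`, `library`,
#'   `origin`, `start`, `strand`, `n_errors`, `has_adaptor`).
#' @export
simulate_libraries <- function(transcripts, design, depth,
                               read_len = 86L, error_rate = 0,
                               rrna = character(0), rrna_fraction = 0,
                               adaptor = "AGATCGGAAGAGC", adaptor_rate = 0,
                               lowq_tail = 0L, q_high = 37L, q_low = 10L,
                               seed = 1L) {
  stopifnot(rrna_fraction >= 0, rrna_fraction <= 1,
            adaptor_rate >= 0, adaptor_rate <= 1,
            error_rate >= 0, error_rate < 1, all(depth >= 0))
  assert_dna(adaptor, "adaptor", iupac = TRUE)
  if (rrna_fraction > 0 && length(rrna) == 0L) {
    stop("rrna_fraction > 0 requires rRNA records", call. = FALSE)
  }
  depth <- as.integer(rep(depth, length.out = 2L))
  usable <- nchar(transcripts) >= read_len
  if (any(!usable)) {
    warning(sum(!usable), " transcript(s) shorter than read_len excluded from sampling")
  }
  pool <- c(transcripts[usable], rrna)

  emit_library <- function(lib, mean_expr, d, seed_i) {
    set.seed(seed_i)
    empty <- tibble::tibble(read_id = character(), library = character(),
                            sequence = character(), quality = character())
    ledger0 <- tibble::tibble(read_id = character(), library = character(),
                              origin = character(), start = integer(),
                              strand = character(), n_errors = integer(),
                              has_adaptor = logical())
    if (d == 0L) return(list(reads = empty, ledger = ledger0))
    w_gene <- mean_expr[usable]
    w_gene <- if (sum(w_gene) > 0) w_gene / sum(w_gene) * (1 - rrna_fraction) else w_gene
    w_rrna <- if (length(rrna)) rep(rrna_fraction / length(rrna), length(rrna)) else numeric(0)
    w <- c(w_gene, w_rrna)
    if (sum(w) == 0) stop("all sampling weights are zero", call. = FALSE)
    n_per <- as.integer(stats::rmultinom(1L, d, prob = w / sum(w)))
    origin <- rep(names(pool), n_per)
    # shuffle so read ids are not grouped by origin
    ord <- sample.int(d)
    origin <- origin[ord]
    tlen <- nchar(pool)[origin]
    start <- floor(stats::runif(d) * (tlen - read_len + 1L)) + 1L
    strand <- sample(c("+", "-"), d, replace = TRUE)
    seqs <- substring(pool[origin], start, start + read_len - 1L)
    flip <- strand == "-"
    seqs[flip] <- revcomp_chr(seqs[flip])
    # adaptor read-through replaces the final a_len bases
    has_ad <- stats::runif(d) < adaptor_rate
    if (any(has_ad)) {
      a_len <- pmin(sample(10:40, d, replace = TRUE), read_len - 1L, nchar(adaptor))
      ad_pref <- substring(adaptor, 1L, a_len)
      seqs[has_ad] <- paste0(substring(seqs[has_ad], 1L, read_len - a_len[has_ad]),
                             ad_pref[has_ad])
    }
    mut <- mutate_seqs(seqs, error_rate)
    qual <- paste0(strrep(rawToChar(as.raw(33L + q_high)), read_len - lowq_tail),
                   strrep(rawToChar(as.raw(33L + q_low)), lowq_tail))
    ids <- sprintf("%s_%07d", lib, seq_len(d))
    list(reads = tibble::tibble(read_id = ids, library = lib,
                                sequence = unname(mut$seq), quality = qual),
         ledger = tibble::tibble(read_id = ids, library = lib,
                                 origin = unname(origin),
                                 start = as.integer(start), strand = strand,
                                 n_errors = mut$n_errors,
                                 has_adaptor = unname(has_ad)))
  }

  lib1 <- emit_library("lib1", design$mean_expr_1, depth[1],
                       child_seed(seed, "libraries"))
  lib2 <- emit_library("lib2", design$mean_expr_2, depth[2],
                       child_seed(seed, "lib2"))
  genes <- design
  list(reads = dplyr::bind_rows(lib1$reads, lib2$reads),
       truth = list(genes = genes,
                    reads = dplyr::bind_rows(lib1$ledger, lib2$ledger)))
}

#' Invert the MacKinney chlorophyll equations
#'
#' Solves the 2x2 linear system of the MacKinney relations for the
#' absorbances that would produce given chlorophyll a and b extract
#' concentrations, i.e. the inverse of [chlorophyll_from_od()] at the
#' extract level. Used to synthesize spectrophotometer readings with known
#' ground truth.
#'
#' @param chl_a,chl_b Chlorophyll a and b concentrations (ug/mL), >= 0.
#' @return A list with `od645` and `od663`.
#' @examples
#' od <- invert_mackinney(13.333, 3.887)
#' chlorophyll_from_od(od$od645, od$od663)
#' @export
invert_mackinney <- function(chl_a, chl_b) {
  stopifnot(length(chl_a) == 1L, length(chl_b) == 1L)
  if (chl_a < 0 || chl_b < 0) {
    stop("infeasible input: chlorophyll concentrations must be >= 0", call. = FALSE)
  }
  # chl_a = 12.7*od663 - 2.69*od645 ; chl_b = 22.9*od645 - 4.48*od663
  M <- matrix(c(-2.69, 12.7,
                22.9, -4.48), nrow = 2, byrow = TRUE)
  od <- solve(M, c(chl_a, chl_b))
  if (any(od < -1e-12)) {
    stop("infeasible input: implied absorbance is negative", call. = FALSE)
  }
  list(od645 = max(od[1], 0), od663 = max(od[2], 0))
}
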