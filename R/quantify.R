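# Per-unigene per-library read counting and RPKM normalization.

#' Count assigned reads per unigene and library
#'
#' Each read contributes at most one count to exactly one unigene. Under the
#' default `"discard-ties"` policy a read with two or more equally-best
#' placements contributes to none; under `"best-unique"` such reads are
#' assigned to one of their best placements at random (seeded). Library
#' sizes are the per-library totals of assigned reads, i.e. a mapped-read
#' denominator.
#'
#' @param hits Alignment hits tibble from [align_reads()] with a `library`
#'   column.
#' @param unigenes Unigene tibble or named character vector: the reference
#'   set the hits were computed against.
#' @param policy `"discard-ties"` or `"best-unique"`.
#' @param libraries Optional character vector fixing the library columns
#'   (useful when one library has no hits).
#' @param seed Seed for the random tie-break under `"best-unique"`.
#' @return A `count_table`: list with `counts` (integer matrix, unigenes x
#'   libraries), `library_sizes`, and `lengths` (unigene lengths, bp).
#' @export
count_reads <- function(hits, unigenes, policy = c("discard-ties", "best-unique"),
                        libraries = NULL, seed = 1L) {
  policy <- match.arg(policy)
  ug_ids <- if (is.data.frame(unigenes)) unigenes$unigene_id else names(unigenes)
  ug_len <- if (is.data.frame(unigenes)) {
    stats::setNames(unigenes$length, unigenes$unigene_id)
  } else stats::setNames(nchar(unigenes), names(unigenes))
  if (!all(hits$unigene_id %in% ug_ids)) {
    stop("hit(s) reference unknown unigene id(s): ",
         paste(utils::head(setdiff(hits$unigene_id, ug_ids), 3), collapse = ", "),
         call. = FALSE)
  }
  if (!("library" %in% names(hits))) {
    stop("hits must carry a 'library' column", call. = FALSE)
  }
  libs <- libraries %||% sort(unique(hits$library))
  if (policy == "discard-ties") {
    assigned <- hits[hits$n_best == 1L, , drop = FALSE]
    assigned <- assigned[!duplicated(assigned$read_id), , drop = FALSE]
  } else {
    # random tie-break: pick one placement per read uniformly among its
    # equally-best placements (requires align_reads(keep_ties = TRUE) for
    # true randomization; with collapsed hits the representative is used)
    set.seed(as.integer(seed))
    h <- data.table::as.data.table(hits)
    data.table::setorderv(h, c("read_id", "unigene_id", "start", "strand"))
    assigned <- tibble::as_tibble(h[, .SD[sample.int(.N, 1L)], by = read_id])
  }
  m <- matrix(0L, nrow = length(ug_ids), ncol = length(libs),
              dimnames = list(ug_ids, libs))
  if (nrow(assigned)) {
    tab <- table(factor(assigned$unigene_id, levels = ug_ids),
                 factor(assigned$library, levels = libs))
    m <- m + as.integer(tab)
    dim(m) <- c(length(ug_ids), length(libs))
    dimnames(m) <- list(ug_ids, libs)
  }
  structure(list(counts = m,
                 library_sizes = colSums(m),
                 lengths = ug_len[ug_ids]),
            class = "count_table")
}

#' Build a count table directly from a count matrix
#'
#' Convenience constructor for simulation studies where counts are drawn
#' from the generative model without read emission.
#'
#' @param counts Integer matrix (genes x libraries) with dimnames.
#' @param lengths Per-gene lengths (bp), named or in row order; default 1 kb
#'   for every gene, which makes RPKM proportional to counts per million.
#' @return A `count_table`.
#' @export
as_count_table <- function(counts, lengths = NULL) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)), all(counts >= 0))
  if (is.null(lengths)) lengths <- rep(1000L, nrow(counts))
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  stopifnot(length(lengths) == nrow(counts), all(lengths > 0))
  structure(list(counts = counts,
                 library_sizes = colSums(counts),
                 lengths = stats::setNames(as.numeric(lengths), rownames(counts))),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "unigenes x", ncol(x$counts),
      "libraries\nlibrary sizes:",
      paste(names(x$library_sizes), x$library_sizes, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' RPKM normalization
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `rpkm = count * 1e9 / (library_size * length)`.
#'
#' @param ct A `count_table`.
#' @return Numeric matrix of RPKM values, same shape as `ct$counts`.
#' @export
compute_rpkm <- function(ct) {
  stopifnot(inherits(ct, "count_table"))
  N <- ct$library_sizes
  bad <- N == 0 & colSums(ct$counts) > 0
  if (any(bad)) stop("zero library size with nonzero counts", call. = FALSE)
  denom <- outer(ct$lengths, N)
  r <- ct$counts * 1e9 / denom
  r[, N == 0] <- 0
  r
}
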