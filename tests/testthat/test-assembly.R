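test_that("screen_ests clips planted vector ends and discards contaminant ESTs", {
  tx <- generate_transcriptome(6, 500, 700, seed = 30)
  cont <- generate_contaminants(1, 2, 1, length = 1200, seed = 31)
  ests <- simulate_ests(tx, 40, len_mean = 300, error_rate = 0, seed = 32)

  clean_out <- screen_ests(ests, cont$vector, cont$bacterial, cont$rrna, 100)
  expect_identical(clean_out$sequence, ests$sequence)   # clean pool unchanged

  # plant vector prefixes on 5 ESTs, one pure-vector EST, one
  # mostly-bacterial EST; pick ESTs whose first base differs from the next
  # vector base so the planted boundary is unambiguous
  planted <- ests
  vpref <- substring(cont$vector[[1]], 51, 110)
  v_next <- substring(cont$vector[[1]], 111, 111)
  pick <- which(substring(ests$sequence, 1, 1) != v_next)[1:5]
  planted$sequence[pick] <- paste0(vpref, planted$sequence[pick])
  planted <- dplyr::bind_rows(
    planted,
    tibble::tibble(est_id = c("vec1", "bac1"),
                   sequence = c(substring(cont$vector[[2]], 101, 400),
                                substring(cont$bacterial[[1]], 1, 350)),
                   origin = NA, start = NA_integer_, strand = "+",
                   n_errors = 0L))
  out <- screen_ests(planted, cont$vector, cont$bacterial, cont$rrna, 100)
  expect_identical(out$sequence[pick], ests$sequence[pick])  # prefixes clipped exactly
  expect_false(any(c("vec1", "bac1") %in% out$est_id))
  expect_equal(attr(out, "n_discarded_contaminant") +
                 attr(out, "n_discarded_short"), 2L)
})

test_that("greedy EST assembly reconstructs transcripts from tiling fragments", {
  # two reads tiling one transcript with a 100 bp exact overlap
  tx1 <- generate_transcriptome(1, 400, 400, seed = 33)
  a <- substring(tx1[[1]], 1, 250)
  b <- substring(tx1[[1]], 151, 400)
  two <- tibble::tibble(est_id = c("a", "b"), sequence = c(a, b))
  ug <- assemble_ests(two, min_overlap = 40)
  expect_equal(nrow(ug), 1L)
  expect_true(ug$sequence %in% c(tx1[[1]], curdseq:::revcomp_chr(tx1[[1]])))
  expect_match(ug$unigene_id, "^PP[0-9]{6}$")

  # disjoint ESTs from two transcripts stay separate
  tx2 <- generate_transcriptome(2, 500, 500, seed = 34)
  disj <- tibble::tibble(est_id = c("x", "y"),
                         sequence = c(substring(tx2[[1]], 1, 300),
                                      substring(tx2[[2]], 1, 300)))
  expect_equal(nrow(assemble_ests(disj, min_overlap = 40)), 2L)

  # ~50 error-free ESTs tiling a 2 kb transcript reassemble it exactly
  big <- generate_transcriptome(1, 2000, 2000, seed = 35)
  ests <- tile_ests(big, len = 120, step = 40)
  expect_gte(nrow(ests), 48L)
  ug <- assemble_ests(ests, min_overlap = 30)
  expect_equal(nrow(ug), 1L)
  expect_true(ug$sequence %in% c(big[[1]], curdseq:::revcomp_chr(big[[1]])))

  # strand-mixed fragments assemble too
  mixed <- tile_ests(tx1, len = 150, step = 70)
  mixed$sequence[c(2, 4)] <- curdseq:::revcomp_chr(mixed$sequence[c(2, 4)])
  ug <- assemble_ests(mixed, min_overlap = 40)
  expect_equal(nrow(ug), 1L)
})

test_that("every EST aligns back to its assembled unigene", {
  tx <- generate_transcriptome(4, 500, 700, seed = 36)
  ests <- tile_ests(tx, len = 200, step = 90)
  ug <- assemble_ests(ests, min_overlap = 40)
  seqs <- stats::setNames(ug$sequence, ug$unigene_id)
  for (i in seq_len(nrow(ests))) {
    s <- ests$sequence[i]
    hit <- any(vapply(seqs, function(u) {
      grepl(s, u, fixed = TRUE) ||
        grepl(curdseq:::revcomp_chr(s), u, fixed = TRUE)
    }, logical(1)))
    expect_true(hit)
  }
})

test_that("read alignment reports best placements and routes the rest to unaligned", {
  tx <- generate_transcriptome(5, 400, 600, seed = 37)
  ug <- tibble::tibble(unigene_id = names(tx), sequence = unname(tx),
                       length = nchar(unname(tx)), provenance = "est",
                       members = vector("list", 5))
  # exact substring: 0 mismatches at the correct 0-based start
  reads <- tibble::tibble(read_id = "r1",
                          sequence = substring(tx[[2]], 51, 136),
                          quality = strrep("F", 86))
  res <- align_reads(reads, ug, 2)
  expect_equal(res$hits$unigene_id, names(tx)[2])
  expect_equal(res$hits$start, 50L)
  expect_equal(res$hits$mismatches, 0L)
  expect_equal(res$hits$strand, "+")

  # read from an unrepresented transcript is unaligned
  other <- generate_transcriptome(1, 400, 400, seed = 38)
  res2 <- align_reads(tibble::tibble(read_id = "r2",
                                     sequence = substring(other[[1]], 1, 86),
                                     quality = strrep("F", 86)), ug, 2)
  expect_equal(nrow(res2$hits), 0L)
  expect_equal(res2$unaligned$read_id, "r2")

  expect_warning(align_reads(reads, ug[0, ], 2), "empty")
})

test_that("error-free synthetic reads align to their true origin coordinates", {
  tx <- generate_transcriptome(10, 300, 500, seed = 39)
  design <- de_design(names(tx), 0, 0, seed = 40)
  libs <- simulate_libraries(tx, design, depth = 800, error_rate = 0, seed = 41)
  ug <- tibble::tibble(unigene_id = names(tx), sequence = unname(tx),
                       length = nchar(unname(tx)), provenance = "est",
                       members = vector("list", length(tx)))
  res <- align_reads(libs$reads, ug, 2)
  led <- libs$truth$reads
  j <- match(res$hits$read_id, led$read_id)
  uniq <- res$hits$n_best == 1L
  expect_gt(mean(uniq), 0.99)
  expect_identical(res$hits$unigene_id[uniq], led$origin[j][uniq])
  expect_identical(res$hits$start[uniq], led$start[j][uniq] - 1L)
  expect_identical(res$hits$strand[uniq], led$strand[j][uniq])
  expect_equal(nrow(res$hits) + nrow(res$unaligned), nrow(libs$reads))
  # every hit verifies by direct Hamming recomputation
  seqs <- stats::setNames(ug$sequence, ug$unigene_id)
  for (i in sample.int(nrow(res$hits), 30)) {
    h <- res$hits[i, ]
    win <- substring(seqs[[h$unigene_id]], h$start + 1L, h$start + 86L)
    rd <- libs$reads$sequence[libs$reads$read_id == h$read_id]
    if (h$strand == "-") rd <- curdseq:::revcomp_chr(rd)
    expect_lte(curdseq:::hamming_chr(rd, win), 2L)
  }
})

test_that("de Bruijn assembly recovers a uniquely covered transcript", {
  tx <- generate_transcriptome(1, 500, 500, seed = 42)
  starts <- unique(c(seq(1, 415, by = 4), 415))
  reads <- tibble::tibble(
    read_id = sprintf("r%03d", seq_along(starts)),
    sequence = substring(tx[[1]], starts, starts + 85),
    quality = strrep("F", 86))
  ug <- denovo_assemble(reads, k = 31, min_contig_len = 100, cov_cutoff = 1)
  expect_equal(nrow(ug), 1L)
  expect_true(ug$sequence %in% c(tx[[1]], curdseq:::revcomp_chr(tx[[1]])))
  expect_identical(ug$provenance, "denovo")

  empty <- denovo_assemble(reads[0, ], k = 31)
  expect_equal(nrow(empty), 0L)
  expect_error(denovo_assemble(tibble::tibble(read_id = "a", sequence = "ACGT",
                                              quality = "FFFF"), k = 31),
               "smaller than the read length")
})

test_that("meta-assembly merges overlapping sets and renumbers deterministically", {
  tx <- generate_transcriptome(3, 600, 800, seed = 43)
  est_ug <- assemble_ests(tile_ests(tx[1], len = 200, step = 90), min_overlap = 40)
  dn_ug <- assemble_ests(tile_ests(tx[2], len = 200, step = 90), min_overlap = 40)
  dn_ug$provenance <- "denovo"

  # disjoint sets: concatenation, renumbered PP ids in decreasing length
  m <- merge_assemblies(est_ug, dn_ug)
  expect_equal(nrow(m$unigenes), 2L)
  expect_identical(m$unigenes$unigene_id, c("PP000001", "PP000002"))
  expect_true(all(diff(m$unigenes$length) <= 0))
  expect_setequal(m$id_map$new_id, m$unigenes$unigene_id)
  expect_equal(nrow(m$id_map), 2L)   # id_map total over inputs

  # an EST-unigene and a de novo contig sharing a 200 bp overlap merge
  left <- tibble::tibble(unigene_id = "PP000001",
                         sequence = substring(tx[[3]], 1, 450),
                         length = 450L, provenance = "est",
                         members = list(tibble::tibble()))
  right <- tibble::tibble(unigene_id = "PP000001",
                          sequence = substring(tx[[3]], 251, 700),
                          length = 450L, provenance = "denovo",
                          members = list(tibble::tibble()))
  m2 <- merge_assemblies(left, right)
  expect_equal(nrow(m2$unigenes), 1L)
  expect_identical(m2$unigenes$provenance, "merged")
  want <- substring(tx[[3]], 1, 700)
  expect_true(m2$unigenes$sequence %in% c(want, curdseq:::revcomp_chr(want)))
  expect_equal(nrow(m2$id_map), 2L)
  expect_identical(unique(m2$id_map$new_id), "PP000001")
})
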