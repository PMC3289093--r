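mk_reads <- function(seqs, quals = NULL) {
  if (is.null(quals)) quals <- strrep("F", nchar(seqs))
  tibble::tibble(read_id = sprintf("r%03d", seq_along(seqs)),
                 sequence = seqs, quality = quals)
}

test_that("trim_reads leaves clean reads untouched and clips adaptors exactly", {
  adaptor <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCACGATCGGAAGAGCACAC"
  clean <- mk_reads(strrep("ACGT", 20))
  out <- trim_reads(clean, quality_min = 20, adaptor = "AGATCGGAAGAGC")
  expect_identical(out$sequence, clean$sequence)

  # 86 bp read whose final 40 bp are exactly the adaptor: 46 bp survive
  body <- substr(strrep("ACGTG", 20), 1, 46)
  read <- mk_reads(paste0(body, substr(adaptor, 1, 40)))
  out <- trim_reads(read, adaptor = adaptor, min_len = 30)
  expect_identical(out$sequence, body)
  expect_equal(attr(out, "n_adaptor_trimmed"), 1L)

  # low-quality 3' tail is trimmed; too-short survivors are discarded
  tail5 <- mk_reads("ACGTACGTACGTACGTACGT",
                    paste0(strrep("F", 15), strrep("+", 5)))
  out <- trim_reads(tail5, quality_min = 20, adaptor = NULL, min_len = 10)
  expect_equal(nchar(out$sequence), 15L)
  expect_equal(nchar(out$quality), 15L)
  out <- trim_reads(tail5, quality_min = 20, adaptor = NULL, min_len = 16)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "n_discarded"), 1L)

  bad <- tibble::tibble(read_id = "r1", sequence = "ACGT", quality = "FFF")
  expect_error(trim_reads(bad), "malformed")
})

test_that("trimming shortens the adaptor-carrying fraction of a synthetic library", {
  tx <- generate_transcriptome(10, 300, 500, seed = 20)
  design <- de_design(names(tx), 0, 0, seed = 21)
  libs <- simulate_libraries(tx, design, depth = 2500, adaptor_rate = 0.2,
                             lowq_tail = 0, seed = 22)
  out <- trim_reads(libs$reads, adaptor = "AGATCGGAAGAGC", min_len = 20)
  n_short <- sum(nchar(out$sequence) < 86) + attr(out, "n_discarded")
  n <- nrow(libs$reads)
  expect_lt(abs(n_short / n - 0.2), 3 * sqrt(0.2 * 0.8 / n))
  # oracle: every planted adaptor read is shortened (chance seed hits in
  # clean reads may add a few)
  planted <- libs$truth$reads$read_id[libs$truth$reads$has_adaptor]
  lens <- stats::setNames(nchar(out$sequence), out$read_id)
  expect_true(all(lens[planted[planted %in% names(lens)]] < 86))
  expect_gte(attr(out, "n_adaptor_trimmed"), length(planted))
  expect_true(all(nchar(out$sequence) <= 86))
})

test_that("screen_rrna removes full-length matches within the mismatch budget", {
  cont <- generate_contaminants(2, 0, 0, length = 1000, seed = 23)
  rrna <- cont$rrna
  sub <- substring(rrna[[1]], 101, 186)
  three_mm <- sub
  for (p in c(5, 40, 70)) {
    old <- substring(three_mm, p, p)
    substr(three_mm, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  reads <- mk_reads(c(sub, three_mm, strrep("ACGTG", 18)))

  scr <- screen_rrna(reads, rrna, max_mismatch = 2)
  expect_identical(scr$removed$read_id, "r001")     # exact substring removed
  expect_true("r002" %in% scr$kept$read_id)         # 3 mismatches kept at k=2
  expect_equal(nrow(scr$kept) + nrow(scr$removed), nrow(reads))  # partition

  # monotonicity: a larger budget never shrinks the removed set
  scr3 <- screen_rrna(reads, rrna, max_mismatch = 3)
  expect_true(all(scr$removed$read_id %in% scr3$removed$read_id))
  expect_true("r002" %in% scr3$removed$read_id)

  expect_warning(screen_rrna(reads, character(0)), "empty")
})

test_that("with zero sequencing error the rRNA screen equals the truth ledger", {
  tx <- generate_transcriptome(15, 300, 600, seed = 24)
  cont <- generate_contaminants(2, 0, 0, seed = 25)
  design <- de_design(names(tx), 0, 0, seed = 26)
  libs <- simulate_libraries(tx, design, depth = 2000, error_rate = 0,
                             rrna = cont$rrna, rrna_fraction = 0.1, seed = 27)
  scr <- screen_rrna(libs$reads, cont$rrna, max_mismatch = 2)
  truth <- libs$truth$reads$read_id[grepl("^rRNA", libs$truth$reads$origin)]
  expect_setequal(scr$removed$read_id, truth)
})
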