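test_that("transcriptome generation respects counts, lengths and GC target", {
  expect_length(generate_transcriptome(0, 100, 200, seed = 1), 0L)

  one <- generate_transcriptome(1, 500, 500, gc = 0.5, seed = 2)
  expect_equal(nchar(unname(one)), 500L)

  tx <- generate_transcriptome(200, 400, 800, gc = 0.4, seed = 3)
  expect_length(tx, 200L)
  expect_false(anyDuplicated(names(tx)) > 0)
  expect_true(all(grepl("^[ACGT]+$", tx)))
  bases <- sum(nchar(tx))
  gc_obs <- sum(vapply(strsplit(tx, ""), function(ch) sum(ch %in% c("G", "C")),
                       numeric(1))) / bases
  se <- sqrt(0.4 * 0.6 / bases)
  expect_lt(abs(gc_obs - 0.4), 3 * se)

  expect_identical(tx, generate_transcriptome(200, 400, 800, gc = 0.4, seed = 3))
  expect_error(generate_transcriptome(5, 300, 200), "length bounds")
})

test_that("contaminant generation is labeled, disjoint and reproducible", {
  expect_length(generate_contaminants(0, 0, 0, seed = 1)$rrna, 0L)
  cont <- generate_contaminants(2, 3, 1, length = 1500, seed = 4)
  expect_length(cont$rrna, 2L)
  expect_equal(unname(nchar(cont$rrna)), c(1500L, 1500L))
  expect_true(grepl("^rRNA", names(cont$rrna)[1]))
  all_ids <- c(names(cont$rrna), names(cont$vector), names(cont$bacterial))
  expect_false(anyDuplicated(all_ids) > 0)
  expect_identical(cont, generate_contaminants(2, 3, 1, length = 1500, seed = 4))
})

test_that("simulated ESTs are subsequences of their origins with the stated error rate", {
  tx <- generate_transcriptome(5, 600, 900, seed = 5)
  expect_equal(nrow(simulate_ests(tx, 0, seed = 1)), 0L)
  expect_error(simulate_ests(character(0), 10, seed = 1), "empty")

  clean <- simulate_ests(tx, 50, len_mean = 300, error_rate = 0, seed = 6)
  for (i in seq_len(nrow(clean))) {
    ori <- tx[[clean$origin[i]]]
    s <- clean$sequence[i]
    expect_true(grepl(s, ori, fixed = TRUE) ||
                  grepl(curdseq:::revcomp_chr(s), ori, fixed = TRUE))
  }

  noisy <- simulate_ests(tx, 1000, len_mean = 500, error_rate = 0.01, seed = 7)
  total_bases <- sum(nchar(noisy$sequence))
  expected <- 0.01 * total_bases
  expect_lt(abs(sum(noisy$n_errors) - expected),
            3 * sqrt(expected * 0.99))
})

test_that("simulated libraries obey depth, rRNA share and the Poisson count model", {
  tx <- generate_transcriptome(20, 300, 600, seed = 8)
  cont <- generate_contaminants(2, 0, 0, seed = 9)
  design <- de_design(names(tx), 0, 0, seed = 10)

  empty <- simulate_libraries(tx, design, depth = 0, seed = 11)
  expect_equal(nrow(empty$reads), 0L)

  libs <- simulate_libraries(tx, design, depth = 10000, error_rate = 0,
                             rrna = cont$rrna, rrna_fraction = 0.1, seed = 12)
  # conservation: emitted reads equal per-library depth, ledger covers reads
  expect_equal(unname(table(libs$reads$library)[c("lib1", "lib2")]),
               c(10000L, 10000L), ignore_attr = TRUE)
  expect_setequal(libs$truth$reads$read_id, libs$reads$read_id)
  # rRNA share within 3 binomial SD per library
  for (lib in c("lib1", "lib2")) {
    n_rrna <- sum(grepl("^rRNA", libs$truth$reads$origin) &
                    libs$truth$reads$library == lib)
    expect_lt(abs(n_rrna - 1000), 3 * sqrt(10000 * 0.1 * 0.9))
  }
  # zero-error reads are exact substrings of their recorded origin
  pool <- c(tx, cont$rrna)
  idx <- sample.int(nrow(libs$reads), 50)
  for (i in idx) {
    led <- libs$truth$reads[i, ]
    win <- substring(pool[[led$origin]], led$start, led$start + 85L)
    rd <- libs$reads$sequence[libs$reads$read_id == led$read_id]
    expect_identical(rd, if (led$strand == "+") win else curdseq:::revcomp_chr(win))
  }
})

test_that("a fold-10 gene's observed count ratio falls in the Poisson 99% interval", {
  genes <- sprintf("g%03d", 1:50)
  base <- rep(100, 50)
  design <- de_design(genes, 0, 0, base_mean = base, seed = 13)
  design$mean_expr_2[1] <- design$mean_expr_1[1] * 10   # plant one fold-10 gene
  design$true_fold[1] <- 10

  # oracle: Monte-Carlo 99% interval of the count ratio at the design means
  lam1 <- 1e4 * design$mean_expr_1[1] / sum(design$mean_expr_1)
  lam2 <- 1e4 * design$mean_expr_2[1] / sum(design$mean_expr_2)
  set.seed(99)
  sim_ratio <- stats::rpois(20000, lam2) / pmax(stats::rpois(20000, lam1), 1)
  bounds <- stats::quantile(sim_ratio, c(0.005, 0.995))

  cm <- simulate_counts(design, depth = 1e4, seed = 14)
  obs <- cm[1, "lib2"] / max(cm[1, "lib1"], 1)
  expect_gte(obs, bounds[[1]])
  expect_lte(obs, bounds[[2]])
})

test_that("library generation is byte-identical for a fixed seed", {
  tx <- generate_transcriptome(10, 300, 500, seed = 15)
  design <- de_design(names(tx), 0.1, 0.1, seed = 16)
  a <- simulate_libraries(tx, design, depth = 500, adaptor_rate = 0.1,
                          lowq_tail = 3, seed = 17)
  b <- simulate_libraries(tx, design, depth = 500, adaptor_rate = 0.1,
                          lowq_tail = 3, seed = 17)
  fa <- tempfile(fileext = ".fastq"); fb <- tempfile(fileext = ".fastq")
  write_fastq(a$reads, fa); write_fastq(b$reads, fb)
  expect_identical(unname(tools::md5sum(fa)), unname(tools::md5sum(fb)))
  ta <- tempfile(fileext = ".fasta"); tb2 <- tempfile(fileext = ".fasta")
  write_fasta(tx, ta); write_fasta(tx, tb2)
  expect_identical(unname(tools::md5sum(ta)), unname(tools::md5sum(tb2)))
  unlink(c(fa, fb, ta, tb2))
})

test_that("invert_mackinney is the exact inverse of the chlorophyll equations", {
  expect_equal(invert_mackinney(0, 0), list(od645 = 0, od663 = 0))
  expect_error(invert_mackinney(12.7, -4.48), "must be >= 0")
  od <- invert_mackinney(13.333, 3.887)
  back <- chlorophyll_from_od(od$od645, od$od663)
  expect_equal(back$chl_a_extract, 13.333, tolerance = 1e-6)
  expect_equal(back$chl_b_extract, 3.887, tolerance = 1e-6)
})
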