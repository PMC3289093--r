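test_that("the R statistic matches a numeric Poisson likelihood-ratio oracle", {
  expect_equal(r_statistic(c(7, 7), c(1e6, 1e6)), 0)   # equal proportions
  expect_equal(r_statistic(c(0, 0), c(1e6, 1e6)), 0)
  expect_error(r_statistic(c(-1, 5), c(1e6, 1e6)), "negative")
  expect_error(r_statistic(5, 1e6), "length")

  set.seed(61)
  for (i in 1:100) {
    m <- sample(2:4, 1)
    x <- stats::rpois(m, lambda = sample(c(2, 10, 40, 200), 1))
    N <- sample(1e4:1e6, m)
    expect_lt(abs(2 * r_statistic(x, N) - numeric_poisson_lrt(x, N)), 1e-8)
  }
})

test_that("p-value calibration is chi-square and bootstrap-consistent", {
  expect_equal(p_from_r(0, 2), 1)
  expect_equal(p_from_r(3.841 / 2, 2), 0.05, tolerance = 1e-3)
  expect_error(p_from_r(1, 2, "bootstrap", x = c(5, 9), N = c(1e5, 1e5),
                        n_boot = 0), "n_boot")

  # large counts: bootstrap agrees with chi2 within Monte-Carlo error
  x <- c(1000, 1100); N <- c(1e6, 1e6)
  R <- r_statistic(x, N)
  p_chi <- p_from_r(R, 2)
  p_boot <- p_from_r(R, 2, "bootstrap", x = x, N = N, n_boot = 1e4, seed = 62)
  se <- sqrt(p_chi * (1 - p_chi) / 1e4)
  expect_lt(abs(p_boot - p_chi), 3 * se + 0.002)
})

test_that("bh_fdr reproduces the exhaustive step-up definition", {
  bh_oracle <- function(p) {          # brute force over the min-over-tails rule
    m <- length(p)
    o <- order(p)
    q_sorted <- vapply(seq_len(m), function(i) {
      min(1, min(p[o][i:m] * m / (i:m)))
    }, numeric(1))
    q <- numeric(m); q[o] <- q_sorted
    q
  }
  expect_equal(bh_fdr(c(0.2, 0.2, 0.2)), c(0.2, 0.2, 0.2))
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)),
               bh_oracle(c(0.01, 0.02, 0.03, 0.04)))
  set.seed(63)
  for (i in 1:20) {
    p <- stats::runif(sample(1:50, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q <= pmin(1, p * length(p))))   # <= Bonferroni
    sh <- sample(length(p))
    expect_equal(bh_fdr(p[sh]), q[sh])              # order invariance
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("fold change follows the published ratio conventions", {
  expect_equal(fold_change(320, 50.6), 6.32411, tolerance = 1e-6)
  expect_equal(round(fold_change(14.5, 3.6), 2), 4.03)
  expect_equal(round(fold_change(0.5, 59.2), 2), 0.01)
  expect_equal(fold_change(23.1, 0), 23.1)
  expect_equal(fold_change(5, 5), 1)
  expect_equal(fold_change(0, 0), 1)
  expect_error(fold_change(-1, 2), ">= 0")
})

test_that("call_de makes no calls when all proportions are identical", {
  cm <- matrix(rep(c(40L, 80L), each = 50), ncol = 2,
               dimnames = list(sprintf("g%02d", 1:50), c("lib1", "lib2")))
  ct <- as_count_table(cm)
  de <- call_de(ct)
  expect_true(all(de$call == "none"))
  expect_true(all(de$R[!is.na(de$R)] < 1e-8))
})

test_that("summary percentages follow the reporting convention", {
  expect_equal(de_percent(4436, 118000), 3.76)
  expect_equal(de_percent(2719, 118000), 2.3)
})

test_that("planted fold-10 genes are recovered with controlled empirical FDR", {
  genes <- sprintf("g%04d", 1:2000)
  design <- de_design(genes, 0.05, 0.05, fold = 10,
                      base_mean = rep(50, 2000), seed = 64)
  cm <- simulate_counts(design, depth = 1e5, seed = 65)
  de <- call_de(as_count_table(cm))
  truth_up <- design$gene_id[design$de_flag == "up"]
  truth_down <- design$gene_id[design$de_flag == "down"]
  called_up <- de$unigene_id[de$call == "up"]
  called_down <- de$unigene_id[de$call == "down"]
  expect_true(all(truth_up %in% called_up))
  expect_true(all(truth_down %in% called_down))
  called <- c(called_up, called_down)
  fdr_hat <- sum(!(called %in% c(truth_up, truth_down))) / max(1, length(called))
  expect_lte(fdr_hat, 0.05)
})

test_that("type-I error is controlled on null simulations", {
  genes <- sprintf("g%04d", 1:2000)
  design <- de_design(genes, 0, 0, seed = 66)
  cm <- simulate_counts(design, depth = 1e5, seed = 67)
  de <- call_de(as_count_table(cm))
  frac <- mean(de$call != "none")
  mc_se <- sqrt(0.01 * 0.99 / nrow(de))
  expect_lte(frac, 0.01 + 3 * mc_se)
})
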