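# Shared fixture builders. Everything is generated in code at test time.

# ESTs tiling each transcript end to end with a fixed overlap, error-free.
tile_ests <- function(tx, len = 250L, step = 120L) {
  rows <- list()
  for (g in names(tx)) {
    L <- nchar(tx[[g]])
    st <- unique(c(seq(1L, max(1L, L - len + 1L), by = step), max(1L, L - len + 1L)))
    for (i in seq_along(st)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        est_id = sprintf("%s_e%02d", g, i),
        sequence = substring(tx[[g]], st[i], min(L, st[i] + len - 1L)),
        origin = g, start = st[i], strand = "+", n_errors = 0L)
    }
  }
  dplyr::bind_rows(rows)
}

# Published RPKM-ratio rows shipped as a plain-text fixture.
published_ratios <- function() {
  path <- system.file("extdata", "published_ratios.tsv", package = "curdseq")
  utils::read.delim(path, colClasses = c("character", "numeric", "numeric",
                                         "character", "integer"))
}

# Decimal places of a printed number given as character.
printed_decimals <- function(x) {
  ifelse(grepl(".", x, fixed = TRUE),
         nchar(sub("^[^.]*[.]", "", x)), 0L)
}

# Independent numeric Poisson likelihood-ratio oracle: maximizes the
# per-library and pooled log-likelihoods by 1-d numeric optimization
# (no closed-form MLE used), returning the LRT statistic 2*(l1 - l0).
numeric_poisson_lrt <- function(x, N) {
  term <- function(lam, xx, nn) xx * log(lam * nn) - lam * nn
  l1 <- sum(mapply(function(xx, nn) {
    if (xx == 0) return(0)  # supremum as lambda -> 0
    stats::optimize(function(l) term(exp(l), xx, nn),
                    interval = log(c(xx / nn / 20, xx / nn * 20)),
                    maximum = TRUE, tol = 1e-12)$objective
  }, x, N))
  if (sum(x) == 0) return(0)
  f0 <- sum(x) / sum(N)
  l0 <- stats::optimize(function(l) sum(term(exp(l), x, N)),
                        interval = log(c(f0 / 20, f0 * 20)),
                        maximum = TRUE, tol = 1e-12)$objective
  2 * (l1 - l0)
}
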