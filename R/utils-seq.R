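# Internal sequence helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' @importFrom Biostrings DNAStringSet reverseComplement
#' @importFrom data.table data.table := .N setkey setkeyv rbindlist
NULL

# Reverse-complement a character vector of DNA strings.
revcomp_chr <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between two equal-length DNA strings; any position
# involving a non-ACGT base (e.g. N) counts as a mismatch.
hamming_chr <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  acgt <- charToRaw("ACGT")
  sum(ra != rb | !(ra %in% acgt))
}

# Draw a random DNA string vector with a target GC fraction.
random_dna <- function(n, len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len[[min(i, length(len))]], replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
}

# Apply substitution errors at a fixed per-base rate; never substitutes a
# base for itself. Returns list(seq, n_errors).
mutate_seqs <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0L) {
    return(list(seq = seqs, n_errors = integer(length(seqs))))
  }
  n_err <- integer(length(seqs))
  out <- seqs
  for (i in seq_along(seqs)) {
    s <- out[[i]]
    L <- nchar(s)
    hit <- which(stats::runif(L) < error_rate)
    if (length(hit)) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      for (j in hit) {
        ch[j] <- sample(setdiff(DNA_BASES, ch[j]), 1L)
      }
      out[[i]] <- paste(ch, collapse = "")
      n_err[i] <- length(hit)
    }
  }
  list(seq = out, n_errors = n_err)
}

# Deterministic per-stage child seeds derived from one master seed.
# Keeps results reproducible while decoupling the stages' RNG streams.
child_seed <- function(seed, stage) {
  offsets <- c(transcriptome = 101L, contaminants = 211L, ests = 307L,
               libraries = 401L, lib2 = 409L, qc = 503L, assembly = 601L,
               counting = 701L, de = 809L, overlap = 907L, misc = 997L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 48271 + off) %% 2147483647)
}

# Validate a DNA/IUPAC character argument.
assert_dna <- function(x, what = "sequence", iupac = FALSE) {
  pat <- if (iupac) "^[ACGTUWSMKRYBDHVNacgtuwsmkrybdhvn]*$" else "^[ACGTN]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains non-IUPAC characters: %s", what,
                 paste(utils::head(x[bad], 3), collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# Extract all substrings of width w from one string (1-based starts).
kmers_of <- function(s, w) {
  L <- nchar(s)
  if (L < w) return(character(0))
  starts <- seq_len(L - w + 1L)
  substring(s, starts, starts + w - 1L)
}
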