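---
title: "Methods: reference-free differential expression for cauliflower curds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-free differential expression for cauliflower curds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curdseq)
```

## The problem

The green-curd cauliflower mutant develops chloroplasts in tissue that is
normally white, and the transcriptional basis of that switch is studied by
comparing gene expression between green and white curds from one RNA-seq
library per condition. Cauliflower has no reference genome, so the
expression reference must be assembled from the data itself: public Sanger
ESTs are cleaned and assembled into unigenes, short reads are aligned to
those EST-unigenes, the reads that fail to align are assembled de novo, and
the two unigene sets are merged. Counts per unigene per library then feed a
digital-expression test. `curdseq` implements this workflow end to end, and
pairs it with a synthetic-data generator whose ground truth makes every
stage testable.

## Statistical model

Counts for one unigene across `m` sequencing libraries are modelled as
independent Poisson draws, `x_i ~ Poisson(N_i * lambda_i)`, where `N_i` is
the library total. The null hypothesis of no differential expression is a
shared proportion `lambda_1 = ... = lambda_m = f`, with pooled estimate
`f = sum(x) / sum(N)`. The log-likelihood-ratio statistic reduces to

    R = sum over {i : x_i > 0} of  x_i * ln( x_i / (N_i * f) )

(the linear terms cancel because the pooled MLE matches the total), and
`2R` is asymptotically chi-square with `m - 1` degrees of freedom. The test
suite verifies `2R` against an independent numeric likelihood maximization
(two 1-d optimizations, no closed form) to `1e-8` on random small cases.

Two p-value calibrations are provided, because the choice is genuinely open
for very low counts:

* `chi2` (default): upper tail of `chisq(m - 1)` at `2R`; asymptotically
  exact under the Poisson model and instantaneous.
* `bootstrap`: Poisson resampling under the pooled rate,
  `p = (1 + #{R* >= R}) / (n_boot + 1)`; preferable when counts are a
  handful, at the cost of resolution `1/(n_boot + 1)`.

P-values are adjusted by Benjamini–Hochberg over the batch of unigenes with
nonzero total count (all-zero unigenes are excluded from testing and from
the batch; they carry `NA` statistics). A unigene is called up when
`q <= 0.01` and its RPKM fold change (test/reference, i.e. green/white) is
at least 3, down when `q <= 0.01` and the fold is at most 1/3. When the
reference RPKM is 0 and the test RPKM positive, the reported ratio equals
the test RPKM — a unit-denominator convention that matches how published
RPKM-ratio tables print such rows — and two zeros give ratio 1.

## Assembly operators

The assembly stages reproduce the *contracts* of the field's tools rather
than the tools themselves, which the original workflow uses as black boxes:

* **EST assembly and meta-assembly** are greedy overlap-layout-consensus:
  repeatedly merge the pair of active sequences with the highest-scoring
  suffix-prefix overlap (score = matching bases; at least `min_overlap`
  bases at `min_identity` or better, either strand), absorbing containments,
  until no qualifying overlap remains. Consensus is a per-column majority
  vote over the laid-out member fragments; ties prefer the alphabetically
  first base, and tied overlap scores break lexicographically by id, so
  assembly is deterministic. Overlap candidates are found by an exact 16-mer
  seed at the junction and verified by direct comparison, so an overlap
  whose junction-end 16-mer is corrupted by an error can be missed; at the
  error rates the generator emulates (<= 1–2%) this is rare, and irrelevant
  for error-free fixtures.
* **Read alignment** is full-length Hamming matching with a bounded
  mismatch budget (default 2, the budget the original workflow gives its
  aligner), found by pigeonhole seeding: a read with at most `k`
  substitutions must contain one of `k + 1` exact seed segments, every seed
  hit is verified by recomputation, and the best placement (fewest
  mismatches) is reported with its tie count. The same matcher drives the
  rRNA screen, where a read is removed only on a full-length match within
  the budget; `N` bases count as mismatches.
* **De novo assembly** builds a de Bruijn graph on canonical k-mers
  (default `k = 31`), drops k-mers below a coverage cutoff (singletons are
  dropped when mean k-mer coverage is at least 10 — the cutoff a 30x
  experiment warrants — otherwise everything is kept), clips short dead-end
  tips (< 2k bases) once, and emits maximal unbranched paths of at least
  `min_contig_len`. Contigs are reported in canonical orientation.

Defaults the original workflow does not state are ours and configurable:
`min_overlap = 40` bp and `min_identity = 0.97` for the overlap assembler
(a Sanger-EST-appropriate stringency), `k = 31` for the de Bruijn graph
(well under the 86 bp read length, specific at transcriptome scale).
Final unigenes are renumbered `PP000001...` in decreasing length order with
ties broken by sequence, making identifiers a pure function of the set.

## Quantification

Each read contributes at most one count to exactly one unigene. The default
`discard-ties` policy drops reads with two or more equally-best placements
(conservative, deterministic); `best-unique` assigns them uniformly at
random among their best placements under a seed. Library sizes are the
per-library totals of *assigned* reads — a mapped-read denominator, which
is what "per million mapped reads" implies — and
`rpkm = count * 1e9 / (library_size * length)`.

## What the generator emulates, and what it does not

`simulate_libraries` emits two libraries of 86-bp reads (the platform's
read length in the study this models). Reads are allocated to transcripts
multinomially with probabilities proportional to the design means, so
per-gene counts are Poisson conditioned on the library total; this respects
both the Poisson count model and exact per-library depths. Positions are
uniform over valid starts, strands 50/50 (the protocol is unstranded),
substitution errors land at a flat per-base rate, an `rrna_fraction` share
of reads originates from rRNA records, and an `adaptor_rate` share carries
3' adaptor read-through of 10–40 bases. Qualities are constant high
(phred 37) except a configurable low-quality 3' tail, so quality trimming
is exercised. A truth ledger records per-gene means, true folds and flags,
and per-read origin coordinates.

Deliberately not emulated: indel errors, paired ends, position- or
quality-dependent error profiles, fragment-length biases, and
overdispersion beyond Poisson (a negative-binomial option was considered
and left out: the single-library design this models cannot estimate
dispersion anyway, and the Poisson assumption is exactly what the R
statistic tests). Passing tests on this generator therefore validate the
pipeline's logic and its statistical calibration under the stated model —
not robustness to real-data pathologies such as overdispersion or biased
coverage.

One consequence of proportion-based testing is worth stating: planting a
large mass of one-directional fold change (say 10% of genes up at fold 10)
inflates the second library's total by ~1.9x, which shifts every null
gene's apparent fold to ~0.53 and lets noise push some past the 1/3
boundary — spurious down-calls that are a genuine property of
single-library RPKM comparisons, not a bug. The generator's planted-DE
study condition is therefore a balanced design (5% up + 5% down at fold 10,
reference mean count 50 at a depth of 1e5), under which recovery is
complete and the empirical FDR stays within its margin; the asymmetric
variant is still exercised where only the up-call fraction is at stake.

## Numerical and degenerate-input choices

* `R` is clamped at 0 against round-off; `sum(x) = 0` gives `R = 0`, `p = 1`.
* Zero library sizes are an error if counts are nonzero, else RPKM is 0.
* Chlorophyll readings implying a negative concentration (e.g. OD663 with
  no OD645) are flagged invalid rather than truncated; the inversion used
  by the generator solves the 2x2 MacKinney system exactly and refuses
  infeasible targets. The per-fresh-weight scale factor is
  `volume_ml / mass_g` (x20 at the default 1 mL per 50 mg geometry),
  applied explicitly.
* The e-value-like quantity in homolog mapping is Karlin–Altschul scaling
  with generic ungapped constants (`K = 0.46`, `lambda = 1.28` for the
  +1/−2 scoring used); it is documented as approximate — only the
  thresholds matter, and the tests assert mapping behaviour, not e-values.
* Genes labelled `both` in a target catalogue count in both the light and
  dark intersections; all four up/down x light/dark intersections are
  reported explicitly.

## Problem sizes

The shipped configurations are desk-scale by design: default pipeline runs
use ~50 genes, 200 ESTs and 5,000 reads per library; statistical
calibration runs use 2,000 genes at a depth of 1e5 counts per library; the
assembly round-trip studies use 50 transcripts with ~30x read coverage.
These sizes keep full runs in seconds to a couple of minutes while leaving
every estimate's Monte-Carlo error far below the margins being tested.
Full-scale figures from the motivating study (118,000 unigenes, 15 million
reads per lane) are outside the intended envelope of the pure-R assemblers.

## Known limitations

* The greedy assembler can misassemble repeats that a graph-based assembler
  would split; transcript fixtures here are repeat-free by construction.
* De novo contigs lose a few bases at transcript ends where terminal k-mer
  coverage falls below the cutoff (~95–99% length recovery at 30x).
* The trimming rule is a simple 3' scan (the original workflow's in-house
  criterion is unstated); adaptor clipping requires the seed region of the
  adaptor to be intact.
* Homolog mapping is one-directional best-hit, mirroring "top hit" tables,
  not reciprocal-best orthology.
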