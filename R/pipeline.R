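# End-to-end orchestration of the reference-free comparative pipeline in
# the analysis order: read QC -> rRNA screen -> EST screen/assembly -> read
# alignment -> de novo assembly of unaligned reads -> meta-assembly ->
# counting/RPKM -> R-statistic DE calling -> (optional) target overlap.

#' Default pipeline configuration
#'
#' A nested list holding every stage parameter with its default; the
#' shipped defaults describe a desk-scale synthetic experiment (two
#' libraries of 86 bp reads over a few hundred genes) with the analysis
#' thresholds used throughout the package (two-mismatch alignment budget,
#' FDR 0.01, fold-change 3).
#'
#' @param seed Master seed; each stage derives a deterministic child seed.
#' @return A `run_config` list, serializable to YAML and back unchanged.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    simulate = list(
      n_genes = 50L, len_min = 300L, len_max = 800L, gc = 0.42,
      n_ests = 200L, est_len_mean = 350L, est_error_rate = 0,
      n_rrna = 2L, n_vector = 2L, n_bacterial = 2L, contaminant_len = 1500L,
      depth = 5000L, read_len = 86L, error_rate = 0,
      rrna_fraction = 0.05, adaptor = "AGATCGGAAGAGC", adaptor_rate = 0.05,
      lowq_tail = 3L,
      fraction_up = 0.05, fraction_down = 0.05, fold = 10),
    qc = list(quality_min = 20L, min_len = 30L, max_mismatch = 2L,
              seed_len = 10L),
    assembly = list(min_overlap = 40L, min_identity = 0.97, kmer = 31L,
                    max_mismatch = 2L, min_contig_len = 100L,
                    min_est_len = 100L),
    quant = list(policy = "discard-ties"),
    de = list(fdr_max = 0.01, min_fold = 3, p_method = "chi2"),
    outdir = NULL),
    class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Checks every stage parameter against its documented constraint and
#' returns one finding per violation; an empty result means the
#' configuration is runnable.
#'
#' @param config A `run_config` list.
#' @return A tibble (`path`, `message`); zero rows iff valid.
#' @export
validate_config <- function(config) {
  f <- list()
  note <- function(path, message) {
    f[[length(f) + 1L]] <<- tibble::tibble(path = path, message = message)
  }
  chk <- function(cond, path, message) if (!isTRUE(cond)) note(path, message)
  s <- config$simulate; q <- config$qc; a <- config$assembly; d <- config$de
  chk(is.numeric(config$seed) && length(config$seed) == 1L, "seed",
      "seed must be a single number")
  if (!is.null(s)) {
    chk(s$n_genes >= 0, "simulate.n_genes", "must be >= 0")
    chk(s$len_min > 0 && s$len_min <= s$len_max, "simulate.len_min",
        "need 0 < len_min <= len_max")
    chk(s$gc >= 0 && s$gc <= 1, "simulate.gc", "must be in [0, 1]")
    chk(s$depth >= 0, "simulate.depth", "must be >= 0")
    chk(s$rrna_fraction >= 0 && s$rrna_fraction <= 1,
        "simulate.rrna_fraction", "must be in [0, 1]")
    chk(s$adaptor_rate >= 0 && s$adaptor_rate <= 1,
        "simulate.adaptor_rate", "must be in [0, 1]")
    chk(s$error_rate >= 0 && s$error_rate < 1, "simulate.error_rate",
        "must be in [0, 1)")
    chk(s$fraction_up + s$fraction_down <= 1, "simulate.fraction_up",
        "fraction_up + fraction_down must be <= 1")
    chk(grepl("^[ACGTUWSMKRYBDHVN]*$", s$adaptor), "simulate.adaptor",
        "adaptor must be IUPAC DNA")
    chk(a$kmer < s$read_len, "assembly.kmer",
        "k-mer size must be smaller than the read length")
  }
  chk(q$quality_min >= 0, "qc.quality_min", "must be >= 0")
  chk(q$min_len >= 1, "qc.min_len", "must be >= 1")
  chk(q$max_mismatch >= 0, "qc.max_mismatch", "must be >= 0")
  chk(a$min_overlap >= 10, "assembly.min_overlap", "must be >= 10")
  chk(a$min_identity >= 0.9 && a$min_identity <= 1, "assembly.min_identity",
      "must be in [0.9, 1]")
  chk(a$kmer >= 15, "assembly.kmer", "must be >= 15")
  chk(config$quant$policy %in% c("discard-ties", "best-unique"),
      "quant.policy", "unknown counting policy")
  chk(d$fdr_max > 0 && d$fdr_max <= 1, "de.fdr_max", "must be in (0, 1]")
  chk(d$min_fold >= 1, "de.min_fold", "must be >= 1")
  chk(d$p_method %in% c("chi2", "bootstrap"), "de.p_method",
      "must be chi2 or bootstrap")
  if (length(f) == 0L) {
    return(tibble::tibble(path = character(), message = character()))
  }
  dplyr::bind_rows(f)
}

#' Save / load a configuration as YAML
#' @param config A `run_config`.
#' @param path YAML file.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- utils::modifyList(unclass(default_config()), cfg)
  if (!("outdir" %in% names(out))) out["outdir"] <- list(NULL)
  structure(out, class = "run_config")
}

#' Run the full pipeline on synthetic data
#'
#' Generates a synthetic experiment from `config$simulate`, then executes
#' every stage in the analysis order and returns a run report. Stage
#' outputs are pure functions of the configuration and seed, so repeated
#' runs are identical. When `config$outdir` is set, per-stage artifacts
#' (FASTA/FASTQ/TSV) are written there.
#'
#' @param config A `run_config` (see [default_config()]).
#' @param targets Optional target catalogue tibble (`reference_id`,
#'   `condition`) together with `reference` sequences for the overlap
#'   stage; both NULL skips it.
#' @param reference Optional named character vector of reference gene
#'   sequences for homolog mapping.
#' @return A list of class `run_report`: `config`, `stages` (per-stage
#'   counts), `unigenes` (n, mean/max length, provenance table), `de`
#'   (summary with percentages), `de_table`, `truth`, `unigene_set`,
#'   and optionally `overlap`.
#' @export
run_all <- function(config = default_config(), targets = NULL,
                    reference = NULL) {
  findings <- validate_config(config)
  if (nrow(findings) > 0L) {
    stop("invalid configuration: ",
         paste(findings$path, findings$message, sep = ": ", collapse = "; "),
         call. = FALSE)
  }
  s <- config$simulate; qc <- config$qc; asm <- config$assembly
  seed <- config$seed
  stages <- list()

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # --- simulate ------------------------------------------------------------
  sim <- run_stage("simulate", {
    tx <- generate_transcriptome(s$n_genes, s$len_min, s$len_max, s$gc,
                                 seed = child_seed(seed, "transcriptome"))
    cont <- generate_contaminants(s$n_rrna, s$n_vector, s$n_bacterial,
                                  s$contaminant_len,
                                  seed = child_seed(seed, "contaminants"))
    ests <- simulate_ests(tx, s$n_ests, s$est_len_mean, s$est_error_rate,
                          seed = child_seed(seed, "ests"))
    design <- de_design(names(tx), s$fraction_up, s$fraction_down, s$fold,
                        seed = child_seed(seed, "misc"))
    libs <- simulate_libraries(tx, design, s$depth, s$read_len, s$error_rate,
                               cont$rrna, s$rrna_fraction, s$adaptor,
                               s$adaptor_rate, s$lowq_tail, seed = seed)
    list(tx = tx, cont = cont, ests = ests, design = design, libs = libs)
  })
  stages$simulate <- list(n_genes = length(sim$tx), n_ests = nrow(sim$ests),
                          n_reads = nrow(sim$libs$reads))

  # --- read QC -------------------------------------------------------------
  qcres <- run_stage("qc", {
    trimmed <- trim_reads(sim$libs$reads, qc$quality_min, s$adaptor,
                          qc$min_len, qc$seed_len)
    scr <- screen_rrna(trimmed, sim$cont$rrna, qc$max_mismatch)
    list(trimmed = trimmed, kept = scr$kept, removed = scr$removed,
         report = scr$report)
  })
  stages$qc <- list(n_in = nrow(sim$libs$reads),
                    n_after_trim = nrow(qcres$trimmed),
                    n_rrna_removed = nrow(qcres$removed),
                    n_clean = nrow(qcres$kept))

  # --- EST screen and assembly --------------------------------------------
  est_ug <- run_stage("est_assembly", {
    clean <- screen_ests(sim$ests, sim$cont$vector, sim$cont$bacterial,
                         sim$cont$rrna, asm$min_est_len)
    assemble_ests(clean, asm$min_overlap, asm$min_identity)
  })
  stages$est_assembly <- list(n_est_unigenes = nrow(est_ug))

  # --- read alignment to EST-unigenes -------------------------------------
  aln <- run_stage("align", {
    align_reads(qcres$kept, est_ug, asm$max_mismatch)
  })
  stages$align <- list(n_aligned = nrow(aln$hits),
                       n_unaligned = nrow(aln$unaligned))

  # --- de novo assembly of unaligned reads --------------------------------
  dn_ug <- run_stage("denovo", {
    denovo_assemble(aln$unaligned, asm$kmer, asm$min_contig_len)
  })
  stages$denovo <- list(n_denovo_unigenes = nrow(dn_ug))

  # --- meta-assembly -------------------------------------------------------
  merged <- run_stage("merge", {
    merge_assemblies(est_ug, dn_ug, asm$min_overlap, asm$min_identity)
  })
  unigenes <- merged$unigenes
  stages$merge <- list(n_unigenes = nrow(unigenes))

  # --- quantification ------------------------------------------------------
  quant <- run_stage("quantify", {
    if (nrow(unigenes) == 0L || nrow(qcres$kept) == 0L) {
      NULL
    } else {
      aln2 <- align_reads(qcres$kept, unigenes, asm$max_mismatch,
                          keep_ties = config$quant$policy == "best-unique")
      ct <- count_reads(aln2$hits, unigenes, config$quant$policy,
                        libraries = c("lib1", "lib2"),
                        seed = child_seed(seed, "counting"))
      list(ct = ct, rpkm = compute_rpkm(ct))
    }
  })
  stages$quantify <- if (is.null(quant)) list(n_assigned = 0L) else
    list(n_assigned = sum(quant$ct$counts))

  # --- differential expression ---------------------------------------------
  de <- run_stage("detest", {
    if (is.null(quant)) NULL else {
      call_de(quant$ct, config$de$fdr_max, config$de$min_fold,
              p_method = config$de$p_method, seed = child_seed(seed, "de"))
    }
  })
  de_summary <- if (is.null(de)) {
    list(n_total = 0L, n_tested = 0L, n_up = 0L, n_down = 0L,
         pct_up = NA_real_, pct_down = NA_real_)
  } else attr(de, "summary")
  stages$detest <- de_summary[c("n_tested", "n_up", "n_down")]

  # --- optional target overlap ---------------------------------------------
  overlap <- NULL
  if (!is.null(targets) && !is.null(reference) && !is.null(de)) {
    overlap <- run_stage("overlap", {
      hm <- map_homologs(unigenes, reference)
      venn_counts(de$unigene_id[de$call == "up"],
                  de$unigene_id[de$call == "down"],
                  hm, targets, universe = unigenes$unigene_id)
    })
  }

  report <- structure(list(
    config = config,
    stages = stages,
    unigenes = list(
      n = nrow(unigenes),
      mean_length = if (nrow(unigenes)) round(mean(unigenes$length), 1) else NA,
      max_length = if (nrow(unigenes)) max(unigenes$length) else NA,
      provenance = if (nrow(unigenes)) table(unigenes$provenance) else table(character())),
    de = de_summary,
    de_table = de,
    truth = sim$libs$truth,
    unigene_set = unigenes,
    id_map = merged$id_map,
    overlap = overlap), class = "run_report")

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$outdir, f)
    write_fasta(sim$tx, p("transcripts.fasta"))
    write_fastq(sim$libs$reads[sim$libs$reads$library == "lib1", ], p("lib1.fastq"))
    write_fastq(sim$libs$reads[sim$libs$reads$library == "lib2", ], p("lib2.fastq"))
    if (nrow(unigenes)) {
      write_fasta(stats::setNames(unigenes$sequence, unigenes$unigene_id),
                  p("unigenes.fasta"))
    }
    write_truth_tsv(sim$libs$truth, p("truth_genes.tsv"), p("truth_reads.tsv"))
    if (!is.null(de)) write_de_tsv(de, p("de_results.tsv"))
    write_report_tsv(report, p("report.tsv"))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Reference-free RNA-seq run report\n")
  cat(sprintf("  unigenes: %d (mean length %.1f bp)\n",
              x$unigenes$n, x$unigenes$mean_length))
  cat(sprintf("  DE calls: %d up (%.2f%%), %d down (%.2f%%) of %d unigenes\n",
              x$de$n_up, x$de$pct_up, x$de$n_down, x$de$pct_down,
              x$de$n_total))
  if (!is.null(x$overlap)) {
    cat(sprintf("  target overlap: %d up + %d down = %d\n",
                x$overlap$n_up_target, x$overlap$n_down_target,
                x$overlap$n_total))
  }
  invisible(x)
}

#' Write the run report's key counts as TSV
#' @param report A `run_report`.
#' @param path Output file.
#' @export
write_report_tsv <- function(report, path) {
  rows <- list(
    c("n_unigenes", report$unigenes$n),
    c("mean_unigene_length", report$unigenes$mean_length),
    c("n_tested", report$de$n_tested),
    c("n_up", report$de$n_up),
    c("n_down", report$de$n_down),
    c("pct_up", report$de$pct_up),
    c("pct_down", report$de$pct_down))
  for (st in names(report$stages)) {
    for (k in names(report$stages[[st]])) {
      rows[[length(rows) + 1L]] <- c(paste(st, k, sep = "."),
                                     report$stages[[st]][[k]])
    }
  }
  df <- data.frame(key = vapply(rows, `[[`, character(1), 1L),
                   value = vapply(rows, function(r) as.character(r[[2]]),
                                  character(1)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
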